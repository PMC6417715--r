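#' Canonical site label for a set of helices
#'
#' A lipid's site in one frame is the set of helices it touches, written
#' as the ascending concatenation of the helix digits: helices
#' \{1, 6, 7\} give `"167"` regardless of input order. Idempotent.
#'
#' @param helix_set Integer helix ids (1-8), in any order, or an
#'   existing label string.
#' @return Canonical label string, or `NA` for an empty set.
#' @export
#' @examples
#' site_label(c(7, 6, 1))  # "167"
site_label <- function(helix_set) {
  if (is.character(helix_set)) helix_set <- parse_site_label(helix_set)
  h <- sort(unique(as.integer(helix_set)))
  if (!length(h)) return(NA_character_)
  if (any(h < 1 | h > 9)) stop("helix ids must be in 1..9")
  paste(h, collapse = "")
}

#' @rdname site_label
#' @param label A canonical label string such as `"167"`.
#' @export
parse_site_label <- function(label)
  as.integer(strsplit(label, "")[[1]])

mask_to_label <- function(mask, labels_cache) {
  # mask: integer bitmask, bit h-1 set when helix h is contacted
  labels_cache[mask + 1L]
}

build_label_cache <- function(max_helix = 8) {
  n <- bitwShiftL(1L, max_helix)
  vapply(0:(n - 1), function(m) {
    h <- which(bitwAnd(m, bitwShiftL(1L, 0:(max_helix - 1))) != 0)
    if (!length(h)) NA_character_ else paste(h, collapse = "")
  }, character(1))
}

#' Retain lipids by interaction occupancy
#'
#' A lipid is retained when it is in contact with the protein in at
#' least `threshold` of the frames (inclusive boundary: a lipid touching
#' in exactly 20% of frames is retained at the default threshold).
#'
#' @param events Logical (frames x lipids) any-contact matrix, e.g.
#'   `accumulate_contacts(...)$events`.
#' @param threshold Occupancy fraction in (0, 1\] (default 0.20).
#' @return Character/integer vector of retained lipid ids (the column
#'   names of `events`, or column indices when unnamed).
#' @export
occupancy_filter <- function(events, threshold = 0.20) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (nrow(events) == 0) stop("zero-frame trajectory")
  keep <- colMeans(events) >= threshold
  ids <- colnames(events)
  if (is.null(ids)) ids <- seq_len(ncol(events))
  ids[keep]
}

#' Per-frame site labels for every lipid
#'
#' For each frame and lipid, the set of helices with any bead of the
#' lipid within the cutoff of any bead of a residue belonging to that
#' helix; residues outside all helix ranges (loops, termini) contribute
#' nothing. `NA` marks frames where the lipid touches no helix.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param helices A `helix_map`.
#' @param cutoff Distance criterion in nm (default 0.5).
#' @return List with `labels` (frames x lipids character matrix of
#'   canonical site labels or `NA`) and `events` (frames x lipids
#'   logical any-protein-contact matrix).
#' @export
frame_sites <- function(traj, system, helices = default_helix_map(),
                        cutoff = 0.5) {
  tab <- accumulate_contacts(traj, system, cutoff = cutoff,
                             helices = helices)
  cache <- build_label_cache(max(helices$helix_id))
  lab <- matrix(mask_to_label(tab$sites, cache), nrow = nrow(tab$sites),
                dimnames = dimnames(tab$sites))
  list(labels = lab, events = tab$events)
}

#' Collapse a per-frame site sequence into a lipid path
#'
#' Drops no-site frames (`NA`), then merges runs of identical labels
#' into a single occurrence, so the path records movements from one
#' visited site to the next. A gap (frames with no helix contact)
#' neither emits a site nor breaks a run. Idempotent.
#'
#' @param site_sequence Character vector of site labels with `NA` gaps.
#' @return Character vector of collapsed site labels (possibly empty).
#' @export
#' @examples
#' collapse_path(c("1", "1", "16", "16", "16", "6", "1"))
#' collapse_path(c("5", NA, "5"))  # "5": the gap does not break the run
collapse_path <- function(site_sequence) {
  x <- site_sequence[!is.na(site_sequence) & site_sequence != ""]
  if (!length(x)) return(character(0))
  rle(x)$values
}

#' Build lipid paths from per-frame site labels
#'
#' Applies the occupancy filter, collapses each retained lipid's label
#' sequence and tags it with its leaflet. Lipids whose collapsed path is
#' empty (never within the cutoff of any helix) are excluded with a
#' message.
#'
#' @param sites Output of [frame_sites()].
#' @param leaflets A [assign_leaflets()] result.
#' @param threshold Occupancy threshold (default 0.20).
#' @return A `lipid_paths` data frame with columns `lipid_id`,
#'   `leaflet` and list-column `path`.
#' @export
lipid_paths <- function(sites, leaflets, threshold = 0.20) {
  keep <- occupancy_filter(sites$events, threshold)
  paths <- lapply(keep, function(id) collapse_path(sites$labels[, id]))
  len <- lengths(paths)
  if (any(len == 0))
    message(sum(len == 0), " retained lipid(s) never contacted a helix; ",
            "excluded from paths")
  keep <- keep[len > 0]; paths <- paths[len > 0]
  lf <- leaflets$leaflet[match(as.integer(keep), leaflets$lipid_id)]
  out <- data.frame(lipid_id = as.integer(keep), leaflet = lf,
                    stringsAsFactors = FALSE)
  out$path <- paths
  class(out) <- c("lipid_paths", "data.frame")
  out
}

#' Build a site-transition network from lipid paths
#'
#' Nodes are site labels weighted by the number of path entries carrying
#' that label; edges connect consecutive path entries, with counts. By
#' default edges are undirected (transition counts are symmetrised by
#' canonical node order); `directed = TRUE` preserves the direction of
#' travel. Conservation holds exactly: the edge counts sum to
#' sum(path length - 1) and the node weights to sum(path length).
#'
#' @param paths A [lipid_paths()] data frame (or any data frame with a
#'   `path` list-column), already restricted to one leaflet, or a plain
#'   list of character paths.
#' @param leaflet Leaflet tag stored on the network.
#' @param directed Preserve transition direction? Default `FALSE`.
#' @return A `site_network`: list with `nodes` (label, weight),
#'   `edges` (from, to, count), `leaflet`, `directed`, `clusters`
#'   (NULL until [cluster_network()]), `modularity`.
#' @export
build_network <- function(paths, leaflet = NA_character_,
                          directed = FALSE) {
  plist <- if (is.data.frame(paths)) paths$path else paths
  plist <- plist[lengths(plist) > 0]
  if (!length(plist)) {
    net <- list(nodes = data.frame(label = character(0), weight = numeric(0),
                                   stringsAsFactors = FALSE),
                edges = data.frame(from = character(0), to = character(0),
                                   count = numeric(0),
                                   stringsAsFactors = FALSE),
                leaflet = leaflet, directed = directed,
                clusters = NULL, modularity = NA_real_)
    class(net) <- "site_network"
    return(net)
  }
  entries <- unlist(plist)
  wt <- table(entries)
  nodes <- data.frame(label = names(wt), weight = as.numeric(wt),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$label), , drop = FALSE]
  rownames(nodes) <- NULL
  from <- unlist(lapply(plist, function(p) p[-length(p)]))
  to <- unlist(lapply(plist, function(p) p[-1]))
  if (length(from)) {
    if (!directed) {
      swap <- from > to
      tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    }
    et <- table(paste(from, to, sep = "->"))
    ft <- strsplit(names(et), "->", fixed = TRUE)
    edges <- data.frame(from = vapply(ft, `[`, "", 1),
                        to = vapply(ft, `[`, "", 2),
                        count = as.numeric(et), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        count = numeric(0), stringsAsFactors = FALSE)
  }
  net <- list(nodes = nodes, edges = edges, leaflet = leaflet,
              directed = directed, clusters = NULL,
              modularity = NA_real_)
  class(net) <- "site_network"
  net
}

#' @export
print.site_network <- function(x, ...) {
  cat("Site-transition network (", if (is.na(x$leaflet)) "unspecified"
      else x$leaflet, " leaflet): ", nrow(x$nodes), " sites, ",
      nrow(x$edges), if (x$directed) " directed" else " undirected",
      " transitions\n", sep = "")
  if (nrow(x$nodes)) {
    top <- x$nodes[order(-x$nodes$weight), ][seq_len(min(5, nrow(x$nodes))), ]
    cat("  top sites:", paste(sprintf("%s (%g)", top$label, top$weight),
                              collapse = ", "), "\n")
  }
  if (!is.null(x$clusters))
    cat(sprintf("  %d communities, modularity %.3f\n",
                length(unique(x$clusters)), x$modularity))
  invisible(x)
}

site_network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = net$directed,
                                     vertices = net$nodes)
  g
}

#' Cluster a site network with the Louvain method
#'
#' Runs Louvain community detection on the transition-count-weighted
#' graph at the given resolution. The node order is fixed by canonical
#' label sort and the RNG is seeded, so the assignment is deterministic.
#'
#' @param net A [build_network()] result.
#' @param resolution Louvain resolution parameter (default 0.8).
#' @param seed RNG seed (default 0).
#' @return The network with `clusters` (named membership vector) and
#'   `modularity` filled in. A single-node network gets one cluster and
#'   modularity 0.
#' @export
cluster_network <- function(net, resolution = 0.8, seed = 0) {
  if (!nrow(net$nodes)) stop("cannot cluster an empty network")
  if (nrow(net$nodes) == 1 || !nrow(net$edges)) {
    net$clusters <- setNames(seq_len(nrow(net$nodes)), net$nodes$label)
    net$modularity <- 0
    return(net)
  }
  g <- site_network_igraph(net)
  if (net$directed) g <- igraph::as_undirected(g, mode = "collapse",
                                               edge.attr.comb = "sum")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$count,
                                resolution = resolution)
  mem <- igraph::membership(cl)
  net$clusters <- setNames(as.integer(mem), names(mem))[net$nodes$label]
  net$modularity <- igraph::modularity(g, mem,
                                       weights = igraph::E(g)$count)
  net
}

#' Leaflet-separated site-transition networks for a trajectory
#'
#' Full pipeline of the lipid-path method: occupancy filter, per-frame
#' helix-set labels, run-collapse into paths, separation by leaflet,
#' network construction and Louvain clustering.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param helices A `helix_map`.
#' @param leaflets A [assign_leaflets()] result (computed from frame 1
#'   when `NULL`).
#' @param cutoff Contact criterion, nm (default 0.5).
#' @param threshold Occupancy fraction (default 0.20).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed for clustering (default 0).
#' @param directed Preserve transition direction? Default `FALSE`.
#' @return Named list of clustered `site_network`s, one per leaflet
#'   (`external`, `internal`), plus the `paths` data frame, as class
#'   `site_network_set`.
#' @export
site_transition_network <- function(traj, system,
                                    helices = default_helix_map(),
                                    leaflets = NULL, cutoff = 0.5,
                                    threshold = 0.20, resolution = 0.8,
                                    seed = 0, directed = FALSE) {
  if (is.null(leaflets)) leaflets <- assign_leaflets(system, traj)
  fs <- frame_sites(traj, system, helices, cutoff)
  paths <- lipid_paths(fs, leaflets, threshold)
  nets <- lapply(c(external = "external", internal = "internal"),
                 function(lf) {
    net <- build_network(paths[paths$leaflet == lf, , drop = FALSE],
                         leaflet = lf, directed = directed)
    if (nrow(net$nodes)) net <- cluster_network(net, resolution, seed)
    net
  })
  structure(c(nets, list(paths = paths)), class = "site_network_set")
}

#' @export
print.site_network_set <- function(x, ...) {
  print(x$external); print(x$internal)
  invisible(x)
}

#' Export a site network to GEXF (Gephi) format
#'
#' Nodes carry `weight` and `cluster` attributes, edges carry `count`.
#'
#' @param net A `site_network` (clustered or not).
#' @param path Output `.gexf` path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path) {
  cl <- net$clusters
  if (is.null(cl)) cl <- setNames(rep(NA_integer_, nrow(net$nodes)),
                                  net$nodes$label)
  nodes <- sprintf(paste0(
    '      <node id="%s" label="%s">\n',
    '        <attvalues><attvalue for="weight" value="%g"/>',
    '<attvalue for="cluster" value="%s"/></attvalues>\n',
    '      </node>'),
    net$nodes$label, net$nodes$label, net$nodes$weight,
    ifelse(is.na(cl[net$nodes$label]), "", cl[net$nodes$label]))
  edges <- if (nrow(net$edges)) sprintf(paste0(
    '      <edge id="%d" source="%s" target="%s" weight="%g">\n',
    '        <attvalues><attvalue for="count" value="%g"/></attvalues>\n',
    '      </edge>'),
    seq_len(nrow(net$edges)) - 1L, net$edges$from, net$edges$to,
    net$edges$count, net$edges$count) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <graph defaultedgetype="%s">',
            if (net$directed) "directed" else "undirected"),
    '    <attributes class="node">',
    '      <attribute id="weight" title="weight" type="double"/>',
    '      <attribute id="cluster" title="cluster" type="integer"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="count" title="count" type="double"/>',
    '    </attributes>',
    '    <nodes>', nodes, '    </nodes>',
    '    <edges>', edges, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path)
  invisible(path)
}

#' Export a site network as a plain edge-list TSV
#'
#' @param net A `site_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
plot.site_network <- function(x, ...) {
  if (!nrow(x$nodes)) {
    graphics::plot.new()
    graphics::title("empty site network")
    return(invisible(x))
  }
  g <- site_network_igraph(x)
  vs <- 8 + 20 * x$nodes$weight / max(x$nodes$weight)
  col <- if (!is.null(x$clusters))
    grDevices::rainbow(max(x$clusters))[x$clusters[x$nodes$label]]
  else "skyblue"
  ew <- if (nrow(x$edges)) 1 + 4 * x$edges$count / max(x$edges$count) else 1
  set.seed(1)
  igraph::plot.igraph(g, vertex.size = vs, vertex.color = col,
                      edge.width = ew, ...)
  invisible(x)
}
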