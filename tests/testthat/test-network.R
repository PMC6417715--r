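test_that("site labels are canonical, order-independent, idempotent", {
  expect_equal(site_label(c(7, 6, 1)), "167")
  expect_equal(site_label(c(1, 6, 7)), "167")
  expect_equal(site_label("761"), "167")
  expect_equal(site_label(site_label(c(6, 6, 1))), "16")
  expect_equal(parse_site_label("167"), c(1L, 6L, 7L))
  expect_true(is.na(site_label(integer(0))))
})

test_that("occupancy filtering is inclusive at the threshold", {
  ev <- matrix(FALSE, 100, 3, dimnames = list(NULL, c("7", "8", "9")))
  ev[1:10, 1] <- TRUE   # 10%
  ev[1:20, 2] <- TRUE   # exactly 20%
  ev[1:90, 3] <- TRUE   # 90%
  expect_equal(occupancy_filter(ev, 0.20), c("8", "9"))
  # threshold 1 keeps only permanent contacts; near-zero keeps any
  ev[, 3] <- TRUE
  expect_equal(occupancy_filter(ev, 1), "9")
  expect_equal(occupancy_filter(ev, 1e-9), c("7", "8", "9"))
  expect_error(occupancy_filter(ev[0, , drop = FALSE]), "zero-frame")
  expect_error(occupancy_filter(ev, 0), "threshold")
})

test_that("path collapse removes gaps and repeated runs, idempotently", {
  expect_equal(collapse_path(c("1", "1", "16", "16", "16", "6", "1")),
               c("1", "16", "6", "1"))
  expect_equal(collapse_path(c("5", NA, "5")), "5")
  expect_equal(collapse_path(rep("167", 500)), "167")
  expect_equal(collapse_path(c(NA, NA)), character(0))
  x <- c("1", NA, "1", "2", "2", NA, "3")
  expect_equal(collapse_path(collapse_path(x)), collapse_path(x))
})

test_that("frame sites label the contacted helix set and ignore loops", {
  # residues 70 (H1) and 315 (H7) within reach; loop residue 133 too
  sys <- toy_system(c(70, 315, 133),
                    rbind(c(0, 0, 0), c(0.35, 0, 0), c(5, 5, 0)),
                    rbind(c(0.18, 0.25, 0), c(5, 5.3, 0)),
                    c(12, 12, 12))
  fs <- frame_sites(one_frame_traj(sys, c(12, 12, 12)), sys)
  expect_equal(unname(fs$labels[1, "1"]), "17")
  # the loop-only lipid has protein contact but no helix label
  expect_true(fs$events[1, "2"])
  expect_true(is.na(fs$labels[1, "2"]))
  # helices 1, 6, 7 combine to the "167" label
  sys2 <- toy_system(c(70, 290, 315),
                     rbind(c(0, 0, 0), c(0.35, 0, 0), c(0, 0.35, 0)),
                     rbind(c(0.18, 0.18, 0)), c(12, 12, 12))
  fs2 <- frame_sites(one_frame_traj(sys2, c(12, 12, 12)), sys2)
  expect_equal(unname(fs2$labels[1, "1"]), "167")
})

test_that("a single path builds the documented network", {
  net <- build_network(list(c("1", "16", "6", "1")))
  w <- setNames(net$nodes$weight, net$nodes$label)
  expect_equal(w, c("1" = 2, "16" = 1, "6" = 1))
  e <- net$edges
  key <- paste(e$from, e$to)
  expect_setequal(key, c("1 16", "16 6", "1 6"))
  expect_true(all(e$count == 1))
})

test_that("networks are linear in path multiplicity", {
  p <- list(c("1", "16", "6", "1"))
  one <- build_network(p)
  two <- build_network(c(p, p))
  expect_equal(two$nodes$weight, 2 * one$nodes$weight)
  expect_equal(two$edges$count, 2 * one$edges$count)
})

test_that("edge totals equal a brute-force pair enumeration", {
  set.seed(23)
  labels <- c("1", "6", "7", "16", "67", "167", "5", "56")
  paths <- lapply(1:50, function(i)
    collapse_path(sample(labels, sample(2:12, 1), replace = TRUE)))
  net <- build_network(paths)
  # oracle: count adjacent unordered pairs directly
  oracle <- new.env()
  for (p in paths) if (length(p) > 1)
    for (k in seq_len(length(p) - 1)) {
      key <- paste(sort(c(p[k], p[k + 1])), collapse = "|")
      oracle[[key]] <- (if (is.null(oracle[[key]])) 0 else oracle[[key]]) + 1
    }
  for (i in seq_len(nrow(net$edges))) {
    key <- paste(sort(c(net$edges$from[i], net$edges$to[i])),
                 collapse = "|")
    expect_equal(net$edges$count[i], oracle[[key]])
  }
  expect_equal(sum(net$edges$count),
               sum(vapply(paths, function(p) length(p) - 1, 0)))
})

test_that("conservation identities hold exactly on random path sets", {
  set.seed(29)
  for (i in 1:50) {
    paths <- lapply(seq_len(sample(1:20, 1)), function(j)
      collapse_path(as.character(sample(1:8, sample(1:15, 1),
                                        replace = TRUE))))
    net <- build_network(paths)
    expect_equal(sum(net$edges$count),
                 sum(pmax(lengths(paths) - 1, 0)))
    expect_equal(sum(net$nodes$weight), sum(lengths(paths)))
  }
  empty <- build_network(list())
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("directed networks preserve transition order", {
  net <- build_network(list(c("1", "2", "1")), directed = TRUE)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("1 2", "2 1"))
  und <- build_network(list(c("1", "2", "1")))
  expect_equal(nrow(und$edges), 1)
  expect_equal(und$edges$count, 2)
})

test_that("two loosely joined 4-cliques split into the exhaustive-best
           partition; a uniform complete graph stays whole", {
  clique <- function(v) {
    e <- t(combn(v, 2))
    data.frame(from = e[, 1], to = e[, 2], count = 1,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(c("1", "2", "3", "4")),
                 clique(c("5", "6", "7", "8")),
                 data.frame(from = "4", to = "5", count = 1))
  paths <- unlist(lapply(seq_len(nrow(edges)), function(i)
    rep(list(c(edges$from[i], edges$to[i])), edges$count[i])),
    recursive = FALSE)
  net <- build_network(paths)
  net <- cluster_network(net)
  oracle <- best_modularity_partition(net$nodes$label, net$edges)
  # same grouping (community ids may be permuted)
  split_ours <- split(net$nodes$label, net$clusters[net$nodes$label])
  split_best <- split(names(oracle$partition), oracle$partition)
  norm <- function(s) sort(vapply(s, function(v)
    paste(sort(v), collapse = ","), ""))
  expect_equal(norm(split_ours), norm(split_best), ignore_attr = TRUE)
  expect_equal(net$modularity, oracle$modularity, tolerance = 1e-9)
  # complete graph with uniform weights: no structure, one community
  full <- build_network(lapply(seq_len(6), function(i)
    combn(as.character(1:4), 2)[, i]))
  full <- cluster_network(full)
  expect_equal(length(unique(full$clusters)), 1)
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(404)
  paths <- lapply(1:40, function(i)
    collapse_path(as.character(sample(1:8, 10, replace = TRUE))))
  net <- build_network(paths)
  a <- cluster_network(net, seed = 3)
  b <- cluster_network(net, seed = 3)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$modularity, b$modularity)
  one <- cluster_network(build_network(list("5")))
  expect_equal(one$modularity, 0)
  expect_equal(length(one$clusters), 1)
})

test_that("half-trajectory networks sum to the whole when no path spans
           the cut", {
  # constructed paths, split into two halves at a lipid boundary
  paths1 <- list(c("1", "2"), c("2", "3", "2"))
  paths2 <- list(c("1", "2"), c("4", "5"))
  whole <- build_network(c(paths1, paths2))
  h1 <- build_network(paths1)
  h2 <- build_network(paths2)
  add <- function(a, b, key) {
    m <- merge(a, b, by = key, all = TRUE)
    m[is.na(m)] <- 0
    m
  }
  nodes <- add(h1$nodes, h2$nodes, "label")
  nodes$weight <- nodes$weight.x + nodes$weight.y
  expect_equal(setNames(whole$nodes$weight, whole$nodes$label),
               setNames(nodes$weight, nodes$label)[whole$nodes$label])
  edges <- add(h1$edges, h2$edges, c("from", "to"))
  edges$count <- edges$count.x + edges$count.y
  key <- function(e) paste(e$from, e$to)
  expect_equal(setNames(whole$edges$count, key(whole$edges)),
               setNames(edges$count, key(edges))[key(whole$edges)])
})

test_that("gexf and edge-list exports are well-formed", {
  net <- cluster_network(build_network(list(c("1", "16", "6", "1"),
                                            c("6", "67"))))
  dir <- withr::local_tempdir()
  g <- file.path(dir, "n.gexf")
  write_gexf(net, g)
  doc <- xml2::read_xml(g)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               nrow(net$edges))
  e <- file.path(dir, "n.tsv")
  write_edge_list(net, e)
  back <- read.delim(e, colClasses = c("character", "character",
                                       "numeric"))
  expect_equal(back$count, net$edges$count)
})
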