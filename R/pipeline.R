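#' Build a validated pipeline run configuration
#'
#' @param structure Path to the structure file (`.pdb`/`.gro`).
#' @param trajectories Character vector of trajectory paths (replicate
#'   runs; pooled for contacts and networks, kept separate for per-run
#'   tables).
#' @param outdir Output directory.
#' @param helix_map A `helix_map` data frame or a TSV path
#'   (default [default_helix_map()]).
#' @param cutoff Contact criterion for frequency maps and networks, nm.
#' @param cutoffs Cutoff set for the sensitivity analysis, nm.
#' @param occupancy Occupancy threshold for the network filter.
#' @param resolution Louvain resolution.
#' @param seed RNG seed (clustering).
#' @param directed Directed transition networks?
#' @param reference_frame Leaflet-assignment reference frame.
#' @return A validated `run_config` list.
#' @export
run_config <- function(structure, trajectories, outdir,
                       helix_map = default_helix_map(),
                       cutoff = 0.5, cutoffs = c(0.5, 0.6, 0.7),
                       occupancy = 0.2, resolution = 0.8, seed = 0,
                       directed = FALSE, reference_frame = 1) {
  if (!file.exists(structure))
    stop("config validation: structure file not found: ", structure)
  missing <- trajectories[!file.exists(trajectories)]
  if (length(missing))
    stop("config validation: trajectory file(s) not found: ",
         paste(missing, collapse = ", "))
  if (is.character(helix_map)) helix_map <- read_helix_map(helix_map)
  helix_map <- validate_helix_map(helix_map)
  if (cutoff <= 0 || any(cutoffs <= 0))
    stop("config validation: cutoffs must be positive")
  if (occupancy <= 0 || occupancy > 1)
    stop("config validation: occupancy must be in (0, 1]")
  structure(list(structure = structure, trajectories = trajectories,
                 outdir = outdir, helix_map = helix_map, cutoff = cutoff,
                 cutoffs = sort(cutoffs), occupancy = occupancy,
                 resolution = resolution, seed = seed,
                 directed = directed, reference_frame = reference_frame),
            class = "run_config")
}

tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

#' Run the full analysis pipeline
#'
#' Executes topology reading, alignment/RMSD, contacts and frequency
#' maps (with cutoff sensitivity), helix tilt, leaflet-separated site
#' networks and membrane descriptors, writing TSV/CSV/GEXF outputs and
#' a JSON manifest into the configured output directory. Outputs are a
#' pure function of (inputs, configuration, seed).
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages? Default `FALSE`.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- file.path
  stages <- c("topology_io", "alignment", "contacts", "helix_tilt",
              "site_network", "membrane_props")

  say("[1/6] topology_io: reading system and trajectories")
  system <- stage("topology_io", read_system(config$structure))
  trajs <- stage("topology_io", lapply(config$trajectories,
                                       read_trajectory, system = system))
  leaflets <- stage("topology_io",
                    assign_leaflets(system, trajs[[1]],
                                    config$reference_frame))
  tsv(leaflets, out(config$outdir, "leaflets.tsv"))

  say("[2/6] alignment: per-helix RMSD")
  rmsd <- stage("alignment", do.call(rbind, lapply(seq_along(trajs),
    function(r) cbind(run = r, per_helix_rmsd(trajs[[r]], system,
                                              config$helix_map)))))
  tsv(rmsd, out(config$outdir, "rmsd.tsv"))

  say("[3/6] contacts: accumulation, frequency maps, cutoff sensitivity")
  tables <- stage("contacts", lapply(trajs, accumulate_contacts,
                                     system = system,
                                     cutoff = config$cutoff,
                                     helices = config$helix_map))
  pooled <- tables[[1]]
  if (length(tables) > 1) {
    for (t in tables[-1]) {
      pooled$counts <- pooled$counts + t$counts
      pooled$events <- rbind(pooled$events, t$events)
      pooled$sites <- rbind(pooled$sites, t$sites)
      pooled$n_frames <- pooled$n_frames + t$n_frames
    }
  }
  tsv(contact_long(pooled), out(config$outdir, "contacts.tsv"))
  per_run <- do.call(rbind, lapply(seq_along(tables), function(r)
    cbind(run = r, contact_long(tables[[r]]))))
  tsv(per_run, out(config$outdir, "contacts_per_run.tsv"))
  fmap <- frequency_map(pooled)
  write_frequency_map(fmap, out(config$outdir, "frequency_map.csv"),
                      out(config$outdir, "frequency_map_track.txt"))
  sens <- stage("contacts", cutoff_sensitivity(
    trajs[[1]], system, config$cutoffs, config$helix_map))
  tsv(as.data.frame(sens$rank_agreement),
      out(config$outdir, "cutoff_rank_agreement.tsv"))

  say("[4/6] helix_tilt: sliding-window tilt profile")
  tilt <- stage("helix_tilt", do.call(rbind, lapply(seq_along(trajs),
    function(r) cbind(run = r, tilt_profile(trajs[[r]], system,
                                            config$helix_map)))))
  tsv(tilt, out(config$outdir, "tilt.tsv"))
  tp <- tilt
  class(tp) <- c("tilt_profile", "data.frame")
  tsv(summary(tp), out(config$outdir, "tilt_summary.tsv"))

  say("[5/6] site_network: lipid paths and leaflet networks")
  nets <- stage("site_network", {
    cache <- build_label_cache(max(config$helix_map$helix_id))
    lab <- matrix(mask_to_label(pooled$sites, cache),
                  nrow = nrow(pooled$sites),
                  dimnames = dimnames(pooled$sites))
    paths <- lipid_paths(list(labels = lab, events = pooled$events),
                         leaflets, config$occupancy)
    res <- lapply(c(external = "external", internal = "internal"),
                  function(lf) {
      net <- build_network(paths[paths$leaflet == lf, , drop = FALSE],
                           leaflet = lf, directed = config$directed)
      if (nrow(net$nodes))
        net <- cluster_network(net, config$resolution, config$seed)
      net
    })
    c(res, list(paths = paths))
  })
  sp <- system$lipid_species[!is.na(system$lipid_species)][1]
  if (is.na(sp)) sp <- "lipid"
  for (lf in c("external", "internal")) {
    write_gexf(nets[[lf]],
               out(config$outdir, sprintf("%s_%s.gexf", sp, lf)))
    write_edge_list(nets[[lf]],
                    out(config$outdir, sprintf("%s_%s_edges.tsv", sp, lf)))
  }

  say("[6/6] membrane_props: area per lipid and thickness")
  memb <- stage("membrane_props", do.call(rbind,
    lapply(seq_along(trajs), function(r)
      cbind(run = r, membrane_summary(trajs[[r]], system, leaflets)))))
  tsv(memb, out(config$outdir, "membrane.tsv"))

  cfg_path <- out(config$outdir, "config.json")
  cfg_json <- config
  cfg_json$helix_map <- as.data.frame(config$helix_map)
  jsonlite::write_json(unclass(cfg_json), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "lipidsites",
    version = as.character(utils::packageVersion("lipidsites")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = as.list(stages),
    n_runs = length(trajs),
    outputs = list.files(config$outdir)
  )
  jsonlite::write_json(manifest, out(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(system = system, leaflets = leaflets, rmsd = rmsd,
                 contacts = pooled, frequency_map = fmap,
                 cutoff_sensitivity = sens, tilt = tilt,
                 networks = nets, membrane = memb, manifest = manifest))
}
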