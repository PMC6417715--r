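#' Configuration for the synthetic bilayer + helix-bundle generator
#'
#' The generator produces desk-scale coarse-grained trajectories with
#' known ground truth: a static ring-shaped bundle of 8 ideal helices
#' spanning a two-leaflet bilayer of rigid 12/13-bead lipids performing
#' lateral Gaussian random walks, with optional planted residence
#' affinities (slowed stepping) near chosen helix faces. Lipids are
#' kinematic: no forces, no leaflet exchange.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (default 300, i.e. a
#'   600-lipid bilayer).
#' @param lipid_species Species name from the species table
#'   (default `"POPC"`).
#' @param n_frames Frames to generate (default 1000).
#' @param frame_stride Saved-iteration interval recorded on the
#'   trajectory (default 1).
#' @param step_sd Lateral random-walk step standard deviation, nm/frame
#'   (default 0.06).
#' @param area_per_lipid Planted area per lipid, squared angstrom
#'   (default 65); fixes the lateral box at
#'   sqrt(n_per_leaflet * APL).
#' @param thickness Planted phosphate-plane separation, angstrom
#'   (default 42).
#' @param box_z Box height, nm (default 9).
#' @param site_affinity Named numeric of residence-bias multipliers,
#'   names are canonical site labels (e.g. `c("67" = 5)`); inside the
#'   site shell the step sd is divided by the square root of the
#'   multiplier, so the time-averaged residence (stationary density
#'   goes as 1/step^2) scales approximately linearly with the
#'   multiplier. Multipliers must be >= 1.
#' @param site_radius Residence-shell radius around a site anchor, nm
#'   (default 0.8).
#' @param helices Helix map defining residue ranges (default
#'   [default_helix_map()]).
#' @param helix_tilts Per-helix tilt angles in degrees (length 8,
#'   default all 0), applied as a rotation of the helix about its
#'   centre, towards the radial direction.
#' @param kink_angles Per-helix additional bend applied to the post-kink
#'   segment, degrees (default all 0; only meaningful for helices with
#'   kink bounds).
#' @param ring_radius Bundle ring radius, nm (default 1.5).
#' @param spiral_radius Backbone spiral radius, nm (default 0.23).
#' @param rise Helical rise per residue, nm (default 0.15).
#' @param twist Helical twist per residue, degrees (default 100).
#' @param exclusion_radius Lateral exclusion radius around each helix
#'   axis for lipid centres, nm (default 0.45).
#' @param z_jitter_sd Per-lipid fixed vertical offset sd, nm
#'   (default 0.05).
#' @param species Species bead tables (default [martini_lipids()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_lipids_per_leaflet = 300,
                             lipid_species = "POPC",
                             n_frames = 1000, frame_stride = 1,
                             step_sd = 0.06,
                             area_per_lipid = 65, thickness = 42,
                             box_z = 9,
                             site_affinity = numeric(0),
                             site_radius = 0.8,
                             helices = default_helix_map(),
                             helix_tilts = rep(0, 8),
                             kink_angles = rep(0, 8),
                             ring_radius = 1.5, spiral_radius = 0.23,
                             rise = 0.15, twist = 100,
                             exclusion_radius = 0.45,
                             z_jitter_sd = 0.05,
                             species = martini_lipids()) {
  if (length(site_affinity) && any(site_affinity < 1))
    stop("site affinity multipliers must be >= 1")
  if (length(site_affinity))
    names(site_affinity) <- vapply(names(site_affinity), site_label, "")
  if (is.null(species[[lipid_species]]))
    stop("unknown lipid species: ", lipid_species)
  cfg <- list(n_lipids_per_leaflet = n_lipids_per_leaflet,
              lipid_species = lipid_species, n_frames = n_frames,
              frame_stride = frame_stride, step_sd = step_sd,
              area_per_lipid = area_per_lipid, thickness = thickness,
              box_z = box_z, site_affinity = site_affinity,
              site_radius = site_radius, helices = helices,
              helix_tilts = helix_tilts, kink_angles = kink_angles,
              ring_radius = ring_radius, spiral_radius = spiral_radius,
              rise = rise, twist = twist,
              exclusion_radius = exclusion_radius,
              z_jitter_sd = z_jitter_sd, species = species)
  class(cfg) <- "generator_config"
  cfg
}

rot_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build the static helix-bundle protein of a generator configuration
#'
#' One backbone bead per residue is placed on an ideal helical spiral;
#' the eight helices stand on a ring, each rotated by its configured
#' tilt about its centre (towards the radial direction) and bent by its
#' configured kink angle after the torsion zone. Helix 8, shorter than
#' the membrane span, is centred on the internal phosphate plane side,
#' as an intracellular helix.
#'
#' @param config A [generator_config()].
#' @return List with `system` (protein-only `cg_system` rows as a data
#'   frame), `coords` ((n x 3) nm).
#' @export
build_protein <- function(config) {
  hm <- config$helices
  nh <- nrow(hm)
  ring_sep <- 2 * config$ring_radius * sin(pi / nh)
  if (ring_sep < 2 * config$spiral_radius + 0.05)
    stop("overlapping helices: ring radius too small for spiral radius")
  span <- config$thickness / 10  # nm
  all_coords <- list(); all_res <- list()
  for (i in seq_len(nh)) {
    nres <- hm$end_residue[i] - hm$begin_residue[i] + 1
    theta <- 2 * pi * (i - 1) / nh
    phase <- theta  # rotational copies keep the bundle 8-fold symmetric
    k <- seq_len(nres) - (nres + 1) / 2
    ang <- phase + (seq_len(nres) - 1) * config$twist * pi / 180
    local <- cbind(config$spiral_radius * cos(ang),
                   config$spiral_radius * sin(ang),
                   k * config$rise)
    if (config$helix_tilts[i] != 0) {
      # tilt towards the radial direction: rotate about the tangent
      tangent <- c(-sin(theta), cos(theta), 0)
      local <- local %*% t(rot_about_axis(tangent, config$helix_tilts[i]))
    }
    if (!is.na(hm$kink_begin[i]) && config$kink_angles[i] != 0) {
      res_ids <- hm$begin_residue[i]:hm$end_residue[i]
      post <- res_ids >= hm$kink_end[i]
      pivot_row <- which(res_ids == hm$kink_end[i])
      pivot <- local[pivot_row, ]
      tangent <- c(-sin(theta), cos(theta), 0)
      R <- rot_about_axis(tangent, config$kink_angles[i])
      local[post, ] <- sweep(sweep(local[post, , drop = FALSE], 2, pivot)
                             %*% t(R), 2, pivot, "+")
    }
    zc <- if (nres * config$rise < span - 0.3)
      -span / 2 else 0  # short helices sit at the internal side
    centre <- c(config$ring_radius * cos(theta),
                config$ring_radius * sin(theta), zc)
    all_coords[[i]] <- sweep(local, 2, centre, "+")
    all_res[[i]] <- hm$begin_residue[i]:hm$end_residue[i]
  }
  coords <- do.call(rbind, all_coords)
  res <- unlist(all_res)
  n <- length(res)
  df <- data.frame(bead_index = seq_len(n), bead_name = "BB",
                   bead_class = "backbone", residue_id = res,
                   residue_name = "BB", molecule_kind = "protein",
                   lipid_species = NA_character_, lipid_id = NA_integer_,
                   stringsAsFactors = FALSE)
  list(system = df, coords = coords)
}

# Anchor point of a planted site: along the mean direction of the member
# helices, at the lateral distance that minimises the largest distance to
# any member helix centre while staying outside every exclusion disk.
site_anchor <- function(label, config) {
  hm <- config$helices
  nh <- nrow(hm)
  hs <- parse_site_label(label)
  th <- 2 * pi * (hs - 1) / nh
  hx <- config$ring_radius * cos(2 * pi * (seq_len(nh) - 1) / nh)
  hy <- config$ring_radius * sin(2 * pi * (seq_len(nh) - 1) / nh)
  dirv <- c(mean(cos(th)), mean(sin(th)))
  dirv <- dirv / sqrt(sum(dirv^2))
  dgrid <- seq(config$ring_radius * 0.5, config$ring_radius + 2,
               by = 0.01)
  best <- NULL; best_obj <- Inf
  for (d in dgrid) {
    p <- d * dirv
    dists <- sqrt((p[1] - hx)^2 + (p[2] - hy)^2)
    reachable <- all(dists >= config$exclusion_radius + 0.02) &&
      sqrt(sum(p^2)) >= config$ring_radius - 0.18
    if (!reachable) next
    obj <- max(dists[hs])
    if (obj < best_obj) { best_obj <- obj; best <- p }
  }
  if (is.null(best)) stop("no reachable anchor for site ", label)
  best
}

#' Simulate the lipid bilayer of a generator configuration
#'
#' Lipid centres perform lateral 2D Gaussian random walks with periodic
#' wrapping, excluded from a disk around each helix axis and from the
#' bundle core; within the residence shell of a planted site the step sd
#' is divided by the site's affinity multiplier. Bead positions are
#' rigid per-species offsets from the centre (head above the phosphate,
#' tails towards the midplane), with a fixed random azimuth per lipid
#' and a fixed per-lipid vertical jitter. Uses the current RNG state;
#' call `set.seed()` (or [generate_cg_trajectory()] with a seed) for
#' reproducibility.
#'
#' @param config A [generator_config()].
#' @param protein Optional [build_protein()] result (rebuilt when NULL).
#' @return List with `system` (full `cg_system`), `trajectory`
#'   ([cg_trajectory()]), `leaflets` (ground-truth assignment data
#'   frame) and `anchors` (planted site anchor coordinates).
#' @export
simulate_lipids <- function(config, protein = NULL) {
  if (is.null(protein)) protein <- build_protein(config)
  hm <- config$helices
  nh <- nrow(hm)
  npl <- config$n_lipids_per_leaflet
  nlip <- 2 * npl
  apl_nm2 <- config$area_per_lipid / 100
  L <- sqrt(npl * apl_nm2)
  box <- c(L, L, config$box_z)
  sep <- config$thickness / 10

  theta <- 2 * pi * (seq_len(nh) - 1) / nh
  excl_xy <- rbind(cbind(config$ring_radius * cos(theta),
                         config$ring_radius * sin(theta)),
                   c(0, 0))
  excl_r <- c(rep(config$exclusion_radius, nh),
              max(config$ring_radius - 0.2, 0))
  excl_area <- pi * sum(excl_r^2)  # crude upper bound, disks overlap
  if (nlip * 0.04 > L * L - excl_area * 0.5)
    stop("density too high to place lipids without overlap")

  # initial placement: uniform rejection sampling outside exclusions
  place <- function(n) {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- 2 * (n - length(xs)) + 16
      x <- runif(m, 0, L); y <- runif(m, 0, L)
      ok <- rep(TRUE, m)
      for (e in seq_len(nrow(excl_xy))) {
        dx <- x - excl_xy[e, 1] - L * round((x - excl_xy[e, 1]) / L)
        dy <- y - excl_xy[e, 2] - L * round((y - excl_xy[e, 2]) / L)
        ok <- ok & (dx^2 + dy^2 >= excl_r[e]^2)
      }
      xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
    }
    cbind(xs[seq_len(n)], ys[seq_len(n)])
  }
  p0 <- place(nlip)

  aff <- config$site_affinity
  if (length(aff)) {
    anchors <- t(vapply(names(aff), site_anchor, numeric(2),
                        config = config))
    site_xy <- anchors
    site_r <- rep(config$site_radius, length(aff))
    # the stationary density of a walk with space-dependent step scales
    # as 1/step^2, so dividing the step by sqrt(multiplier) makes the
    # time-averaged residence inside the shell scale ~linearly with the
    # configured multiplier
    site_mult <- sqrt(as.numeric(aff))
  } else {
    anchors <- matrix(numeric(0), 0, 2)
    site_xy <- matrix(numeric(0), 0, 2)
    site_r <- numeric(0); site_mult <- numeric(0)
  }

  nf <- config$n_frames
  walk <- cpp_lipid_walk(p0[, 1], p0[, 2], nf, config$step_sd,
                         site_xy, site_r, site_mult,
                         excl_xy, excl_r, L, L)

  # species bead geometry: z offsets from the phosphate plane (external
  # leaflet; mirrored for the internal), small lateral offsets rotated
  # by a fixed per-lipid azimuth
  tab <- config$species[[config$lipid_species]]
  nb <- nrow(tab)
  zoff <- numeric(nb); xoff <- numeric(nb); yoff <- numeric(nb)
  chainA <- grepl("A$", tab$bead_name) & tab$bead_class == "tailA"
  chainB <- grepl("B$", tab$bead_name) & tab$bead_class == "tailB"
  zoff[tab$bead_class == "head"] <- 0.10
  zoff[tab$bead_class == "phosphate"] <- 0
  zoff[tab$bead_class == "glycerol"] <-
    -0.15 * seq_len(sum(tab$bead_class == "glycerol"))
  zoff[chainA] <- -0.45 - 0.30 * (seq_len(sum(chainA)) - 1)
  zoff[chainB] <- -0.45 - 0.30 * (seq_len(sum(chainB)) - 1)
  xoff[chainA] <- 0.08; xoff[chainB] <- -0.08
  yoff[tab$bead_class == "head"] <- 0.03

  leaflet <- rep(c("external", "internal"), each = npl)
  zsign <- ifelse(leaflet == "external", 1, -1)
  zph <- zsign * sep / 2 + rnorm(nlip, 0, config$z_jitter_sd)
  psi <- runif(nlip, 0, 2 * pi)
  cpsi <- cos(psi); spsi <- sin(psi)

  nprot <- nrow(protein$coords)
  nbead <- nprot + nlip * nb
  coords <- array(0, dim = c(nbead, 3, max(nf, 0)))
  if (nf > 0) {
    coords[seq_len(nprot), 1, ] <- protein$coords[, 1]
    coords[seq_len(nprot), 2, ] <- protein$coords[, 2]
    coords[seq_len(nprot), 3, ] <- protein$coords[, 3]
    tx <- t(walk$x); ty <- t(walk$y)
    for (b in seq_len(nb)) {
      rows <- nprot + (seq_len(nlip) - 1) * nb + b
      ox <- cpsi * xoff[b] - spsi * yoff[b]
      oy <- spsi * xoff[b] + cpsi * yoff[b]
      # (nlip x nf) = t(walk) + per-lipid offset recycled down columns
      coords[rows, 1, ] <- tx + ox
      coords[rows, 2, ] <- ty + oy
      coords[rows, 3, ] <- zph + zsign * zoff[b]
    }
  }

  lip_df <- data.frame(
    bead_index = nprot + seq_len(nlip * nb),
    bead_name = rep(tab$bead_name, times = nlip),
    bead_class = rep(tab$bead_class, times = nlip),
    residue_id = nprot_res_offset(protein) +
      rep(seq_len(nlip), each = nb),
    residue_name = config$lipid_species,
    molecule_kind = "lipid",
    lipid_species = config$lipid_species,
    lipid_id = rep(seq_len(nlip), each = nb),
    stringsAsFactors = FALSE
  )
  system <- new_cg_system(rbind(protein$system, lip_df),
                          coords = if (nf > 0) coords[, , 1] else NULL,
                          box = box)
  traj <- cg_trajectory(coords, box, config$frame_stride)
  leaf <- data.frame(lipid_id = seq_len(nlip), leaflet = leaflet,
                     stringsAsFactors = FALSE)
  list(system = system, trajectory = traj, leaflets = leaf,
       anchors = anchors)
}

nprot_res_offset <- function(protein) max(protein$system$residue_id)

#' Generate a complete synthetic fixture
#'
#' Seeds the RNG, builds the protein, simulates the lipids and bundles
#' system, trajectory and ground truth. Identical configuration and seed
#' give identical output.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed (default 1).
#' @return A `cg_fixture`: list with `system`, `trajectory`, `truth`
#'   (planted leaflets, affinities, anchors, area per lipid, thickness,
#'   tilts, seed) and `config`.
#' @export
generate_cg_trajectory <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  protein <- build_protein(config)
  sim <- simulate_lipids(config, protein)
  out <- list(system = sim$system, trajectory = sim$trajectory,
              truth = list(leaflets = sim$leaflets,
                           site_affinity = config$site_affinity,
                           anchors = sim$anchors,
                           area_per_lipid = config$area_per_lipid,
                           thickness = config$thickness,
                           helix_tilts = config$helix_tilts,
                           kink_angles = config$kink_angles,
                           seed = seed),
              config = config)
  class(out) <- "cg_fixture"
  out
}

#' @export
print.cg_fixture <- function(x, ...) {
  cat("Synthetic CG fixture (seed ", x$truth$seed, ")\n", sep = "")
  print(x$system)
  print(x$trajectory)
  invisible(x)
}

#' Write a fixture to structure, trajectory and ground-truth files
#'
#' Emits `<basename>.pdb` and `<basename>.gro` structures, a
#' `<basename>.dcd` trajectory and a `<basename>_truth.json` sidecar
#' holding the planted ground truth, all readable back by the topology
#' module.
#'
#' @param fixture A [generate_cg_trajectory()] result.
#' @param dir Output directory (created if needed).
#' @param basename File basename (default `"fixture"`).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, basename = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(basename, ext))
  write_system(fixture$system, p(".pdb"))
  write_system(fixture$system, p(".gro"))
  write_dcd(fixture$trajectory, p(".dcd"))
  truth <- fixture$truth
  truth$leaflets <- as.list(truth$leaflets)
  jsonlite::write_json(truth, p("_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(pdb = p(".pdb"), gro = p(".gro"), dcd = p(".dcd"),
                 truth = p("_truth.json")))
}
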