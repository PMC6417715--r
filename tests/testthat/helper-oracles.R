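# Independent oracles and small constructors shared across tests.

# O(na * nb) minimum-image pair enumeration (strict < cutoff).
brute_pairs <- function(a, b, box, cutoff) {
  pairs <- matrix(integer(0), 0, 2)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    if (k == 1) d2 <- d^2 else d2 <- d2 + d^2
  }
  idx <- which(d2 < cutoff^2, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Ideal helical spiral about the z axis.
ideal_helix <- function(n, radius = 0.23, rise = 0.15, twist = 100,
                        phase = 0) {
  ang <- phase + (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang),
        (seq_len(n) - 1) * rise)
}

rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Brute-force optimal-superposition RMSD: minimise over rotations
# (parameterised by rotation vector) and translations from many starts.
brute_fit_rmsd <- function(P, Q) {
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else
      rotation_about(par[1:3] / th, th * 180 / pi)
    A <- sweep(P %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((A - Q)^2)))
  }
  best <- Inf
  for (i in 1:40) {
    st <- c(rnorm(3), colMeans(Q) - colMeans(P))
    r <- stats::optim(st, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Exhaustive modularity maximisation over all set partitions of the
# vertices of an undirected weighted graph given as an edge data frame.
all_partitions <- function(n) {
  # restricted growth strings
  out <- list()
  rec <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

best_modularity_partition <- function(nodes, edges) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    W[edges$from[i], edges$to[i]] <- W[edges$from[i], edges$to[i]] +
      edges$count[i]
    W[edges$to[i], edges$from[i]] <- W[edges$to[i], edges$from[i]] +
      edges$count[i]
  }
  m2 <- sum(W)
  deg <- rowSums(W)
  best_q <- -Inf; best_p <- NULL
  for (p in all_partitions(n)) {
    q <- 0
    for (c in unique(p)) {
      idx <- which(p == c)
      q <- q + sum(W[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
    }
    if (q > best_q + 1e-12) { best_q <- q; best_p <- p }
  }
  list(partition = stats::setNames(best_p, nodes), modularity = best_q)
}

# Small generator configurations used across tests.
tiny_config <- function(...) {
  args <- list(n_lipids_per_leaflet = 30, n_frames = 40)
  user <- list(...)
  args[names(user)] <- user
  do.call(generator_config, args)
}

equal_helix_map <- function() {
  lipidsites:::validate_helix_map(data.frame(
    helix_id = 1:8,
    begin_residue = seq(1, 281, by = 40),
    end_residue = seq(30, 310, by = 40),
    kink_begin = NA_integer_, kink_end = NA_integer_))
}

# A hand-built two-helix toy system: one backbone bead per residue at
# given positions, plus one single-bead "lipid" per entry of lipid_xyz
# (a phosphate bead, so leaflet logic works).
toy_system <- function(protein_res, protein_xyz, lipid_xyz, box) {
  npro <- length(protein_res)
  nlip <- nrow(lipid_xyz)
  df <- data.frame(
    bead_index = seq_len(npro + 2 * nlip),
    bead_name = c(rep("BB", npro), rep(c("PO4", "C1A"), nlip)),
    bead_class = c(rep("backbone", npro),
                   rep(c("phosphate", "tailA"), nlip)),
    residue_id = c(protein_res, rep(1000 + seq_len(nlip), each = 2)),
    residue_name = c(rep("BB", npro), rep("TOY", 2 * nlip)),
    molecule_kind = c(rep("protein", npro), rep("lipid", 2 * nlip)),
    lipid_species = c(rep(NA, npro), rep("TOY", 2 * nlip)),
    lipid_id = c(rep(NA_integer_, npro), rep(seq_len(nlip), each = 2)),
    stringsAsFactors = FALSE)
  coords <- rbind(protein_xyz,
                  lipid_xyz[rep(seq_len(nlip), each = 2), , drop = FALSE])
  # offset the tail bead slightly below the phosphate
  coords[npro + 2 * seq_len(nlip), 3] <-
    coords[npro + 2 * seq_len(nlip), 3] - 0.3
  sys <- lipidsites:::new_cg_system(df, coords = coords, box = box)
  sys
}

one_frame_traj <- function(sys, box) {
  co <- system_coords(sys)
  cg_trajectory(array(co, dim = c(nrow(co), 3, 1)), box)
}
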