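#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD of
#' the selected beads of `frame` onto the corresponding beads of
#' `reference`, and applies it to the whole frame.
#'
#' @param frame,reference (n x 3) coordinate matrices, nm.
#' @param selection Integer bead indices used for the fit (default: all
#'   rows). The same indices address both matrices.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), `aligned` (the transformed full frame) and `rmsd`
#'   (over the selection, nm).
#' @export
superpose <- function(frame, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  if (!length(selection)) stop("empty selection")
  P <- frame[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection cardinality mismatch")
  if (nrow(P) < 3) stop("need at least 3 non-collinear selected beads")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check: second singular value of the centred cloud
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300))
    stop("need at least 3 non-collinear selected beads")
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cq - as.vector(R %*% cp)
  aligned <- sweep(frame %*% t(R), 2, tr, "+")
  list(rotation = R, translation = tr, aligned = aligned,
       rmsd = rmsd_between(aligned[selection, , drop = FALSE], Q))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b (n x 3) matrices in the same frame of reference.
#' @return RMSD in the coordinate unit (no fitting is performed).
#' @export
rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Whole-protein and per-helix RMSD along a trajectory
#'
#' Each frame is superposed onto the reference with a single global fit
#' over `fit_selection` (default: all protein beads); RMSD is then
#' measured over the whole protein and over each helix's beads without
#' per-helix refitting, so local displacements are reported in the frame
#' of the globally aligned receptor.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param helices A `helix_map` (default [default_helix_map()]).
#' @param reference Reference coordinates (n x 3 nm); default: the
#'   system's structure coordinates, else frame 1.
#' @param fit_selection Bead indices for the global fit; default: all
#'   protein beads.
#' @return An `rmsd_profile` data frame with columns `frame`, `helix`
#'   (`"all"` or `"H1"`..`"H8"`) and `rmsd_A` (angstrom).
#' @export
per_helix_rmsd <- function(traj, system, helices = default_helix_map(),
                           reference = NULL, fit_selection = NULL) {
  prot <- which(system$molecule_kind == "protein")
  if (!length(prot)) stop("system has no protein beads")
  if (is.null(fit_selection)) fit_selection <- prot
  if (is.null(reference)) {
    reference <- system_coords(system)
    if (is.null(reference)) {
      if (traj$n_frames < 1) stop("no reference coordinates available")
      reference <- traj$coords[, , 1]
    }
  }
  hsel <- lapply(seq_len(nrow(helices)), function(i) {
    s <- prot[system$residue_id[prot] >= helices$begin_residue[i] &
                system$residue_id[prot] <= helices$end_residue[i]]
    if (!length(s))
      stop("helix H", helices$helix_id[i], " range is outside the ",
           "protein residues")
    s
  })
  names(hsel) <- paste0("H", helices$helix_id)
  out <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    fit <- superpose(traj$coords[, , f], reference, fit_selection)
    al <- fit$aligned
    r <- c(all = rmsd_between(al[prot, , drop = FALSE],
                              reference[prot, , drop = FALSE]),
           vapply(hsel, function(s)
             rmsd_between(al[s, , drop = FALSE],
                          reference[s, , drop = FALSE]), numeric(1)))
    out[[f]] <- data.frame(frame = f, helix = names(r), rmsd_A = r * 10,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("rmsd_profile", "data.frame")
  res
}

#' @export
summary.rmsd_profile <- function(object, ...) {
  agg <- aggregate(rmsd_A ~ helix, data = object,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  data.frame(helix = agg$helix, mean_rmsd_A = agg$rmsd_A[, "mean"],
             sd_rmsd_A = agg$rmsd_A[, "sd"], stringsAsFactors = FALSE)
}
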