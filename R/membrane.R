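#' Area per lipid
#'
#' Lateral box area divided by the lipid count of the larger leaflet,
#' per frame. The protein cross-section is not subtracted, so in
#' protein-containing systems the value is biased upward relative to a
#' protein-free bilayer at the same lateral density.
#'
#' @param traj A [cg_trajectory()].
#' @param leaflets A [assign_leaflets()] result.
#' @return Numeric vector, one value per frame, in squared angstrom.
#' @export
area_per_lipid <- function(traj, leaflets) {
  n <- table(factor(leaflets$leaflet, levels = c("external", "internal")))
  if (any(n == 0)) stop("empty leaflet")
  traj$box[, 1] * traj$box[, 2] * 100 / max(n)
}

#' Bilayer thickness
#'
#' Absolute difference between the mean z of the external-leaflet
#' phosphate beads and the mean z of the internal-leaflet phosphates,
#' per frame.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param leaflets A [assign_leaflets()] result.
#' @return Numeric vector, one value per frame, in angstrom.
#' @export
bilayer_thickness <- function(traj, system, leaflets) {
  ph <- which(system$bead_class == "phosphate")
  lf <- leaflets$leaflet[match(system$lipid_id[ph], leaflets$lipid_id)]
  if (!any(lf == "external") || !any(lf == "internal"))
    stop("empty leaflet")
  ze <- matrix(traj$coords[ph[lf == "external"], 3, ],
               nrow = sum(lf == "external"))
  zi <- matrix(traj$coords[ph[lf == "internal"], 3, ],
               nrow = sum(lf == "internal"))
  abs(colMeans(ze) - colMeans(zi)) * 10
}

#' Per-frame bilayer descriptor series with summary
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param leaflets A [assign_leaflets()] result (frame-1 assignment when
#'   `NULL`).
#' @return A `membrane_summary` data frame with columns `frame`,
#'   `area_per_lipid_A2`, `thickness_A`; `summary()` reports means and
#'   standard deviations.
#' @export
membrane_summary <- function(traj, system, leaflets = NULL) {
  if (is.null(leaflets)) leaflets <- assign_leaflets(system, traj)
  out <- data.frame(frame = seq_len(traj$n_frames),
                    area_per_lipid_A2 = area_per_lipid(traj, leaflets),
                    thickness_A = bilayer_thickness(traj, system, leaflets))
  th <- out$thickness_A / 10
  if (any(th >= traj$box[, 3]))
    warning("thickness not smaller than box Lz; check leaflet assignment")
  class(out) <- c("membrane_summary", "data.frame")
  out
}

#' @export
summary.membrane_summary <- function(object, ...) {
  data.frame(
    quantity = c("area_per_lipid_A2", "thickness_A"),
    mean = c(mean(object$area_per_lipid_A2), mean(object$thickness_A)),
    sd = c(sd(object$area_per_lipid_A2), sd(object$thickness_A))
  )
}
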