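#' Local helix axes from a sliding window
#'
#' For each window of `window` consecutive backbone beads, the local axis
#' is built from the interior bisector vectors: at each interior bead i,
#' v_i = (P\[i-1\] - P\[i\]) + (P\[i+1\] - P\[i\]) points from the helix
#' surface towards the axis, and the cross products of consecutive
#' bisectors are parallel to the local axis. The construction is exact
#' for an ideal helical spiral of any radius and pitch. Windows whose
#' beads are (near-)collinear have vanishing bisectors; there the window
#' chord is used, which is exact for a straight segment. Axes are unit
#' length and sign-aligned with increasing residue order, so adjacent
#' axes have positive dot product along a smooth helix.
#'
#' @param helix_coords (m x 3) matrix of ordered backbone bead
#'   positions of one helix.
#' @param window Sliding-window length in residues (default 4).
#' @return ((m - window + 1) x 3) matrix of unit axis vectors.
#' @export
local_axes <- function(helix_coords, window = 4) {
  P <- as.matrix(helix_coords)
  m <- nrow(P)
  if (window < 3) stop("window must be at least 3 residues")
  if (m < window)
    stop("helix has ", m, " residues, shorter than the window (", window, ")")
  nw <- m - window + 1
  # bisectors at interior beads 2..m-1
  V <- matrix(0, m, 3)
  if (m >= 3) {
    i <- 2:(m - 1)
    V[i, ] <- (P[i - 1, , drop = FALSE] - P[i, , drop = FALSE]) +
      (P[i + 1, , drop = FALSE] - P[i, , drop = FALSE])
  }
  cross3 <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  axes <- matrix(0, nw, 3)
  chords <- P[window:m, , drop = FALSE] - P[1:nw, , drop = FALSE]
  scale2 <- max(rowSums(chords^2), .Machine$double.eps)
  for (w in seq_len(nw)) {
    ii <- (w + 1):(w + window - 2)        # interior beads of this window
    if (length(ii) >= 2) {
      cr <- cross3(V[ii[-length(ii)], , drop = FALSE],
                   V[ii[-1], , drop = FALSE])
      ax <- colSums(cr)
    } else ax <- c(0, 0, 0)
    if (sum(ax^2) < 1e-12 * scale2) ax <- chords[w, ]
    if (sum(ax * chords[w, ]) < 0) ax <- -ax
    n <- sqrt(sum(ax^2))
    if (n == 0) stop("degenerate window: coincident beads")
    axes[w, ] <- ax / n
  }
  axes
}

#' Maximum tilt of a set of local axes against a reference axis
#'
#' Angles are folded into \[0, 90\] degrees: the sign of an axis vector
#' carries no meaning for tilt.
#'
#' @param axes Matrix of axis vectors (rows), e.g. from [local_axes()].
#' @param reference_axis Unit reference direction; default the membrane
#'   normal `c(0, 0, 1)`.
#' @return Maximum angle over the windows, degrees.
#' @export
max_tilt <- function(axes, reference_axis = c(0, 0, 1)) {
  axes <- rbind(axes)
  if (!nrow(axes)) stop("need at least one axis")
  nr <- sqrt(sum(reference_axis^2))
  na <- sqrt(rowSums(axes^2))
  if (nr == 0 || any(na == 0)) stop("zero-length axis vector")
  cosang <- abs(as.vector(axes %*% reference_axis)) / (na * nr)
  max(acos(pmin(1, cosang)) * 180 / pi)
}

#' Tilt of the two sub-segments of a kinked helix
#'
#' Evaluates [max_tilt()] independently on the residues from the helix
#' start to `kink_begin` and from `kink_end` to the helix end; residues
#' strictly between the two bounds (the torsion zone) enter neither
#' segment.
#'
#' @param helix_coords (m x 3) ordered backbone positions of the helix.
#' @param residue_ids Residue id of each row of `helix_coords`.
#' @param kink_begin,kink_end Last residue of the first segment and
#'   first residue of the second.
#' @param window Sliding-window length (default 4).
#' @param reference_axis Reference direction (default membrane normal).
#' @return Named numeric: `pre_kink`, `post_kink` tilt in degrees.
#' @export
segment_tilts <- function(helix_coords, residue_ids, kink_begin, kink_end,
                          window = 4, reference_axis = c(0, 0, 1)) {
  if (is.na(kink_begin) || is.na(kink_end)) stop("kink bounds undefined")
  pre <- residue_ids <= kink_begin
  post <- residue_ids >= kink_end
  if (sum(pre) < window || sum(post) < window)
    stop("sub-segment shorter than the sliding window")
  c(pre_kink = max_tilt(local_axes(helix_coords[pre, , drop = FALSE],
                                   window), reference_axis),
    post_kink = max_tilt(local_axes(helix_coords[post, , drop = FALSE],
                                    window), reference_axis))
}

#' Per-frame helix tilt profile of a trajectory
#'
#' For every frame and helix, the maximum local-axis tilt against the
#' membrane normal; helices with a declared kink additionally get the
#' two sub-segment tilts. Reported per frame; use [summary()] for the
#' mean and standard deviation over frames.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param helices A `helix_map`.
#' @param window Sliding-window length (default 4).
#' @param reference_axis Reference direction (default `c(0, 0, 1)`).
#' @return A `tilt_profile` data frame with columns `frame`, `helix`,
#'   `segment` (`full`, `pre_kink`, `post_kink`), `tilt_deg`.
#' @export
tilt_profile <- function(traj, system, helices = default_helix_map(),
                         window = 4, reference_axis = c(0, 0, 1)) {
  prot <- which(system$molecule_kind == "protein")
  rows <- lapply(seq_len(nrow(helices)), function(i) {
    s <- prot[system$residue_id[prot] >= helices$begin_residue[i] &
                system$residue_id[prot] <= helices$end_residue[i]]
    s[order(system$residue_id[s])]
  })
  out <- list()
  for (f in seq_len(traj$n_frames)) {
    fr <- traj$coords[, , f]
    for (i in seq_len(nrow(helices))) {
      sel <- rows[[i]]
      hid <- paste0("H", helices$helix_id[i])
      tl <- max_tilt(local_axes(fr[sel, , drop = FALSE], window),
                     reference_axis)
      out[[length(out) + 1]] <- data.frame(
        frame = f, helix = hid, segment = "full", tilt_deg = tl,
        stringsAsFactors = FALSE)
      if (!is.na(helices$kink_begin[i])) {
        st <- segment_tilts(fr[sel, , drop = FALSE],
                            system$residue_id[sel],
                            helices$kink_begin[i], helices$kink_end[i],
                            window, reference_axis)
        out[[length(out) + 1]] <- data.frame(
          frame = f, helix = hid,
          segment = c("pre_kink", "post_kink"),
          tilt_deg = as.numeric(st), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tilt_profile", "data.frame")
  res
}

#' @export
summary.tilt_profile <- function(object, ...) {
  agg <- aggregate(tilt_deg ~ helix + segment, data = object,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(helix = agg$helix, segment = agg$segment,
                    mean_tilt_deg = agg$tilt_deg[, "mean"],
                    sd_tilt_deg = agg$tilt_deg[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$helix, out$segment != "full"), ]
}
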