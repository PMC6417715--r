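#' Construct a trajectory object
#'
#' @param coords Numeric array of dimension (n beads, 3, n frames), nm.
#' @param box Per-frame orthorhombic box lengths: an (n frames x 3)
#'   matrix or a length-3 vector recycled over frames, nm.
#' @param frame_stride Saved-iteration interval between stored frames.
#' @return A `cg_trajectory`: list with `coords`, `box` (n frames x 3),
#'   `n_frames`, `frame_stride`.
#' @export
cg_trajectory <- function(coords, box, frame_stride = 1) {
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3)
    stop("coords must be an (n_beads, 3, n_frames) array")
  n_frames <- d[3]
  if (is.null(dim(box)))
    box <- matrix(box, nrow = max(n_frames, 1), ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (n_frames > 0 && nrow(box) != n_frames)
    stop("box must have one row per frame")
  if (n_frames > 0 && any(box <= 0)) stop("box lengths must be positive")
  structure(list(coords = coords, box = box, n_frames = n_frames,
                 frame_stride = frame_stride),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Coarse-grained trajectory:", x$n_frames, "frames,",
      dim(x$coords)[1], "beads, stride", x$frame_stride, "\n")
  if (x$n_frames > 0)
    cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n",
                x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Read a trajectory file
#'
#' Supports binary DCD (angstrom-native, read via bio3d, converted to nm)
#' and concatenated multi-frame GRO (nm-native). Every frame must carry an
#' orthorhombic box; triclinic cells are rejected.
#'
#' @param trajectory_path Path to a `.dcd` or `.gro` file.
#' @param system The `cg_system` the frames belong to; the per-frame atom
#'   count must match its bead count.
#' @param frame_stride Saved-iteration interval, recorded on the object.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(trajectory_path, system, frame_stride = 1) {
  if (!file.exists(trajectory_path))
    stop("cannot read trajectory file: ", trajectory_path)
  nbead <- nrow(system)
  ext <- tolower(tools::file_ext(trajectory_path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    cell <- bio3d::read.dcd(trajectory_path, verbose = FALSE, cell = TRUE)
    if (ncol(xyz) != 3 * nbead)
      stop("atom-count mismatch: trajectory has ", ncol(xyz) / 3,
           " atoms per frame, system has ", nbead, " beads")
    if (any(abs(cell[, 4:6] - 90) > 1e-3))
      stop("triclinic boxes are not supported (orthorhombic only)")
    nf <- nrow(xyz)
    coords <- aperm(array(t(xyz) / 10, dim = c(3, nbead, nf)), c(2, 1, 3))
    cg_trajectory(coords, cell[, 1:3, drop = FALSE] / 10, frame_stride)
  } else if (ext == "gro") {
    lines <- readLines(trajectory_path)
    frames <- list(); boxes <- list(); off <- 0
    while (off < length(lines)) {
      fr <- parse_gro_frame(lines, off)
      if (nrow(fr$coords) != nbead)
        stop("atom-count mismatch: trajectory frame has ", nrow(fr$coords),
             " atoms, system has ", nbead, " beads")
      frames[[length(frames) + 1]] <- fr$coords
      boxes[[length(boxes) + 1]] <- fr$box
      off <- fr$next_offset
    }
    nf <- length(frames)
    coords <- array(unlist(frames), dim = c(nbead, 3, nf))
    cg_trajectory(coords, do.call(rbind, boxes), frame_stride)
  } else {
    stop("unsupported trajectory dialect: .", ext,
         " (expected .dcd or .gro)")
  }
}

#' Write a trajectory as a CHARMM-style DCD file
#'
#' Binary little/native-endian DCD with a per-frame unit-cell block,
#' coordinates written in angstrom. Readable by bio3d and standard MD
#' viewers.
#'
#' @param traj A [cg_trajectory()] (coordinates in nm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  nf <- traj$n_frames
  nbead <- dim(traj$coords)[1]
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L   # unit-cell block present
  icntrl[20] <- 24L  # CHARMM version tag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- formatC("Written by lipidsites", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nbead), con, size = 4), 4)
  for (f in seq_len(nf)) {
    b <- traj$box[f, ] * 10
    # XTL convention: a, cos(gamma), b, cos(beta), cos(alpha), c
    rec(function() writeBin(c(b[1], 0, b[2], 0, 0, b[3]), con, size = 8), 48)
    fr <- traj$coords[, , f, drop = FALSE] * 10
    for (k in 1:3)
      rec(function() writeBin(as.numeric(fr[, k, 1]), con, size = 4),
          4 * nbead)
  }
  invisible(path)
}

#' Write a trajectory as a concatenated multi-frame GRO file
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system` (for names and residue ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_gro <- function(traj, system, path) {
  out <- character(0)
  for (f in seq_len(traj$n_frames)) {
    out <- c(out,
             sprintf("frame %d", f),
             sprintf("%5d", nrow(system)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     system$residue_id %% 100000L,
                     substr(system$residue_name, 1, 5),
                     substr(system$bead_name, 1, 5),
                     system$bead_index %% 100000L,
                     traj$coords[, 1, f], traj$coords[, 2, f],
                     traj$coords[, 3, f]),
             sprintf("%10.5f%10.5f%10.5f",
                     traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Assign each lipid to a bilayer leaflet
#'
#' The bilayer midplane is the mean z of all phosphate beads in the
#' reference frame; a lipid is `external` when its phosphate lies above
#' the midplane, `internal` otherwise. Assignment is made once per
#' trajectory from the reference frame. Lipids whose frame-by-frame
#' assignment (against the per-frame midplane) would differ from the
#' reference assignment in more than 10% of frames are reported in a
#' flip-flop warning.
#'
#' @param system A `cg_system` containing lipids.
#' @param traj The matching [cg_trajectory()].
#' @param reference_frame Frame used for the assignment (default 1).
#' @return A `leaflet_assignment` data frame with columns `lipid_id`,
#'   `leaflet` and attribute `midplane_z` (nm).
#' @export
assign_leaflets <- function(system, traj, reference_frame = 1) {
  ph <- which(system$bead_class == "phosphate")
  if (!length(ph)) stop("no lipids present: no phosphate beads in system")
  if (traj$n_frames < 1) stop("trajectory has no frames")
  if (reference_frame < 1 || reference_frame > traj$n_frames)
    stop("reference_frame out of range")
  lip <- system$lipid_id[ph]
  zref <- traj$coords[ph, 3, reference_frame]
  mid <- mean(zref)
  leaflet <- ifelse(zref > mid, "external", "internal")
  if (length(unique(leaflet)) == 1)
    warning("all lipids assigned to one leaflet (", leaflet[1], ")")
  # flip-flop audit across all frames
  if (traj$n_frames > 1) {
    zs <- matrix(traj$coords[ph, 3, ], nrow = length(ph))  # lipid x frame
    mids <- colMeans(zs)
    ext <- sweep(zs, 2, mids) > 0
    frac <- rowMeans(ext != (leaflet == "external"))
    if (any(frac > 0.10))
      warning("possible leaflet flip-flop for lipid id(s): ",
              paste(lip[frac > 0.10], collapse = ", "))
  }
  out <- data.frame(lipid_id = lip, leaflet = leaflet,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lipid_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("leaflet_assignment", "data.frame")
  attr(out, "midplane_z") <- mid
  out
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat("Leaflet assignment:", sum(x$leaflet == "external"), "external /",
      sum(x$leaflet == "internal"), "internal lipids; midplane z =",
      sprintf("%.3f nm\n", attr(x, "midplane_z")))
  invisible(x)
}
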