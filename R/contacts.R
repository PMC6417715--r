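#' Find protein-lipid bead pairs within a distance cutoff
#'
#' Returns all (protein bead, lipid bead) pairs whose minimum-image
#' distance on the orthorhombic box is strictly below the cutoff. A cell
#' grid accelerates the search; the result is contractually identical to
#' the all-pairs computation.
#'
#' @param coords (n x 3) bead coordinates of one frame, nm.
#' @param box Length-3 orthorhombic box, nm.
#' @param protein_beads,lipid_beads Integer bead indices of the two sets.
#' @param cutoff Contact distance criterion in nm (default 0.5).
#' @return Data frame with columns `protein_bead`, `lipid_bead`
#'   (original bead indices).
#' @export
find_contacts <- function(coords, box, protein_beads, lipid_beads,
                          cutoff = 0.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff > min(box) / 2)
    stop("cutoff exceeds half the smallest box length ",
         "(minimum-image violation)")
  if (!length(protein_beads) || !length(lipid_beads))
    return(data.frame(protein_bead = integer(0), lipid_bead = integer(0)))
  pr <- cpp_find_pairs(coords[protein_beads, , drop = FALSE],
                       coords[lipid_beads, , drop = FALSE],
                       as.numeric(box), cutoff)
  data.frame(protein_bead = protein_beads[pr[, 1]],
             lipid_bead = lipid_beads[pr[, 2]])
}

# Shared precomputation for the trajectory contact scan.
contact_indexing <- function(system, helices) {
  prot <- which(system$molecule_kind == "protein")
  lip <- which(system$molecule_kind == "lipid")
  res_ids <- sort(unique(system$residue_id[prot]))
  helix_of_res <- rep(NA_integer_, length(res_ids))
  if (!is.null(helices))
    for (i in seq_len(nrow(helices))) {
      inh <- res_ids >= helices$begin_residue[i] &
        res_ids <= helices$end_residue[i]
      helix_of_res[inh] <- helices$helix_id[i]
    }
  key <- paste(system$lipid_species[lip], system$bead_name[lip], sep = ":")
  key_levels <- unique(key)
  lip_ids <- sort(unique(system$lipid_id[lip]))
  list(prot = prot, lip = lip, res_ids = res_ids,
       helix_of_res = helix_of_res,
       pres_row = match(system$residue_id[prot], res_ids) - 1L,
       phelix = ifelse(is.na(helix_of_res[match(system$residue_id[prot],
                                                res_ids)]), -1L,
                       helix_of_res[match(system$residue_id[prot],
                                          res_ids)] - 1L),
       lkey = match(key, key_levels) - 1L, key_levels = key_levels,
       llip = match(system$lipid_id[lip], lip_ids) - 1L,
       lip_ids = lip_ids)
}

#' Accumulate protein-lipid contacts over a trajectory
#'
#' Counts every protein-bead/lipid-bead pair within the cutoff, per
#' frame, keyed by (protein residue, lipid species, lipid bead name);
#' one residue-lipid pair can contribute several bead contacts per
#' frame. Per-frame any-contact events per lipid (used by the occupancy
#' filter) and per-frame contacted-helix sets (used by the site
#' networks) are recorded in the same pass.
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param cutoff Distance criterion in nm (default 0.5, strict `<`).
#' @param helices A `helix_map` used for the helix-set record (default
#'   [default_helix_map()]; pass `NULL` to skip).
#' @return A `contact_table`: list with `counts` (residues x
#'   species:bead keys matrix), `events` (frames x lipids logical),
#'   `sites` (frames x lipids helix bitmask), `residues`, `bead_keys`,
#'   `lipid_ids`, `cutoff`, `n_frames`, and per-bead metadata.
#' @export
accumulate_contacts <- function(traj, system, cutoff = 0.5,
                                helices = default_helix_map()) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (traj$n_frames > 0 && cutoff > min(traj$box) / 2)
    stop("cutoff exceeds half the smallest box length ",
         "(minimum-image violation)")
  ix <- contact_indexing(system, helices)
  nres <- length(ix$res_ids); nkey <- length(ix$key_levels)
  nlip <- length(ix$lip_ids)
  if (traj$n_frames == 0 || !length(ix$prot) || !length(ix$lip)) {
    res <- list(counts = matrix(0, nres, nkey,
                                dimnames = list(ix$res_ids, ix$key_levels)),
                events = matrix(FALSE, traj$n_frames, nlip,
                                dimnames = list(NULL, ix$lip_ids)),
                sites = matrix(0L, traj$n_frames, nlip,
                               dimnames = list(NULL, ix$lip_ids)))
  } else {
    sc <- cpp_traj_contacts(traj$coords, dim(traj$coords), traj$box,
                            ix$prot - 1L, ix$pres_row, ix$phelix,
                            ix$lip - 1L, ix$lkey, ix$llip,
                            cutoff, nres, nkey, nlip)
    res <- list(counts = sc$counts, events = sc$events, sites = sc$sites)
    dimnames(res$counts) <- list(ix$res_ids, ix$key_levels)
    colnames(res$events) <- ix$lip_ids
    colnames(res$sites) <- ix$lip_ids
  }
  meta_res <- match(ix$res_ids, system$residue_id)
  out <- list(counts = res$counts, events = res$events, sites = res$sites,
              residues = data.frame(
                residue_id = ix$res_ids,
                residue_name = system$residue_name[meta_res],
                helix = ix$helix_of_res, stringsAsFactors = FALSE),
              bead_keys = do.call(rbind, strsplit(ix$key_levels, ":",
                                                  fixed = TRUE)),
              lipid_ids = ix$lip_ids, cutoff = cutoff,
              n_frames = traj$n_frames)
  class(out) <- "contact_table"
  out
}

#' @export
print.contact_table <- function(x, ...) {
  cat("Contact table: cutoff", x$cutoff, "nm,", x$n_frames, "frames,",
      sum(x$counts), "bead-pair contacts over", nrow(x$counts),
      "residues\n")
  invisible(x)
}

#' Long-format view of a contact table
#'
#' @param table A `contact_table`.
#' @param drop_zero Drop zero-count rows (default TRUE).
#' @return Data frame with columns `residue_id`, `residue_name`, `helix`,
#'   `lipid_species`, `bead_name`, `bead_class`, `cutoff`, `count`.
#' @export
contact_long <- function(table, drop_zero = TRUE) {
  cnt <- table$counts
  species <- table$bead_keys[, 1]
  beads <- table$bead_keys[, 2]
  cls <- bead_class_of(species, beads)
  out <- data.frame(
    residue_id = rep(table$residues$residue_id, times = ncol(cnt)),
    residue_name = rep(table$residues$residue_name, times = ncol(cnt)),
    helix = rep(table$residues$helix, times = ncol(cnt)),
    lipid_species = rep(species, each = nrow(cnt)),
    bead_name = rep(beads, each = nrow(cnt)),
    bead_class = rep(cls, each = nrow(cnt)),
    cutoff = table$cutoff,
    count = as.vector(cnt),
    stringsAsFactors = FALSE
  )
  if (drop_zero) out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

bead_class_of <- function(species, beads) {
  tabs <- martini_lipids()
  vapply(seq_along(species), function(i) {
    t <- tabs[[species[i]]]
    if (is.null(t)) return(NA_character_)
    m <- match(beads[i], t$bead_name)
    if (is.na(m)) NA_character_ else t$bead_class[m]
  }, character(1))
}

#' Per-bead-type contact totals
#'
#' Aggregates a contact table over protein residues, per lipid species
#' and lipid bead name (the per-bead contact-count profile of the
#' system).
#'
#' @param table A `contact_table`.
#' @return Data frame `lipid_species`, `bead_name`, `bead_class`,
#'   `count`, in intra-lipid bead order.
#' @export
bead_type_counts <- function(table) {
  species <- table$bead_keys[, 1]
  beads <- table$bead_keys[, 2]
  out <- data.frame(lipid_species = species, bead_name = beads,
                    bead_class = bead_class_of(species, beads),
                    count = colSums(table$counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalised per-residue contact-frequency map
#'
#' Residue totals expressed as percentages of the largest per-residue
#' total, so the most-contacted residue maps to 100% and untouched
#' residues to 0%.
#'
#' @param table A `contact_table`.
#' @return A `frequency_map` data frame with columns `residue_id`,
#'   `residue_name`, `helix`, `count`, `frequency_pct`.
#' @export
frequency_map <- function(table) {
  tot <- rowSums(table$counts)
  mx <- max(tot)
  if (mx == 0) {
    warning("contact table is all zero; frequency map is all zero")
    pct <- rep(0, length(tot))
  } else pct <- 100 * tot / mx
  out <- cbind(table$residues,
               data.frame(count = as.numeric(tot), frequency_pct = pct))
  rownames(out) <- NULL
  class(out) <- c("frequency_map", "data.frame")
  attr(out, "cutoff") <- table$cutoff
  out
}

#' @export
plot.frequency_map <- function(x, ...) {
  graphics::barplot(x$frequency_pct, names.arg = x$residue_id,
                    xlab = "residue", ylab = "contact frequency (%)",
                    border = NA, ...)
  invisible(x)
}

#' Cutoff-sensitivity analysis of the contact frequency map
#'
#' Recomputes the frequency map at each cutoff and measures the Spearman
#' rank agreement between every pair of maps over residues with at least
#' one contact at either cutoff of the pair. Raw per-residue counts are
#' non-decreasing in the cutoff by construction (a pair within 0.5 nm is
#' within 0.7 nm).
#'
#' @param traj A [cg_trajectory()].
#' @param system The matching `cg_system`.
#' @param cutoffs Ascending cutoffs in nm (default `c(0.5, 0.6, 0.7)`).
#' @param helices Helix map forwarded to [accumulate_contacts()].
#' @return A `cutoff_sensitivity` list: `maps` (one [frequency_map()]
#'   per cutoff), `residue_counts` (residues x cutoffs matrix),
#'   `rank_agreement` (cutoffs x cutoffs Spearman matrix).
#' @export
cutoff_sensitivity <- function(traj, system, cutoffs = c(0.5, 0.6, 0.7),
                               helices = default_helix_map()) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be sorted ascending")
  tabs <- lapply(cutoffs, function(cc)
    accumulate_contacts(traj, system, cutoff = cc, helices = helices))
  maps <- lapply(tabs, frequency_map)
  names(maps) <- as.character(cutoffs)
  counts <- vapply(tabs, function(t) rowSums(t$counts),
                   numeric(nrow(tabs[[1]]$counts)))
  counts <- matrix(counts, ncol = length(cutoffs),
                   dimnames = list(rownames(tabs[[1]]$counts),
                                   as.character(cutoffs)))
  k <- length(cutoffs)
  rk <- matrix(1, k, k, dimnames = list(cutoffs, cutoffs))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    nz <- counts[, i] > 0 | counts[, j] > 0
    rho <- if (sum(nz) >= 2)
      stats::cor(counts[nz, i], counts[nz, j], method = "spearman")
    else NA_real_
    rk[i, j] <- rk[j, i] <- rho
  }
  structure(list(maps = maps, residue_counts = counts,
                 rank_agreement = rk),
            class = "cutoff_sensitivity")
}

#' @export
print.cutoff_sensitivity <- function(x, ...) {
  cat("Cutoff sensitivity over", ncol(x$residue_counts), "cutoffs (nm):",
      paste(colnames(x$residue_counts), collapse = ", "), "\n")
  cat("Spearman rank agreement:\n")
  print(round(x$rank_agreement, 3))
  invisible(x)
}

#' Write a frequency map as CSV and as an annotated sequence track
#'
#' @param map A [frequency_map()].
#' @param csv_path Output CSV path, or `NULL` to skip.
#' @param track_path Optional FASTA-style two-line-per-block track:
#'   a header, the one-letter/name sequence line and a per-residue
#'   percentage line.
#' @return Invisibly, the map.
#' @export
write_frequency_map <- function(map, csv_path = NULL, track_path = NULL) {
  if (!is.null(csv_path))
    utils::write.table(map, csv_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(track_path)) {
    lines <- c(sprintf(">contact_frequency cutoff=%snm",
                       attr(map, "cutoff")),
               paste(map$residue_name, collapse = " "),
               paste(sprintf("%.1f", map$frequency_pct), collapse = " "))
    writeLines(lines, track_path)
  }
  invisible(map)
}
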