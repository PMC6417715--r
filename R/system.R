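#' Built-in bead tables for common phospholipid species
#'
#' Bead names and classes for the 13-bead POPC and POPE and the 12-bead
#' DPPC coarse-grained lipid models: a choline (CHO) or ethanolamine (NH3)
#' head bead, one phosphate bead (PO4, the per-lipid anchor used for
#' leaflet assignment), two glycerol/ester beads (GL1, GL2) and two acyl
#' chains of 4-5 beads. The D3B bead marks the chain-B unsaturation in
#' POPC/POPE; in DPPC both chains are saturated (C3B) and chain B lacks
#' the terminal C5B bead.
#'
#' @return Named list of data frames, one per species, each with columns
#'   `bead_name` and `bead_class` in intra-lipid order. Classes are
#'   `head`, `phosphate`, `glycerol`, `tailA`, `tailB`.
#' @export
#' @examples
#' martini_lipids()$POPC
martini_lipids <- function() {
  mk <- function(head, tailB) {
    data.frame(
      bead_name = c(head, "PO4", "GL1", "GL2",
                    "C1A", "C2A", "C3A", "C4A", tailB),
      bead_class = c("head", "phosphate", "glycerol", "glycerol",
                     rep("tailA", 4), rep("tailB", length(tailB))),
      stringsAsFactors = FALSE
    )
  }
  list(
    POPC = mk("CHO", c("C1B", "C2B", "D3B", "C4B", "C5B")),
    DPPC = mk("CHO", c("C1B", "C2B", "C3B", "C4B")),
    POPE = mk("NH3", c("C1B", "C2B", "D3B", "C4B", "C5B"))
  )
}

#' Read a lipid species table from a TSV file
#'
#' The file must have columns `species`, `bead_name`, `bead_class`, with
#' one row per bead in intra-lipid order.
#'
#' @param path Path to a tab-separated table.
#' @return Named list of per-species data frames, as [martini_lipids()].
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("cannot read species table: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("species", "bead_name", "bead_class")
  if (!all(need %in% names(tab)))
    stop("species table needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$species)[unique(tab$species)],
         function(d) d[, c("bead_name", "bead_class")])
}

#' Transmembrane helix definitions of the mu opioid receptor
#'
#' Residue ranges of the eight helices of the mu opioid receptor (PDB
#' 4DKL) used throughout the package as the default helix map. Helix H5
#' carries a proline-induced torsion zone: its two sub-segments run
#' 226-240 and 244-257 and the residues strictly between (241-243) belong
#' to neither segment, encoded as `kink_begin`/`kink_end` = 240/244.
#'
#' @return A `helix_map` data frame with columns `helix_id`,
#'   `begin_residue`, `end_residue`, `kink_begin`, `kink_end`.
#' @export
#' @examples
#' default_helix_map()
default_helix_map <- function() {
  hm <- data.frame(
    helix_id = 1:8,
    begin_residue = c(65L, 103L, 138L, 180L, 226L, 273L, 312L, 341L),
    end_residue   = c(95L, 130L, 169L, 204L, 257L, 304L, 340L, 352L),
    kink_begin = c(NA, NA, NA, NA, 240L, NA, NA, NA),
    kink_end   = c(NA, NA, NA, NA, 244L, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  validate_helix_map(hm)
}

#' Read a helix-definition table
#'
#' @param path TSV with columns `helix_id`, `begin_residue`,
#'   `end_residue` and optional `kink_begin`, `kink_end` (or a single
#'   `kink_residue`, taken as both bounds).
#' @return A validated `helix_map` data frame.
#' @export
read_helix_map <- function(path) {
  hm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("kink_residue" %in% names(hm) && !("kink_begin" %in% names(hm))) {
    hm$kink_begin <- hm$kink_residue
    hm$kink_end <- hm$kink_residue
  }
  if (!("kink_begin" %in% names(hm))) hm$kink_begin <- NA_integer_
  if (!("kink_end" %in% names(hm))) hm$kink_end <- NA_integer_
  validate_helix_map(hm[, c("helix_id", "begin_residue", "end_residue",
                            "kink_begin", "kink_end")])
}

validate_helix_map <- function(hm) {
  stopifnot(all(c("helix_id", "begin_residue", "end_residue") %in% names(hm)))
  if (any(hm$begin_residue > hm$end_residue))
    stop("helix map: begin_residue must be <= end_residue")
  rngs <- mapply(seq, hm$begin_residue, hm$end_residue, SIMPLIFY = FALSE)
  if (anyDuplicated(unlist(rngs)))
    stop("helix map: helix residue ranges must be pairwise disjoint")
  kb <- hm$kink_begin; ke <- hm$kink_end
  has <- !is.na(kb)
  if (any(has & is.na(ke)) || any(!has & !is.na(ke)))
    stop("helix map: kink_begin and kink_end must be given together")
  if (any(has & (kb <= hm$begin_residue | ke >= hm$end_residue | kb > ke)))
    stop("helix map: kink bounds must lie strictly inside the helix range")
  class(hm) <- c("helix_map", "data.frame")
  hm
}

new_cg_system <- function(df, coords = NULL, box = NULL) {
  need <- c("bead_index", "bead_name", "bead_class", "residue_id",
            "residue_name", "molecule_kind", "lipid_species", "lipid_id")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$bead_index)) stop("duplicate bead index in system")
  class(df) <- c("cg_system", "data.frame")
  attr(df, "coords") <- coords
  attr(df, "box") <- box
  df
}

#' Reference coordinates stored with a system
#'
#' @param system A `cg_system`.
#' @return Matrix (n beads x 3) of the structure-file coordinates, in nm.
#' @export
system_coords <- function(system) attr(system, "coords")

#' @export
print.cg_system <- function(x, ...) {
  kinds <- table(x$molecule_kind)
  cat("Coarse-grained system:", nrow(x), "beads\n")
  for (k in names(kinds)) cat(sprintf("  %-8s %6d beads\n", k, kinds[[k]]))
  if (any(x$molecule_kind == "lipid")) {
    sp <- table(x$lipid_species[!is.na(x$lipid_id) & !duplicated(x$lipid_id)])
    cat("  lipids: ",
        paste(sprintf("%s x %d", names(sp), as.integer(sp)), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(attr(x, "box")))
    cat(sprintf("  box: %.3f x %.3f x %.3f nm\n",
                attr(x, "box")[1], attr(x, "box")[2], attr(x, "box")[3]))
  invisible(x)
}

# Amino-acid residue names accepted as protein, plus the generic CG
# backbone placeholder used by the synthetic generator.
.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
  "TYR", "VAL", "BB"
)

#' Read a coarse-grained structure file and classify its beads
#'
#' Parses a PDB (via bio3d, angstrom-native) or GRO (nm-native) structure
#' and classifies every bead as protein, lipid, solvent or ion. Lipid
#' residues are matched against the species table and their beads receive
#' the table's bead classes; each lipid gets a sequential `lipid_id`.
#' Coordinates are converted to nm on read and stored as an attribute
#' (see [system_coords()]).
#'
#' @param structure_path Path to a `.pdb` or `.gro` file.
#' @param species Named list of per-species bead tables
#'   (default [martini_lipids()]).
#' @param solvent_names,ion_names Residue names classified as solvent/ion.
#' @return A `cg_system` data frame (one row per bead) with attributes
#'   `coords` (nm) and `box` (nm, or NULL if the file has no box).
#' @export
read_system <- function(structure_path, species = martini_lipids(),
                        solvent_names = c("W", "WF", "PW"),
                        ion_names = c("ION", "NA", "CL", "NA+", "CL-")) {
  if (!file.exists(structure_path))
    stop("cannot read structure file: ", structure_path)
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "gro") {
    parsed <- parse_gro_frame(readLines(structure_path))
    atoms <- parsed$atoms
    coords <- parsed$coords
    box <- parsed$box
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
    at <- pdb$atom
    atoms <- data.frame(residue_id = at$resno, residue_name = at$resid,
                        bead_name = at$elety, stringsAsFactors = FALSE)
    coords <- cbind(at$x, at$y, at$z) / 10  # angstrom -> nm
    box <- pdb_box_nm(structure_path)
  } else {
    stop("unsupported structure dialect: .", ext,
         " (expected .pdb or .gro)")
  }
  classify_beads(atoms, coords, box, species, solvent_names, ion_names)
}

classify_beads <- function(atoms, coords, box, species,
                           solvent_names, ion_names) {
  n <- nrow(atoms)
  kind <- rep("solvent", n)
  kind[toupper(atoms$residue_name) %in% .protein_resnames] <- "protein"
  kind[atoms$residue_name %in% names(species)] <- "lipid"
  kind[toupper(atoms$residue_name) %in% toupper(ion_names)] <- "ion"
  lipid_species <- ifelse(kind == "lipid", atoms$residue_name, NA_character_)

  # residue_id can wrap in file formats; use change points for molecules
  res_key <- cumsum(c(TRUE, atoms$residue_id[-1] != atoms$residue_id[-n] |
                        atoms$residue_name[-1] != atoms$residue_name[-n]))
  lipid_id <- rep(NA_integer_, n)
  is_lip <- kind == "lipid"
  if (any(is_lip))
    lipid_id[is_lip] <- as.integer(factor(res_key[is_lip],
                                          levels = unique(res_key[is_lip])))
  bead_class <- rep(NA_character_, n)
  bead_class[kind == "protein"] <- "backbone"
  for (sp in names(species)) {
    tab <- species[[sp]]
    sel <- which(is_lip & lipid_species == sp)
    if (!length(sel)) next
    m <- match(atoms$bead_name[sel], tab$bead_name)
    if (anyNA(m))
      stop("lipid species ", sp, " has beads not in the species table: ",
           paste(unique(atoms$bead_name[sel][is.na(m)]), collapse = ", "))
    bead_class[sel] <- tab$bead_class[m]
    # every lipid of a species must carry the identical ordered bead list
    per <- split(atoms$bead_name[sel], lipid_id[sel])
    ref <- tab$bead_name
    ok <- vapply(per, function(b) identical(b, ref), logical(1))
    if (!all(ok))
      stop("lipid(s) of species ", sp,
           " do not match the species bead list (missing/extra beads): ",
           paste(names(per)[!ok], collapse = ", "))
  }
  sys <- new_cg_system(data.frame(
    bead_index = seq_len(n),
    bead_name = atoms$bead_name,
    bead_class = bead_class,
    residue_id = atoms$residue_id,
    residue_name = atoms$residue_name,
    molecule_kind = kind,
    lipid_species = lipid_species,
    lipid_id = lipid_id,
    stringsAsFactors = FALSE
  ), coords = coords, box = box)
  # one phosphate bead per lipid
  if (any(is_lip)) {
    nph <- tapply(sys$bead_class[is_lip] == "phosphate",
                  sys$lipid_id[is_lip], sum)
    if (any(nph != 1))
      stop("every lipid must have exactly one phosphate bead; offending ",
           "lipid ids: ", paste(names(nph)[nph != 1], collapse = ", "))
  }
  sys
}

parse_gro_frame <- function(lines, offset = 0) {
  if (length(lines) < offset + 3) stop("truncated GRO input")
  natom <- as.integer(trimws(lines[offset + 2]))
  if (is.na(natom)) stop("bad GRO atom-count line")
  if (length(lines) < offset + 2 + natom + 1) stop("truncated GRO frame")
  al <- lines[offset + 2 + seq_len(natom)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  bead <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  boxl <- as.numeric(strsplit(trimws(lines[offset + 2 + natom + 1]),
                              "[[:space:]]+")[[1]])
  if (length(boxl) < 3 || anyNA(boxl[1:3]))
    stop("missing or malformed GRO box line")
  if (length(boxl) > 3 && any(abs(boxl[-(1:3)]) > 1e-9))
    stop("triclinic boxes are not supported (orthorhombic only)")
  list(atoms = data.frame(residue_id = resid, residue_name = resname,
                          bead_name = bead, stringsAsFactors = FALSE),
       coords = cbind(x, y, z), box = boxl[1:3],
       next_offset = offset + 2 + natom + 1)
}

pdb_box_nm <- function(path) {
  hdr <- readLines(path, n = 200)
  cr <- grep("^CRYST1", hdr, value = TRUE)
  if (!length(cr)) return(NULL)
  abc <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33)))
  ang <- as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                      substr(cr[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("triclinic boxes are not supported (orthorhombic only)")
  abc / 10
}

#' Write a system to a structure file
#'
#' Writes a PDB (angstrom) or GRO (nm) file, chosen by extension,
#' preserving bead order, names and residue ids so that
#' `read_system(write_system(...))` round-trips.
#'
#' @param system A `cg_system`.
#' @param path Output path ending in `.pdb` or `.gro`.
#' @param coords Bead coordinates in nm (default: the system's stored
#'   reference coordinates).
#' @param box Box lengths in nm (default: the system's stored box).
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path, coords = system_coords(system),
                         box = attr(system, "box")) {
  stopifnot(!is.null(coords), nrow(coords) == nrow(system))
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    lines <- c(
      "coarse-grained system written by lipidsites",
      sprintf("%5d", nrow(system)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              system$residue_id %% 100000L,
              substr(system$residue_name, 1, 5),
              substr(system$bead_name, 1, 5),
              system$bead_index %% 100000L,
              coords[, 1], coords[, 2], coords[, 3]),
      if (is.null(box)) "   0.000   0.000   0.000" else
        sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
    )
    writeLines(lines, path)
  } else if (ext == "pdb") {
    xyz <- coords * 10
    lines <- character(0)
    if (!is.null(box))
      lines <- sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90)
    nm <- ifelse(nchar(system$bead_name) < 4,
                 sprintf(" %-3s", system$bead_name),
                 substr(system$bead_name, 1, 4))
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      system$bead_index %% 100000L, nm,
      substr(system$residue_name, 1, 4), system$residue_id %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3]), "END")
    writeLines(lines, path)
  } else {
    stop("unsupported structure dialect: .", ext)
  }
  invisible(path)
}
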