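test_that("a 13-bead POPC record set yields one classified lipid", {
  tab <- martini_lipids()$POPC
  df <- data.frame(residue_id = rep(1L, 13), residue_name = "POPC",
                   bead_name = tab$bead_name, stringsAsFactors = FALSE)
  co <- cbind(runif(13), runif(13), runif(13))
  sys <- lipidsites:::classify_beads(df, co, c(5, 5, 9),
                                     martini_lipids(),
                                     c("W"), c("ION"))
  expect_equal(nrow(sys), 13)
  expect_true(all(sys$molecule_kind == "lipid"))
  expect_equal(sys$bead_class[sys$bead_name == "PO4"], "phosphate")
  expect_equal(unique(sys$lipid_id), 1L)
  expect_equal(sum(sys$bead_class == "phosphate"), 1)
})

test_that("an empty protein section is not an error", {
  tab <- martini_lipids()$DPPC
  df <- data.frame(residue_id = rep(1:2, each = 12),
                   residue_name = "DPPC",
                   bead_name = rep(tab$bead_name, 2),
                   stringsAsFactors = FALSE)
  co <- matrix(runif(72), ncol = 3)
  sys <- lipidsites:::classify_beads(df, co, c(5, 5, 9),
                                     martini_lipids(), c("W"), c("ION"))
  expect_equal(sum(sys$molecule_kind == "protein"), 0)
  expect_equal(max(sys$lipid_id), 2L)
})

test_that("a lipid with a wrong bead list is rejected", {
  tab <- martini_lipids()$POPC
  df <- data.frame(residue_id = rep(1L, 12), residue_name = "POPC",
                   bead_name = tab$bead_name[-2],  # drop PO4
                   stringsAsFactors = FALSE)
  co <- matrix(runif(36), ncol = 3)
  expect_error(
    lipidsites:::classify_beads(df, co, c(5, 5, 9), martini_lipids(),
                                c("W"), c("ION")),
    "species bead list")
})

test_that("helix tables read from TSV, with single-kink shorthand", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(default_helix_map()), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  hm <- read_helix_map(f)
  expect_equal(as.data.frame(hm), as.data.frame(default_helix_map()))
  # a single kink_residue is taken as both bounds
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("helix_id\tbegin_residue\tend_residue\tkink_residue",
               "1\t10\t40\t25"), f2)
  hm2 <- read_helix_map(f2)
  expect_equal(hm2$kink_begin, 25)
  expect_equal(hm2$kink_end, 25)
  # overlapping ranges are invalid
  expect_error(lipidsites:::validate_helix_map(data.frame(
    helix_id = 1:2, begin_residue = c(1, 15), end_residue = c(20, 30),
    kink_begin = NA, kink_end = NA)), "disjoint")
})

test_that("the shipped species table matches the built-in defaults", {
  tsv <- system.file("extdata", "martini_species.tsv",
                     package = "lipidsites")
  tab <- read_species_table(tsv)
  builtin <- martini_lipids()
  expect_setequal(names(tab), names(builtin))
  for (sp in names(builtin))
    expect_equal(as.data.frame(tab[[sp]]), as.data.frame(builtin[[sp]]),
                 ignore_attr = TRUE)
  expect_error(read_species_table(tempfile()), "cannot")
})

test_that("structure round trip preserves bead order, names, residue ids", {
  fx <- generate_cg_trajectory(tiny_config(), seed = 5)
  dir <- withr::local_tempdir()
  for (ext in c("pdb", "gro")) {
    p <- file.path(dir, paste0("s.", ext))
    write_system(fx$system, p)
    back <- read_system(p)
    expect_identical(back$bead_name, fx$system$bead_name)
    expect_identical(back$residue_id, fx$system$residue_id)
    expect_identical(back$bead_index, fx$system$bead_index)
    expect_identical(back$molecule_kind, fx$system$molecule_kind)
    expect_identical(back$bead_class, fx$system$bead_class)
  }
})

test_that("angstrom- and nm-native dialects agree to 1e-6 nm", {
  # coordinates on a 0.001 nm grid are exactly representable in both
  # the PDB (0.001 A) and the GRO (0.001 nm) fixed-decimal fields
  fx <- generate_cg_trajectory(tiny_config(), seed = 6)
  co <- round(system_coords(fx$system), 3)
  dir <- withr::local_tempdir()
  write_system(fx$system, file.path(dir, "s.pdb"), coords = co)
  write_system(fx$system, file.path(dir, "s.gro"), coords = co)
  a <- system_coords(read_system(file.path(dir, "s.pdb")))
  b <- system_coords(read_system(file.path(dir, "s.gro")))
  expect_lt(max(abs(a - b)), 1e-6)
  expect_lt(max(abs(a - co)), 1e-6)
})

test_that("trajectory reading checks frame count and atom count", {
  fx <- generate_cg_trajectory(tiny_config(n_frames = 10), seed = 7)
  dir <- withr::local_tempdir()
  dcd <- file.path(dir, "t.dcd")
  write_dcd(fx$trajectory, dcd)
  tr <- read_trajectory(dcd, fx$system)
  expect_equal(tr$n_frames, 10)
  expect_lt(max(abs(tr$coords - fx$trajectory$coords)), 1e-5)
  expect_equal(tr$box, fx$trajectory$box, ignore_attr = TRUE)

  smaller <- fx$system[1:100, ]
  expect_error(read_trajectory(dcd, smaller), "atom-count mismatch")

  # GRO single frame
  gro <- file.path(dir, "one.gro")
  one <- cg_trajectory(fx$trajectory$coords[, , 1, drop = FALSE],
                       fx$trajectory$box[1, ])
  write_trajectory_gro(one, fx$system, gro)
  tg <- read_trajectory(gro, fx$system)
  expect_equal(tg$n_frames, 1)
})

test_that("triclinic boxes are rejected", {
  lines <- c("t", "    1",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "POPC", "PO4",
                     1L, 1, 1, 1),
             "   5.0   5.0   9.0   0.0   0.0   1.2")
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, f)
  expect_error(read_system(f), "triclinic")
})

test_that("leaflet assignment splits phosphates about the midplane", {
  # two lipids at z = +/- 1.9 nm about a zero midplane
  sys <- toy_system(integer(0), matrix(0, 0, 3),
                    rbind(c(1, 1, 1.9), c(1, 1, -1.9)), c(5, 5, 9))
  traj <- one_frame_traj(sys, c(5, 5, 9))
  lf <- assign_leaflets(sys, traj)
  expect_equal(lf$leaflet, c("external", "internal"))
  expect_equal(attr(lf, "midplane_z"), 0)
})

test_that("one-sided bilayers trigger a warning, empty systems an error", {
  sys <- toy_system(integer(0), matrix(0, 0, 3),
                    rbind(c(1, 1, 1.9), c(2, 2, 1.9)), c(5, 5, 9))
  traj <- one_frame_traj(sys, c(5, 5, 9))
  expect_warning(assign_leaflets(sys, traj), "one leaflet")
  psys <- toy_system(1:5, matrix(rnorm(15), 5, 3),
                     matrix(0, 0, 3), c(5, 5, 9))
  expect_error(assign_leaflets(psys, one_frame_traj(psys, c(5, 5, 9))),
               "no lipids")
})

test_that("a symmetric 600-lipid bilayer splits 300/300 and matches the
           generator ground truth exactly", {
  cfg <- generator_config(n_lipids_per_leaflet = 300, n_frames = 3)
  fx <- generate_cg_trajectory(cfg, seed = 9)
  lf <- assign_leaflets(fx$system, fx$trajectory)
  expect_equal(sum(lf$leaflet == "external"), 300)
  expect_equal(sum(lf$leaflet == "internal"), 300)
  truth <- fx$truth$leaflets[order(fx$truth$leaflets$lipid_id), ]
  expect_equal(lf$leaflet, truth$leaflet)
})
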