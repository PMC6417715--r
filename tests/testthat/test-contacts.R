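test_that("the distance criterion is a strict inequality", {
  co <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.5, 0, 0))
  box <- c(10, 10, 10)
  p <- find_contacts(co, box, 1, 2:3, cutoff = 0.5)
  expect_equal(nrow(p), 1)
  expect_equal(p$lipid_bead, 2)
})

test_that("minimum image wraps across periodic boundaries", {
  co <- rbind(c(0.1, 5, 5), c(9.9, 5, 5))
  p <- find_contacts(co, c(10, 10, 10), 1, 2, cutoff = 0.5)
  expect_equal(nrow(p), 1)  # true separation 0.2
})

test_that("cutoffs beyond the minimum-image bound are rejected", {
  co <- matrix(runif(30), 10, 3)
  expect_error(find_contacts(co, c(1, 10, 10), 1:5, 6:10, cutoff = 0.6),
               "minimum-image")
  expect_error(find_contacts(co, c(10, 10, 10), 1:5, 6:10, cutoff = 0),
               "positive")
})

test_that("grid search equals brute force on random periodic systems", {
  set.seed(77)
  for (i in 1:20) {
    box <- runif(3, 2, 10)
    na <- sample(20:120, 1); nb <- sample(100:500, 1)
    co <- cbind(runif(na + nb, -5, 15), runif(na + nb, -5, 15),
                runif(na + nb, -5, 15))
    cutoff <- runif(1, 0.2, min(box) / 2 - 1e-6)
    ours <- find_contacts(co, box, 1:na, na + 1:nb, cutoff)
    oracle <- brute_pairs(co[1:na, , drop = FALSE],
                          co[na + 1:nb, , drop = FALSE], box, cutoff)
    got <- ours[order(ours$protein_bead, ours$lipid_bead), ]
    expect_equal(unname(got$protein_bead), unname(oracle[, 1]))
    expect_equal(unname(got$lipid_bead), unname(oracle[, 2]) + na)
  }
})

test_that("accumulation is linear in repeated frames", {
  sys <- toy_system(1:4, cbind(seq(0, 0.9, by = 0.3), 0, 0),
                    rbind(c(0.2, 0.3, 0)), c(6, 6, 6))
  co <- system_coords(sys)
  one <- cg_trajectory(array(co, dim = c(nrow(co), 3, 1)), c(6, 6, 6))
  t1 <- accumulate_contacts(one, sys, helices = NULL)
  expect_equal(sum(t1$counts), nrow(find_contacts(
    co, c(6, 6, 6), which(sys$molecule_kind == "protein"),
    which(sys$molecule_kind == "lipid"), 0.5)))
  expect_true(t1$events[1, 1])
  ten <- cg_trajectory(array(rep(co, 10), dim = c(nrow(co), 3, 10)),
                       c(6, 6, 6))
  t10 <- accumulate_contacts(ten, sys, helices = NULL)
  expect_equal(t10$counts, 10 * t1$counts)
})

test_that("concatenating two trajectory halves sums the counts", {
  fx <- generate_cg_trajectory(tiny_config(n_frames = 20), seed = 14)
  tr <- fx$trajectory
  half <- function(idx) cg_trajectory(tr$coords[, , idx, drop = FALSE],
                                      tr$box[idx, , drop = FALSE])
  a <- accumulate_contacts(half(1:10), fx$system)
  b <- accumulate_contacts(half(11:20), fx$system)
  whole <- accumulate_contacts(tr, fx$system)
  expect_equal(whole$counts, a$counts + b$counts)
})

test_that("frequency maps normalise to the most-contacted residue", {
  sys <- toy_system(1:3, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                    rbind(c(0, 0.3, 0), c(1, 0.3, 0), c(1, -0.3, 0)),
                    c(8, 8, 8))
  tab <- accumulate_contacts(one_frame_traj(sys, c(8, 8, 8)), sys,
                             helices = NULL)
  fm <- frequency_map(tab)
  pct <- setNames(fm$frequency_pct, fm$residue_id)
  # residue 2 touches two lipid columns (4 bead pairs), residue 1 one,
  # residue 3 none
  expect_equal(unname(pct["2"]), 100)
  expect_equal(unname(pct["1"]), 50)
  expect_equal(unname(pct["3"]), 0)
  expect_true(all(fm$frequency_pct >= 0 & fm$frequency_pct <= 100))
})

test_that("an all-zero table maps to zero with a warning", {
  sys <- toy_system(1:3, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                    rbind(c(4, 4, 0)), c(8, 8, 8))
  tab <- accumulate_contacts(one_frame_traj(sys, c(8, 8, 8)), sys,
                             helices = NULL)
  expect_warning(fm <- frequency_map(tab), "all zero")
  expect_true(all(fm$frequency_pct == 0))
})

test_that("per-bead-class aggregation sums to the residue totals", {
  fx <- generate_cg_trajectory(tiny_config(n_frames = 10), seed = 15)
  tab <- accumulate_contacts(fx$trajectory, fx$system)
  btc <- bead_type_counts(tab)
  expect_equal(sum(btc$count), sum(rowSums(tab$counts)))
  expect_false(anyNA(btc$bead_class))
  long <- contact_long(tab)
  agg <- tapply(long$count, long$residue_id, sum)
  tot <- rowSums(tab$counts)
  expect_equal(as.vector(agg), unname(tot[names(agg)]))
})

test_that("raw counts are non-decreasing in the cutoff and empty lipid
           sets give empty maps", {
  fx <- generate_cg_trajectory(tiny_config(n_frames = 10), seed = 16)
  cs <- cutoff_sensitivity(fx$trajectory, fx$system)
  rc <- cs$residue_counts
  expect_true(all(rc[, 2] >= rc[, 1]))
  expect_true(all(rc[, 3] >= rc[, 2]))
  expect_error(cutoff_sensitivity(fx$trajectory, fx$system,
                                  cutoffs = c(0.7, 0.5)), "ascending")
  psys <- toy_system(1:5, cbind(1:5 / 10, 0, 0), matrix(0, 0, 3),
                     c(6, 6, 6))
  cs0 <- suppressWarnings(cutoff_sensitivity(
    one_frame_traj(psys, c(6, 6, 6)), psys, helices = NULL))
  expect_true(all(cs0$residue_counts == 0))
})

test_that("a planted 2:1 contact ratio appears in the frequency map", {
  # residue 1 is contacted by two lipids in every frame, residue 5 by
  # one: planted ratio 2:1
  sys <- toy_system(c(1, 5), rbind(c(0, 0, 0), c(3, 0, 0)),
                    rbind(c(0, 0.3, 0), c(0, -0.3, 0), c(3, 0.3, 0)),
                    c(9, 9, 9))
  tr <- one_frame_traj(sys, c(9, 9, 9))
  fm <- frequency_map(accumulate_contacts(tr, sys, helices = NULL))
  pct <- setNames(fm$frequency_pct, fm$residue_id)
  expect_equal(unname(pct["1"]), 100)
  expect_equal(unname(pct["5"]), 50)
})
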