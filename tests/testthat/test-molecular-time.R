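grid_T <- seq(0.1, 0.9, by = 0.1)

test_that("every estimator is exact on the model's expected counts", {
  for (T in grid_T) {
    ex21 <- expected_multiplicity_counts(gain_event_spec("s", 2, 1, T, 100))
    expect_equal(time_trisomy(ex21), T, tolerance = 1e-12)
    ex20 <- expected_multiplicity_counts(gain_event_spec("s", 2, 0, T, 100))
    expect_equal(time_cnloh(ex20), T, tolerance = 1e-12)
  }
  pairs <- t(combn(grid_T, 2))
  for (i in seq_len(nrow(pairs))) {
    ex <- expected_multiplicity_counts(
      gain_event_spec("s", 3, 1, pairs[i, ], 120))
    expect_equal(unname(time_multigain(ex, "3:1")), pairs[i, ],
                 tolerance = 1e-12)
  }
  triples <- t(combn(grid_T, 3))
  for (i in seq_len(nrow(triples))) {
    ex <- expected_multiplicity_counts(
      gain_event_spec("s", 4, 1, triples[i, ], 100))
    expect_equal(unname(time_multigain(ex, "4:1")), triples[i, ],
                 tolerance = 1e-12)
  }
})

test_that("trisomy timing boundary and example values", {
  expect_equal(time_trisomy(c(CN2 = 0, CN1 = 200)), 0)
  expect_equal(time_trisomy(c(CN2 = 70, CN1 = 70)), 1)
  expect_equal(time_trisomy(c(CN2 = 60, CN1 = 180)), 0.6)
  expect_error(time_trisomy(c(CN1 = 10, CN2 = 5, CN3 = 2)), "inconsistent")
  expect_error(time_trisomy(c(CN1 = 0, CN2 = 0)), "no assigned")
})

test_that("CN-LOH default estimator is model-consistent where the printed form overshoots", {
  expect_equal(time_cnloh(c(CN2 = 0, CN1 = 100)), 0)
  # all lineage mutations duplicated: default hits T = 1, the as-printed
  # form reaches 2 before clipping
  expect_equal(time_cnloh(c(CN2 = 80, CN1 = 0)), 1)
  raw <- 2 * 80 / (80 + 0)
  expect_equal(raw, 2)
  expect_equal(time_cnloh(c(CN2 = 80, CN1 = 0), mode = "as-printed"), 1)
  expect_equal(time_cnloh(c(CN2 = 50, CN1 = 100)), 0.5)
})

test_that("multi-gain timing matches the printed formulas and stays ordered", {
  expect_equal(unname(time_multigain(c(CN3 = 30, CN2 = 30, CN1 = 330),
                                     "3:1")), c(0.25, 0.5))
  expect_equal(unname(time_multigain(
    c(CN4 = 20, CN3 = 30, CN2 = 30, CN1 = 270), "4:1")), c(0.2, 0.5, 0.8))
  expect_equal(unname(time_multigain(c(CN3 = 0, CN2 = 40, CN1 = 200),
                                     "3:1"))[1], 0)
  # order preservation under arbitrary noisy counts
  set.seed(41)
  for (i in 1:100) {
    cn <- c(CN1 = rpois(1, 150), CN2 = rpois(1, 30), CN3 = rpois(1, 25),
            CN4 = rpois(1, 15))
    t4 <- time_multigain(cn, "4:1")
    expect_true(all(diff(t4) >= 0))
    expect_true(all(t4 >= 0 & t4 <= 1))
    t3 <- time_multigain(cn[1:3], "3:1")
    expect_true(all(diff(t3) >= 0))
  }
})

test_that("single versus sequential gain calls follow the cluster structure", {
  # one cluster of tripled SNVs, no doubled cluster: one single event
  expect_equal(single_vs_sequential(c(CN3 = 40, CN2 = 0, CN1 = 200), "3:1"),
               "single")
  # distinct tripled and doubled clusters: two independent gains
  expect_equal(single_vs_sequential(c(CN3 = 40, CN2 = 35, CN1 = 200),
                                    "3:1"), "sequential")
  expect_equal(single_vs_sequential(c(CN1 = 0), "3:1"), "indeterminate")
  # a 2:2-style tetrasomy shows only one duplicated cluster
  expect_equal(single_vs_sequential(c(CN2 = 50, CN1 = 120), "2:2"),
               "single")
  expect_error(single_vs_sequential(c(CN2 = 10, CN1 = 10), "2:1"),
               "extra copies")
})

test_that("bootstrap intervals contain the point estimate and shrink with n", {
  set.seed(42)
  classes <- rep(c(1L, 2L), c(140, 60))
  bt <- bootstrap_timing(classes, "2:1", n_boot = 500, seed = 1,
                         segment_id = "seg1")
  expect_true(bt$ci["lower", 1] <= bt$estimates[1] &&
                bt$estimates[1] <= bt$ci["upper", 1])
  expect_identical(bootstrap_timing(classes, "2:1", n_boot = 200, seed = 9)$ci,
                   bootstrap_timing(classes, "2:1", n_boot = 200, seed = 9)$ci)
  # doubling the mutation count halves the interval width (sqrt-n scaling)
  w1 <- median(replicate(20, {
    cl <- rep(c(1L, 2L), c(140, 60))
    b <- bootstrap_timing(cl, "2:1", n_boot = 300,
                          seed = sample.int(1e6, 1))
    diff(b$ci[, 1])
  }))
  w2 <- median(replicate(20, {
    cl <- rep(c(1L, 2L), c(280, 120))
    b <- bootstrap_timing(cl, "2:1", n_boot = 300,
                          seed = sample.int(1e6, 1))
    diff(b$ci[, 1])
  }))
  expect_equal(w2 / w1, 1 / sqrt(2), tolerance = 0.2)
  expect_error(bootstrap_timing(classes, "2:1", n_boot = 50), "n_boot")
  expect_error(bootstrap_timing(c(1L), "2:1"), "at least 2")
})

test_that("time windows recover planted groupings and respect serial evidence", {
  # a single segment forms one window
  one <- bootstrap_timing(rep(c(1L, 2L), c(100, 50)), "2:1", n_boot = 200,
                          seed = 2, segment_id = "only")
  expect_identical(group_time_windows(list(one)), c(only = 1L))

  # two well-separated planted windows
  set.seed(43)
  mk <- function(T, id) {
    am <- sim_segment_fit("2:1", T, rate = 200, depth = 60)
    bootstrap_timing(am, "2:1", n_boot = 200, seed = sample.int(1e6, 1),
                     segment_id = id)
  }
  timings <- list(mk(0.1, "a"), mk(0.1, "b"), mk(0.1, "c"),
                  mk(0.7, "d"), mk(0.7, "e"))
  w <- group_time_windows(timings)
  expect_equal(unname(w), c(1L, 1L, 1L, 2L, 2L))

  # fully overlapping bootstrap distributions share a window
  same <- list(mk(0.4, "x"), mk(0.4, "y"))
  expect_equal(length(unique(group_time_windows(same))), 1L)

  # serial rule: a gain absent at diagnosis is forced past gains present
  presence <- rbind(a = c(TRUE, TRUE), b = c(TRUE, TRUE),
                    c = c(TRUE, TRUE), d = c(TRUE, TRUE),
                    e = c(FALSE, TRUE))
  w2 <- group_time_windows(timings, serial_presence = presence)
  expect_gt(w2["e"], max(w2[c("a", "b", "c", "d")]))
})

test_that("ploidy is length-weighted and the WGD threshold is strict", {
  segs <- data.frame(start = c(1, 1), end = c(1e7, 1e7),
                     total_cn = c(2, 2))
  p <- genome_ploidy(segs, "s1")
  expect_equal(p$ploidy, 2)
  expect_false(p$wgd)
  # equal lengths of CN 2 and CN 4 average to exactly 3: not WGD
  segs$total_cn <- c(2, 4)
  p3 <- genome_ploidy(segs)
  expect_equal(p3$ploidy, 3)
  expect_false(p3$wgd)
  segs$total_cn <- c(4, 4)
  expect_true(genome_ploidy(segs)$wgd)
  # unequal lengths weight accordingly
  segs2 <- data.frame(start = c(1, 1), end = c(3e7, 1e7),
                      major_cn = c(2, 1), minor_cn = c(2, 1))
  expect_equal(genome_ploidy(segs2)$ploidy, (3e7 * 4 + 1e7 * 2) / 4e7)
  expect_error(genome_ploidy(segs2[0, ]), "empty")
})
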