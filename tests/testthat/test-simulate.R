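test_that("gain histories match closed-form expectations", {
  # trisomy at T = 0: the gain precedes every mutation, so nothing is
  # duplicated
  h0 <- simulate_gain_history(gain_event_spec("s", 2, 1, 0, rate = 100),
                              seed = 1)
  expect_equal(sum(h0$multiplicity == 2), 0)

  # Monte-Carlo means against E[CN2] = rT, E[CN1] = r(3 - 2T)
  set.seed(42)
  reps <- 500
  counts <- t(vapply(seq_len(reps), function(i) {
    h <- simulate_gain_history(gain_event_spec("s", 2, 1, 0.6, rate = 100))
    c(sum(h$multiplicity == 1), sum(h$multiplicity == 2))
  }, numeric(2)))
  se <- apply(counts, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(counts[, 1]) - 180), 3 * se[1])
  expect_lt(abs(mean(counts[, 2]) - 60), 3 * se[2])
})

test_that("4:1 chain histories obey the copy-weighted total", {
  spec <- gain_event_spec("s", 4, 1, c(0.2, 0.5, 0.8), rate = 100)
  ex <- expected_multiplicity_counts(spec)
  expect_equal(unname(ex), c(270, 30, 30, 20))
  # weighted sum equals (number of terminal copies) x rate
  expect_equal(sum(seq_len(4) * ex), 5 * 100)
  set.seed(7)
  h <- do.call(rbind, lapply(1:200, function(i) simulate_gain_history(spec)))
  obs <- tabulate(h$multiplicity, 4) / 200
  expect_lt(max(abs(obs - ex)), 5)
})

test_that("invalid gain specifications are rejected", {
  expect_error(gain_event_spec("s", 3, 1, c(0.5, 0.2), 100),
               "strictly increasing")
  expect_error(gain_event_spec("s", 3, 1, 0.5, 100), "2 event time")
  expect_error(gain_event_spec("s", 5, 1, c(0.1, 0.2, 0.3, 0.4), 100),
               "unsupported")
})

test_that("read simulation hits the expected VAFs and is seed-deterministic", {
  muts <- data.frame(mutation_id = paste0("m", 1:20000), segment_id = "s",
                     multiplicity = 2L, total_cn = 3L, ccf = 1)
  r <- simulate_reads(muts, purity = 1, depth = 60, seed = 5)
  expect_equal(sum(r$alt_reads) / sum(r$total_reads), 2 / 3,
               tolerance = 0.005)
  # purity 0.8 trisomy, multiplicity 2: expected VAF = 1.6 / 2.8
  r2 <- simulate_reads(muts, purity = 0.8, depth = 60, seed = 5)
  expect_equal(sum(r2$alt_reads) / sum(r2$total_reads), 1.6 / 2.8,
               tolerance = 0.005)
  # diploid clonal heterozygous mutation: VAF 1/2
  muts$multiplicity <- 1L; muts$total_cn <- 2L
  r3 <- simulate_reads(muts[1:2000, ], purity = 1, depth = 100, seed = 2)
  expect_equal(sum(r3$alt_reads) / sum(r3$total_reads), 0.5,
               tolerance = 0.01)
  expect_identical(simulate_reads(muts, 1, 60, seed = 11),
                   simulate_reads(muts, 1, 60, seed = 11))
  expect_error(simulate_reads(muts, purity = 0, depth = 60), "purity")
})

test_that("cohort matrices follow their planted gates", {
  net <- list(A = list(prevalence = 0.5), B = list(prevalence = 0.5),
              C = list(parents = c("A", "B"), gate = "AND"))
  m <- simulate_cohort_matrix(net, 500, noise = 0, seed = 3)
  expect_identical(m[, "C"], as.integer(m[, "A"] & m[, "B"]))

  # maximal noise destroys the association with the parents
  set.seed(8)
  ps <- replicate(200, {
    mm <- simulate_cohort_matrix(net, 100, noise = 0.5)
    tab <- table(factor(mm[, "A"], 0:1), factor(mm[, "C"], 0:1))
    fisher_exact(tab)
  })
  expect_gt(mean(ps < 0.05), 0)   # not degenerate
  expect_lt(mean(ps < 0.05), 0.15)

  cyc <- list(A = list(parents = "B", gate = "NOT"),
              B = list(parents = "A", gate = "NOT"))
  expect_error(simulate_cohort_matrix(cyc, 10), "cyclic")
})

test_that("whole-patient simulation is consistent and reproducible", {
  segs <- data.frame(segment_id = c("g1", "d1"), chrom = c("3", "2"),
                     start = 1, end = 5e6,
                     major_cn = c(2L, 1L), minor_cn = 1L,
                     t1 = c(0.4, NA), t2 = NA, t3 = NA)
  sub <- list(parent = c(0L, 1L), ccf = rbind(c(1, 1), c(0.4, 0.7)),
              n_mutations = c(0L, 80L))
  p1 <- simulate_patient(segs, purity = 0.9, rate = 100, subclones = sub,
                         depth = 80, seed = 21)
  p2 <- simulate_patient(segs, purity = 0.9, rate = 100, subclones = sub,
                         depth = 80, seed = 21)
  expect_identical(p1$reads, p2$reads)
  # subclonal mutations inherit the planted per-sample CCFs
  subm <- p1$mutations[p1$mutations$subclone == 2L, ]
  expect_true(all(subm$ccf.S1 == 0.4 & subm$ccf.S2 == 0.7))
  expect_true(all(subm$multiplicity == 1L))
  # clonal gained-segment mutations never exceed the state's multiplicity
  g <- p1$mutations[p1$mutations$segment_id == "g1", ]
  expect_true(all(g$multiplicity %in% 1:2))
  expect_true(all(p1$reads$alt_reads <= p1$reads$total_reads))
})
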