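# Small planted-read generator for clustering tests.
planted_reads <- function(ccfs, n_per, depth = 100, purity = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(ccfs); ns <- ncol(ccfs)
  rows <- list()
  for (j in seq_len(k)) {
    ids <- sprintf("c%d_m%03d", j, seq_len(n_per))
    for (s in seq_len(ns)) {
      ev <- ccfs[j, s] * purity / (purity * 2 + 2 * (1 - purity))
      tot <- rpois(n_per, depth)
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = ids, sample_id = paste0("S", s),
        alt_reads = rbinom(n_per, tot, ev), total_reads = tot,
        segment_id = "d")
    }
  }
  list(reads = do.call(rbind, rows),
       truth = rep(seq_len(k), each = n_per),
       ids = sprintf("c%d_m%03d", rep(seq_len(k), each = n_per),
                     sequence(rep(n_per, k))))
}

test_that("a single planted clone is recovered as one cluster at CCF 1", {
  pr <- planted_reads(matrix(1, 1, 1), 200, depth = 100, seed = 51)
  ch <- gibbs_cluster(pr$reads, purity = 1, n_iter = 400, n_burnin = 150,
                      seed = 5)
  ss <- posterior_point_estimates(ch)
  expect_equal(length(ss$clusters), 1L)
  expect_equal(ss$clusters[[1]]$weight, 1)
  expect_lt(abs(ss$clusters[[1]]$ccf[["S1"]] - 1), 0.03)
})

test_that("the chain is bit-for-bit reproducible under a fixed seed", {
  pr <- planted_reads(rbind(c(1, 1), c(0.5, 0.2)), 40, seed = 52)
  ch1 <- gibbs_cluster(pr$reads, 1, n_iter = 150, n_burnin = 50, seed = 99)
  ch2 <- gibbs_cluster(pr$reads, 1, n_iter = 150, n_burnin = 50, seed = 99)
  expect_identical(ch1$z, ch2$z)
  expect_identical(ch1$f, ch2$f)
})

test_that("co-clustering matrix is symmetric with unit diagonal", {
  pr <- planted_reads(rbind(c(1, 1), c(0.4, 0.6)), 30, seed = 53)
  ch <- gibbs_cluster(pr$reads, 1, n_iter = 200, n_burnin = 80, seed = 3)
  co <- coclustering_matrix(ch)
  expect_identical(co, t(co))
  expect_true(all(diag(co) == 1))
  expect_true(all(co >= 0 & co <= 1))
})

test_that("point estimates are invariant to a relabeling of the chain", {
  pr <- planted_reads(rbind(c(1, 1), c(0.4, 0.6)), 30, seed = 54)
  ch <- gibbs_cluster(pr$reads, 1, n_iter = 200, n_burnin = 80, seed = 4)
  perm <- sample(seq_len(max(ch$z)))
  ch2 <- ch
  ch2$z <- matrix(perm[ch$z], nrow(ch$z), ncol(ch$z))
  # permute the CCF array rows to match the relabeled assignments
  ch2$f <- array(0, dim(ch$f))
  for (it in seq_len(dim(ch$f)[3])) {
    ch2$f[perm, , it] <- ch$f[seq_along(perm), , it]
  }
  s1 <- posterior_point_estimates(ch)
  s2 <- posterior_point_estimates(ch2)
  expect_equal(s1$assignments, s2$assignments)
  for (j in seq_along(s1$clusters)) {
    expect_equal(s1$clusters[[j]]$ccf, s2$clusters[[j]]$ccf,
                 tolerance = 1e-12)
  }
})

test_that("mutations with zero depth everywhere are dropped with a warning", {
  pr <- planted_reads(matrix(1, 1, 1), 20, seed = 55)
  pr$reads$total_reads[pr$reads$mutation_id == "c1_m001"] <- 0L
  pr$reads$alt_reads[pr$reads$mutation_id == "c1_m001"] <- 0L
  expect_warning(
    ch <- gibbs_cluster(pr$reads, 1, n_iter = 120, n_burnin = 40, seed = 1),
    "zero depth")
  expect_equal(length(ch$mutation_ids), 19L)
})

test_that("noiseless expected counts give back the planted CCFs", {
  # deterministic read counts at the exact expected VAF
  ccfs <- rbind(c(1, 1), c(0.5, 0.25))
  rows <- list()
  for (j in 1:2) for (s in 1:2) {
    ids <- sprintf("c%d_m%03d", j, 1:60)
    rows[[length(rows) + 1L]] <- data.frame(
      mutation_id = ids, sample_id = paste0("S", s),
      alt_reads = as.integer(round(200 * ccfs[j, s] / 2)),
      total_reads = 200L, segment_id = "d")
  }
  ch <- gibbs_cluster(do.call(rbind, rows), 1, n_iter = 300, n_burnin = 100,
                      seed = 6)
  ss <- posterior_point_estimates(ch)
  expect_equal(length(ss$clusters), 2L)
  got <- t(vapply(ss$clusters, function(cl) unname(cl$ccf), numeric(2)))
  want <- ccfs[order(-rowMeans(ccfs)), ]
  expect_true(all(abs(got - want) <= 1 / (2 * 200) + 0.01))
})
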