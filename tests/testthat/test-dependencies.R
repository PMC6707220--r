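test_that("fisher_exact matches the enumeration oracle and fisher.test", {
  set.seed(91)
  for (i in 1:80) {
    tab <- matrix(rpois(4, sample(3:30, 1)), 2)
    p <- fisher_exact(tab)
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # degenerate margins
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 3, 0, 4), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1)
  expect_error(fisher_exact(matrix(-1:2, 2)), "nonnegative")
})

test_that("logic-gate fitting finds planted gates and honors tie-breaks", {
  net <- list(A = list(prevalence = 0.5), B = list(prevalence = 0.5),
              C = list(parents = c("A", "B"), gate = "AND"))
  m <- simulate_cohort_matrix(net, 300, noise = 0.03, seed = 92)
  g <- fit_logic_gate(m, "C", c("A", "B"))
  expect_equal(g$expression, "AND(p1,p2)")
  expect_equal(g$gate_count, 1)

  # child identical to a single parent: the identity function
  m2 <- cbind(m, D = m[, "A"])
  g2 <- fit_logic_gate(m2, "D", "A")
  expect_equal(g2$truth_table, c(0L, 1L))
  expect_equal(g2$gate_count, 0)

  # invariance to parent ordering
  ga <- fit_logic_gate(m, "C", c("A", "B"))
  gb <- fit_logic_gate(m, "C", c("B", "A"))
  expect_identical(ga$truth_table, gb$truth_table)
  expect_identical(ga$fisher_p, gb$fisher_p)
  expect_error(fit_logic_gate(m, "C", c("A", "B", "A", "B")), "parents")
})

test_that("gate decompositions over AND/OR/NOT are minimal", {
  gc2 <- mmchron:::gate_costs(2)
  # projections cost nothing; AND and OR cost one gate
  and_tt <- c(0L, 0L, 0L, 1L)
  or_tt <- c(0L, 1L, 1L, 1L)
  id_of <- function(tt) sum(tt * 2^(seq_along(tt) - 1)) + 1
  expect_equal(gc2$cost[id_of(and_tt)], 1)
  expect_equal(gc2$cost[id_of(or_tt)], 1)
  # NAND needs two (NOT of AND); XOR needs more than two
  nand_tt <- 1L - and_tt
  expect_equal(gc2$cost[id_of(nand_tt)], 2)
  xor_tt <- c(0L, 1L, 1L, 0L)
  expect_gte(gc2$cost[id_of(xor_tt)], 3)
})

test_that("exact structure search recovers planted structure and refuses big inputs", {
  # independent columns: empty graph
  set.seed(93)
  ind <- matrix(rbinom(1600, 1, 0.4), 400, 4,
                dimnames = list(NULL, paste0("X", 1:4)))
  bn <- learn_structure_small(ind)
  expect_equal(sum(lengths(bn$parents)), 0L)

  # planted chain: skeleton X--Y--Z
  x <- rbinom(400, 1, 0.5)
  y <- ifelse(runif(400) < 0.9, x, 1 - x)
  z <- ifelse(runif(400) < 0.9, y, 1 - y)
  ch <- cbind(X = x, Y = y, Z = z)
  bn2 <- learn_structure_small(ch)
  expect_equal(mmchron:::bn_skeleton(bn2), c("X--Y", "Y--Z"))

  # single event: empty graph
  single <- matrix(rbinom(100, 1, 0.5), 100, 1,
                   dimnames = list(NULL, "A"))
  expect_equal(lengths(learn_structure_small(single)$parents), c(A = 0L))

  big <- matrix(0L, 10, 15, dimnames = list(NULL, paste0("E", 1:15)))
  expect_error(learn_structure_small(big), "subset")
})

test_that("DP search attains the exhaustive-DAG optimum on 4 events", {
  set.seed(94)
  net <- list(A = list(prevalence = 0.4),
              B = list(parents = "A", gate = function(p) p[, 1]),
              C = list(prevalence = 0.5),
              D = list(parents = c("B", "C"), gate = "OR"))
  m <- simulate_cohort_matrix(net, 300, noise = 0.1, seed = 95)
  bn <- learn_structure_small(m)
  oracle <- all_dags_oracle(m)
  expect_equal(bn$score, oracle$score, tolerance = 1e-9)
  expect_equal(mmchron:::bn_skeleton(bn), oracle$skeleton)
})

test_that("pairwise association map labels directions and calibrates type I error", {
  set.seed(96)
  co <- matrix(0L, 200, 2, dimnames = list(NULL, c("A", "B")))
  co[, "A"] <- rbinom(200, 1, 0.4)
  co[, "B"] <- co[, "A"]                 # perfectly co-occurring
  pm <- pairwise_association_map(co)
  expect_equal(pm$direction, "co-occurrence")
  expect_lt(pm$q, 1e-10)

  # planted mutual exclusivity
  ex <- matrix(0L, 200, 2, dimnames = list(NULL, c("A", "B")))
  idx <- sample(200, 120)
  ex[idx[1:60], "A"] <- 1L
  ex[idx[61:120], "B"] <- 1L
  pmx <- pairwise_association_map(ex)
  expect_equal(pmx$direction, "exclusivity")

  # independent pairs: p < 0.05 about 5% of the time
  hits <- replicate(400, {
    m <- matrix(rbinom(120, 1, 0.5), 60, 2,
                dimnames = list(NULL, c("A", "B")))
    pairwise_association_map(m)$p < 0.05
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.09)
})
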