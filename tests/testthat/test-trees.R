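cfg <- pigeonhole_config()

test_that("candidate roots require dominance in every sample", {
  expect_equal(candidate_roots(rbind(1.0, 0.4), cfg), 1L)
  # neither subclone dominates across both samples
  expect_length(candidate_roots(rbind(c(0.9, 0.3), c(0.4, 0.8)), cfg), 0)
  # two fully clonal subclones both qualify (within tolerance)
  expect_equal(candidate_roots(rbind(1.0, 1.0), cfg), c(1L, 2L))
  expect_error(candidate_roots(matrix(numeric(), 0, 1), cfg), "empty")
})

test_that("enumeration handles the canonical configurations", {
  # single subclone: the one-node tree
  t1 <- enumerate_trees(matrix(1, 1, 1), cfg)
  expect_length(t1, 1)
  expect_equal(t1[[1]]$parent, 0L)

  # branching: both children fit beside each other under the root only
  tr <- enumerate_trees(rbind(c(1, 1), c(0.6, 0.2), c(0.3, 0.7)), cfg)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$parent, c(0L, 1L, 1L))

  # 0.6 + 0.5 > 1: they cannot be siblings, so 0.5 must nest inside 0.6
  # (the pigeonhole rule: p_A + p_B > 1 with p_B < p_A nests B under A)
  nested <- enumerate_trees(rbind(1, 0.6, 0.5), cfg)
  expect_length(nested, 1)
  expect_equal(nested[[1]]$parent, c(0L, 1L, 2L))
  # with 0.2 both the nested and the sibling shape fit
  expect_length(enumerate_trees(rbind(1, 0.6, 0.2), cfg), 2)
})

test_that("the tolerance boundary sits exactly at 0.001", {
  # sibling sum 1.0008 is allowed, 1.002 is not (the nested shape remains)
  trees_ok <- enumerate_trees(rbind(1, 0.6, 0.4008), cfg)
  expect_true("0,1,1" %in% tree_keys(trees_ok))
  trees_no <- enumerate_trees(rbind(1, 0.6, 0.402), cfg)
  expect_false("0,1,1" %in% tree_keys(trees_no))
  # monotonicity: more tolerance never removes trees
  loose <- pigeonhole_config(tolerated_error = 0.01)
  expect_true(all(tree_keys(trees_no) %in%
                    tree_keys(enumerate_trees(rbind(1, 0.6, 0.402), loose))))
})

test_that("enumeration agrees exactly with the brute-force oracle", {
  set.seed(61)
  n_nonempty <- 0L
  n_empty <- 0L
  for (i in 1:60) {
    k <- sample(2:5, 1)
    s <- sample(1:2, 1)
    ccf <- matrix(runif(k * s), k, s)
    if (i %% 3 == 0) ccf[1, ] <- 1     # sometimes plant a clear root
    a <- tree_keys(enumerate_trees(ccf, cfg))
    b <- tree_keys(brute_force_trees(ccf, cfg))
    expect_identical(a, b)
    if (length(a)) n_nonempty <- n_nonempty + 1L else n_empty <- n_empty + 1L
  }
  # the instance mix must exercise both outcomes
  expect_gt(n_nonempty, 0L)
  expect_gt(n_empty, 0L)
})

test_that("emitted trees are structurally valid and deterministic", {
  ccf <- rbind(c(1, 1), c(0.55, 0.3), c(0.3, 0.3), c(0.1, 0.25))
  tr <- enumerate_trees(ccf, cfg)
  expect_true(all(vapply(tr, mmchron:::tree_is_valid, logical(1))))
  expect_identical(tree_keys(tr), sort(tree_keys(tr)))
  expect_error(brute_force_trees(matrix(runif(16), 8, 2), cfg), "k > 7")
})

test_that("the mutation-count filter excludes small subclones", {
  ss <- subclone_set(rbind(c(1, 1), c(0.5, 0.5), c(0.2, 0.1)),
                     n_mutations = c(300L, 40L, 120L))
  tr <- enumerate_trees(ss, cfg)
  # the 40-mutation subclone is dropped: trees span two nodes
  expect_true(all(vapply(tr, function(t) length(t$parent), integer(1)) == 2L))
})

test_that("newick output carries branch lengths as mutation counts", {
  tree <- clone_tree(c(0L, 1L, 1L), n_mutations = c(300, 120, 80))
  nwk <- tree_newick(tree)
  expect_match(nwk, "^\\(C2:120,C3:80\\)C1:300;$")
})
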