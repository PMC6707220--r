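# Independent oracles and small utilities shared across the test files.
# Everything here is deliberately written from first principles (choose(),
# explicit enumeration, grid search) so it never shares code paths with the
# package implementations it checks.

# Two-sided Fisher p by explicit enumeration over tables with fixed margins,
# hypergeometric probabilities from choose() directly.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Grid-search maximizer of the ridge-augmented Bradley-Terry log-likelihood
# (reference ability fixed at 0), refined over shrinking grids.
bt_grid_oracle <- function(wins, ridge = 1e-3, rounds = 6) {
  m <- nrow(wins)
  waug <- wins + ridge * (1 - diag(m))
  ll <- function(beta) {
    p <- exp(beta)
    s <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && waug[i, j] > 0) {
        s <- s + waug[i, j] * (beta[i] - log(p[i] + p[j]))
      }
    }
    s
  }
  centre <- rep(0, m - 1)
  width <- 4
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(m - 1), function(i)
      seq(centre[i] - width, centre[i] + width, length.out = 11))
    combos <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(combos, 1, function(b) ll(c(0, b)))
    centre <- combos[which.max(vals), ]
    width <- width / 4
  }
  c(0, centre)
}

# Exhaustive Bayesian-network oracle: enumerate every DAG over <= 4 events
# (all acyclic combinations of parent sets), score with the same BDeu local
# scores the package exposes via learn_structure_small's scoring rule, and
# return the best score and its skeleton.
all_dags_oracle <- function(mat, ess = 1) {
  events <- colnames(mat)
  n <- length(events)
  stopifnot(n <= 4)
  parent_sets <- lapply(seq_len(n), function(v) {
    others <- setdiff(seq_len(n), v)
    sets <- list(integer())
    for (sz in seq_len(min(3, n - 1))) {
      sets <- c(sets, utils::combn(others, sz, simplify = FALSE))
    }
    sets
  })
  local <- lapply(seq_len(n), function(v) {
    vapply(parent_sets[[v]], function(ps) {
      q <- 2^length(ps)
      j <- if (!length(ps)) rep(1L, nrow(mat))
           else as.integer(mat[, ps, drop = FALSE] %*%
                             2^(seq_along(ps) - 1L)) + 1L
      a_j <- ess / q; a_jk <- ess / (2 * q)
      s <- 0
      for (jj in seq_len(q)) {
        rows <- j == jj
        n1 <- sum(mat[rows, v]); n0 <- sum(rows) - n1
        s <- s + lgamma(a_j) - lgamma(a_j + n0 + n1) +
          lgamma(a_jk + n0) - lgamma(a_jk) + lgamma(a_jk + n1) - lgamma(a_jk)
      }
      s
    }, numeric(1))
  })
  is_acyclic <- function(choice) {
    par <- lapply(seq_len(n), function(v) parent_sets[[v]][[choice[v]]])
    placed <- integer(); remaining <- seq_len(n)
    while (length(remaining)) {
      ready <- remaining[vapply(remaining, function(v)
        all(par[[v]] %in% placed), logical(1))]
      if (!length(ready)) return(FALSE)
      placed <- c(placed, ready); remaining <- setdiff(remaining, ready)
    }
    TRUE
  }
  grid <- as.matrix(do.call(expand.grid,
                            lapply(parent_sets, function(s) seq_along(s))))
  best <- -Inf; best_choice <- NULL
  for (g in seq_len(nrow(grid))) {
    ch <- grid[g, ]
    sc <- sum(vapply(seq_len(n), function(v) local[[v]][ch[v]], numeric(1)))
    if (sc > best && is_acyclic(ch)) { best <- sc; best_choice <- ch }
  }
  edges <- character()
  for (v in seq_len(n)) {
    for (p in parent_sets[[v]][[best_choice[v]]]) {
      edges <- c(edges, paste(sort(c(events[v], events[p])), collapse = "--"))
    }
  }
  list(score = best, skeleton = sort(unique(edges)))
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Simulate one gained segment end to end and return the multiplicity fit.
sim_segment_fit <- function(state, times, rate = 100, depth = 60,
                            purity = 1) {
  major <- as.integer(sub(":.*", "", state))
  minor <- as.integer(sub(".*:", "", state))
  spec <- gain_event_spec("seg", major, minor, times, rate)
  h <- simulate_gain_history(spec)
  h$total_cn <- major + minor
  reads <- simulate_reads(h, purity, depth)
  assign_multiplicity(reads$alt_reads, reads$total_reads, purity,
                      major, minor)
}

# Planted-truth estimate of the gain time(s) for one simulated segment.
sim_segment_estimate <- function(state, times, rate = 100, depth = 60,
                                 purity = 1) {
  am <- sim_segment_fit(state, times, rate, depth, purity)
  soft <- am$expected_counts
  switch(state,
    "2:1" = time_trisomy(soft),
    "2:0" = time_cnloh(soft),
    time_multigain(soft, state))
}

# Parent-vector strings of a tree list, for oracle comparisons.
tree_keys <- function(trees) {
  vapply(trees, function(t) paste(t$parent, collapse = ","), character(1))
}
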