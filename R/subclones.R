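## -------------------------------------------------------------------------
## Dirichlet-process binomial mixture clustering of mutations into subclones
## across (serial) samples, via truncated stick-breaking Gibbs sampling.
##
## Model: alt_is ~ Binomial(tot_is, c_is * f_{z_i, s}) where f_{k,s} is the
## cancer cell fraction of subclone k in sample s and
## c_is = purity * multiplicity_i / (purity * total_cn_i + 2 (1 - purity))
## maps CCF to expected read fraction.  Cluster weights carry a
## stick-breaking DP prior (truncation K); the concentration parameter gets
## a Gamma(1, 1) prior and is resampled every sweep.  CCFs are updated on a
## discrete grid (step 0.01) with a uniform prior, which keeps the
## non-conjugate update exact and fast.
## -------------------------------------------------------------------------

#' Gibbs sampler for the Dirichlet-process binomial mixture
#'
#' @param reads Data.frame with `mutation_id`, `sample_id`, `alt_reads`,
#'   `total_reads` (one row per mutation x sample).
#' @param purity Tumor purity in `(0, 1]` (single value or named per-sample
#'   vector).
#' @param multiplicity Per-mutation multiplicity (single value, or named
#'   vector by `mutation_id`); defaults to 1.
#' @param total_cn Per-mutation segment total copy number (single value or
#'   named vector); defaults to 2.
#' @param n_iter Total MCMC sweeps (default 1000).
#' @param n_burnin Sweeps discarded as burn-in (default 300).
#' @param K Stick-breaking truncation level (default 30).
#' @param ccf_grid_step CCF grid resolution (default 0.01).
#' @param seed Integer seed; fixed seeds reproduce the chain exactly.
#' @return Object of class `dp_chain`: list with `z` (n_iter x N assignment
#'   matrix), `f` (K x S x n_iter CCF array), `alpha` (per-sweep
#'   concentration), `mutation_ids`, `sample_ids`, `n_iter`, `n_burnin`.
#' @export
gibbs_cluster <- function(reads, purity, multiplicity = 1, total_cn = 2,
                          n_iter = 1000, n_burnin = 300, K = 30,
                          ccf_grid_step = 0.01, seed = NULL) {
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin", call. = FALSE)
  muts <- sort(unique(reads$mutation_id))
  samps <- sort(unique(reads$sample_id))
  n <- length(muts)
  ns <- length(samps)
  if (n < 2L) stop("need at least 2 mutations", call. = FALSE)

  idx <- function(v, keys, default) {
    if (length(v) == 1L) rep(v, length(keys))
    else if (!is.null(names(v))) unname(v[keys])
    else v
  }
  pur <- idx(purity, samps)
  for (p in pur) check_purity(p)
  mult <- idx(multiplicity, muts)
  tcn <- idx(total_cn, muts)

  Y <- Ntot <- matrix(0L, n, ns, dimnames = list(muts, samps))
  Y[cbind(match(reads$mutation_id, muts), match(reads$sample_id, samps))] <-
    reads$alt_reads
  Ntot[cbind(match(reads$mutation_id, muts), match(reads$sample_id, samps))] <-
    reads$total_reads

  zero <- rowSums(Ntot) == 0L
  if (any(zero)) {
    warning(sum(zero), " mutation(s) with zero depth in all samples dropped")
    Y <- Y[!zero, , drop = FALSE]
    Ntot <- Ntot[!zero, , drop = FALSE]
    mult <- mult[!zero]
    tcn <- tcn[!zero]
    muts <- muts[!zero]
    n <- length(muts)
  }

  # CCF -> read-fraction conversion constants, mutation x sample
  C <- vapply(seq_len(ns), function(s)
    expected_vaf(pur[s], mult, 1, tcn), numeric(n))
  C <- matrix(C, n, ns)

  grid <- seq(0, 1, by = ccf_grid_step)
  ng <- length(grid)
  loggrid <- log(pmax(grid, 1e-300))

  with_seed(seed, {
    z <- sample.int(min(K, max(2L, n %/% 10L)), n, replace = TRUE)
    f <- matrix(stats::runif(K * ns), K, ns)
    alpha <- 1
    z_chain <- matrix(0L, n_iter, n)
    f_chain <- array(0, c(K, ns, n_iter))
    a_chain <- numeric(n_iter)

    for (it in seq_len(n_iter)) {
      ## 1. CCF update per cluster/sample on the grid
      for (k in seq_len(K)) {
        members <- which(z == k)
        for (s in seq_len(ns)) {
          if (!length(members)) { f[k, s] <- grid[sample.int(ng, 1L)]; next }
          y <- Y[members, s]; m <- Ntot[members, s]; cc <- C[members, s]
          # group by unique conversion constant: the grid log-likelihood is
          # sum(y) log g + sum_i (m_i - y_i) log(1 - c_i g) up to constants
          lg <- sum(y) * loggrid
          for (u in unique(cc)) {
            w <- which(cc == u)
            lg <- lg + sum(m[w] - y[w]) * log(pmax(1 - u * grid, 1e-300))
          }
          lg <- lg - max(lg)
          pg <- exp(lg)
          f[k, s] <- grid[sample.int(ng, 1L, prob = pg)]
        }
      }

      ## 2. stick-breaking weights and concentration
      nk <- tabulate(z, nbins = K)
      ngt <- rev(cumsum(rev(nk)))[-1L]   # counts in clusters > k
      v <- stats::rbeta(K - 1L, 1 + nk[-K], alpha + ngt)
      v <- pmin(v, 1 - 1e-12)
      logw <- c(0, cumsum(log1p(-v))) + c(log(v), 0)
      alpha <- stats::rgamma(1L, shape = 1 + K - 1L,
                             rate = 1 - sum(log1p(-v)))

      ## 3. assignments
      ll <- matrix(rep(logw, each = n), n, K)
      for (s in seq_len(ns)) {
        P <- C[, s] %o% f[, s]
        ll <- ll + Y[, s] * log(pmax(P, 1e-300)) +
          (Ntot[, s] - Y[, s]) * log(pmax(1 - P, 1e-300))
      }
      # Gumbel-max categorical sampling, rowwise
      g <- -log(-log(matrix(stats::runif(n * K), n, K)))
      z <- max.col(ll + g, ties.method = "first")

      z_chain[it, ] <- z
      f_chain[, , it] <- f
      a_chain[it] <- alpha
    }

    structure(list(z = z_chain, f = f_chain, alpha = a_chain,
                   mutation_ids = muts, sample_ids = samps,
                   conversion = C, n_iter = n_iter, n_burnin = n_burnin),
              class = "dp_chain")
  })
}

#' @export
print.dp_chain <- function(x, ...) {
  keep <- seq(x$n_burnin + 1L, x$n_iter)
  occ <- mean(apply(x$z[keep, , drop = FALSE], 1L,
                    function(z) length(unique(z))))
  cat(sprintf(
    "<dp_chain> %d mutations, %d sample(s), %d sweeps (%d burn-in), mean %.1f occupied clusters\n",
    length(x$mutation_ids), length(x$sample_ids), x$n_iter, x$n_burnin, occ))
  invisible(x)
}

#' Pairwise posterior co-clustering probabilities
#'
#' @param chain A `dp_chain`.
#' @param thin Keep every `thin`-th post-burn-in sweep (default 5).
#' @return Symmetric N x N matrix of co-assignment frequencies (unit
#'   diagonal).
#' @export
coclustering_matrix <- function(chain, thin = 5L) {
  keep <- seq(chain$n_burnin + 1L, chain$n_iter, by = thin)
  n <- length(chain$mutation_ids)
  co <- matrix(0, n, n)
  for (it in keep) {
    zi <- chain$z[it, ]
    co <- co + outer(zi, zi, "==")
  }
  co <- co / length(keep)
  dimnames(co) <- list(chain$mutation_ids, chain$mutation_ids)
  co
}

#' Point estimates of subclone structure from a posterior chain
#'
#' Consensus assignments come from average-linkage clustering of the
#' pairwise co-assignment matrix, cut at co-clustering probability 0.5
#' (robust to label switching). Consensus clusters holding less than
#' `min_weight` of the mutations (outlier fragments, not subclones) are
#' absorbed into the cluster with which their members co-assign most often.
#' Cluster CCFs are posterior medians over the retained sweeps and member
#' mutations; weights are assigned fractions.
#'
#' @param chain A `dp_chain` from [gibbs_cluster()].
#' @param thin Thinning for the co-clustering consensus (default 5).
#' @param min_weight Minimum fraction of mutations for a consensus cluster
#'   to stand on its own (default 0.02).
#' @return Object of class `subclone_set`: list with `clusters` (each:
#'   `weight`, `ccf` named by sample, `mutation_ids`), `assignments` (named
#'   integer vector), `n_iterations`, `n_burnin`. Clusters are ordered by
#'   decreasing mean CCF.
#' @export
posterior_point_estimates <- function(chain, thin = 5L, min_weight = 0.02) {
  if (chain$n_iter <= chain$n_burnin) stop("empty chain", call. = FALSE)
  co <- coclustering_matrix(chain, thin = thin)
  n <- nrow(co)
  lab <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
    stats::cutree(hc, h = 0.5)
  }
  # absorb outlier fragments into their highest-affinity major cluster
  sizes <- table(lab)
  small <- names(sizes)[sizes < max(1, min_weight * n)]
  big <- setdiff(names(sizes), small)
  if (length(small) && length(big)) {
    for (g in small) {
      members <- which(lab == as.integer(g))
      aff <- vapply(big, function(h)
        mean(co[members, lab == as.integer(h), drop = FALSE]), numeric(1))
      lab[members] <- as.integer(big[which.max(aff)])
    }
  }
  keep <- seq(chain$n_burnin + 1L, chain$n_iter, by = thin)
  ns <- length(chain$sample_ids)
  clusters <- lapply(sort(unique(lab)), function(g) {
    members <- which(lab == g)
    ccf <- vapply(seq_len(ns), function(s) {
      draws <- vapply(keep, function(it)
        stats::median(chain$f[chain$z[it, members], s, it]), numeric(1))
      stats::median(draws)
    }, numeric(1))
    list(weight = length(members) / n,
         ccf = stats::setNames(ccf, chain$sample_ids),
         mutation_ids = chain$mutation_ids[members])
  })
  ord <- order(vapply(clusters, function(cl) -mean(cl$ccf), numeric(1)))
  clusters <- clusters[ord]
  assignments <- integer(n)
  for (j in seq_along(clusters)) {
    assignments[match(clusters[[j]]$mutation_ids, chain$mutation_ids)] <- j
  }
  structure(list(clusters = clusters,
                 assignments = stats::setNames(assignments,
                                               chain$mutation_ids),
                 sample_ids = chain$sample_ids,
                 n_iterations = chain$n_iter, n_burnin = chain$n_burnin),
            class = "subclone_set")
}

#' Construct a subclone set directly from CCF estimates
#'
#' Used when subclone CCFs come from elsewhere (tests, external callers)
#' and only the tree machinery is needed.
#'
#' @param ccf Matrix (subclones x samples) of cancer cell fractions.
#' @param n_mutations Integer vector of mutations per subclone.
#' @param ids Optional subclone labels.
#' @return A `subclone_set`.
#' @export
subclone_set <- function(ccf, n_mutations = NULL, ids = NULL) {
  ccf <- as.matrix(ccf)
  k <- nrow(ccf)
  if (is.null(n_mutations)) n_mutations <- rep(100L, k)
  if (is.null(ids)) ids <- rownames(ccf) %||% paste0("C", seq_len(k))
  samples <- colnames(ccf) %||% paste0("S", seq_len(ncol(ccf)))
  clusters <- lapply(seq_len(k), function(j) {
    list(weight = n_mutations[j] / sum(n_mutations),
         ccf = stats::setNames(ccf[j, ], samples),
         mutation_ids = paste0(ids[j], "_m", seq_len(n_mutations[j])),
         id = ids[j], n_mutations = n_mutations[j])
  })
  structure(list(clusters = clusters, assignments = NULL,
                 sample_ids = samples, n_iterations = NA, n_burnin = NA),
            class = "subclone_set")
}

#' @export
print.subclone_set <- function(x, ...) {
  cat(sprintf("<subclone_set> %d cluster(s), %d sample(s)\n",
              length(x$clusters), length(x$sample_ids)))
  for (j in seq_along(x$clusters)) {
    cl <- x$clusters[[j]]
    cat(sprintf("  %d: weight %.3f  n = %d  CCF (%s)\n", j, cl$weight,
                length(cl$mutation_ids),
                paste(sprintf("%.2f", cl$ccf), collapse = ", ")))
  }
  invisible(x)
}

# k x S CCF matrix of a subclone_set
ccf_matrix <- function(subclones) {
  ns <- length(subclones$sample_ids)
  matrix(vapply(subclones$clusters, function(cl) as.numeric(cl$ccf),
                numeric(ns)),
         ncol = ns, byrow = TRUE,
         dimnames = list(NULL, subclones$sample_ids))
}

# per-cluster mutation counts
cluster_sizes <- function(subclones) {
  vapply(subclones$clusters, function(cl)
    cl$n_mutations %||% length(cl$mutation_ids), numeric(1))
}
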