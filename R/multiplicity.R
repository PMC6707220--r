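## -------------------------------------------------------------------------
## c-VAF correction and multiplicity-class assignment within gained segments.
## -------------------------------------------------------------------------

#' Correct a raw VAF for normal-cell contamination and local copy number
#'
#' Converts the fraction of all reads carrying a variant into the fraction of
#' tumor allele copies carrying it (c-VAF):
#' `cvaf = raw_vaf * (purity * total_cn + 2 * (1 - purity)) / (purity * total_cn)`,
#' clipped to `[0, 1]`. For a clonal single-copy mutation the c-VAF is
#' `1 / total_cn`; a mutation duplicated by a trisomy sits at 2/3.
#'
#' @param raw_vaf Observed variant allele fraction(s) in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param total_cn Tumor total copy number of the segment (>= 1).
#' @return Numeric vector of c-VAFs in `[0, 1]`.
#' @examples
#' compute_cvaf(2 / 3, purity = 1, total_cn = 3)   # duplicated: 2/3
#' compute_cvaf(0.571, purity = 0.8, total_cn = 3) # back to ~2/3
#' @export
compute_cvaf <- function(raw_vaf, purity, total_cn) {
  check_purity(purity)
  if (any(total_cn < 1)) stop("total_cn must be >= 1", call. = FALSE)
  clip(raw_vaf * (purity * total_cn + 2 * (1 - purity)) / (purity * total_cn))
}

#' Assign clonal SNVs in a gained segment to multiplicity classes
#'
#' Fits a finite mixture whose component locations are fixed at the only
#' values the copy-number state allows -- c-VAF `m / total_cn` for
#' `m = 1..major_cn` -- so only the mixture weights (and, in Gaussian mode, a
#' shared dispersion) are estimated. Each SNV is assigned to the
#' maximum-posterior component when that posterior reaches
#' `min_assign_prob`; otherwise it is left unassigned (the "gray dots").
#'
#' The default `model = "binomial"` evaluates component likelihoods on the
#' observed read counts, giving the correct variance at any depth;
#' `model = "gaussian"` is an equal-variance Gaussian mixture on the c-VAFs
#' (mclust-like), provided for comparability.
#'
#' @param alt_reads,total_reads Integer vectors of per-SNV read counts
#'   (required for the binomial model; `total_reads` also sets depth-aware
#'   behavior of downstream checks).
#' @param purity Tumor purity in `(0, 1]`.
#' @param major_cn,minor_cn Allele-specific copy numbers of the segment.
#' @param model `"binomial"` (default) or `"gaussian"`.
#' @param min_assign_prob Posterior-probability threshold below which an SNV
#'   stays unassigned (default 0.80).
#' @param max_iter,tol EM controls.
#' @return Object of class `multiplicity_counts`: list with `counts` (named
#'   vector CN1..CN4 of hard-assigned tallies), `n_unassigned`,
#'   `assignments` (per-SNV class, NA when unassigned), `posterior`
#'   (n x major_cn matrix), `expected_counts` (posterior column sums --
#'   threshold-free class tallies; preferred as timing-estimator input
#'   because hard tallies after exclusion are selection-biased against
#'   classes squeezed between larger neighbors), `weights`, `state`.
#' @export
assign_multiplicity <- function(alt_reads, total_reads, purity,
                                major_cn, minor_cn,
                                model = c("binomial", "gaussian"),
                                min_assign_prob = 0.80,
                                max_iter = 500, tol = 1e-8) {
  model <- match.arg(model)
  check_purity(purity)
  if (major_cn < 2) stop("segment must carry a gain (major_cn >= 2)",
                         call. = FALSE)
  n <- length(alt_reads)
  if (n < 2L) stop("need at least 2 SNVs to fit the mixture", call. = FALSE)
  if (length(total_reads) != n) stop("alt/total length mismatch", call. = FALSE)
  total_cn <- major_cn + minor_cn
  m_cand <- seq_len(major_cn)
  # expected raw VAF of a clonal mutation on m copies
  p_m <- expected_vaf(purity, m_cand, 1, total_cn)

  if (model == "binomial") {
    ll <- vapply(p_m, function(p)
      stats::dbinom(alt_reads, total_reads, clip(p, 1e-12, 1)) , numeric(n))
    ll <- log(pmax(ll, 1e-300))
  } else {
    cvaf <- compute_cvaf(alt_reads / pmax(total_reads, 1L), purity, total_cn)
    mu <- m_cand / total_cn
    sd0 <- max(stats::sd(cvaf), 0.02)
    ll <- NULL                          # recomputed each EM step below
  }

  w <- rep(1 / major_cn, major_cn)
  loglik_old <- -Inf
  for (it in seq_len(max_iter)) {
    if (model == "gaussian") {
      ll <- vapply(seq_along(mu), function(j)
        stats::dnorm(cvaf, mu[j], sd0, log = TRUE), numeric(n))
    }
    lw <- sweep(ll, 2L, log(pmax(w, 1e-12)), "+")
    mx <- apply(lw, 1L, max)
    post <- exp(lw - mx)
    rs <- rowSums(post)
    post <- post / rs
    loglik <- sum(mx + log(rs))
    w <- colMeans(post)
    if (model == "gaussian") {
      # shared dispersion update around the fixed component means
      resid2 <- sweep(matrix(cvaf, n, length(mu)), 2L, mu)^2
      sd0 <- sqrt(max(sum(post * resid2) / n, 1e-6))
    }
    if (abs(loglik - loglik_old) < tol) break
    loglik_old <- loglik
  }

  cls <- max.col(post, ties.method = "first")
  keep <- post[cbind(seq_len(n), cls)] >= min_assign_prob
  assignments <- ifelse(keep, m_cand[cls], NA_integer_)
  counts <- c(CN1 = 0L, CN2 = 0L, CN3 = 0L, CN4 = 0L)
  tab <- table(factor(assignments, levels = 1:4))
  counts[] <- as.integer(tab)
  expected_counts <- c(CN1 = 0, CN2 = 0, CN3 = 0, CN4 = 0)
  expected_counts[m_cand] <- colSums(post)
  res <- structure(
    list(counts = counts, n_unassigned = sum(!keep),
         assignments = assignments, posterior = post,
         expected_counts = expected_counts, weights = w,
         state = c(major_cn = major_cn, minor_cn = minor_cn),
         model = model, min_assign_prob = min_assign_prob),
    class = "multiplicity_counts")
  if (all(!keep)) attr(res, "degenerate") <- TRUE
  res
}

#' @export
print.multiplicity_counts <- function(x, ...) {
  cat(sprintf("<multiplicity_counts> state %d:%d  %s  unassigned %d\n",
              x$state["major_cn"], x$state["minor_cn"],
              paste(names(x$counts), x$counts, sep = "=", collapse = " "),
              x$n_unassigned))
  invisible(x)
}

#' Build a multiplicity_counts object from known class counts
#'
#' Convenience constructor used when the CN1..CN4 tallies are already known
#' (e.g. from expectations, external tools or tests).
#'
#' @param CN1,CN2,CN3,CN4 Nonnegative counts of mutations on 1..4 copies.
#' @param major_cn,minor_cn Segment state.
#' @return A `multiplicity_counts` object (without per-SNV detail).
#' @export
multiplicity_counts <- function(CN1 = 0, CN2 = 0, CN3 = 0, CN4 = 0,
                                major_cn = 2, minor_cn = 1) {
  counts <- c(CN1 = CN1, CN2 = CN2, CN3 = CN3, CN4 = CN4)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  occupied <- which(counts > 0)
  if (length(occupied) && max(occupied) > major_cn) {
    stop("CN_m > 0 for m above major_cn", call. = FALSE)
  }
  structure(list(counts = counts, n_unassigned = 0L, assignments = NULL,
                 state = c(major_cn = major_cn, minor_cn = minor_cn)),
            class = "multiplicity_counts")
}

#' Keep segments eligible for molecular timing
#'
#' Applies the timing eligibility filter: a segment is kept only when its
#' length strictly exceeds 1 Mb and its clonal SNV count strictly exceeds 50
#' (both inequalities strict; boundary values are dropped).
#'
#' @param segments Data.frame with `start`/`end` (1-based, inclusive) or a
#'   precomputed `length` column, plus `n_clonal_snvs`.
#' @param min_length Minimum length in bp (exclusive; default 1e6).
#' @param min_snvs Minimum clonal SNV count (exclusive; default 50).
#' @return The eligible subset of `segments`.
#' @export
filter_segments <- function(segments, min_length = 1e6, min_snvs = 50) {
  len <- if ("length" %in% names(segments)) segments$length
         else segments$end - segments$start + 1
  keep <- len > min_length & segments$n_clonal_snvs > min_snvs
  segments[keep, , drop = FALSE]
}
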