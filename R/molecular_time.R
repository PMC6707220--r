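## -------------------------------------------------------------------------
## Molecular timing of clonal copy-number gains.
##
## Under a constant clonal mutation rate r per allele copy per unit molecular
## time, the expected multiplicity-class counts of a gained segment are a
## linear function of the gain time(s):
##   2:1  E[CN2] = rT,            E[CN1] = r(3 - 2T)
##   2:0  E[CN2] = rT,            E[CN1] = 2r(1 - T)
##   3:1  E[CN3] = rT1, E[CN2] = r(T2 - T1), E[CN1] = r(4 - T1 - 2*T2)
##   4:1  E[CN4] = rT1, E[CN3] = r(T2 - T1), E[CN2] = r(T3 - T2),
##        E[CN1] = r(5 - T1 - T2 - 2*T3)
## Each estimator below inverts these relations and is exact on expectations.
## -------------------------------------------------------------------------

counts_of <- function(counts) {
  if (inherits(counts, "multiplicity_counts")) counts$counts
  else {
    cn <- c(CN1 = 0, CN2 = 0, CN3 = 0, CN4 = 0)
    cn[names(counts)] <- counts
    cn
  }
}

check_state <- function(cn, allowed_top) {
  above <- which(cn > 0)
  if (length(above) && max(above) > allowed_top) {
    stop("multiplicity classes above CN", allowed_top,
         " are inconsistent with this copy-number state", call. = FALSE)
  }
}

#' Molecular time of a trisomy (2:1)
#'
#' `T = 3 * CN2 / (2 * CN2 + CN1)`, clipped to `[0, 1]`: the ratio of
#' duplicated to all gained-lineage clonal mutations, scaled so that the
#' estimator is unbiased under the constant-rate model (algebraically equal
#' to `CN2 / (CN2 + (CN1 - CN2) / 3)`).
#'
#' @param counts A [multiplicity_counts()] object or named vector with
#'   `CN1`, `CN2`.
#' @return Molecular time in `[0, 1]`.
#' @examples
#' time_trisomy(c(CN2 = 60, CN1 = 180))  # 0.6
#' @export
time_trisomy <- function(counts) {
  cn <- counts_of(counts)
  check_state(cn, 2L)
  if (cn["CN1"] + cn["CN2"] == 0) stop("no assigned mutations", call. = FALSE)
  unname(clip(3 * cn["CN2"] / (2 * cn["CN2"] + cn["CN1"])))
}

#' Molecular time of a copy-neutral LOH (2:0)
#'
#' Default (model-consistent) estimator `T = 2 * CN2 / (2 * CN2 + CN1)`.
#' `mode = "as-printed"` instead returns `CN2 / ((CN2 + CN1) / 2)`, a
#' commonly quoted form that equals 2 (before clipping) at `T = 1` because
#' its denominator omits the doubled post-event accrual; it is retained for
#' comparability only.
#'
#' @param counts Multiplicity counts (`CN1`, `CN2`).
#' @param mode `"default"` or `"as-printed"`.
#' @return Molecular time in `[0, 1]` (clipped).
#' @export
time_cnloh <- function(counts, mode = c("default", "as-printed")) {
  mode <- match.arg(mode)
  cn <- counts_of(counts)
  check_state(cn, 2L)
  if (cn["CN1"] + cn["CN2"] == 0) stop("no assigned mutations", call. = FALSE)
  t <- if (mode == "default") 2 * cn["CN2"] / (2 * cn["CN2"] + cn["CN1"])
       else cn["CN2"] / ((cn["CN2"] + cn["CN1"]) / 2)
  unname(clip(t))
}

#' Molecular times of sequential multi-gains (3:1 and 4:1)
#'
#' For 3:1, `T1st = CN3 / D` and `T2nd = (CN3 + CN2) / D` with
#' `D = CN3 + CN2 + (CN1 - 2 * CN2 - CN3) / 4` (the inner term is clipped at
#' zero before division when sampling noise drives it negative). For 4:1,
#' `Tk = 5 * (cumulative top-class count) / W` with
#' `W = CN1 + 2 * CN2 + 3 * CN3 + 4 * CN4`. Estimates are clipped to
#' `[0, 1]` and sorted, so `T1st <= T2nd <= T3rd` always holds.
#'
#' @param counts Multiplicity counts.
#' @param final_state `"3:1"` or `"4:1"`.
#' @return Named numeric vector `T1st`, `T2nd` (and `T3rd` for 4:1).
#' @examples
#' time_multigain(c(CN3 = 30, CN2 = 30, CN1 = 330), "3:1")  # 0.25 0.50
#' @export
time_multigain <- function(counts, final_state = c("3:1", "4:1")) {
  final_state <- match.arg(final_state)
  cn <- counts_of(counts)
  if (final_state == "3:1") {
    check_state(cn, 3L)
    inner <- max(cn["CN1"] - 2 * cn["CN2"] - cn["CN3"], 0)
    d <- cn["CN3"] + cn["CN2"] + inner / 4
    if (d == 0) stop("no assigned mutations", call. = FALSE)
    t <- c(T1st = unname(cn["CN3"] / d),
           T2nd = unname((cn["CN3"] + cn["CN2"]) / d))
  } else {
    w <- cn["CN1"] + 2 * cn["CN2"] + 3 * cn["CN3"] + 4 * cn["CN4"]
    if (w == 0) stop("no assigned mutations", call. = FALSE)
    t <- c(T1st = unname(5 * cn["CN4"] / w),
           T2nd = unname(5 * (cn["CN4"] + cn["CN3"]) / w),
           T3rd = unname(5 * (cn["CN4"] + cn["CN3"] + cn["CN2"]) / w))
  }
  sort(clip(t))
}

#' Single-event versus sequential acquisition of a multi-gain
#'
#' A state with two or more extra copies acquired in one event (e.g. a
#' tetrasomy arising as a single duplication of both homologues' copies)
#' leaves its intermediate multiplicity classes empty: only one duplicated
#' cluster is seen (at c-VAF 0.75 for a 2:2-style tetrasomy). Distinct
#' intermediate clusters imply sequential, independent gains.
#'
#' Intermediate classes are treated as empty when their count is consistent
#' with pure misassignment noise: count below
#' `max(min_count, noise_frac * n_assigned)`.
#'
#' @param counts Multiplicity counts.
#' @param final_state Copy state with at least two extra copies
#'   (`"3:1"`, `"4:1"`, `"2:2"`...).
#' @param min_count,noise_frac Emptiness threshold controls.
#' @return `"single"`, `"sequential"`, or `"indeterminate"` (no mutations).
#' @export
single_vs_sequential <- function(counts, final_state, min_count = 3,
                                 noise_frac = 0.02) {
  cn <- counts_of(counts)
  major <- as.integer(sub(":.*", "", final_state))
  minor <- as.integer(sub(".*:", "", final_state))
  extra <- (major - 1L) + max(0L, minor - 1L)
  if (is.na(extra) || extra < 2L) {
    stop("state must carry at least two extra copies", call. = FALSE)
  }
  if (sum(cn) == 0) return("indeterminate")
  top <- max(which(cn > 0))
  if (top < 2L) return("indeterminate")
  if (top == 2L) return("single")       # one duplicated cluster only
  inter <- cn[seq(2L, top - 1L)]
  thresh <- max(min_count, noise_frac * sum(cn))
  if (all(inter < thresh)) "single" else "sequential"
}

#' Bootstrap confidence intervals for gain timing
#'
#' Resamples the per-mutation multiplicity classes with replacement,
#' recomputes the appropriate timing estimator on each replicate, and
#' returns percentile intervals.
#'
#' @param classes Either an integer vector of per-mutation multiplicity
#'   classes (NA entries, i.e. unassigned SNVs, are dropped) or a
#'   [assign_multiplicity()] result / per-mutation posterior matrix, in
#'   which case each bootstrap replicate resamples mutations and sums their
#'   posterior class probabilities (threshold-free expected counts, the
#'   recommended timing input).
#' @param final_state `"2:1"`, `"2:0"`, `"3:1"` or `"4:1"`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param alpha Interval level is `1 - alpha` (default 0.05).
#' @param seed Integer seed; fixed seeds reproduce the intervals.
#' @param segment_id Optional label carried into the result.
#' @return Object of class `gain_timing`: list with `segment_id`, `state`,
#'   `estimates` (named point estimates), `ci` (matrix with `lower`/`upper`
#'   rows), `boot` (replicate matrix), `n_mutations`, `n_bootstrap`.
#' @export
bootstrap_timing <- function(classes, final_state, n_boot = 1000,
                             alpha = 0.05, seed = NULL, segment_id = NA) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (inherits(classes, "multiplicity_counts")) {
    classes <- classes$posterior
  }
  if (is.matrix(classes)) {
    post <- classes
    n <- nrow(post)
    if (n < 2L) stop("need at least 2 assigned mutations", call. = FALSE)
    counts_fun <- function(idx) {
      cn <- c(CN1 = 0, CN2 = 0, CN3 = 0, CN4 = 0)
      cs <- colSums(post[idx, , drop = FALSE])
      cn[seq_along(cs)] <- cs
      cn
    }
  } else {
    classes <- classes[!is.na(classes)]
    n <- length(classes)
    if (n < 2L) stop("need at least 2 assigned mutations", call. = FALSE)
    counts_fun <- function(idx) tab_classes(classes[idx])
  }
  est_base <- switch(final_state,
    "2:1" = time_trisomy,
    "2:0" = time_cnloh,
    "3:1" = function(cn) time_multigain(cn, "3:1"),
    "4:1" = function(cn) time_multigain(cn, "4:1"),
    stop("unsupported state ", final_state, call. = FALSE))
  est_fun <- function(idx) est_base(counts_fun(idx))
  point <- est_fun(seq_len(n))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      est_fun(sample.int(n, n, replace = TRUE)),
      numeric(length(point)))
  })
  boot <- matrix(boot, nrow = length(point))
  rownames(boot) <- names(point) %||% "T"
  ci <- apply(boot, 1L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  dimnames(ci) <- list(c("lower", "upper"), rownames(boot))
  structure(list(segment_id = segment_id, state = final_state,
                 estimates = stats::setNames(point, rownames(boot)), ci = ci,
                 boot = boot, n_mutations = n, n_bootstrap = n_boot,
                 alpha = alpha),
            class = "gain_timing")
}

tab_classes <- function(cl) {
  tb <- tabulate(cl, nbins = 4L)
  c(CN1 = tb[1], CN2 = tb[2], CN3 = tb[3], CN4 = tb[4])
}

#' @export
print.gain_timing <- function(x, ...) {
  cat(sprintf("<gain_timing> %s (%s), n = %d, %d bootstraps\n",
              x$segment_id, x$state, x$n_mutations, x$n_bootstrap))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s = %.3f  [%.3f, %.3f]\n", nm, x$estimates[nm],
                x$ci["lower", nm], x$ci["upper", nm]))
  }
  invisible(x)
}

#' Group gain timings into shared time windows
#'
#' Clusters segments over their bootstrap time distributions: within each
#' bootstrap replicate the segment times are clustered by complete-linkage
#' agglomeration, cut at two standard errors of a pairwise time difference
#' (`2 * sqrt(2)` times the pooled bootstrap standard deviation) -- the
#' scale below which two estimates of the same underlying time are expected
#' to fall; the per-replicate co-clustering frequencies are then
#' consensus-clustered (majority: cut at co-assignment probability 0.5).
#' Window labels are ordered by mean time (1 = earliest).
#'
#' When serial-sample information is supplied, a segment whose CNA is absent
#' in an earlier sample is forced into a later window than every gain
#' already present there.
#'
#' @param timings List of `gain_timing` objects (first estimate of each is
#'   used).
#' @param serial_presence Optional logical matrix (segments x serial
#'   samples, earliest first): is the CNA present in that sample?
#' @return Integer vector of window labels, named by segment id.
#' @export
group_time_windows <- function(timings, serial_presence = NULL) {
  k <- length(timings)
  if (k == 0L) stop("need at least one timing", call. = FALSE)
  ids <- vapply(timings, function(t) as.character(t$segment_id), character(1))
  if (k == 1L) return(stats::setNames(1L, ids))
  # bootstrap draws of the (first) gain time of each segment
  nb <- min(vapply(timings, function(t) ncol(t$boot), integer(1)))
  bmat <- vapply(timings, function(t) t$boot[1L, seq_len(nb)], numeric(nb))
  pooled_sd <- sqrt(mean(apply(bmat, 2L, stats::var)))
  cut_h <- max(2 * sqrt(2) * pooled_sd, 1e-6)
  co <- matrix(0, k, k)
  for (b in seq_len(nb)) {
    hc <- stats::hclust(stats::dist(bmat[b, ]), method = "complete")
    lab <- stats::cutree(hc, h = cut_h)
    co <- co + outer(lab, lab, "==")
  }
  co <- co / nb
  cons <- stats::hclust(stats::as.dist(1 - co), method = "average")
  lab <- stats::cutree(cons, h = 0.5)
  # order windows by mean point estimate, 1 = earliest
  pt <- vapply(timings, function(t) unname(t$estimates[1L]), numeric(1))
  ord <- rank(vapply(split(pt, lab), mean, numeric(1)), ties.method = "first")
  lab <- unname(ord[as.character(lab)])
  if (!is.null(serial_presence)) {
    lab <- enforce_serial_order(lab, serial_presence)
  }
  stats::setNames(as.integer(lab), ids)
}

# Serial-consistency rule: a gain absent in an earlier sample must postdate
# every gain already present there; bump its window past theirs.
enforce_serial_order <- function(lab, presence) {
  presence <- as.matrix(presence)
  n_samp <- ncol(presence)
  if (n_samp < 2L) return(lab)
  for (s in seq_len(n_samp - 1L)) {
    absent <- !presence[, s]
    present <- presence[, s]
    if (any(absent) && any(present)) {
      floor_w <- max(lab[present])
      bump <- absent & lab <= floor_w
      lab[bump] <- floor_w + 1L
    }
  }
  # renumber to consecutive labels preserving order
  as.integer(factor(rank(lab, ties.method = "min")))
}

#' Genome ploidy and whole-genome duplication call
#'
#' Ploidy is the segment-length-weighted mean total copy number; a sample is
#' called whole-genome duplicated when ploidy strictly exceeds 3 (a sample
#' at exactly 3.0 is not flagged).
#'
#' @param segments Data.frame with `start`, `end` (or `length`) and either
#'   `total_cn` or `major_cn` + `minor_cn`.
#' @param sample_id Optional label.
#' @return List of class `ploidy_call`: `sample_id`, `ploidy`, `wgd`.
#' @export
genome_ploidy <- function(segments, sample_id = NA) {
  if (nrow(segments) == 0L) stop("empty segment set", call. = FALSE)
  len <- if ("length" %in% names(segments)) segments$length
         else segments$end - segments$start + 1
  if (sum(len) <= 0) stop("segments cover no bases", call. = FALSE)
  tcn <- if ("total_cn" %in% names(segments)) segments$total_cn
         else segments$major_cn + segments$minor_cn
  ploidy <- sum(len * tcn) / sum(len)
  structure(list(sample_id = sample_id, ploidy = ploidy, wgd = ploidy > 3),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> %s  ploidy %.2f  WGD: %s\n",
              x$sample_id, x$ploidy, if (x$wgd) "yes" else "no"))
  invisible(x)
}
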