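## -------------------------------------------------------------------------
## Timing structural variants relative to chromosomal gains.
##
## Inside a clonal trisomy (2:1), a clonal SV on the gained allele acquired
## before the duplication is supported by reads from two of the three tumor
## copies (adjusted VAF ~2/3); an SV on a single copy -- either the minor
## allele at any time or one duplicated copy after the gain -- sits at ~1/3.
## The one-copy ambiguity is broken by the copy-number outcome of deletions
## or by SNVs/SNPs phased onto the SV-supporting reads.
## -------------------------------------------------------------------------

#' Adjusted rearrangement VAF (r-VAF)
#'
#' Corrects the raw fraction of SV-supporting reads for tumor purity, local
#' total copy number and the cancer cell fraction of the rearrangement:
#' `rvaf = (supporting / total) * (purity * total_cn + 2 (1 - purity)) /
#' (purity * total_cn) / ccf`, clipped to `[0, 1]`. The result estimates
#' the fraction of tumor allele copies carrying the breakpoint.
#'
#' @param supporting_reads,total_reads Read counts at the breakpoint
#'   (`total_reads > 0`).
#' @param purity Tumor purity in `(0, 1]`.
#' @param total_cn Tumor total copy number at the breakpoint.
#' @param ccf Cancer cell fraction of the SV (> 0; 1 = clonal).
#' @return r-VAF in `[0, 1]`.
#' @examples
#' compute_rvaf(20, 100, purity = 0.5, total_cn = 3, ccf = 1)  # 1/3
#' @export
compute_rvaf <- function(supporting_reads, total_reads, purity, total_cn,
                         ccf = 1) {
  check_purity(purity)
  if (any(total_reads <= 0)) stop("total_reads must be > 0", call. = FALSE)
  if (any(ccf <= 0)) stop("ccf must be > 0", call. = FALSE)
  raw <- supporting_reads / total_reads
  clip(raw * (purity * total_cn + 2 * (1 - purity)) /
         (purity * total_cn) / ccf)
}

#' Provisional SV timing from the r-VAF alone
#'
#' Two-hypothesis binomial classification of an SV inside a clonal 2:1
#' gain: the supporting-read count is compared under expected adjusted
#' fractions 2/3 (both duplicated copies, hence pre-gain) and 1/3 (a single
#' copy). Posterior (equal priors) at least `threshold` is required for a
#' call; otherwise the SV is `"indeterminate"`.
#'
#' @param rvaf Adjusted rearrangement VAF.
#' @param depth Effective read depth behind the r-VAF.
#' @param threshold Posterior-probability threshold (default 0.9).
#' @return List: `call` (`"pre-gain"`, `"one-allele"` (ambiguous single
#'   copy), `"indeterminate"`), `posterior_pre`, `evidence = "rvaf"`.
#' @export
classify_by_rvaf <- function(rvaf, depth, threshold = 0.9) {
  x <- round(clip(rvaf) * depth)
  lpre <- stats::dbinom(x, depth, 2 / 3, log = TRUE)
  lone <- stats::dbinom(x, depth, 1 / 3, log = TRUE)
  post_pre <- 1 / (1 + exp(lone - lpre))
  call <- if (post_pre >= threshold) "pre-gain"
          else if (post_pre <= 1 - threshold) "one-allele"
          else "indeterminate"
  list(call = call, posterior_pre = post_pre, evidence = "rvaf")
}

#' SV timing from the copy-number outcome of a nested deletion
#'
#' A deletion inside a 2:1 gained region betrays its timing through the
#' allele-specific state it leaves behind: after the gain, deleting the
#' non-duplicated allele yields CN-LOH (2:0) and deleting one duplicated
#' copy yields a normal diploid 1:1; deleting the (future) duplicated
#' allele before the gain yields a 1:0 deletion. Any other inner state is
#' indeterminate.
#'
#' @param inner_major,inner_minor Allele-specific copy numbers observed
#'   inside the deletion.
#' @param sv_class SV class; only `"deletion"` is supported.
#' @return List of class `sv_timing_call`: `call`, `allele`, `evidence`.
#' @export
classify_by_cn_outcome <- function(inner_major, inner_minor,
                                   sv_class = "deletion") {
  if (!identical(sv_class, "deletion")) {
    stop("copy-number-outcome timing supports deletions only", call. = FALSE)
  }
  state <- paste0(inner_major, ":", inner_minor)
  out <- switch(state,
    "2:0" = list(call = "post-gain", allele = "non-duplicated"),
    "1:1" = list(call = "post-gain", allele = "duplicated"),
    "1:0" = list(call = "pre-gain",  allele = "duplicated"),
    list(call = "indeterminate", allele = NA_character_))
  structure(c(out, list(evidence = "cn-outcome", inner_state = state)),
            class = "sv_timing_call")
}

#' SV timing from SNVs/SNPs phased onto the supporting reads
#'
#' Requires a clonal SNV (or SNP) present on all SV-supporting reads. The
#' joint c-VAF / r-VAF pattern resolves the placement: (i) both ~2/3: the
#' rearrangement and the substitution sat on the duplicated allele before
#' the gain; (ii) SNV ~2/3 with r-VAF ~1/3: the SV hit one of the two
#' duplicated copies after the gain; (iii) both ~1/3: both sit on the minor
#' non-duplicated allele.
#'
#' @param snv_class SNV c-VAF class, `"2/3"` or `"1/3"`.
#' @param rvaf_class SV r-VAF class, `"2/3"` or `"1/3"`.
#' @param phased_fraction Fraction of SV-supporting reads carrying the SNV;
#'   values below `min_phased` trigger an inconsistent-phasing warning and
#'   an indeterminate call.
#' @param min_phased Phasing completeness threshold (default 1, i.e. all
#'   reads).
#' @return List of class `sv_timing_call`: `call`, `allele`, `evidence`.
#' @export
classify_by_phased_snv <- function(snv_class, rvaf_class,
                                   phased_fraction = 1, min_phased = 1) {
  snv_class <- match.arg(snv_class, c("2/3", "1/3"))
  rvaf_class <- match.arg(rvaf_class, c("2/3", "1/3"))
  if (phased_fraction < min_phased) {
    warning("SNV phased onto only part of the SV-supporting reads; ",
            "call is indeterminate")
    return(structure(list(call = "indeterminate", allele = NA_character_,
                          evidence = "phasing"),
                     class = "sv_timing_call"))
  }
  out <- if (snv_class == "2/3" && rvaf_class == "2/3") {
    list(call = "pre-gain", allele = "duplicated")
  } else if (snv_class == "2/3" && rvaf_class == "1/3") {
    list(call = "post-gain", allele = "duplicated")
  } else if (snv_class == "1/3" && rvaf_class == "1/3") {
    list(call = "minor-allele", allele = "non-duplicated")
  } else {
    # SNV on one copy but SV on two is not a consistent phasing
    list(call = "indeterminate", allele = NA_character_)
  }
  structure(c(out, list(evidence = "phasing")), class = "sv_timing_call")
}

#' @export
print.sv_timing_call <- function(x, ...) {
  cat(sprintf("<sv_timing_call> %s (allele: %s; evidence: %s)\n",
              x$call, x$allele, x$evidence))
  invisible(x)
}

#' Time a table of SVs inside clonal trisomies
#'
#' Convenience wrapper applying [compute_rvaf()] and [classify_by_rvaf()]
#' rowwise; deletions with observed inner copy-number states are refined by
#' [classify_by_cn_outcome()].
#'
#' @param svs Data.frame with `sv_id`, `supporting_reads`, `total_reads`,
#'   `total_cn`, `ccf`, optionally `sv_class`, `inner_major`, `inner_minor`.
#' @param purity Tumor purity.
#' @param threshold Posterior threshold for the r-VAF classifier.
#' @return Data.frame with `sv_id`, `rvaf`, `call`, `evidence`.
#' @export
time_svs <- function(svs, purity, threshold = 0.9) {
  rvaf <- compute_rvaf(svs$supporting_reads, svs$total_reads, purity,
                       svs$total_cn, svs$ccf %||% 1)
  out <- data.frame(sv_id = svs$sv_id, rvaf = rvaf,
                    call = NA_character_, evidence = NA_character_)
  for (i in seq_len(nrow(svs))) {
    cl <- classify_by_rvaf(rvaf[i], svs$total_reads[i], threshold)
    call <- cl$call
    evidence <- "rvaf"
    if (call == "one-allele" &&
        identical(svs$sv_class[i], "deletion") &&
        !is.null(svs$inner_major) && !is.na(svs$inner_major[i])) {
      cn <- classify_by_cn_outcome(svs$inner_major[i], svs$inner_minor[i])
      call <- cn$call
      evidence <- "cn-outcome"
    }
    out$call[i] <- call
    out$evidence[i] <- evidence
  }
  out
}
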