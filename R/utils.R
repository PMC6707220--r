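#' @keywords internal
"_PACKAGE"

## Shared low-level helpers. Nothing here is exported.

# clamp numeric vector into [lo, hi], preserving names
clip <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Expected fraction of all reads (tumor + normal) carrying a variant that sits
# on `multiplicity` copies in a fraction `ccf` of tumor cells, inside a segment
# of tumor total copy number `total_cn`, at the given tumor purity.  Normal
# cells contribute two reference-bearing copies each.
expected_vaf <- function(purity, multiplicity, ccf, total_cn) {
  stopifnot(all(purity > 0), all(purity <= 1))
  purity * multiplicity * ccf / (purity * total_cn + 2 * (1 - purity))
}

check_purity <- function(purity) {
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("`purity` must be a single number in (0, 1]", call. = FALSE)
  }
  invisible(purity)
}

# seed handling: run `expr` under a fixed seed without clobbering the caller's
# RNG state; seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
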