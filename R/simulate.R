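## -------------------------------------------------------------------------
## Forward simulator: tumor histories with known ground truth.
##
## The generative model mirrors the one the timing estimators invert: point
## mutations accrue on each allele copy as a Poisson process with a constant
## rate r per copy per unit molecular time on [0, 1] (1 = emergence of the
## most recent common ancestor), and a copy-number gain duplicates every
## mutation already present on the gained copy.  Multi-gain states (3:1, 4:1)
## follow a chain lineage: each subsequent duplication copies a descendant of
## the previously duplicated copy.
## -------------------------------------------------------------------------

#' Specify a clonal copy-number gain event
#'
#' Describes the history of one gained segment: its final allele-specific
#' copy-number state and the molecular times of the sequential duplications
#' that produced it.
#'
#' @param segment_id Identifier for the segment.
#' @param major_cn,minor_cn Final allele copy numbers. Supported states are
#'   2:1 (trisomy), 2:0 (copy-neutral LOH), 3:1 and 4:1 (multi-gain).
#' @param event_times Molecular times in `[0, 1]`, strictly increasing, one
#'   per sequential duplication (`major_cn - 1` of them).
#' @param rate Expected number of mutations per allele copy per unit
#'   molecular time (the constant clonal mutation rate r).
#' @return An object of class `gain_event_spec`.
#' @examples
#' gain_event_spec("chr3", 2, 1, event_times = 0.4, rate = 100)
#' @export
gain_event_spec <- function(segment_id, major_cn, minor_cn, event_times,
                            rate = 100) {
  state <- paste0(major_cn, ":", minor_cn)
  if (!state %in% c("2:1", "2:0", "3:1", "4:1")) {
    stop("unsupported final state ", state,
         " (supported: 2:1, 2:0, 3:1, 4:1)", call. = FALSE)
  }
  if (length(event_times) != major_cn - 1L) {
    stop("need ", major_cn - 1L, " event time(s) for a ", state, " state",
         call. = FALSE)
  }
  if (any(event_times < 0) || any(event_times > 1)) {
    stop("event_times must lie in [0, 1]", call. = FALSE)
  }
  if (length(event_times) > 1L && any(diff(event_times) <= 0)) {
    stop("event_times must be strictly increasing", call. = FALSE)
  }
  if (rate < 0) stop("rate must be nonnegative", call. = FALSE)
  structure(
    list(segment_id = segment_id, major_cn = as.integer(major_cn),
         minor_cn = as.integer(minor_cn), event_times = as.numeric(event_times),
         rate = rate),
    class = "gain_event_spec"
  )
}

#' @export
print.gain_event_spec <- function(x, ...) {
  cat(sprintf("<gain_event_spec> %s  state %d:%d  T = (%s)  rate %g\n",
              x$segment_id, x$major_cn, x$minor_cn,
              paste(signif(x$event_times, 3), collapse = ", "), x$rate))
  invisible(x)
}

# Decompose the chain-lineage gain history into copy-lineage intervals.
# Each row is a stretch of one allele-copy lineage: mutations landing on it
# end up at the stated final multiplicity.  Durations sum, weighted by
# multiplicity, to the number of terminal copies.
gain_lineage_intervals <- function(spec) {
  tt <- spec$event_times
  g <- length(tt)                       # number of duplications
  out <- list()
  # chain intervals on the gained allele: a mutation in (t_{j-1}, t_j) on the
  # chain copy is propagated to all later daughters -> multiplicity M - j + 1
  t0 <- c(0, tt)
  for (j in seq_len(g)) {
    out[[length(out) + 1L]] <- data.frame(
      lineage = paste0("chain", j), start = t0[j], end = t0[j + 1L],
      multiplicity = spec$major_cn - j + 1L)
  }
  # terminal copies on the gained allele: the off-chain daughter of each gain
  # (two for the last gain) accrues single-copy mutations until the present
  for (j in seq_len(g)) {
    n_copies <- if (j == g) 2L else 1L
    for (cc in seq_len(n_copies)) {
      out[[length(out) + 1L]] <- data.frame(
        lineage = paste0("terminal", j, letters[cc]), start = tt[j], end = 1,
        multiplicity = 1L)
    }
  }
  # minor-allele copies (lost entirely in CN-LOH, so contribute nothing)
  for (m in seq_len(spec$minor_cn)) {
    out[[length(out) + 1L]] <- data.frame(
      lineage = paste0("minor", m), start = 0, end = 1, multiplicity = 1L)
  }
  do.call(rbind, out)
}

#' Expected clonal mutation counts per multiplicity class
#'
#' Closed-form expectations of the CN1..CN4 multiplicity-class counts under
#' the constant-rate chain-lineage model, i.e. the analytic fixed points the
#' timing estimators invert.
#'
#' @param spec A [gain_event_spec()].
#' @return Named numeric vector `c(CN1 = ..., CN2 = ..., CN3 = ..., CN4 = ...)`.
#' @examples
#' expected_multiplicity_counts(gain_event_spec("s", 2, 1, 0.6, rate = 100))
#' @export
expected_multiplicity_counts <- function(spec) {
  iv <- gain_lineage_intervals(spec)
  ex <- c(CN1 = 0, CN2 = 0, CN3 = 0, CN4 = 0)
  for (i in seq_len(nrow(iv))) {
    m <- iv$multiplicity[i]
    ex[m] <- ex[m] + spec$rate * (iv$end[i] - iv$start[i])
  }
  ex
}

#' Simulate the clonal mutation history of a gained segment
#'
#' Draws mutations as Poisson counts on each allele-copy lineage interval
#' (uniform times within the interval); a mutation present on a copy at
#' duplication time appears on both daughter copies, fixing its final
#' multiplicity.
#'
#' @param spec A [gain_event_spec()].
#' @param seed Optional integer seed.
#' @return A data.frame with one row per mutation: `mutation_id`,
#'   `segment_id`, `lineage`, `time` (molecular time of acquisition) and
#'   `multiplicity`.
#' @export
simulate_gain_history <- function(spec, seed = NULL) {
  if (!inherits(spec, "gain_event_spec")) {
    stop("`spec` must be a gain_event_spec", call. = FALSE)
  }
  with_seed(seed, {
    iv <- gain_lineage_intervals(spec)
    rows <- lapply(seq_len(nrow(iv)), function(i) {
      dur <- iv$end[i] - iv$start[i]
      n <- stats::rpois(1L, spec$rate * dur)
      if (n == 0L) return(NULL)
      data.frame(segment_id = spec$segment_id, lineage = iv$lineage[i],
                 time = iv$start[i] + stats::runif(n) * dur,
                 multiplicity = iv$multiplicity[i])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(segment_id = character(), lineage = character(),
                        time = numeric(), multiplicity = integer())
    }
    out <- out[order(out$time), , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out)) {
      out <- cbind(mutation_id = paste0(spec$segment_id, "_m",
                                        seq_len(nrow(out))), out)
    } else {
      out <- cbind(mutation_id = character(), out)
    }
    out
  })
}

#' Simulate sequencing read counts for a mutation table
#'
#' Per mutation and sample, total depth is Poisson and the alternate-read
#' count binomial at the expected variant allele fraction
#' `purity * multiplicity * ccf / (purity * total_cn + 2 * (1 - purity))`.
#'
#' @param mutations Data.frame with columns `mutation_id`, `segment_id`,
#'   `multiplicity`, `total_cn` and either a single `ccf` column (one sample)
#'   or one `ccf.<sample_id>` column per sample.
#' @param purity Tumor purity in `(0, 1]`.
#' @param depth Mean sequencing coverage (> 0).
#' @param samples Character vector of sample ids; defaults to the `ccf.*`
#'   columns found, else a single sample `"S1"`.
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @return A data.frame (one row per mutation x sample): `mutation_id`,
#'   `sample_id`, `alt_reads`, `total_reads`, `segment_id`.
#' @export
simulate_reads <- function(mutations, purity, depth, samples = NULL,
                           seed = NULL) {
  check_purity(purity)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  ccf_cols <- grep("^ccf\\.", names(mutations), value = TRUE)
  if (is.null(samples)) {
    samples <- if (length(ccf_cols)) sub("^ccf\\.", "", ccf_cols) else "S1"
  }
  with_seed(seed, {
    out <- lapply(samples, function(s) {
      col <- if (paste0("ccf.", s) %in% names(mutations)) {
        mutations[[paste0("ccf.", s)]]
      } else if ("ccf" %in% names(mutations)) {
        mutations$ccf
      } else {
        rep(1, nrow(mutations))
      }
      ev <- expected_vaf(purity, mutations$multiplicity, col,
                         mutations$total_cn)
      if (any(ev > 1 + 1e-9)) stop("expected VAF above 1; check inputs",
                                   call. = FALSE)
      tot <- stats::rpois(nrow(mutations), depth)
      alt <- stats::rbinom(nrow(mutations), tot, clip(ev))
      data.frame(mutation_id = mutations$mutation_id, sample_id = s,
                 alt_reads = alt, total_reads = tot,
                 segment_id = mutations$segment_id)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

## -------------------------------------------------------------------------
## Whole-patient simulation
## -------------------------------------------------------------------------

#' Simulate a tumor with known gain times, subclone tree and read counts
#'
#' Builds a complete synthetic patient: clonal mutations accrued on gained
#' and diploid segments under the constant-rate model, subclonal mutations
#' placed on terminal copies after the last gain, per-sample subclone CCFs
#' from a planted clone tree, and binomial read counts at the requested
#' depth.
#'
#' @param segments Data.frame with columns `segment_id`, `chrom`, `start`,
#'   `end`, `major_cn`, `minor_cn` and up to three event-time columns `t1`,
#'   `t2`, `t3` (NA where unused; all NA for ungained 1:1 segments).
#' @param purity Tumor purity in `(0, 1]`.
#' @param rate Clonal mutation rate per copy per unit molecular time.
#' @param subclones Optional list with `parent` (parent vector over k
#'   subclones, 0 for the root), `ccf` (k x n_samples matrix of per-sample
#'   CCFs; row 1 is the clone/root at CCF 1) and `n_mutations` (length-k
#'   vector). Defaults to a single fully clonal node carrying no extra
#'   mutations.
#' @param depth Mean coverage for the read simulation.
#' @param sample_ids Sample names (default `"S1"`, ... matching `ccf` cols).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `tumor_truth`: list with `mutations` (truth
#'   table incl. multiplicity, subclone and per-sample CCF), `reads`,
#'   `segments`, `purity`, `subclones`.
#' @export
simulate_patient <- function(segments, purity = 1, rate = 100,
                             subclones = NULL, depth = 60,
                             sample_ids = NULL, seed = NULL) {
  check_purity(purity)
  if (is.null(subclones)) {
    subclones <- list(parent = 0L, ccf = matrix(1, 1, 1), n_mutations = 0L)
  }
  ccf <- as.matrix(subclones$ccf)
  k <- nrow(ccf)
  n_samp <- ncol(ccf)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samp))
  with_seed(seed, {
    muts <- list()
    for (i in seq_len(nrow(segments))) {
      seg <- segments[i, ]
      total_cn <- seg$major_cn + seg$minor_cn
      tt <- unlist(seg[intersect(c("t1", "t2", "t3"), names(seg))])
      tt <- as.numeric(tt[!is.na(tt)])
      if (seg$major_cn >= 2 && length(tt)) {
        spec <- gain_event_spec(seg$segment_id, seg$major_cn, seg$minor_cn,
                                tt, rate)
        h <- simulate_gain_history(spec)
      } else {
        n <- stats::rpois(1L, rate * total_cn)
        h <- data.frame(
          mutation_id = if (n) paste0(seg$segment_id, "_m", seq_len(n))
                        else character(),
          segment_id = rep(seg$segment_id, n),
          lineage = rep("diploid", n), time = stats::runif(n),
          multiplicity = rep(1L, n))
      }
      if (nrow(h) == 0L) next
      h$total_cn <- total_cn
      h$subclone <- 1L                   # clonal: root of the tree
      muts[[length(muts) + 1L]] <- h
    }
    # subclonal mutations: single terminal copies, CCF from the planted tree;
    # placed on ungained (or post-last-gain) copies so multiplicity is 1
    for (j in seq_len(k)) {
      nm <- subclones$n_mutations[j]
      if (j == 1L || nm == 0L) next
      host <- segments[which.max(segments$end - segments$start), ]
      muts[[length(muts) + 1L]] <- data.frame(
        mutation_id = paste0("sub", j, "_m", seq_len(nm)),
        segment_id = host$segment_id, lineage = "subclonal",
        time = 1 + stats::runif(nm), multiplicity = 1L,
        total_cn = host$major_cn + host$minor_cn, subclone = j)
    }
    mutations <- do.call(rbind, muts)
    rownames(mutations) <- NULL
    for (s in seq_len(n_samp)) {
      mutations[[paste0("ccf.", sample_ids[s])]] <- ccf[mutations$subclone, s]
    }
    reads <- simulate_reads(mutations, purity, depth, samples = sample_ids)
    structure(list(mutations = mutations, reads = reads, segments = segments,
                   purity = purity, rate = rate,
                   subclones = c(subclones, list(sample_ids = sample_ids))),
              class = "tumor_truth")
  })
}

#' @export
print.tumor_truth <- function(x, ...) {
  cat(sprintf(
    "<tumor_truth> purity %.2f, %d segment(s), %d mutation(s), %d subclone(s), %d sample(s)\n",
    x$purity, nrow(x$segments), nrow(x$mutations),
    nrow(as.matrix(x$subclones$ccf)), length(x$subclones$sample_ids)))
  invisible(x)
}

#' Simulate structural variants placed before or after a trisomy
#'
#' Places SV breakpoints inside clonal 2:1 segments either on the gained
#' allele before the duplication (expected adjusted VAF 2/3) or on a single
#' copy after it (expected 1/3), then draws supporting-read counts through
#' the same read model as for point mutations.
#'
#' @param n Number of SVs.
#' @param purity Tumor purity in `(0, 1]`.
#' @param depth Mean coverage at the breakpoints.
#' @param prop_pregain Fraction of SVs placed before the gain.
#' @param seed Integer seed.
#' @return Data.frame with `sv_id`, `placement` (truth: `"pre"`/`"post"`),
#'   `multiplicity`, `supporting_reads`, `total_reads`, `total_cn`, `ccf`.
#' @export
simulate_svs <- function(n, purity = 1, depth = 100, prop_pregain = 0.5,
                         seed = NULL) {
  check_purity(purity)
  with_seed(seed, {
    pre <- stats::runif(n) < prop_pregain
    mult <- ifelse(pre, 2L, 1L)
    ev <- expected_vaf(purity, mult, 1, 3)
    tot <- stats::rpois(n, depth)
    sup <- stats::rbinom(n, tot, clip(ev))
    data.frame(sv_id = paste0("sv", seq_len(n)),
               placement = ifelse(pre, "pre", "post"),
               multiplicity = mult, supporting_reads = sup,
               total_reads = tot, total_cn = 3L, ccf = 1)
  })
}

## -------------------------------------------------------------------------
## Cohort-level driver-matrix simulation (logic gates on a DAG)
## -------------------------------------------------------------------------

# evaluate a named gate or truth-table on a 0/1 parent matrix (rows patients)
apply_gate <- function(gate, parents) {
  if (is.function(gate)) return(as.integer(gate(parents)))
  if (is.numeric(gate)) {               # truth table, parent-config indexed
    idx <- as.integer(parents %*% 2^(seq_len(ncol(parents)) - 1L)) + 1L
    return(as.integer(gate[idx]))
  }
  switch(toupper(gate),
    AND  = as.integer(rowSums(parents) == ncol(parents)),
    OR   = as.integer(rowSums(parents) > 0),
    XOR  = as.integer(rowSums(parents) %% 2L == 1L),
    NAND = as.integer(rowSums(parents) < ncol(parents)),
    NOT  = as.integer(1L - parents[, 1L]),
    stop("unknown gate: ", gate, call. = FALSE))
}

#' Simulate a binary patient-by-driver event matrix from a gate network
#'
#' Root events are independent Bernoulli draws; each child node is a boolean
#' gate of its parents (at most three), with independent bit-flip noise
#' applied to every entry afterwards.
#'
#' @param network List describing the DAG, one element per event, each a list
#'   with `parents` (character vector, possibly empty), `gate` (`"AND"`,
#'   `"OR"`, `"XOR"`, `"NAND"`, a 0/1 truth table over parent configurations,
#'   or a function) and, for roots, `prevalence`.
#' @param n_patients Number of rows to draw.
#' @param noise Per-entry bit-flip probability in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix, patients x events.
#' @export
simulate_cohort_matrix <- function(network, n_patients, noise = 0,
                                   seed = NULL) {
  events <- names(network)
  if (is.null(events)) stop("`network` must be a named list", call. = FALSE)
  for (e in events) {
    p <- network[[e]]$parents %||% character()
    if (length(p) > 3L) stop("at most three parents per node", call. = FALSE)
    if (!all(p %in% events)) stop("unknown parent of ", e, call. = FALSE)
  }
  order <- topo_order(lapply(network, function(x) x$parents %||% character()))
  with_seed(seed, {
    mat <- matrix(0L, n_patients, length(events),
                  dimnames = list(NULL, events))
    for (e in order) {
      nd <- network[[e]]
      parents <- nd$parents %||% character()
      mat[, e] <- if (length(parents) == 0L) {
        stats::rbinom(n_patients, 1L, nd$prevalence %||% 0.5)
      } else {
        apply_gate(nd$gate %||% "AND", mat[, parents, drop = FALSE])
      }
    }
    if (noise > 0) {
      flip <- matrix(stats::rbinom(length(mat), 1L, noise), nrow(mat))
      mat <- abs(mat - flip)
    }
    storage.mode(mat) <- "integer"
    mat
  })
}

# topological order of a parent-list DAG; errors on cycles
topo_order <- function(parents) {
  nodes <- names(parents)
  placed <- character()
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n)
      all(parents[[n]] %in% placed), logical(1))]
    if (!length(ready)) stop("network specification is cyclic", call. = FALSE)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Simulate within-patient precedence pairs from planted earliness abilities
#'
#' For each synthetic patient, a random subset of events is observed and
#' every observed pair is ordered by a Bradley-Terry draw on the planted
#' abilities; used to test cohort-level ranking recovery.
#'
#' @param abilities Named numeric vector of planted log-abilities.
#' @param n_patients Number of patients.
#' @param events_per_patient Number of events observed per patient.
#' @param seed Integer seed.
#' @return Data.frame of `patient_id`, `event_a`, `event_b`, `a_before_b`.
#' @export
simulate_precedence_cohort <- function(abilities, n_patients,
                                       events_per_patient = length(abilities),
                                       seed = NULL) {
  ev <- names(abilities)
  with_seed(seed, {
    out <- list()
    for (p in seq_len(n_patients)) {
      obs <- sample(ev, min(events_per_patient, length(ev)))
      if (length(obs) < 2L) next
      prs <- utils::combn(sort(obs), 2L)
      pa <- stats::plogis(abilities[prs[1L, ]] - abilities[prs[2L, ]])
      out[[p]] <- data.frame(patient_id = paste0("P", p),
                             event_a = prs[1L, ], event_b = prs[2L, ],
                             a_before_b = stats::runif(ncol(prs)) < pa)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}
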