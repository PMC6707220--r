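## -------------------------------------------------------------------------
## Per-patient end-to-end reconstruction: multiplicity assignment ->
## subclone clustering -> tree enumeration -> gain timing and time windows
## -> SV timing -> annotated, time-ordered event tree.
## -------------------------------------------------------------------------

#' Reconstruct the chronology of one patient
#'
#' Runs the full pipeline on one patient's inputs with a shared
#' configuration: per-gained-segment multiplicity assignment, Dirichlet
#' process subclone clustering of confidently classed mutations, pigeonhole
#' tree enumeration, molecular timing of eligible gains with bootstrap CIs
#' and time-window grouping, and r-VAF-based SV timing. Stages fail soft:
#' a stage that errors or abstains leaves its slot `NULL` and a message in
#' the log, and later stages still run where their inputs exist.
#'
#' @param reads SNV read table (`mutation_id`, `sample_id`, `alt_reads`,
#'   `total_reads`, `segment_id`).
#' @param segments Segment table (`segment_id`, `start`, `end`, `major_cn`,
#'   `minor_cn`, `purity`; optional per-sample presence columns
#'   `present.<sample_id>` for serial consistency).
#' @param svs Optional SV table for [time_svs()] (may be `NULL` or empty).
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed (clustering and bootstraps).
#' @return Object of class `timed_event_tree`: list with `tree` (a
#'   `clone_tree` or NULL), `trees` (all enumerated trees), `subclones`,
#'   `timings` (list of `gain_timing`), `windows` (named labels,
#'   1 = earliest), `sv_calls`, `ploidy`, `multiplicity` (per segment),
#'   `log` (character vector of stage messages).
#' @export
reconstruct_patient <- function(reads, segments, svs = NULL,
                                config = default_config(), seed = 1) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  seg_samples <- sort(unique(reads$sample_id))
  if (!all(reads$segment_id %in% segments$segment_id)) {
    stop("read table references segments missing from the segment table",
         call. = FALSE)
  }
  purity <- segments$purity[1]
  note("inputs: %d read rows, %d segments, %d sample(s)",
       nrow(reads), nrow(segments), length(seg_samples))

  ## stage 1: multiplicity assignment within gained segments -------------
  mult <- rep(1L, length(unique(reads$mutation_id)))
  names(mult) <- sort(unique(reads$mutation_id))
  tcn <- stats::setNames(
    segments$major_cn + segments$minor_cn, segments$segment_id)
  mut_seg <- reads$segment_id[match(names(mult), reads$mutation_id)]
  mult_results <- list()
  confident <- rep(TRUE, length(mult))
  names(confident) <- names(mult)
  first_sample <- seg_samples[1L]
  for (sid in segments$segment_id[segments$major_cn >= 2]) {
    in_seg <- names(mult)[mut_seg == sid]
    rr <- reads[reads$mutation_id %in% in_seg &
                  reads$sample_id == first_sample, ]
    if (nrow(rr) < 2L) next
    res <- tryCatch(
      assign_multiplicity(rr$alt_reads, rr$total_reads, purity,
                          segments$major_cn[segments$segment_id == sid],
                          segments$minor_cn[segments$segment_id == sid],
                          min_assign_prob = config$min_assign_prob),
      error = function(e) { note("multiplicity[%s]: %s", sid,
                                 conditionMessage(e)); NULL })
    if (is.null(res)) next
    mult_results[[sid]] <- res
    cls <- stats::setNames(res$assignments, rr$mutation_id)
    mult[names(cls)] <- ifelse(is.na(cls), 1L, cls)
    confident[names(cls)] <- !is.na(cls)
    note("multiplicity[%s]: %s, %d unassigned", sid,
         paste(names(res$counts), res$counts, sep = "=", collapse = " "),
         res$n_unassigned)
  }

  ## stage 2: subclone clustering ----------------------------------------
  keep_ids <- names(mult)[confident]
  cl_reads <- reads[reads$mutation_id %in% keep_ids, , drop = FALSE]
  subclones <- NULL
  chain <- tryCatch(
    gibbs_cluster(cl_reads, purity,
                  multiplicity = mult[keep_ids],
                  total_cn = stats::setNames(
                    tcn[mut_seg[match(keep_ids, names(mult))]], keep_ids),
                  n_iter = config$n_iter, n_burnin = config$n_burnin,
                  seed = seed),
    error = function(e) { note("clustering: %s", conditionMessage(e)); NULL })
  if (!is.null(chain)) {
    subclones <- posterior_point_estimates(chain)
    note("clustering: %d cluster(s)", length(subclones$clusters))
  }

  ## stage 3: tree enumeration -------------------------------------------
  trees <- list()
  if (!is.null(subclones)) {
    cfg <- pigeonhole_config(config$tolerated_error, config$min_mutations)
    trees <- tryCatch(enumerate_trees(subclones, cfg),
                      error = function(e) {
                        note("trees: %s", conditionMessage(e)); list() })
    note("trees: %d compatible tree(s)", length(trees))
  }

  ## stage 4: gain timing + time windows ---------------------------------
  gained <- segments[segments$major_cn >= 2, , drop = FALSE]
  gained$n_clonal_snvs <- vapply(gained$segment_id, function(sid) {
    r <- mult_results[[sid]]
    if (is.null(r)) 0L else sum(!is.na(r$assignments))
  }, integer(1))
  eligible <- filter_segments(gained, config$min_segment_length,
                              config$min_clonal_snvs)
  timings <- list()
  for (sid in eligible$segment_id) {
    res <- mult_results[[sid]]
    state <- paste0(eligible$major_cn[eligible$segment_id == sid], ":",
                    eligible$minor_cn[eligible$segment_id == sid])
    t <- tryCatch(
      bootstrap_timing(res, state, n_boot = config$n_boot,
                       alpha = config$alpha, seed = seed, segment_id = sid),
      error = function(e) { note("timing[%s]: %s", sid,
                                 conditionMessage(e)); NULL })
    if (!is.null(t)) timings[[sid]] <- t
  }
  note("timing: %d eligible gain(s) timed (of %d gained segments)",
       length(timings), nrow(gained))
  windows <- NULL
  if (length(timings)) {
    pres_cols <- grep("^present\\.", names(segments), value = TRUE)
    presence <- NULL
    if (length(pres_cols) >= 2L) {
      presence <- as.matrix(
        segments[match(names(timings), segments$segment_id), pres_cols])
    }
    windows <- group_time_windows(timings, presence)
    note("windows: %d window(s)", max(windows))
  }

  ## stage 5: SV timing ----------------------------------------------------
  sv_calls <- NULL
  if (!is.null(svs) && nrow(svs) > 0L) {
    sv_calls <- tryCatch(time_svs(svs, purity, config$rvaf_threshold),
                         error = function(e) {
                           note("sv timing: %s", conditionMessage(e)); NULL })
    if (!is.null(sv_calls)) {
      note("sv timing: %d SV(s), %d indeterminate", nrow(sv_calls),
           sum(sv_calls$call == "indeterminate"))
    }
  } else {
    note("sv timing: no SVs supplied")
  }

  ploidy <- genome_ploidy(segments, sample_id = first_sample)
  structure(list(tree = if (length(trees)) trees[[1L]] else NULL,
                 trees = trees, subclones = subclones,
                 timings = timings, windows = windows, sv_calls = sv_calls,
                 ploidy = ploidy, multiplicity = mult_results, log = log),
            class = "timed_event_tree")
}

#' @export
print.timed_event_tree <- function(x, ...) {
  cat("<timed_event_tree>\n")
  cat(sprintf("  ploidy %.2f (WGD: %s)\n", x$ploidy$ploidy,
              if (x$ploidy$wgd) "yes" else "no"))
  if (!is.null(x$windows)) {
    for (w in sort(unique(x$windows))) {
      segs <- names(x$windows)[x$windows == w]
      ts <- vapply(segs, function(s) unname(x$timings[[s]]$estimates[1L]),
                   numeric(1))
      cat(sprintf("  window %d: %s\n", w,
                  paste(sprintf("%s (T=%.2f)", segs, ts), collapse = ", ")))
    }
  }
  if (!is.null(x$tree)) cat("  tree:", tree_newick(x$tree), "\n")
  if (!is.null(x$sv_calls)) {
    cat(sprintf("  SVs: %s\n",
                paste(sprintf("%s=%s", x$sv_calls$sv_id, x$sv_calls$call),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Consistency of single-sample molecular timing with serial samples
#'
#' Compares the within-sample time-window ordering of gains (from the
#' latest sample alone) against the model-free ordering implied by
#' presence/absence across the serial samples: for every pair of gains
#' where one is present and the other absent in an earlier sample, the
#' present gain should sit in an earlier (or equal) molecular-time window.
#'
#' @param windows Named window labels (1 = earliest) from
#'   [group_time_windows()] on the latest sample.
#' @param presence Logical matrix (segments x serial samples, earliest
#'   first): CNA present in that sample?
#' @return List: `n_pairs` informative pairs, `n_agree`, `agreement`
#'   (fraction; `NaN` when vacuous -- reported as 1 with `vacuous = TRUE`).
#' @export
validate_serial_timing <- function(windows, presence) {
  presence <- as.matrix(presence)
  if (ncol(presence) < 2L) stop("need >= 2 serial samples", call. = FALSE)
  segs <- names(windows)
  n_pairs <- 0L
  n_agree <- 0L
  for (s in seq_len(ncol(presence) - 1L)) {
    for (a in seq_along(segs)) {
      for (b in seq_along(segs)) {
        if (a == b) next
        # a present early, b not yet there: a should not be in a later window
        if (presence[a, s] && !presence[b, s]) {
          n_pairs <- n_pairs + 1L
          if (windows[a] <= windows[b]) n_agree <- n_agree + 1L
        }
      }
    }
  }
  vacuous <- n_pairs == 0L
  list(n_pairs = n_pairs, n_agree = n_agree,
       agreement = if (vacuous) 1 else n_agree / n_pairs,
       vacuous = vacuous)
}
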