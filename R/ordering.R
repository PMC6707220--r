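## -------------------------------------------------------------------------
## Cohort-level ordering of recurrent lesions: within-patient precedence
## pairs from molecular times (CI separation) and CCFs (clonal before
## subclonal), fed into a Bradley-Terry paired-comparison model.
## -------------------------------------------------------------------------

#' Derive within-patient precedence pairs
#'
#' For two molecularly timed gains, event a precedes b only when a's
#' bootstrap interval lies strictly below b's. For lesions ordered by
#' clonality (deletions and other untimed events), a clonal lesion
#' (CCF >= `clonal_ccf`) precedes a subclonal one in the same sample.
#' Ambiguous evidence (overlapping intervals, both clonal, both subclonal)
#' emits no pair. With `use_earliest_sample_only` (the default), only each
#' patient's earliest sample contributes.
#'
#' @param events Data.frame with one row per lesion per patient sample:
#'   `patient_id`, `sample_id`, `event` (recurrent-lesion label),
#'   `sample_order` (1 = earliest), and either `t_lower`/`t_upper`
#'   (bootstrap CI of the molecular time; NA when untimed) or `ccf`.
#' @param use_earliest_sample_only Keep only `sample_order == 1` rows.
#' @param clonal_ccf CCF at or above which a lesion counts as clonal
#'   (default 0.95).
#' @return Data.frame of `patient_id`, `event_a`, `event_b`, `a_before_b`.
#' @export
derive_precedence_pairs <- function(events, use_earliest_sample_only = TRUE,
                                    clonal_ccf = 0.95) {
  ev <- events
  if (use_earliest_sample_only && "sample_order" %in% names(ev)) {
    ev <- ev[ev$sample_order == 1, , drop = FALSE]
  }
  has <- function(col) col %in% names(ev)
  out <- list()
  for (pid in unique(ev$patient_id)) {
    sub <- ev[ev$patient_id == pid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in seq(i + 1L, nrow(sub))) {
        a <- sub[i, ]; b <- sub[j, ]
        if (a$event == b$event) next
        verdict <- NA
        timed_a <- has("t_lower") && !is.na(a$t_lower)
        timed_b <- has("t_lower") && !is.na(b$t_lower)
        if (timed_a && timed_b) {
          if (a$t_upper < b$t_lower) verdict <- TRUE
          else if (b$t_upper < a$t_lower) verdict <- FALSE
        } else if (has("ccf") && !is.na(a$ccf) && !is.na(b$ccf)) {
          clon_a <- a$ccf >= clonal_ccf
          clon_b <- b$ccf >= clonal_ccf
          if (clon_a && !clon_b) verdict <- TRUE
          else if (clon_b && !clon_a) verdict <- FALSE
        }
        if (!is.na(verdict)) {
          out[[length(out) + 1L]] <- data.frame(
            patient_id = pid, event_a = a$event, event_b = b$event,
            a_before_b = verdict)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), event_a = character(),
                      event_b = character(), a_before_b = logical()))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit a Bradley-Terry earliness ranking from precedence pairs
#'
#' Maximum-likelihood abilities for `P(a before b) =
#' exp(beta_a) / (exp(beta_a) + exp(beta_b))` via the standard monotone
#' minorization-maximization updates, regularized by a symmetric pseudo-win
#' augmentation (`ridge` added to both directions of every pair), which
#' keeps separable data (an event with only wins) finite. The augmented
#' log-likelihood is asserted to be nondecreasing across iterations.
#' Abilities are reported relative to the first event (fixed at 0).
#'
#' @param pairs Data.frame from [derive_precedence_pairs()] (or any with
#'   `event_a`, `event_b`, `a_before_b`).
#' @param ridge Pseudo-win weight added in both directions of every event
#'   pair (default 1e-3).
#' @param max_iter,tol Convergence controls (max absolute ability change
#'   below `tol` stops; default 1e-8).
#' @return Object of class `bt_ranking`: data.frame `ranking` (event,
#'   ability, se, rank), plus `wins` matrix, `logLik`, `iterations`,
#'   `separable` flag.
#' @export
fit_bradley_terry <- function(pairs, ridge = 1e-3, max_iter = 10000,
                              tol = 1e-8) {
  events <- sort(unique(c(pairs$event_a, pairs$event_b)))
  m <- length(events)
  if (m < 2L) stop("need at least two events", call. = FALSE)
  wins <- matrix(0, m, m, dimnames = list(events, events))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$event_a[i]; b <- pairs$event_b[i]
    if (pairs$a_before_b[i]) wins[a, b] <- wins[a, b] + 1
    else wins[b, a] <- wins[b, a] + 1
  }
  check_connected_components(wins)
  separable <- any(rowSums(wins) > 0 & colSums(wins) == 0) ||
    any(colSums(wins) > 0 & rowSums(wins) == 0)
  # symmetric augmentation: weak prior toward equal abilities
  waug <- wins + ridge * (1 - diag(m))
  nmat <- waug + t(waug)
  ll_fun <- function(p) {
    lp <- log(p)
    s <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && waug[i, j] > 0) {
        s <- s + waug[i, j] * (lp[i] - log(p[i] + p[j]))
      }
    }
    s
  }
  p <- rep(1, m)
  ll_old <- ll_fun(p)
  it <- 0L
  repeat {
    it <- it + 1L
    p_new <- p
    for (i in seq_len(m)) {
      denom <- sum(nmat[i, -i] / (p_new[i] + p_new[-i]))
      p_new[i] <- sum(waug[i, ]) / denom
    }
    p_new <- p_new / exp(mean(log(p_new)))    # fix the gauge
    ll_new <- ll_fun(p_new)
    if (ll_new < ll_old - 1e-9) {
      stop("internal error: MM update decreased the likelihood",
           call. = FALSE)
    }
    delta <- max(abs(log(p_new) - log(p)))
    p <- p_new
    ll_old <- ll_new
    if (delta < tol || it >= max_iter) break
  }
  beta <- log(p) - log(p)[1L]            # reference event fixed at 0
  se <- bt_standard_errors(p, nmat)
  ranking <- data.frame(event = events, ability = beta, se = se,
                        rank = rank(-beta, ties.method = "min"))
  ranking <- ranking[order(ranking$rank), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, wins = wins, logLik = ll_old,
                 iterations = it, ridge = ridge, separable = separable),
            class = "bt_ranking")
}

# observed-information standard errors on the log-ability scale, with the
# reference (first) ability fixed; NA for the reference itself
bt_standard_errors <- function(p, nmat) {
  m <- length(p)
  info <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j || nmat[i, j] == 0) next
    w <- nmat[i, j] * p[i] * p[j] / (p[i] + p[j])^2
    info[i, i] <- info[i, i] + w
    info[i, j] <- info[i, j] - w
  }
  free <- seq_len(m)[-1L]
  se <- rep(NA_real_, m)
  cov <- try(solve(info[free, free, drop = FALSE]), silent = TRUE)
  if (!inherits(cov, "try-error")) se[free] <- sqrt(pmax(diag(cov), 0))
  se
}

check_connected_components <- function(wins) {
  m <- nrow(wins)
  adj <- (wins + t(wins)) > 0
  seen <- logical(m)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    warning("comparison graph is disconnected; abilities are only ",
            "comparable within connected components")
  }
  invisible(all(seen))
}

#' @export
print.bt_ranking <- function(x, ...) {
  cat(sprintf("<bt_ranking> %d events, %d comparisons, %d MM iterations%s\n",
              nrow(x$ranking), sum(x$wins), x$iterations,
              if (x$separable) " (separable data; ridge-regularized)" else ""))
  print(x$ranking, digits = 3)
  invisible(x)
}
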