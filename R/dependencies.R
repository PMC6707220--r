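## -------------------------------------------------------------------------
## Dependency analysis of a binary patient x driver-event matrix: exact
## Fisher tests, logic-gate fitting of parent -> child relations, and exact
## (dynamic-programming) Bayesian-network structure search with a <= 3
## parent constraint.
## -------------------------------------------------------------------------

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Direct hypergeometric tail summation: with margins fixed, the p-value is
#' the sum of probabilities of all tables no more probable than the
#' observed one (the usual two-sided convention, with the customary 1e-7
#' relative slack on the comparison). A table with a zero margin has p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(8, 1, 2, 9), 2))
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0)) {
    stop("need a 2x2 table of nonnegative counts", call. = FALSE)
  }
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2L]) == 0) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

## ---- logic gates ---------------------------------------------------------

# A boolean function of k inputs is its truth table: an integer vector of
# length 2^k indexed by 1 + sum(input_j * 2^(j-1)).

# truth tables of the input projections
projection_tables <- function(k) {
  configs <- as.matrix(expand.grid(rep(list(0:1), k)))
  lapply(seq_len(k), function(j) configs[, j])
}

# does the function depend on every input?
depends_on_all <- function(tt, k) {
  configs <- as.matrix(expand.grid(rep(list(0:1), k)))
  for (j in seq_len(k)) {
    flipped <- configs
    flipped[, j] <- 1L - flipped[, j]
    idx <- as.integer(flipped %*% 2^(seq_len(k) - 1L)) + 1L
    if (all(tt == tt[idx])) return(FALSE)
  }
  TRUE
}

# Minimal number of {AND, OR, NOT} gates realizing each k-input function,
# with a readable expression; label-propagation to a fixpoint over the
# (at most 256) truth tables.  Memoized per k.
gate_cost_env <- new.env(parent = emptyenv())

gate_costs <- function(k) {
  key <- as.character(k)
  if (!is.null(gate_cost_env[[key]])) return(gate_cost_env[[key]])
  nfun <- 2^(2^k)
  cost <- rep(Inf, nfun)
  expr <- rep(NA_character_, nfun)
  tt_id <- function(tt) as.integer(sum(tt * 2^(seq_along(tt) - 1L))) + 1L
  proj <- projection_tables(k)
  tabs <- vector("list", nfun)
  for (j in seq_len(k)) {
    id <- tt_id(proj[[j]])
    cost[id] <- 0
    expr[id] <- paste0("p", j)
    tabs[[id]] <- proj[[j]]
  }
  repeat {
    changed <- FALSE
    known <- which(is.finite(cost))
    for (a in known) {
      # NOT
      nt <- 1L - tabs[[a]]
      id <- tt_id(nt)
      if (cost[a] + 1 < cost[id]) {
        cost[id] <- cost[a] + 1
        expr[id] <- paste0("NOT(", expr[a], ")")
        tabs[[id]] <- nt
        changed <- TRUE
      }
      for (b in known) {
        for (op in c("AND", "OR")) {
          ot <- if (op == "AND") tabs[[a]] & tabs[[b]]
                else tabs[[a]] | tabs[[b]]
          ot <- as.integer(ot)
          id <- tt_id(ot)
          newc <- cost[a] + cost[b] + 1
          if (newc < cost[id]) {
            cost[id] <- newc
            expr[id] <- paste0(op, "(", expr[a], ",", expr[b], ")")
            tabs[[id]] <- ot
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  res <- list(cost = cost, expr = expr)
  gate_cost_env[[key]] <- res
  res
}

#' Fit the best logic gate linking parent events to a child event
#'
#' Enumerates every boolean function of the (at most three) parents that
#' depends on all of them, scores each function's output vector against the
#' child column with the two-sided Fisher exact test, and returns the most
#' significant function; ties are broken by the smallest {AND, OR, NOT}
#' gate decomposition, then by truth-table order (deterministic and
#' invariant to parent ordering).
#'
#' @param mat Binary patient x event matrix with column names.
#' @param child Child event label.
#' @param parents Character vector of 1-3 parent event labels.
#' @return Object of class `gate_formula`: `child`, `parents`,
#'   `truth_table`, `expression` (over the sorted parents), `gate_count`,
#'   `fisher_p`.
#' @export
fit_logic_gate <- function(mat, child, parents) {
  if (length(parents) < 1L || length(parents) > 3L) {
    stop("1 to 3 parents required", call. = FALSE)
  }
  parents <- sort(parents)               # ordering invariance
  k <- length(parents)
  pm <- mat[, parents, drop = FALSE]
  y <- mat[, child]
  idx <- as.integer(pm %*% 2^(seq_len(k) - 1L)) + 1L
  gc <- gate_costs(k)
  best <- NULL
  for (fid in seq_len(2^(2^k))) {
    tt <- as.integer(intToBits(fid - 1L))[seq_len(2^k)]
    if (!depends_on_all(tt, k)) next
    out <- tt[idx]
    tab <- table(factor(out, levels = 0:1), factor(y, levels = 0:1))
    p <- fisher_exact(tab)
    cand <- list(p = p, gates = gc$cost[fid], fid = fid, tt = tt,
                 expr = gc$expr[fid])
    if (is.null(best) || p < best$p - 1e-15 ||
        (abs(p - best$p) <= 1e-15 && cand$gates < best$gates)) {
      best <- cand
    }
  }
  structure(list(child = child, parents = parents,
                 truth_table = best$tt, expression = best$expr,
                 gate_count = best$gates, fisher_p = best$p),
            class = "gate_formula")
}

#' @export
print.gate_formula <- function(x, ...) {
  expr <- x$expression
  for (j in seq_along(x$parents)) {
    expr <- gsub(paste0("p", j), x$parents[j], expr, fixed = TRUE)
  }
  cat(sprintf("<gate_formula> %s = %s  (%d gate%s, Fisher p = %.3g)\n",
              x$child, expr, x$gate_count, if (x$gate_count == 1) "" else "s",
              x$fisher_p))
  invisible(x)
}

## ---- BDeu scoring and exact structure search -----------------------------

# BDeu local score of `child` (0/1 vector) given binary parent columns,
# equivalent sample size `ess`
bdeu_local_score <- function(child, parent_mat, ess = 1) {
  q <- if (is.null(parent_mat) || ncol(parent_mat) == 0L) 1L
       else 2L^ncol(parent_mat)
  j <- if (q == 1L) rep(1L, length(child))
       else as.integer(parent_mat %*% 2^(seq_len(ncol(parent_mat)) - 1L)) + 1L
  a_j <- ess / q
  a_jk <- ess / (2 * q)
  s <- 0
  for (jj in seq_len(q)) {
    rows <- j == jj
    n1 <- sum(child[rows])
    n0 <- sum(rows) - n1
    s <- s + lgamma(a_j) - lgamma(a_j + n0 + n1) +
      lgamma(a_jk + n0) - lgamma(a_jk) +
      lgamma(a_jk + n1) - lgamma(a_jk)
  }
  s
}

#' Exact Bayesian-network structure search for small event sets
#'
#' Finds the globally BDeu-optimal DAG under a maximum-parents constraint
#' by exact dynamic programming over variable orders: best parent-set
#' scores are propagated over subsets, then the optimal order (and with it
#' the optimal network) is reconstructed. Deterministic; refuses more than
#' `max_events` variables (the subset lattice doubles per event).
#'
#' @param mat Binary patient x event matrix with column names.
#' @param max_parents Parent-count cap (default 3).
#' @param ess BDeu equivalent sample size (default 1).
#' @param max_events Hard cap on the number of events (default 14).
#' @return Object of class `bn_structure`: `parents` (named list), `score`
#'   (total BDeu log score), `local_scores` of the chosen parent sets.
#' @export
learn_structure_small <- function(mat, max_parents = 3, ess = 1,
                                  max_events = 14) {
  events <- colnames(mat)
  n <- length(events)
  if (n > max_events) {
    stop("too many events for exact search (", n, " > ", max_events,
         "); subset the matrix", call. = FALSE)
  }
  if (n == 1L) {
    sc <- bdeu_local_score(mat[, 1L], NULL, ess)
    return(structure(list(parents = stats::setNames(list(character()),
                                                    events),
                          score = sc,
                          local_scores = stats::setNames(sc, events)),
                     class = "bn_structure"))
  }
  full <- bitwShiftL(1L, n) - 1L
  bit <- bitwShiftL(1L, seq_len(n) - 1L)

  # best parent-set score (and set) of v among parents within each mask
  bps_score <- matrix(-Inf, n, full + 1L)
  bps_set <- matrix(0L, n, full + 1L)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    # score all parent sets up to max_parents
    for (sz in 0:min(max_parents, n - 1L)) {
      sets <- if (sz == 0L) list(integer()) else
        utils::combn(others, sz, simplify = FALSE)
      for (ps in sets) {
        msk <- sum(bit[ps])
        sc <- bdeu_local_score(mat[, v],
                               if (sz) mat[, ps, drop = FALSE] else NULL,
                               ess)
        if (sc > bps_score[v, msk + 1L]) {
          bps_score[v, msk + 1L] <- sc
          bps_set[v, msk + 1L] <- msk
        }
      }
    }
    # propagate: best over subsets of each mask
    for (msk in 0:full) {
      if (bitwAnd(msk, bit[v]) != 0L) next
      for (b in bit) {
        if (bitwAnd(msk, b) == 0L) next
        sub <- msk - b
        if (bps_score[v, sub + 1L] > bps_score[v, msk + 1L]) {
          bps_score[v, msk + 1L] <- bps_score[v, sub + 1L]
          bps_set[v, msk + 1L] <- bps_set[v, sub + 1L]
        }
      }
    }
  }

  # order DP: f[mask] = best score of a network over the events in mask
  f <- rep(-Inf, full + 1L)
  back <- integer(full + 1L)
  f[1L] <- 0  # placeholder; recomputed below (mask 0 -> score 0)
  f[0L + 1L] <- 0
  for (msk in 1:full) {
    for (v in seq_len(n)) {
      if (bitwAnd(msk, bit[v]) == 0L) next
      rest <- msk - bit[v]
      cand <- f[rest + 1L] + bps_score[v, rest + 1L]
      if (cand > f[msk + 1L]) {
        f[msk + 1L] <- cand
        back[msk + 1L] <- v
      }
    }
  }

  parents <- stats::setNames(vector("list", n), events)
  local <- stats::setNames(numeric(n), events)
  msk <- full
  while (msk > 0L) {
    v <- back[msk + 1L]
    rest <- msk - bit[v]
    pm <- bps_set[v, rest + 1L]
    ps <- which(bitwAnd(pm, bit) != 0L)
    parents[[events[v]]] <- events[ps]
    local[events[v]] <- bps_score[v, rest + 1L]
    msk <- rest
  }
  structure(list(parents = parents, score = f[full + 1L],
                 local_scores = local),
            class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("<bn_structure> %d events, BDeu score %.3f\n",
              length(x$parents), x$score))
  for (e in names(x$parents)) {
    p <- x$parents[[e]]
    cat(sprintf("  %s <- %s\n", e,
                if (length(p)) paste(p, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

# undirected skeleton edge list (sorted pairs) of a bn_structure
bn_skeleton <- function(bn) {
  edges <- character()
  for (e in names(bn$parents)) {
    for (p in bn$parents[[e]]) {
      edges <- c(edges, paste(sort(c(e, p)), collapse = "--"))
    }
  }
  sort(unique(edges))
}

#' Pairwise co-occurrence / mutual-exclusivity map
#'
#' Tests every pair of events with the two-sided Fisher exact test, labels
#' the direction by the sign of the log odds ratio (Haldane 0.5 correction
#' when a cell is empty), and adjusts p-values by Benjamini-Hochberg.
#'
#' @param mat Binary patient x event matrix with column names.
#' @return Data.frame with `event_a`, `event_b`, `odds_ratio`, `p`, `q`,
#'   `direction` (`"co-occurrence"` / `"exclusivity"` / `"none"`).
#' @export
pairwise_association_map <- function(mat) {
  events <- colnames(mat)
  if (length(events) < 2L) stop("need at least 2 events", call. = FALSE)
  prs <- utils::combn(events, 2L)
  out <- data.frame(event_a = prs[1L, ], event_b = prs[2L, ],
                    odds_ratio = NA_real_, p = NA_real_, q = NA_real_,
                    direction = NA_character_)
  for (i in seq_len(ncol(prs))) {
    a <- mat[, prs[1L, i]]; b <- mat[, prs[2L, i]]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2L)
    out$p[i] <- fisher_exact(tab)
    h <- tab + if (any(tab == 0)) 0.5 else 0
    out$odds_ratio[i] <- (h[1, 1] * h[2, 2]) / (h[1, 2] * h[2, 1])
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$odds_ratio > 1, "co-occurrence",
                          ifelse(out$odds_ratio < 1, "exclusivity", "none"))
  out
}
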