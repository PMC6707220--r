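## -------------------------------------------------------------------------
## Enumeration of subclone phylogenies compatible with the pigeonhole
## principle: in every sample, the CCFs of a node's children may not exceed
## the node's own CCF by more than a small tolerated error.
## -------------------------------------------------------------------------

#' Pigeonhole configuration
#'
#' @param tolerated_error How far (in CCF units) the summed CCF of a node's
#'   daughters may exceed the node's own CCF before the assignment is
#'   declared a violation (default 0.001).
#' @param min_mutations Subclones carrying fewer mutations than this are
#'   excluded before tree building (default 50).
#' @return List of class `pigeonhole_config`.
#' @export
pigeonhole_config <- function(tolerated_error = 0.001, min_mutations = 50) {
  if (tolerated_error < 0) stop("tolerated_error must be >= 0", call. = FALSE)
  if (min_mutations < 0) stop("min_mutations must be >= 0", call. = FALSE)
  structure(list(tolerated_error = tolerated_error,
                 min_mutations = min_mutations),
            class = "pigeonhole_config")
}

# apply the mutation-count filter; returns the CCF matrix + sizes + ids kept
filter_subclones <- function(subclones, cfg) {
  ccf <- ccf_matrix(subclones)
  sizes <- cluster_sizes(subclones)
  keep <- sizes >= cfg$min_mutations
  if (!any(keep)) stop("no subclone passes the mutation-count filter",
                       call. = FALSE)
  list(ccf = ccf[keep, , drop = FALSE], sizes = sizes[keep],
       index = which(keep))
}

#' Candidate root subclones
#'
#' A subclone is a candidate root when every other subclone is an allowed
#' daughter of it, i.e. its CCF is at least the other's CCF minus the
#' tolerated error in every sample.
#'
#' @param subclones A [subclone_set()] (or matrix of CCFs, subclones x
#'   samples).
#' @param cfg A [pigeonhole_config()].
#' @return Integer vector of candidate root indices (into the filtered
#'   subclone list).
#' @export
candidate_roots <- function(subclones, cfg = pigeonhole_config()) {
  ccf <- if (is.matrix(subclones)) subclones else
    filter_subclones(subclones, cfg)$ccf
  k <- nrow(ccf)
  if (k == 0L) stop("empty subclone set", call. = FALSE)
  tol <- cfg$tolerated_error
  which(vapply(seq_len(k), function(r) {
    others <- setdiff(seq_len(k), r)
    all(ccf[others, , drop = FALSE] <=
          rep(ccf[r, ], each = length(others)) + tol)
  }, logical(1)))
}

# is `anc` an ancestor of `node` (or equal) in partial parent vector `par`?
is_ancestor <- function(anc, node, par) {
  while (node != 0L) {
    if (node == anc) return(TRUE)
    node <- par[node]
  }
  FALSE
}

# children-sum pigeonhole check for node p in parent vector par
children_ok <- function(p, par, ccf, tol) {
  ch <- which(par == p)
  if (!length(ch)) return(TRUE)
  all(colSums(ccf[ch, , drop = FALSE]) <= ccf[p, ] + tol)
}

#' Enumerate all pigeonhole-compatible subclone trees
#'
#' Depth-first search over parent assignments: step 1 finds the candidate
#' roots; step 2 assigns each remaining subclone a parent among the
#' non-descendant subclones, accepting an assignment only while, in every
#' sample, the summed CCF of each node's current daughters exceeds the
#' node's CCF by at most the tolerated error. The result may be empty (no
#' compatible tree) and often contains exactly one tree.
#'
#' @param subclones A [subclone_set()] or CCF matrix (subclones x samples).
#' @param cfg A [pigeonhole_config()].
#' @return List of `clone_tree` objects, in lexicographic order of their
#'   parent vectors.
#' @export
enumerate_trees <- function(subclones, cfg = pigeonhole_config()) {
  if (is.matrix(subclones)) {
    ccf <- subclones
    sizes <- rep(NA_real_, nrow(ccf))
  } else {
    fl <- filter_subclones(subclones, cfg)
    ccf <- fl$ccf
    sizes <- fl$sizes
  }
  k <- nrow(ccf)
  tol <- cfg$tolerated_error
  if (k == 1L) {
    return(list(clone_tree(0L, ccf = ccf, n_mutations = sizes)))
  }
  roots <- candidate_roots(ccf, cfg)
  trees <- list()
  for (r in roots) {
    todo <- setdiff(seq_len(k), r)
    par <- integer(k)                   # 0 = unassigned / root
    recurse <- function(pos) {
      if (pos > length(todo)) {
        trees[[length(trees) + 1L]] <<- clone_tree(par, ccf = ccf,
                                                   n_mutations = sizes)
        return(invisible())
      }
      i <- todo[pos]
      for (p in seq_len(k)) {
        if (p == i || is_ancestor(i, p, par)) next
        par[i] <<- p
        if (children_ok(p, par, ccf, tol)) recurse(pos + 1L)
        par[i] <<- 0L
      }
    }
    recurse(1L)
  }
  sort_trees(trees)
}

#' Brute-force oracle for tree enumeration
#'
#' Enumerates every rooted parent vector over the subclones, keeps those
#' that form a valid single-rooted acyclic tree, whose root has every other
#' subclone as an allowed daughter, and in which every node satisfies the
#' children-sum pigeonhole constraint in every sample. Intended as an
#' independent correctness oracle for [enumerate_trees()] at small k.
#'
#' @param subclones A [subclone_set()] or CCF matrix.
#' @param cfg A [pigeonhole_config()].
#' @return List of `clone_tree` objects in lexicographic order.
#' @export
brute_force_trees <- function(subclones, cfg = pigeonhole_config()) {
  if (is.matrix(subclones)) {
    ccf <- subclones
    sizes <- rep(NA_real_, nrow(ccf))
  } else {
    fl <- filter_subclones(subclones, cfg)
    ccf <- fl$ccf
    sizes <- fl$sizes
  }
  k <- nrow(ccf)
  if (k > 7L) stop("brute force refuses k > 7 (combinatorial guard)",
                   call. = FALSE)
  tol <- cfg$tolerated_error
  if (k == 1L) return(list(clone_tree(0L, ccf = ccf, n_mutations = sizes)))
  trees <- list()
  choices <- lapply(seq_len(k), function(i) c(0L, setdiff(seq_len(k), i)))
  grid <- do.call(expand.grid, choices)
  for (g in seq_len(nrow(grid))) {
    par <- as.integer(grid[g, ])
    if (sum(par == 0L) != 1L) next
    root <- which(par == 0L)
    # acyclic + connected: every node reaches the root
    ok <- TRUE
    for (i in seq_len(k)) {
      node <- i; steps <- 0L
      while (node != root && steps <= k) { node <- par[node]; steps <- steps + 1L }
      if (node != root) { ok <- FALSE; break }
    }
    if (!ok) next
    # root candidacy: every other subclone an allowed daughter of the root
    others <- setdiff(seq_len(k), root)
    if (!all(ccf[others, , drop = FALSE] <=
             rep(ccf[root, ], each = length(others)) + tol)) next
    # children-sum constraint at every node
    if (!all(vapply(seq_len(k), function(p)
      children_ok(p, par, ccf, tol), logical(1)))) next
    trees[[length(trees) + 1L]] <- clone_tree(par, ccf = ccf,
                                              n_mutations = sizes)
  }
  sort_trees(trees)
}

sort_trees <- function(trees) {
  if (length(trees) < 2L) return(trees)
  keys <- vapply(trees, function(t)
    paste(t$parent, collapse = ","), character(1))
  trees[order(keys)]
}

#' Clone tree
#'
#' @param parent Integer parent vector (`parent[i]` is the parent of
#'   subclone i; 0 marks the root).
#' @param ccf Optional CCF matrix (subclones x samples).
#' @param n_mutations Optional per-subclone mutation counts (branch
#'   lengths).
#' @return Object of class `clone_tree`.
#' @export
clone_tree <- function(parent, ccf = NULL, n_mutations = NULL) {
  parent <- as.integer(parent)
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("exactly one root required", call. = FALSE)
  structure(list(parent = parent, root = root, ccf = ccf,
                 n_mutations = n_mutations),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d node(s), root %d, parents (%s)\n",
              length(x$parent), x$root, paste(x$parent, collapse = ", ")))
  invisible(x)
}

#' @export
format.clone_tree <- function(x, ...) tree_newick(x)

#' Newick representation of a clone tree
#'
#' Branch lengths are per-subclone mutation counts when available.
#'
#' @param tree A `clone_tree`.
#' @param labels Optional node labels (default `C1..Ck`).
#' @return Newick string (terminated by `;`).
#' @export
tree_newick <- function(tree, labels = NULL) {
  k <- length(tree$parent)
  if (is.null(labels)) labels <- paste0("C", seq_len(k))
  bl <- tree$n_mutations
  emit <- function(node) {
    ch <- which(tree$parent == node)
    lab <- labels[node]
    if (!is.null(bl) && !is.na(bl[node])) {
      lab <- paste0(lab, ":", format(bl[node], scientific = FALSE))
    }
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")",
           lab)
  }
  paste0(emit(tree$root), ";")
}

# structural validity check used by tests
tree_is_valid <- function(tree) {
  par <- tree$parent
  k <- length(par)
  if (sum(par == 0L) != 1L) return(FALSE)
  root <- which(par == 0L)
  for (i in seq_len(k)) {
    node <- i; steps <- 0L
    while (node != root) {
      node <- par[node]; steps <- steps + 1L
      if (steps > k) return(FALSE)
    }
  }
  TRUE
}
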