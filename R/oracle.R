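# ---------------------------------------------------------------------------
# Brute-force ground truth: enumerate all frequent subtrees by leaf-subset
# enumeration, filter to maximal ones by pairwise display tests, and a
# restriction-based reference join classifier. Deliberately naive; used as
# the independent test bed for the mining engine.
# ---------------------------------------------------------------------------

ORACLE_MAX_LEAVES <- 16L

#' Tally restriction topologies over all leaf subsets
#'
#' For every leaf subset of size 3 up to `max_leaves`, restricts each tree
#' containing the subset and tallies the canonical topologies observed with
#' their supporting tree sets. Feeding the tally to [brute_force_fsts()]
#' lets several thresholds reuse one pass.
#'
#' @param trees list of `ptree` (coercibles accepted).
#' @param max_leaves largest subset size considered (default: the whole
#'   universe).
#' @return opaque tally structure.
#' @export
fst_tally <- function(trees, max_leaves = NULL) {
  trees <- lapply(trees, as_ptree)
  n <- max(vapply(trees, function(t) max(t$idft), integer(1)))
  if (n > ORACLE_MAX_LEAVES) {
    stop("oracle subset enumeration refused for more than ",
         ORACLE_MAX_LEAVES, " leaves", call. = FALSE)
  }
  if (is.null(max_leaves)) max_leaves <- n
  presence <- matrix(FALSE, length(trees), n)
  for (i in seq_along(trees)) presence[i, trees[[i]]$idft] <- TRUE
  m <- length(trees)
  entries <- list()
  keep <- logical(n)
  for (s in 3:max_leaves) {
    if (s > n) break
    sets <- utils::combn(n, s)
    for (ci in seq_len(ncol(sets))) {
      S <- sets[, ci]
      holders <- which(rowSums(presence[, S, drop = FALSE]) == length(S))
      if (length(holders) == 0L) next
      keep[] <- FALSE
      keep[S] <- TRUE
      tally <- list()
      for (t in holders) {
        key <- node_restrict_key(trees[[t]]$root, keep)$s
        if (is.null(tally[[key]])) tally[[key]] <- logical(m)
        tally[[key]][t] <- TRUE
      }
      entries[[paste(S, collapse = ".")]] <-
        list(leaves = S, mask = sum(bitwShiftL(1L, S - 1L)), tally = tally)
    }
  }
  structure(list(entries = entries, m = m, n = n, trees = trees),
            class = "fst_tally")
}

#' Brute-force enumeration of all frequent subtrees
#'
#' For every leaf subset of size >= 3, records the (unique, since
#' `threshold > m/2`) topology displayed by at least `threshold` of the
#' input trees, with its support set.
#'
#' @param trees list of `ptree` (ignored when `tally` is given).
#' @param threshold integer support threshold, > m/2.
#' @param max_leaves optional cap on subtree size.
#' @param tally optional precomputed [fst_tally()].
#' @return list of records `list(leaves, mask, newick, support, witness)`,
#'   where `witness` is one supporting tree index.
#' @export
brute_force_fsts <- function(trees = NULL, threshold, max_leaves = NULL,
                             tally = NULL) {
  if (is.null(tally)) tally <- fst_tally(trees, max_leaves = max_leaves)
  stopifnot(inherits(tally, "fst_tally"), threshold > tally$m / 2)
  out <- list()
  for (e in tally$entries) {
    counts <- vapply(e$tally, sum, integer(1))
    w <- which(counts >= threshold)
    if (length(w) == 1L) {
      sup <- e$tally[[w]]
      out[[length(out) + 1L]] <- list(
        leaves = e$leaves, mask = e$mask, newick = names(e$tally)[w],
        support = sup, witness = which(sup)[1L]
      )
    } else if (length(w) > 1L) {
      stop("multiple frequent topologies on one leaf set; threshold <= m/2?",
           call. = FALSE)
    }
  }
  attr(out, "m") <- tally$m
  attr(out, "trees") <- tally$trees
  out
}

# does fst record B display fst record A? (restriction computed on one of
# B's supporting input trees, which restricts to B on B's leaves)
oracle_displays <- function(B, A, trees) {
  if (bitwAnd(A$mask, B$mask) != A$mask) return(FALSE)
  witness <- trees[[B$witness]]
  keep <- logical(max(witness$idft))
  keep[A$leaves] <- TRUE
  identical(node_restrict_key(witness$root, keep)$s, A$newick)
}

#' Brute-force maximal frequent subtrees
#'
#' Filters [brute_force_fsts()] output to the records displayed by no other
#' record.
#'
#' @param fsts output of [brute_force_fsts()].
#' @return list of records, sorted by (leaf count descending, Newick).
#' @export
brute_force_mfsts <- function(fsts) {
  trees <- attr(fsts, "trees")
  k <- length(fsts)
  if (k == 0L) return(fsts)
  nl <- vapply(fsts, function(r) length(r$leaves), integer(1))
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || nl[j] <= nl[i]) next
      if (oracle_displays(fsts[[j]], fsts[[i]], trees)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- fsts[keep]
  nw <- vapply(out, function(r) r$newick, character(1))
  out <- out[order(-nl[keep], nw)]
  attr(out, "m") <- attr(fsts, "m")
  attr(out, "trees") <- trees
  out
}

#' Brute-force maximum agreement subtrees
#'
#' Agreement subtrees (threshold = m) of maximum leaf count.
#'
#' @param trees list of `ptree`.
#' @param tally optional precomputed [fst_tally()].
#' @return list of records as in [brute_force_fsts()] (possibly several of
#'   equal maximum size), sorted by Newick.
#' @export
brute_force_masts <- function(trees = NULL, tally = NULL) {
  if (is.null(tally)) tally <- fst_tally(trees)
  fsts <- brute_force_fsts(threshold = tally$m, tally = tally)
  if (length(fsts) == 0L) return(fsts)
  nl <- vapply(fsts, function(r) length(r$leaves), integer(1))
  out <- fsts[nl == max(nl)]
  out <- out[order(vapply(out, function(r) r$newick, character(1)))]
  attr(out, "m") <- attr(fsts, "m")
  attr(out, "trees") <- attr(fsts, "trees")
  out
}

#' Reference (restriction-based) join classifier
#'
#' The definitional baseline for join classification: restrict the input
#' tree to the union of the operands' leaves, canonicalize, and identify
#' the result among the candidate joined trees constructed for each
#' admissible type. Used in tests as the independent check of the
#' constant-time classifier.
#'
#' @param input_tree a `ptree`.
#' @param Tx,Ty `fst` records as in [join_support()].
#' @return one of `"TYPE1"`..`"TYPE4"`, `"NONE"`.
#' @export
reference_join_classify <- function(input_tree, Tx, Ty) {
  input_tree <- as_ptree(input_tree)
  lu <- union(Tx$tree$idft, Ty$tree$idft)
  if (!all(lu %in% input_tree$idft)) return("NONE")
  keep <- logical(max(input_tree$idft))
  keep[lu] <- TRUE
  restr <- node_restrict_key(input_tree$root, keep)$s
  x <- Tx$rightmost
  y <- Ty$rightmost
  cands <- character(0)
  if (Tx$depth_p == Ty$depth_p) {
    if (x < y) cands <- c("TYPE1", "TYPE2")
    if (Ty$nchild_p == 2L) cands <- c(cands, "TYPE3")
  } else if (Tx$depth_p > Ty$depth_p) {
    cands <- "TYPE4"
  }
  for (jt in cands) {
    # a candidate must itself satisfy the join contract (canonical, Tx as
    # prefix, displays Ty); shapes that violate it are not joins at all
    cand <- tryCatch(construct_join(Tx, Ty, jt, verify = TRUE),
                     error = function(e) NULL)
    if (!is.null(cand) && identical(cand$newick, restr)) return(jt)
  }
  "NONE"
}
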