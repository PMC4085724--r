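# ---------------------------------------------------------------------------
# Pairwise-join engine: per-input-tree classification of the four join
# types (constant-time, from LCA-depth look-ups and stored parent-of-
# rightmost-leaf depths), support aggregation, and construction of the
# joined canonical tree.
# ---------------------------------------------------------------------------

JOIN_LEVELS <- c("TYPE1", "TYPE2", "TYPE3", "TYPE4", "NONE")

#' Frequent-subtree record
#'
#' Bundles a canonical tree with its support set and the cached quantities
#' the join engine needs: the rightmost leaf, and the depth and child count
#' of its parent within this tree.
#'
#' @param tree a `ptree`.
#' @param support logical vector over input-tree indices (the support set).
#' @return an object of class `fst` with fields `tree`, `support`,
#'   `rightmost`, `depth_p` and `nchild_p`.
#' @export
fst_record <- function(tree, support) {
  tree <- as_ptree(tree)
  info <- node_rml_info(tree$root)
  structure(
    list(tree = tree, support = support, rightmost = info$rightmost,
         depth_p = info$depth_p, nchild_p = info$nchild_p),
    class = "fst"
  )
}

#' @export
print.fst <- function(x, ...) {
  cat("<fst> ", x$tree$newick, ";  support ", sum(x$support), "\n", sep = "")
  invisible(x)
}

#' Classify the join type an input tree induces on an ordered pair
#'
#' Given the rightmost leaf `r` of the common core, the rightmost leaves
#' `x`, `y` of the two operands, and the depths of their parents *within
#' the operands*, the join type displayed by one input tree is determined
#' by the topology of the triple `{r, x, y}` in that tree:
#' equal parent depths give TYPE1 for the star `(r,x,y)` (with `x < y`),
#' TYPE2 for `(r,(x,y))` (with `x < y`), TYPE3 for `((r,x),y)`; a strictly
#' deeper `x`-parent gives TYPE4 for `((r,x),y)`; a strictly deeper
#' `y`-parent admits no join. A tree missing any of the three leaves
#' supports no join and yields NONE.
#'
#' @param table an `lca_table` for the input tree.
#' @param r,x,y distinct leaf labels.
#' @param depth_px,depth_py depths of the rightmost-leaf parents inside the
#'   two operands (not inside the input tree).
#' @return one of `"TYPE1"`..`"TYPE4"`, `"NONE"`.
#' @export
classify_join_in_tree <- function(table, r, x, y, depth_px, depth_py) {
  if (!(table$present[r] && table$present[x] && table$present[y])) {
    return("NONE")
  }
  D <- table$depth
  drx <- D[r, x]; dry <- D[r, y]; dxy <- D[x, y]
  if (depth_px == depth_py) {
    if (drx == dry) {
      if (dxy == drx) {
        if (x < y) return("TYPE1") else return("NONE")
      }
      # dxy > drx: (r,(x,y))
      if (x < y) return("TYPE2") else return("NONE")
    }
    if (drx > dry) return("TYPE3")   # ((r,x),y)
    return("NONE")                   # ((r,y),x)
  }
  if (depth_px > depth_py) {
    if (drx > dry) return("TYPE4")
    return("NONE")
  }
  "NONE"                             # depth_py > depth_px: no joins possible
}

#' Join an ordered pair of frequent subtrees and estimate support
#'
#' Classifies every input tree in the intersection of the operands' support
#' sets and returns the unique join type whose per-type support reaches the
#' threshold (at most one can, since the threshold exceeds m/2), together
#' with that support set and, if requested, the joined canonical tree.
#' The structural TYPE3 precondition (the `y`-parent has exactly two
#' children in `Ty`) is enforced here: trees classified TYPE3 contribute
#' nothing when it fails.
#'
#' @param Tx,Ty `fst` records sharing the common prefix whose rightmost
#'   leaf is `r`; their rightmost leaves must differ.
#' @param r rightmost leaf of the shared core tree.
#' @param tables list of `lca_table` for the input collection.
#' @param threshold integer support threshold (> m/2).
#' @param construct build the joined tree (set `FALSE` to only classify).
#' @return list with `join_type` (`"NONE"` if no type reaches the
#'   threshold), `support` (logical vector) and `joined` (an `fst` record
#'   or `NULL`).
#' @export
join_support <- function(Tx, Ty, r, tables, threshold, construct = TRUE) {
  x <- Tx$rightmost
  y <- Ty$rightmost
  stopifnot(x != y)
  cand <- which(Tx$support & Ty$support)
  m <- length(tables)
  counts <- integer(4L)
  sup <- matrix(FALSE, m, 4L)
  type3_ok <- Ty$nchild_p == 2L
  left <- length(cand)
  for (t in cand) {
    jt <- classify_join_in_tree(tables[[t]], r, x, y, Tx$depth_p, Ty$depth_p)
    left <- left - 1L
    if (jt != "NONE" && (jt != "TYPE3" || type3_ok)) {
      k <- match(jt, JOIN_LEVELS)
      counts[k] <- counts[k] + 1L
      sup[t, k] <- TRUE
    }
    if (max(counts) + left < threshold) break  # no type can reach threshold
  }
  w <- which(counts >= threshold)
  if (length(w) == 0L) {
    return(list(join_type = "NONE", support = logical(m), joined = NULL))
  }
  stopifnot(length(w) == 1L)   # threshold > m/2 guarantees uniqueness
  jt <- JOIN_LEVELS[w]
  support <- sup[, w]
  joined <- NULL
  if (construct) {
    joined <- fst_record(construct_join(Tx, Ty, jt), support)
  }
  list(join_type = jt, support = support, joined = joined)
}

#' Construct the joined canonical tree for a given join type
#'
#' TYPE1 grafts `y` as a further child of the `x`-parent; TYPE2 replaces
#' `x` by the cherry `(x,y)` one level deeper; TYPE3 subdivides the edge
#' entering the `x`-parent so the new node becomes its parent; TYPE4
#' re-applies to `Tx` the graft (relative to the shared core's rightmost
#' path) that produced `Ty` from the core. The result is verified to be
#' canonical as built (no re-sorting), to have `Tx` as its prefix, to
#' display `Ty`, and to have `y` as its rightmost leaf; a violation signals
#' a classification bug and raises an error.
#'
#' @param Tx,Ty `fst` records (see [join_support()]).
#' @param jt join type, one of `"TYPE1"`..`"TYPE4"`.
#' @param verify run the defensive postcondition checks (default TRUE).
#' @return the joined tree as a `ptree`.
#' @export
construct_join <- function(Tx, Ty, jt, verify = TRUE) {
  y <- Ty$rightmost
  raw <- switch(
    jt,
    TYPE1 = node_attach_rightmost(Tx$tree$root, y, Tx$depth_p, edge_graft = FALSE),
    TYPE2 = node_attach_rightmost(Tx$tree$root, y, Tx$depth_p + 1L, edge_graft = TRUE),
    TYPE3 = node_attach_rightmost(Tx$tree$root, y, Tx$depth_p, edge_graft = TRUE),
    TYPE4 = node_attach_rightmost(Tx$tree$root, y, Ty$depth_p,
                                  edge_graft = Ty$nchild_p == 2L),
    stop("invalid join type: ", jt, call. = FALSE)
  )
  out <- new_ptree(raw)
  if (verify) {
    ok <- identical(node_newick(raw), out$newick) &&           # canonical as built
      identical(out$idft[[length(out$idft)]], y) &&            # rightmost is y
      identical(prefix_tree(out)$newick, Tx$tree$newick) &&    # Tx is the prefix
      displays(out, Ty$tree)                                   # Ty is displayed
    if (!ok) {
      stop("constructed join violates the join contract (classification bug?): ",
           jt, " on ", Tx$tree$newick, " + ", Ty$tree$newick, call. = FALSE)
    }
  }
  out
}
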