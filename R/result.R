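# ---------------------------------------------------------------------------
# mfst_result: the output of mine_mfst(), carried as a tibble of maximal
# frequent subtrees plus run metadata/counters, with broom-style verbs.
# ---------------------------------------------------------------------------

new_mfst_result <- function(candidates, counters, m, n_labels, f, threshold,
                            mode, label_map = NULL) {
  tbl <- tibble::tibble(
    newick = vapply(candidates, function(c) c$tree$newick, character(1)),
    n_leaves = vapply(candidates, function(c) length(c$tree$idft), integer(1)),
    support_count = vapply(candidates, function(c) sum(c$support), integer(1)),
    support = purrr::map(candidates, function(c) which(c$support)),
    tree = purrr::map(candidates, "tree")
  )
  structure(
    list(mfst = tbl, counters = counters, m = m, n_labels = n_labels,
         f = f, threshold = threshold, mode = mode, label_map = label_map),
    class = "mfst_result"
  )
}

#' @export
print.mfst_result <- function(x, ...) {
  cat("Maximal frequent subtree mining (", toupper(x$mode), " mode)\n",
      sep = "")
  cat("  trees: ", x$m, "   leaf universe: ", x$n_labels,
      "   f = ", x$f$num, "/", x$f$den,
      "   support threshold: ", x$threshold, "\n", sep = "")
  cat("  maximal frequent subtrees: ", nrow(x$mfst), "\n", sep = "")
  if (nrow(x$mfst) > 0L) {
    for (i in seq_len(min(nrow(x$mfst), 10L))) {
      cat(sprintf("  %s;  [%d leaves, support %d/%d]\n",
                  x$mfst$newick[i], x$mfst$n_leaves[i],
                  x$mfst$support_count[i], x$m))
    }
    if (nrow(x$mfst) > 10L) cat("  ... and", nrow(x$mfst) - 10L, "more\n")
  }
  invisible(x)
}

#' Maximal frequent subtrees as a tibble
#'
#' One row per maximal frequent subtree, sorted by (leaf count descending,
#' Newick string): `newick`, `n_leaves`, `support_count`, and `support`
#' (list-column of 1-based input-tree indices).
#'
#' @param x an `mfst_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mfst_result <- function(x, ...) {
  x$mfst[, c("newick", "n_leaves", "support_count", "support")]
}

#' One-row summary of a mining run
#'
#' @param x an `mfst_result`.
#' @param ... unused.
#' @return a tibble with collection size, threshold, result counts and the
#'   main traversal counters.
#' @export
glance.mfst_result <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    n_labels = x$n_labels,
    f = x$f$num / x$f$den,
    threshold = x$threshold,
    mode = x$mode,
    n_mfst = nrow(x$mfst),
    max_leaves = if (nrow(x$mfst)) max(x$mfst$n_leaves) else NA_integer_,
    nodes_visited = unname(x$counters["nodes_visited"]),
    joins_attempted = unname(x$counters["joins_attempted"]),
    fsts_materialized = unname(x$counters["fsts_materialized"]),
    removed_by_filter = unname(x$counters["removed_by_filter"])
  )
}

#' Plot the size/support profile of mined subtrees
#'
#' Each maximal frequent subtree is one point: leaf count against support
#' count, with the overplotting count shown by size.
#'
#' @param object an `mfst_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mfst_result <- function(object, ...) {
  df <- object$mfst[, c("n_leaves", "support_count")]
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = list(n_leaves = df$n_leaves,
                                    support_count = df$support_count),
                          FUN = sum)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$n_leaves,
                                    y = .data$support_count,
                                    size = .data$n)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(name = "subtrees", max_size = 6) +
    ggplot2::labs(
      x = "leaves in subtree",
      y = sprintf("supporting trees (of %d)", object$m),
      title = "Maximal frequent subtrees"
    )
}

#' Write mined subtrees to a Newick file
#'
#' @param x an `mfst_result`.
#' @param path output file; one Newick line per subtree.
#' @param label_map optional `label_map` to restore taxon names (defaults
#'   to the map recorded during mining, if any).
#' @return `path`, invisibly.
#' @export
write_mfst <- function(x, path, label_map = NULL) {
  stopifnot(inherits(x, "mfst_result"))
  if (is.null(label_map)) label_map <- x$label_map
  lines <- vapply(x$mfst$tree, write_newick, character(1),
                  label_map = label_map)
  writeLines(lines, path)
  invisible(path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
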