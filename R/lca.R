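# ---------------------------------------------------------------------------
# One-time preprocessing: per-tree LCA-depth tables, triplet-topology
# queries, and enumeration of frequent triplets with their support sets.
# ---------------------------------------------------------------------------

#' Build the LCA-depth table of one tree
#'
#' For every unordered pair of leaves present in the tree, records the depth
#' of their lowest common ancestor (root depth 0). Quadratic time and space
#' per tree; stored as a flat pair-to-depth matrix so that later join
#' classification is a constant number of array look-ups.
#'
#' @param tree a `ptree`.
#' @param n_labels size of the leaf-label universe (defaults to the largest
#'   label in the tree).
#' @param index integer identifier of the tree within its collection.
#' @return an `lca_table`: list with `index`, `depth` (an
#'   `n_labels` x `n_labels` integer matrix, `NA` for absent leaves) and
#'   `present` (logical vector over labels).
#' @export
build_lca_depth_table <- function(tree, n_labels = NULL, index = NA_integer_) {
  tree <- as_ptree(tree)
  if (is.null(n_labels)) n_labels <- max(tree$idft)
  D <- matrix(NA_integer_, n_labels, n_labels)
  rec <- function(node, depth) {
    if (!is.list(node)) {
      D[node, node] <<- depth
      return(node)
    }
    sets <- lapply(node, rec, depth = depth + 1L)
    k <- length(sets)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        D[sets[[i]], sets[[j]]] <<- depth
        D[sets[[j]], sets[[i]]] <<- depth
      }
    }
    unlist(sets, use.names = FALSE)
  }
  rec(tree$root, 0L)
  present <- logical(n_labels)
  present[tree$idft] <- TRUE
  structure(list(index = index, depth = D, present = present),
            class = "lca_table")
}

#' Build LCA-depth tables for a whole collection
#' @param trees list of `ptree`.
#' @param n_labels leaf-label universe size (defaults to the largest label
#'   anywhere in the collection).
#' @return list of `lca_table`.
#' @export
build_lca_tables <- function(trees, n_labels = NULL) {
  if (is.null(n_labels)) {
    n_labels <- max(vapply(trees, function(t) max(as_ptree(t)$idft), integer(1)))
  }
  lapply(seq_along(trees), function(i) {
    build_lca_depth_table(trees[[i]], n_labels = n_labels, index = i)
  })
}

# Topology codes for a sorted leaf triple a < b < c:
#   0 = star (a,b,c); 1 = ((a,b),c); 2 = ((a,c),b); 3 = (a,(b,c))
TRIPLET_LEVELS <- c("STAR", "AB_C", "AC_B", "BC_A")

triplet_code <- function(D, a, b, c) {
  dab <- D[a, b]; dac <- D[a, c]; dbc <- D[b, c]
  if (is.na(dab) || is.na(dac) || is.na(dbc)) return(NA_integer_)
  if (dab > dac) 1L
  else if (dac > dab) 2L
  else if (dbc > dab) 3L
  else 0L
}

#' Triplet topology displayed by one tree
#'
#' Classifies the rooted 3-leaf topology over `{a, b, c}` from three
#' LCA-depth look-ups: the pair whose LCA is strictly deeper than the others
#' forms the cherry; equal depths all round give the star. Agrees with
#' `canonicalize(restrict_tree(tree, c(a, b, c)))`.
#'
#' @param table an `lca_table`.
#' @param a,b,c distinct leaf labels present in the table's tree.
#' @return one of `"STAR"`, `"AB_C"` (= `((a,b),c)`), `"AC_B"`, `"BC_A"`,
#'   where the roles follow the sorted order of the three labels.
#' @export
triplet_topology <- function(table, a, b, c) {
  s <- sort(c(a, b, c))
  if (anyDuplicated(s)) stop("leaf labels must be distinct", call. = FALSE)
  if (!all(table$present[s])) {
    stop("leaf absent from tree: ", paste(s[!table$present[s]], collapse = ","),
         call. = FALSE)
  }
  TRIPLET_LEVELS[triplet_code(table$depth, s[1L], s[2L], s[3L]) + 1L]
}

#' Enumerate frequent triplets
#'
#' For every sorted leaf triple, tallies the displayed topology across the
#' trees that contain all three leaves and keeps the (unique, since the
#' threshold exceeds m/2) topology displayed by at least `threshold` trees,
#' together with its support set. With `threshold = m` the stored triples
#' are the agreement triplets.
#'
#' @param tables list of `lca_table` over a common label universe.
#' @param threshold integer support threshold, strictly greater than m/2.
#' @return a `triplet_table`: environment mapping `"a.b.c"` keys to
#'   `list(code, topology, support)`, with attributes `n_labels`, `m`,
#'   `threshold`.
#' @export
enumerate_frequent_triplets <- function(tables, threshold) {
  m <- length(tables)
  if (threshold <= m / 2) {
    stop("threshold must exceed half the collection size", call. = FALSE)
  }
  n <- nrow(tables[[1L]]$depth)
  depths <- lapply(tables, function(t) t$depth)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (n >= 3L) {
    for (a in 1:(n - 2L)) {
      for (b in (a + 1L):(n - 1L)) {
        for (cc in (b + 1L):n) {
          counts <- integer(4L)
          sup <- matrix(FALSE, m, 4L)
          for (t in seq_len(m)) {
            code <- triplet_code(depths[[t]], a, b, cc)
            if (!is.na(code)) {
              counts[code + 1L] <- counts[code + 1L] + 1L
              sup[t, code + 1L] <- TRUE
            }
          }
          w <- which(counts >= threshold)
          if (length(w) == 1L) {
            assign(triple_key(a, b, cc),
                   list(code = w - 1L, topology = TRIPLET_LEVELS[w],
                        support = sup[, w]),
                   envir = env)
          }
        }
      }
    }
  }
  attr(env, "n_labels") <- n
  attr(env, "m") <- m
  attr(env, "threshold") <- threshold
  class(env) <- "triplet_table"
  env
}

triple_key <- function(a, b, c) paste(a, b, c, sep = ".")

# look up a frequent triple by unsorted labels; NULL if not frequent
triplet_lookup <- function(tab, x, y, z) {
  s <- sort(c(x, y, z))
  get0(triple_key(s[1L], s[2L], s[3L]), envir = tab, inherits = FALSE)
}

#' @export
print.triplet_table <- function(x, ...) {
  cat("<triplet_table> ", length(ls(x)), " frequent triple(s); m = ",
      attr(x, "m"), ", threshold = ", attr(x, "threshold"), "\n", sep = "")
  invisible(x)
}

#' Frequent triplets as a tibble
#' @param x a `triplet_table`.
#' @param ... unused.
#' @return tibble with columns `a`, `b`, `c`, `topology`, `support_count`.
#' @export
tidy.triplet_table <- function(x, ...) {
  keys <- sort(ls(x))
  rows <- purrr::map(keys, function(k) {
    v <- get(k, envir = x)
    abc <- as.integer(strsplit(k, ".", fixed = TRUE)[[1L]])
    tibble::tibble(a = abc[1L], b = abc[2L], c = abc[3L],
                   topology = v$topology, support_count = sum(v$support))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(a = integer(), b = integer(), c = integer(),
                          topology = character(), support_count = integer())
  }
  out[order(out$a, out$b, out$c), ]
}
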