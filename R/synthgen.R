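# ---------------------------------------------------------------------------
# Deterministic generator of phylogeny collections with controllable
# agreement structure: a random base tree perturbed per replicate by leaf
# prune-and-regraft moves, designated rogue taxa re-placed in every
# replicate, optional multifurcations and partial leaf overlap. Emulates
# bootstrap-replicate collections where most structure is shared but a few
# taxa wander.
# ---------------------------------------------------------------------------

#' Specification of a synthetic tree collection
#'
#' @param n_leaves leaf universe size (>= 3).
#' @param m_trees number of replicate trees.
#' @param moves_per_tree leaf prune-and-regraft moves applied independently
#'   per replicate.
#' @param n_rogue number of designated rogue taxa re-grafted at a uniformly
#'   random position in every replicate.
#' @param multifurcation_prob probability per internal edge of the base
#'   tree of collapsing it (0 = binary base tree, 1 = star).
#' @param overlap_frac fraction of the leaf universe retained per replicate
#'   (< 1 gives partially overlapping leaf sets; each replicate keeps at
#'   least 3 leaves or the spec errors).
#' @param seed RNG seed; the same spec and seed give byte-identical output.
#' @return a `synth_spec`.
#' @export
synth_spec <- function(n_leaves, m_trees, moves_per_tree = 0L, n_rogue = 0L,
                       multifurcation_prob = 0, overlap_frac = 1,
                       seed = 1L) {
  stopifnot(n_leaves >= 3L, m_trees >= 1L, moves_per_tree >= 0L,
            n_rogue >= 0L, n_rogue < n_leaves,
            multifurcation_prob >= 0, multifurcation_prob <= 1,
            overlap_frac > 0, overlap_frac <= 1)
  if (overlap_frac < 1 && ceiling(overlap_frac * n_leaves) < 3) {
    stop("overlap_frac retains fewer than 3 leaves per replicate",
         call. = FALSE)
  }
  structure(
    list(n_leaves = as.integer(n_leaves), m_trees = as.integer(m_trees),
         moves_per_tree = as.integer(moves_per_tree),
         n_rogue = as.integer(n_rogue),
         multifurcation_prob = multifurcation_prob,
         overlap_frac = overlap_frac, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# paths addressing every non-root node (for edge grafts), and every
# internal node (for node grafts), in canonical order
node_paths <- function(n, internal_only = FALSE, .path = integer(0)) {
  out <- list()
  if (is.list(n)) {
    # the root itself is addressed by integer(0); callers add it explicitly
    for (i in seq_along(n)) {
      p <- c(.path, i)
      if (!internal_only || is.list(n[[i]])) out <- c(out, list(p))
      out <- c(out, node_paths(n[[i]], internal_only, p))
    }
  }
  out
}

#' Generate a random rooted tree topology
#'
#' Uniform random rooted binary topology by sequential leaf attachment
#' (each new leaf grafted on a uniformly chosen edge or above the root),
#' followed by random edge collapses with the given probability.
#'
#' @param labels integer leaf labels (>= 3 of them).
#' @param multifurcation_prob per-internal-edge collapse probability.
#' @param seed optional seed (omit to use the current RNG stream).
#' @return a canonical `ptree`.
#' @export
random_tree <- function(labels, multifurcation_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.integer(labels)
  if (length(labels) < 3L) stop("need at least 3 labels", call. = FALSE)
  ord <- sample(labels)
  t <- new_ptree(list(ord[1L], ord[2L]))
  for (leaf in ord[-(1:2)]) {
    paths <- node_paths(t$root)
    pos <- sample.int(length(paths) + 1L, 1L)
    t <- if (pos > length(paths)) {
      graft_leaf(t, leaf, on = "root-top")
    } else {
      graft_leaf(t, leaf, on = "edge", path = paths[[pos]])
    }
  }
  if (multifurcation_prob > 0) {
    p <- multifurcation_prob
    collapse_rec <- function(n) {
      if (!is.list(n)) return(n)
      ch <- lapply(n, collapse_rec)
      out <- list()
      for (c in ch) {
        if (is.list(c) && stats::runif(1L) < p) out <- c(out, c)
        else out <- c(out, list(c))
      }
      out
    }
    t <- new_ptree(collapse_rec(t$root))
  }
  t
}

# prune a leaf and regraft it at a uniformly random position (any internal
# node, any edge, or above the root)
regraft_leaf <- function(t, leaf) {
  t <- prune_leaf(t, leaf)
  node_positions <- if (is.list(t$root)) {
    c(list(list(on = "node", path = integer(0))),
      lapply(node_paths(t$root, internal_only = TRUE),
             function(p) list(on = "node", path = p)))
  } else {
    list()
  }
  edge_positions <- lapply(node_paths(t$root),
                           function(p) list(on = "edge", path = p))
  positions <- c(node_positions, edge_positions,
                 list(list(on = "root-top", path = integer(0))))
  sel <- positions[[sample.int(length(positions), 1L)]]
  graft_leaf(t, leaf, on = sel$on, path = sel$path)
}

#' Generate a perturbed tree collection with known ground truth
#'
#' Draws a base tree, then for each replicate re-places the rogue taxa and
#' applies the requested number of random leaf prune-and-regraft moves;
#' with `overlap_frac < 1` each replicate is restricted to a random leaf
#' subset. The base tree and per-replicate move log are returned so tests
#' can assert the planted structure: the restriction of the base tree to a
#' replicate's unmoved retained leaves is displayed by that replicate, by
#' construction.
#'
#' @param spec a [synth_spec()].
#' @return a `synth_collection`: list with `trees` (list of `ptree`),
#'   `base` (ptree), `rogues` (integer), `moved` and `kept` (per-replicate
#'   integer vectors), `spec`.
#' @export
perturb_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_leaves
  base <- random_tree(seq_len(n), spec$multifurcation_prob)
  rogues <- if (spec$n_rogue > 0L) sort(sample.int(n, spec$n_rogue)) else integer(0)
  non_rogue <- setdiff(seq_len(n), rogues)
  trees <- vector("list", spec$m_trees)
  moved <- vector("list", spec$m_trees)
  kept <- vector("list", spec$m_trees)
  for (i in seq_len(spec$m_trees)) {
    t <- base
    mv <- integer(0)
    for (r in rogues) {
      t <- regraft_leaf(t, r)
      mv <- c(mv, r)
    }
    if (spec$moves_per_tree > 0L) {
      for (k in seq_len(spec$moves_per_tree)) {
        leaf <- non_rogue[sample.int(length(non_rogue), 1L)]
        t <- regraft_leaf(t, leaf)
        mv <- c(mv, leaf)
      }
    }
    kp <- seq_len(n)
    if (spec$overlap_frac < 1) {
      kp <- sort(sample.int(n, max(3L, ceiling(spec$overlap_frac * n))))
      t <- restrict_tree(t, kp)
    }
    trees[[i]] <- t
    moved[[i]] <- unique(mv)
    kept[[i]] <- kp
  }
  structure(
    list(trees = trees, base = base, rogues = rogues, moved = moved,
         kept = kept, spec = spec),
    class = "synth_collection"
  )
}

#' @export
print.synth_collection <- function(x, ...) {
  cat("<synth_collection> ", length(x$trees), " trees on ",
      x$spec$n_leaves, " leaves (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Synthetic collection as a tibble
#' @param x a `synth_collection`.
#' @param ... unused.
#' @return tibble with `tree_index`, `newick`, `moved`, `kept`.
#' @export
tidy.synth_collection <- function(x, ...) {
  tibble::tibble(
    tree_index = seq_along(x$trees),
    newick = vapply(x$trees, function(t) t$newick, character(1)),
    moved = x$moved,
    kept = x$kept
  )
}

#' Write a tree collection to a Newick file
#'
#' One Newick line per tree; with a `label_map`, taxon names are restored
#' and the map is written to a `<path>.labels.tsv` sidecar
#' (name<TAB>integer) for reproducibility.
#'
#' @param x a `synth_collection`, list of `ptree`, or character vector of
#'   Newick strings.
#' @param path output file path.
#' @param label_map optional `label_map`.
#' @return `path`, invisibly.
#' @export
write_collection <- function(x, path, label_map = NULL) {
  trees <- if (inherits(x, "synth_collection")) x$trees
           else if (is.character(x)) lapply(x, as_ptree)
           else x
  if (length(trees) == 0L) stop("empty collection", call. = FALSE)
  lines <- vapply(trees, function(t) write_newick(as_ptree(t), label_map),
                  character(1))
  writeLines(lines, path)
  if (!is.null(label_map)) {
    sidecar <- paste0(path, ".labels.tsv")
    utils::write.table(
      data.frame(name = names(label_map), label = as.integer(label_map)),
      sidecar, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}
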