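#' @importFrom ape read.tree write.tree collapse.singles
NULL

# ---------------------------------------------------------------------------
# ptree: a rooted leaf-labeled phylogenetic tree held in canonical form.
# Canonical form: at every internal node, children are ordered ascending by
# virtual label (the minimum leaf label among the child's descendants). Two
# trees are isomorphic iff their canonical serializations are equal.
# ---------------------------------------------------------------------------

new_ptree <- function(root) {
  cn <- canonical_node(root)
  root <- cn$node
  idft <- node_idft(root)
  if (any(idft < 1L) || anyDuplicated(idft)) {
    stop("leaf labels must be distinct positive integers", call. = FALSE)
  }
  structure(
    list(root = root, newick = node_newick(root), idft = as.integer(idft)),
    class = "ptree"
  )
}

#' Coerce to a canonical phylogenetic tree
#'
#' Accepts a `ptree`, a Newick string (integer leaf labels), or a raw nested
#' node structure, and returns the tree in canonical (virtual-label) order.
#'
#' @param x object to coerce.
#' @param ... passed on to [parse_newick()] for character input.
#' @return a `ptree`.
#' @export
as_ptree <- function(x, ...) {
  if (inherits(x, "ptree")) return(x)
  if (is.character(x)) return(parse_newick(x, ...))
  new_ptree(x)
}

#' @export
print.ptree <- function(x, ...) {
  cat("<ptree> ", x$newick, ";  (", length(x$idft), " leaves)\n", sep = "")
  invisible(x)
}

#' @export
plot.ptree <- function(x, ...) {
  plot(ape::read.tree(text = paste0(x$newick, ";")), ...)
}

#' Number of leaves of a tree
#' @param tree a `ptree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) length(as_ptree(tree)$idft)

#' Leaf label set of a tree
#' @param tree a `ptree`.
#' @return sorted integer vector of leaf labels.
#' @export
leaf_set <- function(tree) sort(as_ptree(tree)$idft)

# ---------------------------------------------------------------------------
# Label maps: taxon-name <-> integer bijection. Integers are assigned by
# lexicographic sort of the name set, so the mapping is deterministic.
# ---------------------------------------------------------------------------

#' Build a taxon-name to integer label map
#'
#' Names are sorted lexicographically (C locale) and assigned 1..n, so the
#' assignment is deterministic given the name set.
#'
#' @param names character vector of taxon names.
#' @return named integer vector of class `label_map` (names are taxa).
#' @export
label_map <- function(names) {
  names <- unique(as.character(names))
  sorted <- c_sort(names)
  structure(stats::setNames(seq_along(sorted), sorted), class = "label_map")
}

# locale-independent sort
c_sort <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

# Extend a label map with unseen names (appended after existing integers,
# sorted among themselves).
label_map_extend <- function(map, names) {
  new <- setdiff(unique(as.character(names)), names(map))
  if (length(new) == 0L) return(map)
  add <- stats::setNames(length(map) + seq_along(c_sort(new)),
                         c_sort(new))
  structure(c(unclass(map), add), class = "label_map")
}

# ---------------------------------------------------------------------------
# Newick I/O (via ape; branch lengths, internal labels and singleton nodes
# are discarded on ingest).
# ---------------------------------------------------------------------------

#' Parse a rooted Newick string
#'
#' Branch lengths, internal node labels and comments are discarded; internal
#' single-child chains are suppressed on ingest. Leaf names that are all
#' positive integers are used directly as labels; otherwise names are mapped
#' through `label_map` (which is consulted, and must then cover all names).
#'
#' @param text a single Newick expression (trailing semicolon optional).
#' @param label_map optional `label_map` for non-integer taxon names.
#' @return a `ptree`.
#' @export
parse_newick <- function(text, label_map = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!endsWith(txt, ";")) txt <- paste0(txt, ";")
  # single-leaf degenerate case (ape cannot represent it)
  if (grepl("^[^();,]+;$", txt)) {
    nm <- trimws(sub(";$", "", txt))
    nm <- gsub("^'|'$", "", nm)
    lab <- resolve_labels(nm, label_map)
    return(new_ptree(lab))
  }
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("malformed Newick expression: ", text, call. = FALSE)
  }
  phy <- ape::collapse.singles(phy)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf name within one tree", call. = FALSE)
  }
  labs <- resolve_labels(phy$tip.label, label_map)
  new_ptree(phylo_to_node(phy, labs))
}

resolve_labels <- function(nms, map) {
  if (is.null(map)) {
    if (!all(grepl("^[0-9]+$", nms))) {
      stop("non-integer taxon names require a label_map", call. = FALSE)
    }
    return(as.integer(nms))
  }
  if (!all(nms %in% names(map))) {
    stop("taxon name(s) missing from label_map: ",
         paste(setdiff(nms, names(map)), collapse = ", "), call. = FALSE)
  }
  as.integer(unclass(map)[nms])
}

phylo_to_node <- function(phy, labs) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(id) {
    if (id <= ntip) return(labs[[id]])
    lapply(kids[[as.character(id)]], build)
  }
  build(ntip + 1L)
}

#' Write a tree as a rooted Newick string
#'
#' Children are emitted in canonical order; a trailing semicolon is always
#' emitted. `parse_newick(write_newick(t))` is isomorphic to `t`.
#'
#' @param tree a `ptree`.
#' @param label_map optional `label_map`; when given, integer labels are
#'   replaced by their taxon names.
#' @return a single Newick string.
#' @export
write_newick <- function(tree, label_map = NULL) {
  tree <- as_ptree(tree)
  if (is.null(label_map)) return(paste0(tree$newick, ";"))
  inv <- stats::setNames(names(label_map), unclass(label_map))
  rec <- function(n) {
    if (!is.list(n)) return(inv[[as.character(n)]])
    paste0("(", paste(vapply(n, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

#' Read a collection of trees
#'
#' @param x a file path to newline-delimited Newick, a character vector of
#'   Newick strings, or a data frame with a `newick` column.
#' @param min_leaves minimum leaf count per tree (collection trees must have
#'   at least 3 leaves for meaningful inference).
#' @return list with `trees` (list of `ptree`) and `label_map`.
#' @export
read_tree_collection <- function(x, min_leaves = 3L) {
  if (is.data.frame(x)) {
    stopifnot("newick" %in% names(x))
    lines <- as.character(x$newick)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    lines <- readLines(x)
  } else {
    lines <- as.character(x)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty tree collection", call. = FALSE)
  nms <- unlist(lapply(lines, newick_leaf_names), use.names = FALSE)
  map <- NULL
  if (!all(grepl("^[0-9]+$", nms))) map <- label_map(nms)
  trees <- lapply(lines, parse_newick, label_map = map)
  nl <- vapply(trees, n_leaves, integer(1))
  if (any(nl < min_leaves)) {
    stop("collection trees must have at least ", min_leaves, " leaves",
         call. = FALSE)
  }
  list(trees = trees, label_map = map)
}

# crude leaf-name scan used only to decide integer vs named labels
newick_leaf_names <- function(line) {
  line <- gsub("\\[[^]]*\\]", "", line)          # comments
  line <- gsub(":[0-9eE+.-]+", "", line)         # branch lengths
  toks <- strsplit(line, "[(),;]")[[1]]
  toks <- trimws(toks)
  toks <- gsub("^'|'$", "", toks)
  toks[nzchar(toks)]
}

# ---------------------------------------------------------------------------
# Structural operations
# ---------------------------------------------------------------------------

#' Canonicalize a tree
#'
#' Sorts children ascending by virtual label at every internal node.
#' Idempotent; preserves the isomorphism class.
#'
#' @param tree a `ptree`, Newick string, or raw node structure.
#' @return a canonical `ptree`.
#' @export
canonicalize <- function(tree) as_ptree(tree)

#' Canonical Newick serialization (no trailing semicolon)
#' @param tree a `ptree` or coercible object.
#' @return character scalar.
#' @export
canonical_newick <- function(tree) as_ptree(tree)$newick

#' Leaves in inorder depth-first (IDFT) order
#'
#' The last element is the rightmost leaf; the first is always the globally
#' minimum label (a consequence of virtual-label ordering).
#'
#' @param tree a `ptree`.
#' @return integer vector of leaf labels.
#' @export
idft_leaves <- function(tree) as_ptree(tree)$idft

#' Rightmost leaf of a canonical tree
#' @param tree a `ptree`.
#' @return integer leaf label.
#' @export
rightmost_leaf <- function(tree) {
  idft <- as_ptree(tree)$idft
  idft[[length(idft)]]
}

#' Is two trees' topology identical (including leaf labels)?
#' @param t1,t2 trees coercible with [as_ptree()].
#' @return logical.
#' @export
is_isomorphic <- function(t1, t2) {
  identical(as_ptree(t1)$newick, as_ptree(t2)$newick)
}

#' Suppress a single-child internal node
#'
#' Contracts the edge below an internal, non-root node that has exactly one
#' child. Such nodes only occur transiently during edits, so this operates
#' on raw nested-list structures (leaf = integer, internal node = list of
#' children).
#'
#' @param tree raw node structure.
#' @param path integer vector of child indices addressing the node.
#' @return raw node structure.
#' @export
suppress_node <- function(tree, path) {
  if (length(path) == 0L) stop("cannot suppress the root", call. = FALSE)
  node <- node_at_path(tree, path)
  if (!is.list(node) || length(node) != 1L) {
    stop("node is not a single-child internal node", call. = FALSE)
  }
  node_set_path(tree, path, node[[1L]])
}

#' Prune a leaf
#'
#' Deletes the leaf; a resulting single-child non-root parent is suppressed,
#' and a degree-one root is deleted (its remaining child becomes the root).
#'
#' @param tree a `ptree`.
#' @param leaf integer leaf label, present in the tree.
#' @return a `ptree` with one fewer leaf.
#' @export
prune_leaf <- function(tree, leaf) {
  tree <- as_ptree(tree)
  if (!(leaf %in% tree$idft)) stop("leaf not in tree: ", leaf, call. = FALSE)
  if (length(tree$idft) < 2L) stop("cannot prune the last leaf", call. = FALSE)
  new_ptree(node_drop_leaf(tree$root, as.integer(leaf)))
}

#' Graft a leaf
#'
#' The reverse of pruning: attach a new leaf either as an extra child of an
#' existing internal node (`on = "node"`), by subdividing an existing edge
#' (`on = "edge"`, where `path` addresses the child endpoint), or above the
#' root (`on = "root-top"`).
#'
#' @param tree a `ptree`.
#' @param leaf integer label not already present.
#' @param on one of `"node"`, `"edge"`, `"root-top"`.
#' @param path integer child-index path (in canonical order) addressing the
#'   target node (for `"node"`) or the child endpoint of the target edge
#'   (for `"edge"`); ignored for `"root-top"`.
#' @return a `ptree` with one more leaf.
#' @export
graft_leaf <- function(tree, leaf, on = c("node", "edge", "root-top"),
                       path = integer(0)) {
  tree <- as_ptree(tree)
  on <- match.arg(on)
  leaf <- as.integer(leaf)
  if (leaf %in% tree$idft) stop("leaf already present: ", leaf, call. = FALSE)
  root <- tree$root
  if (on == "root-top") {
    return(new_ptree(list(root, leaf)))
  }
  if (on == "node") {
    node <- node_at_path(root, path)
    if (!is.list(node)) stop("cannot graft on a leaf node", call. = FALSE)
    node[[length(node) + 1L]] <- leaf
    return(new_ptree(node_set_path(root, path, node)))
  }
  # on an edge: subdivide above the child at `path`
  if (length(path) == 0L) stop("an edge needs a non-root child endpoint",
                               call. = FALSE)
  v <- node_at_path(root, path)
  new_ptree(node_set_path(root, path, list(v, leaf)))
}

#' Prefix tree (prune the rightmost leaf)
#'
#' The result of pruning the rightmost IDFT leaf of a canonical tree is
#' itself canonical with no re-sorting required.
#'
#' @param tree a `ptree` with at least 2 leaves.
#' @return a `ptree`.
#' @export
prefix_tree <- function(tree) {
  tree <- as_ptree(tree)
  if (length(tree$idft) < 2L) stop("prefix of a single-leaf tree", call. = FALSE)
  new_ptree(node_drop_leaf(tree$root, tree$idft[[length(tree$idft)]]))
}

#' Heaviest subtree (rooted at the parent of the rightmost leaf)
#' @param tree a `ptree` with at least 2 leaves.
#' @return a `ptree`.
#' @export
heaviest_subtree <- function(tree) {
  tree <- as_ptree(tree)
  if (length(tree$idft) < 2L) stop("tree has a single leaf", call. = FALSE)
  info <- node_rml_info(tree$root)
  n <- tree$root
  for (i in seq_len(info$depth_p)) n <- n[[length(n)]]
  new_ptree(n)
}

#' Restrict a tree to a leaf subset
#'
#' Returns the minimal homeomorphic subtree connecting `labels`, rooted at
#' their LCA, with single-child nodes suppressed; output is canonical.
#'
#' @param tree a `ptree`.
#' @param labels integer leaf labels, a non-empty subset of the tree's leaves.
#' @return a `ptree`.
#' @export
restrict_tree <- function(tree, labels) {
  tree <- as_ptree(tree)
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label set", call. = FALSE)
  if (!all(labels %in% tree$idft)) {
    stop("label(s) not in tree: ",
         paste(setdiff(labels, tree$idft), collapse = ", "), call. = FALSE)
  }
  keep <- logical(max(tree$idft))
  keep[labels] <- TRUE
  new_ptree(node_restrict(tree$root, keep))
}

#' Does one tree display another?
#'
#' `big` displays `small` iff the leaves of `small` are a subset of the
#' leaves of `big` and `small` equals the restriction of `big` to them.
#'
#' @param big,small trees coercible with [as_ptree()].
#' @return logical.
#' @export
displays <- function(big, small) {
  big <- as_ptree(big)
  small <- as_ptree(small)
  if (!all(small$idft %in% big$idft)) return(FALSE)
  keep <- logical(max(big$idft))
  keep[small$idft] <- TRUE
  identical(node_restrict_key(big$root, keep)$s, small$newick)
}
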