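# Internal node representation for rooted leaf-labeled trees:
#   leaf          -> integer scalar (its label, >= 1)
#   internal node -> unnamed list of >= 2 child nodes
# All user-facing functions wrap nodes in the `ptree` class (see trees.R),
# which stores the canonical form. Raw nodes only occur transiently.

is_leaf_node <- function(n) !is.list(n)

# Canonicalize a raw node: children ordered ascending by virtual label
# (minimum leaf label below the child). Returns list(node=, vl=).
canonical_node <- function(n) {
  if (!is.list(n)) {
    return(list(node = n, vl = n))
  }
  if (length(n) < 2L) {
    stop("internal node with fewer than 2 children", call. = FALSE)
  }
  ch <- lapply(n, canonical_node)
  vls <- vapply(ch, function(c) c$vl, integer(1))
  if (anyDuplicated(vls)) {
    # sibling leaf-descendant sets are disjoint, so equal virtual labels
    # can only arise from duplicated leaf labels
    stop("duplicate virtual labels among siblings (duplicated leaf label?)",
         call. = FALSE)
  }
  o <- order(vls)
  list(node = lapply(ch[o], function(c) c$node), vl = vls[o[1L]])
}

# Serialize a node in its current child order (no trailing semicolon).
node_newick <- function(n) {
  if (!is.list(n)) return(as.character(n))
  paste0("(", paste(vapply(n, node_newick, character(1)), collapse = ","), ")")
}

# Leaves in inorder depth-first order of the current child order.
node_idft <- function(n) {
  if (!is.list(n)) return(n)
  unlist(lapply(n, node_idft), use.names = FALSE)
}

# Depth and child count of the parent of the rightmost leaf, plus the
# rightmost leaf itself; assumes canonical order. For a single-leaf tree
# depth_p is NA.
node_rml_info <- function(root) {
  if (!is.list(root)) {
    return(list(rightmost = root, depth_p = NA_integer_, nchild_p = NA_integer_))
  }
  d <- -1L
  n <- root
  nch <- NA_integer_
  while (is.list(n)) {
    d <- d + 1L
    nch <- length(n)
    n <- n[[length(n)]]
  }
  list(rightmost = n, depth_p = d, nchild_p = nch)
}

# Delete a leaf, suppressing any resulting single-child node (including a
# degree-one root, whose child becomes the new root). Returns the new node,
# or NULL if the tree had only that leaf.
node_drop_leaf <- function(n, leaf) {
  if (!is.list(n)) {
    return(if (identical(n, leaf)) NULL else n)
  }
  ch <- lapply(n, node_drop_leaf, leaf = leaf)
  ch <- ch[!vapply(ch, is.null, logical(1))]
  if (length(ch) == 0L) return(NULL)
  if (length(ch) == 1L) return(ch[[1L]])
  ch
}

# Minimal homeomorphic restriction to the leaves with keep[label] TRUE,
# rooted at their LCA. Returns a raw node or NULL.
node_restrict <- function(n, keep) {
  if (!is.list(n)) {
    return(if (keep[n]) n else NULL)
  }
  ch <- lapply(n, node_restrict, keep = keep)
  ch <- ch[!vapply(ch, is.null, logical(1))]
  if (length(ch) == 0L) return(NULL)
  if (length(ch) == 1L) return(ch[[1L]])
  ch
}

# Fast path for the oracle: canonical Newick of the restriction in one pass.
# Returns list(s=, vl=) or NULL.
node_restrict_key <- function(n, keep) {
  if (!is.list(n)) {
    if (keep[n]) return(list(s = as.character(n), vl = n)) else return(NULL)
  }
  ch <- lapply(n, node_restrict_key, keep = keep)
  ch <- ch[!vapply(ch, is.null, logical(1))]
  if (length(ch) == 0L) return(NULL)
  if (length(ch) == 1L) return(ch[[1L]])
  vls <- vapply(ch, function(c) c$vl, integer(1))
  o <- order(vls)
  list(s = paste0("(", paste(vapply(ch[o], function(c) c$s, character(1)),
                             collapse = ","), ")"),
       vl = vls[o[1L]])
}

node_leaf_count <- function(n) {
  if (!is.list(n)) return(1L)
  sum(vapply(n, node_leaf_count, integer(1)))
}

# Fetch the subtree at a child-index path (integer(0) = root).
node_at_path <- function(n, path) {
  for (i in path) {
    if (!is.list(n) || i < 1L || i > length(n)) {
      stop("invalid node path", call. = FALSE)
    }
    n <- n[[i]]
  }
  n
}

# Replace the subtree at a path with `value` (value = NULL deletes it).
node_set_path <- function(n, path, value) {
  if (length(path) == 0L) return(value)
  i <- path[[1L]]
  if (!is.list(n) || i < 1L || i > length(n)) {
    stop("invalid node path", call. = FALSE)
  }
  sub <- node_set_path(n[[i]], path[-1L], value)
  if (is.null(sub)) n[[i]] <- NULL else n[[i]] <- sub
  n
}

# Attach a new leaf relative to the rightmost path of a canonical node:
# either as an extra child of the rightmost-path node at `target_depth`
# (edge_graft = FALSE), or by subdividing the rightmost-path edge entering
# depth `target_depth` (edge_graft = TRUE; target_depth 0 creates a new
# root above everything). Used by construct_join(); leaves everything in
# canonical order when the join-type preconditions hold.
node_attach_rightmost <- function(n, leaf, target_depth, edge_graft) {
  if (edge_graft && target_depth == 0L) {
    return(list(n, leaf))
  }
  rec <- function(node, depth) {
    stopifnot(is.list(node))
    k <- length(node)
    if (!edge_graft && depth == target_depth) {
      node[[k + 1L]] <- leaf
      return(node)
    }
    if (edge_graft && depth == target_depth - 1L) {
      node[[k]] <- list(node[[k]], leaf)
      return(node)
    }
    node[[k]] <- rec(node[[k]], depth + 1L)
    node
  }
  rec(n, 0L)
}

node_is_binary <- function(n) {
  if (!is.list(n)) return(TRUE)
  length(n) == 2L && all(vapply(n, node_is_binary, logical(1)))
}
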