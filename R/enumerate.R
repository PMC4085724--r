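# ---------------------------------------------------------------------------
# Enumeration-tree traversal: equivalence classes, recursive expansion by
# pairwise joins, pruning (sibling / cousin / pruner-list rules), and
# emission of maximal frequent subtrees.
#
# The enumeration tree is rooted two levels below the triplets: a root
# pass collects the frequent single leaves and frequent cherries, and the
# per-minimum-leaf classes (single-leaf core, cherry members) then feed the
# ordinary class expansion, so the triplet level needs no special casing.
#
# Output exactness does not rest on the pruning rules being complete:
# the core of an empty class is emitted only after an exact local
# maximality test (no frequent single-leaf extension displays it), so the
# sibling/cousin/pruner-list rules are pure work-skipping devices whose
# only obligation is soundness (never pruning a branch that holds a
# maximal subtree).
#
# The sibling/cousin/pruner-list rules rest on a uniqueness property (at
# most one topology can display two overlapping joins unless both are
# type 2) that holds for binary trees but fails in the presence of
# polytomies: a tree can display both (1,2,4,6) and (1,2,6,8) via
# (1,2,6,(4,8)) as well as via (1,2,4,6,8), because a type-1 join leaves
# the relation between the two added leaves unpinned. Rule-based
# pruning is therefore applied only when every input tree is fully
# binary; multifurcating collections are enumerated without pruning
# (still exact, merely slower).
#
# A second, subtler gap: composing *two* pinned extensions does not pin
# their mutual placement (trees can agree on [x,y,a] and [x,y,b] yet
# split on [x,a,b]), so pruning decisions that combine entries across
# children (pruner-list inheritance, common-label class pruning) can cut
# branches that still hold maximal subtrees. Pruning therefore only ever
# draws on single-extension facts: the sibling rule pins every triple
# the pruned branch can reach, and the childless-class veto fires only
# on directly seeded (non-inherited) pruner entries. Inherited entries
# are still maintained and reported.
# ---------------------------------------------------------------------------

#' Exact support fraction
#'
#' Parses `f` into an exact rational so that thresholding never depends on
#' floating-point rounding. Accepts a decimal string (`"0.55"` -> 11/20),
#' a fraction string (`"3/4"`), or a numeric (converted through its decimal
#' representation).
#'
#' @param f support fraction in (1/2, 1].
#' @return list with integer-valued `num` and `den`.
#' @export
support_fraction <- function(f) {
  if (is.numeric(f)) f <- format(f, digits = 15, scientific = FALSE)
  stopifnot(is.character(f), length(f) == 1L)
  f <- trimws(f)
  if (grepl("^[0-9]+/[0-9]+$", f)) {
    parts <- as.numeric(strsplit(f, "/", fixed = TRUE)[[1L]])
    num <- parts[1L]; den <- parts[2L]
  } else if (grepl("^[0-9]+(\\.[0-9]+)?$", f)) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1L]]
    whole <- as.numeric(parts[1L])
    frac <- if (length(parts) == 2L) parts[2L] else ""
    den <- 10^nchar(frac)
    num <- whole * den + if (nzchar(frac)) as.numeric(frac) else 0
  } else {
    stop("cannot parse support fraction: ", f, call. = FALSE)
  }
  if (den == 0) stop("zero denominator", call. = FALSE)
  g <- gcd2(num, den)
  num <- num / g; den <- den / g
  if (2 * num <= den) stop("support fraction must exceed 1/2", call. = FALSE)
  if (num > den) stop("support fraction must be at most 1", call. = FALSE)
  list(num = num, den = den)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Support threshold count
#'
#' Smallest integer `c` with `c >= f * m`, computed by exact integer
#' arithmetic on the rational `f` (no floating point).
#'
#' @param m collection size (>= 1).
#' @param f support fraction in (1/2, 1] (anything [support_fraction()]
#'   accepts).
#' @return integer threshold.
#' @export
threshold_count <- function(m, f) {
  stopifnot(m >= 1)
  fr <- support_fraction(f)
  q <- (fr$num * m) %/% fr$den
  r <- (fr$num * m) %% fr$den
  as.integer(q + (r > 0))
}

# ---------------------------------------------------------------------------
# internal: mining context (one environment threaded through the recursion)
# ---------------------------------------------------------------------------

new_mining_ctx <- function(tables, triplets, threshold, m, prune, max_nodes) {
  rules <- c("sibling", "cousin", "pruner")
  if (isTRUE(prune)) prune <- rules
  if (isFALSE(prune)) prune <- character(0)
  stopifnot(all(prune %in% rules))
  ctx <- new.env(parent = emptyenv())
  ctx$tables <- tables
  ctx$triplets <- triplets
  ctx$threshold <- threshold
  ctx$m <- m
  ctx$p_sib <- "sibling" %in% prune
  ctx$p_cousin <- "cousin" %in% prune
  ctx$p_pruner <- "pruner" %in% prune
  ctx$max_nodes <- max_nodes
  ctx$nodes <- 0L
  ctx$joins_attempted <- 0L
  ctx$fsts_materialized <- 0L
  ctx$prunes_sibling <- 0L
  ctx$prunes_cousin <- 0L
  ctx$prunes_pruner_childless <- 0L
  ctx$nonmaximal_leaves <- 0L
  ctx$cand <- list()
  ctx
}

# Exact local maximality test for a candidate core: a frequent subtree C is
# maximal iff no leaf outside C admits a frequent topology on
# L(C) + {leaf} that displays C. Restrictions of the trees supporting C are
# tallied directly, so the answer is exact regardless of pruning.
is_locally_maximal <- function(member, ctx) {
  tree <- member$tree
  sup_idx <- which(member$support)
  n <- ncol(ctx$presence)
  keep <- logical(max(n, max(tree$idft)))
  for (leaf in seq_len(n)) {
    if (keep_candidate_leaf(leaf, tree, ctx)) {
      holders <- sup_idx[ctx$presence[sup_idx, leaf]]
      if (length(holders) < ctx$threshold) next
      keep[] <- FALSE
      keep[tree$idft] <- TRUE
      keep[leaf] <- TRUE
      tally <- integer(0)
      best <- 0L
      for (t in holders) {
        key <- node_restrict_key(ctx$trees[[t]]$root, keep)$s
        cnt <- if (is.na(match(key, names(tally)))) 1L else tally[[key]] + 1L
        tally[[key]] <- cnt
        if (cnt > best) best <- cnt
      }
      if (best >= ctx$threshold) return(FALSE)
    }
  }
  TRUE
}

keep_candidate_leaf <- function(leaf, tree, ctx) {
  ctx$freq_leaf[leaf] && !(leaf %in% tree$idft)
}

is_subset <- function(a, b) !any(a & !b)   # a subseteq b, logical vectors

# Sibling rule: does sibling class X (core x_rec) prune sibling
# class Y (core y_rec)?  Jxy is the (existing) join record of (x, y);
# joins_of_y maps sibling rightmost label z -> join record of (y, z).
prunes_sibling <- function(x_rec, y_rec, Jxy, joins_of_y, ctx) {
  # support containment with the join itself: every tree backing Y's branch
  # must display T_xy, otherwise the displaying supertrees in X's branch
  # need not be frequent (containment with X's core alone is not enough)
  if (!is_subset(y_rec$support, Jxy$support)) return(FALSE)
  if (Jxy$join_type != "TYPE2") return(TRUE)                     # case (a)
  # case (b): descendants of Y can only add the rightmost leaves of Y's
  # existing sibling joins (set Z), so the branch is dominated by x as
  # soon as every triple {x, u, v} over Y's leaves plus Z is frequent
  # with support containing Y's: then every tree backing a subtree S in
  # Y's branch places x identically relative to S, giving a frequent
  # supertree of S in X's branch. Checking only the {x, y, z} triples
  # is not enough: trees can agree on [x,y,a] and [x,y,b] yet split on
  # [x,a,b].
  x <- x_rec$rightmost
  P <- c(y_rec$tree$idft, as.integer(names(joins_of_y)))
  if (length(P) < 2L) return(TRUE)
  for (i in seq_len(length(P) - 1L)) {
    for (j in seq.int(i + 1L, length(P))) {
      trip <- triplet_lookup(ctx$triplets, x, P[i], P[j])
      if (is.null(trip) || !is_subset(y_rec$support, trip$support)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Cousin rule: does the class of T_xy prune the class of T_yz?
prunes_cousin <- function(Jxy, Jyz, ctx) {
  Jxy$join_type == "TYPE2" && Jyz$join_type != "TYPE2" &&
    is_subset(Jyz$support, Jxy$support)
}

# Pruner-list conditions 1-2 (new entries contributed by sibling x) for the
# class whose core is the join T_yz. Returns NULL or list(label=, support=).
pruner_entry_from_sibling <- function(x_rec, y_rec, z_rec, Jxy, Jyz, ctx) {
  if (Jxy$join_type != "TYPE2") {
    S <- Jxy$support
  } else {
    trip <- triplet_lookup(ctx$triplets, x_rec$rightmost, y_rec$rightmost,
                           z_rec$rightmost)
    if (is.null(trip)) return(NULL)
    S <- Jxy$support & trip$support
  }
  if (sum(S & Jyz$support) < ctx$threshold) return(NULL)
  list(label = x_rec$rightmost, support = S, direct = TRUE)
}

# Pruner-list condition 3: inheritance from the intersection of the two
# parent members' pruner-lists.
pruner_inherit <- function(pruner_y, pruner_z, Jyz_support, ctx) {
  out <- list()
  for (w in intersect(names(pruner_y), names(pruner_z))) {
    S <- pruner_y[[w]]$support & pruner_z[[w]]$support
    if (sum(S & Jyz_support) >= ctx$threshold) {
      out[[w]] <- list(support = S, direct = FALSE)
    }
  }
  out
}

# Full pruner-list class check: for a label `a` carried by every
# member's pruner-list, a member whose support equals the intersection of
# the `a`-entries has a dominated class, and if all members qualify the
# whole class is dominated. Exposed for inspection and unit tests; the
# miner does NOT consult it, because the rule combines entries across
# children and such compositions can cut branches that still hold maximal
# subtrees (trees may agree on [x,y,a] and [x,y,b] yet split on [x,a,b]).
pruner_class_check <- function(members) {
  labsets <- lapply(members, function(m) names(m$pruner))
  common <- Reduce(intersect, labsets)
  member_hit <- logical(length(members))
  whole <- FALSE
  for (a in common) {
    S <- Reduce(`&`, lapply(members, function(m) m$pruner[[a]]$support))
    hit <- vapply(members, function(m) all(m$support == S), logical(1))
    member_hit <- member_hit | hit
    if (all(hit)) whole <- TRUE
  }
  list(whole = whole, member_pruned = member_hit)
}

# does a pruner-list hold at least one directly seeded entry?
has_direct_entry <- function(pruner) {
  any(vapply(pruner, function(e) isTRUE(e$direct), logical(1)))
}

# ---------------------------------------------------------------------------
# internal: the recursive expansion of one equivalence class
# ---------------------------------------------------------------------------

# core_rec: fst record of the class's core tree; members: list of fst
# records (each with extra fields $pruner, $pruned) sharing the core as
# prefix. Emits candidate cores of empty classes into ctx$cand.
enumerate_node <- function(core_rec, members, ctx) {
  ctx$nodes <- ctx$nodes + 1L
  if (ctx$nodes > ctx$max_nodes) {
    stop("enumeration exceeded max_nodes = ", ctx$max_nodes,
         " (raise the cap or increase f)", call. = FALSE)
  }
  r <- core_rec$rightmost
  o <- order(vapply(members, function(m) m$rightmost, integer(1)))
  members <- members[o]
  k <- length(members)
  rml <- vapply(members, function(m) m$rightmost, integer(1))

  # all ordered pairwise joins
  J <- vector("list", k * k)
  jidx <- function(i, j) (i - 1L) * k + j
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ctx$joins_attempted <- ctx$joins_attempted + 1L
      out <- join_support(members[[i]], members[[j]], r, ctx$tables,
                          ctx$threshold, construct = TRUE)
      if (out$join_type != "NONE") {
        rec <- out$joined
        rec$join_type <- out$join_type
        rec$pruner <- list()
        rec$pruned <- FALSE
        J[[jidx(i, j)]] <- rec
        if (length(rec$tree$idft) >= 3L) {
          ctx$fsts_materialized <- ctx$fsts_materialized + 1L
        }
      }
    }
  }

  pruned_child <- vapply(members, function(m) isTRUE(m$pruned), logical(1))

  if (ctx$p_sib) {
    # sibling rule
    for (y in seq_len(k)) {
      if (pruned_child[y]) next
      joins_of_y <- list()
      for (z in seq_len(k)) {
        if (z != y && !is.null(J[[jidx(y, z)]])) {
          joins_of_y[[as.character(rml[z])]] <- J[[jidx(y, z)]]
        }
      }
      for (x in seq_len(k)) {
        if (x == y || is.null(J[[jidx(x, y)]])) next
        if (prunes_sibling(members[[x]], members[[y]], J[[jidx(x, y)]],
                           joins_of_y, ctx)) {
          pruned_child[y] <- TRUE
          ctx$prunes_sibling <- ctx$prunes_sibling + 1L
          break
        }
      }
    }
  }
  if (ctx$p_cousin) {
    # cousin rule
    for (x in seq_len(k)) {
      for (y in seq_len(k)) {
        if (x == y || is.null(J[[jidx(x, y)]])) next
        if (J[[jidx(x, y)]]$join_type != "TYPE2") next
        for (z in seq_len(k)) {
          if (z == y || z == x) next
          ij <- jidx(y, z)
          if (is.null(J[[ij]]) || J[[ij]]$pruned) next
          if (prunes_cousin(J[[jidx(x, y)]], J[[ij]], ctx)) {
            J[[ij]]$pruned <- TRUE
            ctx$prunes_cousin <- ctx$prunes_cousin + 1L
          }
        }
      }
    }
  }
  if (ctx$p_pruner && length(core_rec$tree$idft) >= 2L) {
    # pruner-list assignment for the classes the joins will core; only at
    # classes whose core has >= 2 leaves (below that the uniqueness
    # argument behind the entries has no rightmost core leaf to anchor to)
    for (y in seq_len(k)) {
      if (pruned_child[y]) next
      for (z in seq_len(k)) {
        if (z == y) next
        ij <- jidx(y, z)
        if (is.null(J[[ij]]) || J[[ij]]$pruned) next
        pl <- list()
        for (x in seq_len(k)) {
          if (x == y || x == z || is.null(J[[jidx(x, y)]])) next
          e <- pruner_entry_from_sibling(members[[x]], members[[y]],
                                         members[[z]], J[[jidx(x, y)]],
                                         J[[ij]], ctx)
          if (!is.null(e)) {
            key <- as.character(e$label)
            if (is.null(pl[[key]])) {
              pl[[key]] <- list(support = e$support, direct = TRUE)
            }
          }
        }
        inh <- pruner_inherit(members[[y]]$pruner, members[[z]]$pruner,
                              J[[ij]]$support, ctx)
        for (w in names(inh)) if (is.null(pl[[w]])) pl[[w]] <- inh[[w]]
        J[[ij]]$pruner <- pl
      }
    }
  }

  # expansion / emission, in rightmost-label order
  for (i in seq_len(k)) {
    if (pruned_child[i]) next
    ch <- list()
    for (j in seq_len(k)) {
      if (j != i && !is.null(J[[jidx(i, j)]])) ch[[length(ch) + 1L]] <- J[[jidx(i, j)]]
    }
    if (length(ch) == 0L) {
      if (length(members[[i]]$tree$idft) < 3L) next
      if (ctx$p_pruner && has_direct_entry(members[[i]]$pruner)) {
        ctx$prunes_pruner_childless <- ctx$prunes_pruner_childless + 1L
        next
      }
      if (!is_locally_maximal(members[[i]], ctx)) {
        ctx$nonmaximal_leaves <- ctx$nonmaximal_leaves + 1L
        next
      }
      ctx$cand[[length(ctx$cand) + 1L]] <-
        list(tree = members[[i]]$tree, support = members[[i]]$support)
    } else {
      enumerate_node(members[[i]], ch, ctx)
    }
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# internal: root pass over single leaves and cherries (levels 0 and 1)
# ---------------------------------------------------------------------------

# Builds the frequent cherries per minimum leaf, applies the root-level
# sibling rule and pruner-list seeding (joins of two single leaves are
# type-2), then expands each surviving minimum-leaf class.
root_pass <- function(presence, ctx) {
  n <- ncol(presence)
  supc <- colSums(presence)
  freq_leaf <- which(supc >= ctx$threshold)
  ctx$freq_leaf <- seq_len(n) %in% freq_leaf

  for (y in freq_leaf) {
    members <- list()
    for (z in freq_leaf[freq_leaf > y]) {
      sup <- presence[, y] & presence[, z]
      if (sum(sup) >= ctx$threshold) {
        rec <- fst_record(new_ptree(list(y, z)), sup)
        rec$pruner <- list()
        rec$pruned <- FALSE
        members[[length(members) + 1L]] <- rec
      }
    }
    if (length(members) == 0L) next
    core <- fst_record(new_ptree(y), presence[, y])
    enumerate_node(core, members, ctx)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# initial classes (triplet level) as a standalone, inspectable structure
# ---------------------------------------------------------------------------

triplet_tree <- function(a, b, c, code) {
  switch(code + 1L,
         list(a, b, c),          # star
         list(list(a, b), c),    # ((a,b),c)
         list(list(a, c), b),    # ((a,c),b)
         list(a, list(b, c)))    # (a,(b,c))
}

#' Equivalence classes of the frequent triplets
#'
#' Turns every frequent triplet into a 3-leaf frequent subtree and groups
#' them into equivalence classes keyed by their 2-leaf prefix (the first
#' two IDFT leaves). Classes and members are sorted deterministically.
#'
#' @param triplets a `triplet_table` from [enumerate_frequent_triplets()].
#' @return list of classes, each `list(core = ptree, members = list of fst)`,
#'   sorted by the core's Newick string; members sorted by rightmost leaf.
#' @export
initial_classes <- function(triplets) {
  keys <- ls(triplets)
  if (length(keys) == 0L) return(list())
  classes <- list()
  for (k in keys) {
    v <- get(k, envir = triplets)
    abc <- as.integer(strsplit(k, ".", fixed = TRUE)[[1L]])
    tr <- new_ptree(triplet_tree(abc[1L], abc[2L], abc[3L], v$code))
    rec <- fst_record(tr, v$support)
    core_key <- paste(tr$idft[1L], tr$idft[2L], sep = ".")
    classes[[core_key]] <- c(classes[[core_key]], list(rec))
  }
  out <- lapply(names(classes), function(ck) {
    ij <- as.integer(strsplit(ck, ".", fixed = TRUE)[[1L]])
    mem <- classes[[ck]]
    mem <- mem[order(vapply(mem, function(m) m$rightmost, integer(1)))]
    list(core = new_ptree(list(ij[1L], ij[2L])), members = mem)
  })
  out[order(vapply(out, function(cl) cl$core$newick, character(1)))]
}

# ---------------------------------------------------------------------------
# finalization
# ---------------------------------------------------------------------------

#' Maximality safety filter over emitted candidates
#'
#' Removes any candidate displayed by another candidate and sorts the rest
#' by (leaf count descending, Newick string). With a correct pruning stage
#' nothing should ever be removed; the removal count is reported so tests
#' can treat a nonzero value as a pruning-logic regression.
#'
#' @param candidates list of `list(tree = ptree, support = logical)`.
#' @param safety_filter apply the display filter (default TRUE).
#' @return list with `candidates` (filtered, sorted) and `removed` (count).
#' @export
finalize_maximal <- function(candidates, safety_filter = TRUE) {
  if (length(candidates) == 0L) {
    return(list(candidates = list(), removed = 0L))
  }
  nl <- vapply(candidates, function(c) length(c$tree$idft), integer(1))
  nw <- vapply(candidates, function(c) c$tree$newick, character(1))
  o <- order(-nl, nw)
  candidates <- candidates[o]
  nl <- nl[o]
  removed <- 0L
  if (safety_filter && length(candidates) > 1L) {
    keep <- rep(TRUE, length(candidates))
    for (i in seq_along(candidates)) {
      for (j in seq_along(candidates)) {
        if (i == j || !keep[j] || nl[j] <= nl[i]) next
        if (displays(candidates[[j]]$tree, candidates[[i]]$tree)) {
          keep[i] <- FALSE
          removed <- removed + 1L
          break
        }
      }
    }
    candidates <- candidates[keep]
  }
  list(candidates = candidates, removed = removed)
}

# ---------------------------------------------------------------------------
# the miner
# ---------------------------------------------------------------------------

#' Mine all maximal frequent subtrees of a tree collection
#'
#' Enumerates, exactly and non-redundantly, every maximal `f`-frequent
#' subtree (with at least 3 leaves) of a collection of rooted phylogenetic
#' trees: a subtree displayed by at least `f * m` of the `m` input trees
#' and not displayed by any larger frequent subtree. With `f = 1` these
#' are the maximal agreement subtrees.
#'
#' @param x the collection: a file path, character vector of Newick
#'   strings, data frame with a `newick` column, or list of `ptree`.
#' @param f support fraction in (1/2, 1]; decimal strings such as
#'   `"0.55"` are converted to exact rationals (see [support_fraction()]).
#' @param mode `"mfst"` (general), `"mxst"` (forces `f = 1`), or `"auto"`.
#' @param safety_filter run the final pairwise maximality filter (default
#'   TRUE); its removal count is reported in the counters and should be 0.
#' @param prune `TRUE` (all pruning rules), `FALSE` (none; audit mode in
#'   which every frequent subtree is materialized exactly once), or a
#'   character subset of `c("sibling", "cousin", "pruner")`.
#' @param max_nodes cap on enumeration-tree nodes visited (resource guard).
#' @return an object of class `mfst_result`; see [tidy.mfst_result()].
#' @export
#' @examples
#' trees <- c("(((1,2),(3,4)),5);", "((1,2),((3,4),5));")
#' res <- mine_mfst(trees, f = 1)
#' tidy(res)
mine_mfst <- function(x, f = 1, mode = c("auto", "mfst", "mxst"),
                      safety_filter = TRUE, prune = TRUE,
                      max_nodes = 200000L) {
  mode <- match.arg(mode)
  if (mode == "mxst") f <- 1
  if (inherits(x, "ptree")) x <- list(x)
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1), "ptree"))) {
    trees <- x
    lmap <- NULL
  } else {
    coll <- read_tree_collection(x)
    trees <- coll$trees
    lmap <- coll$label_map
  }
  if (any(vapply(trees, n_leaves, integer(1)) < 3L)) {
    stop("every collection tree needs at least 3 leaves", call. = FALSE)
  }
  m <- length(trees)
  fr <- support_fraction(f)
  threshold <- threshold_count(m, f)
  if (mode == "auto") mode <- if (fr$num == fr$den) "mxst" else "mfst"

  n_labels <- max(vapply(trees, function(t) max(t$idft), integer(1)))
  binary <- all(vapply(trees, function(t) node_is_binary(t$root), logical(1)))
  if (!binary) prune <- FALSE   # pruning rules need binary input trees
  tables <- build_lca_tables(trees, n_labels = n_labels)
  presence <- do.call(rbind, lapply(tables, function(t) t$present))
  triplets <- enumerate_frequent_triplets(tables, threshold)

  ctx <- new_mining_ctx(tables, triplets, threshold, m, prune, max_nodes)
  ctx$trees <- trees
  ctx$presence <- presence
  root_pass(presence, ctx)

  fin <- finalize_maximal(ctx$cand, safety_filter = safety_filter)
  counters <- c(
    nodes_visited = ctx$nodes,
    joins_attempted = ctx$joins_attempted,
    fsts_materialized = ctx$fsts_materialized,
    prunes_sibling = ctx$prunes_sibling,
    prunes_cousin = ctx$prunes_cousin,
    prunes_pruner_childless = ctx$prunes_pruner_childless,
    nonmaximal_leaves = ctx$nonmaximal_leaves,
    candidates_emitted = length(ctx$cand),
    removed_by_filter = fin$removed
  )
  new_mfst_result(fin$candidates, counters = counters, m = m,
                  n_labels = n_labels, f = fr, threshold = threshold,
                  mode = mode, label_map = lmap)
}
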