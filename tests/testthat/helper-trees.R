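# shared helpers: tiny constructors and randomized-tree utilities

pt <- function(s) parse_newick(s)
cn <- function(s) canonical_newick(parse_newick(s))

# random ptree on 1..n via the package generator, isolated RNG
rtree <- function(n, p_multi = 0, seed = NULL) {
  random_tree(seq_len(n), multifurcation_prob = p_multi, seed = seed)
}

# randomly permute children orders of a tree (breaking canonical order)
# and return the raw node structure
shuffle_node <- function(n) {
  if (!is.list(n)) return(n)
  ch <- lapply(n, shuffle_node)
  ch[sample(length(ch))]
}

# a small random collection: base + perturbations, full leaf overlap
rcollection <- function(n, m, moves = 1, rogue = 0, p_multi = 0, seed = 1) {
  perturb_collection(synth_spec(
    n_leaves = n, m_trees = m, moves_per_tree = moves, n_rogue = rogue,
    multifurcation_prob = p_multi, seed = seed
  ))$trees
}

# mined vs oracle comparison keyed on topology + support set
result_keys <- function(res) {
  paste(res$mfst$newick,
        vapply(res$mfst$support, paste, character(1), collapse = ","))
}

oracle_keys <- function(records) {
  vapply(records, function(r) {
    paste(r$newick, paste(which(r$support), collapse = ","))
  }, character(1))
}

expect_matches_oracle <- function(trees, f, tally = NULL) {
  m <- length(trees)
  th <- threshold_count(m, f)
  res <- mine_mfst(trees, f = f)
  orc <- brute_force_mfsts(brute_force_fsts(trees, threshold = th,
                                            tally = tally))
  expect_setequal(result_keys(res), oracle_keys(orc))
  expect_identical(res$counters[["removed_by_filter"]], 0L)
  invisible(res)
}

# shared random (core, x, y, input tree) instance generator: two same-class
# subtrees carved out of a base tree by restriction, plus an input tree
# (a perturbation of the base) that displays both operands -- the premise
# under which the constant-time classification rule is defined, and the only
# situation in which the miner consults it (operand support intersection)
random_join_instances <- function(n_instances, seed) {
  set.seed(seed)
  out <- list()
  while (length(out) < n_instances) {
    n <- sample(6:12, 1)
    base <- rtree(n, p_multi = sample(c(0, 0.3), 1))
    t_input <- base
    for (mv in seq_len(sample(0:2, 1))) {
      t_input <- phylomfst:::regraft_leaf(t_input, sample(n, 1))
    }
    core_size <- sample(2:(n - 2), 1)
    lv <- sample(n, core_size + 2L)
    core_lv <- lv[seq_len(core_size)]
    xz <- lv[core_size + 1:2]
    Txr <- restrict_tree(base, c(core_lv, xz[1]))
    Tyr <- restrict_tree(base, c(core_lv, xz[2]))
    # both must be one-leaf extensions of a shared prefix
    px <- prefix_tree(Txr)
    if (!identical(px$newick, prefix_tree(Tyr)$newick)) next
    if (rightmost_leaf(Txr) == rightmost_leaf(Tyr)) next
    if (!displays(t_input, Txr) || !displays(t_input, Tyr)) next
    out[[length(out) + 1L]] <- list(
      input = t_input,
      Tx = fst_record(Txr, TRUE), Ty = fst_record(Tyr, TRUE),
      r = rightmost_leaf(px)
    )
  }
  out
}

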