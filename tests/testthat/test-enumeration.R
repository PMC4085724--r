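# enumeration-tree traversal: thresholds, classes, pruning, end-to-end mining

test_that("threshold_count uses exact rational arithmetic", {
  expect_identical(threshold_count(10, "0.51"), 6L)
  expect_identical(threshold_count(4, "3/4"), 3L)
  expect_identical(threshold_count(7, "1"), 7L)
  expect_identical(threshold_count(3, "0.6666666667"), 3L)
  expect_identical(threshold_count(100, 0.51), 51L)
  expect_error(threshold_count(10, "0.5"), "exceed 1/2")
  expect_error(threshold_count(10, "1.2"), "at most 1")
  expect_identical(support_fraction("0.55"), list(num = 11, den = 20))
})

test_that("initial_classes groups frequent triplets by 2-leaf prefix", {
  tt <- enumerate_frequent_triplets(
    build_lca_tables(lapply(rep("((1,2),(3,4));", 2), pt)), threshold = 2)
  cls <- initial_classes(tt)
  cores <- vapply(cls, function(cl) cl$core$newick, character(1))
  expect_identical(cores, sort(cores))
  # triples {1,2,3} -> ((1,2),3) and {1,2,4} -> ((1,2),4): one class (1,2)
  c12 <- cls[[match("(1,2)", cores)]]
  expect_identical(vapply(c12$members, function(m) m$rightmost, integer(1)),
                   3:4)
  # {1,3,4} -> (1,(3,4)): IDFT 1,3,4 -> class core (1,3)
  c13 <- cls[[match("(1,3)", cores)]]
  expect_identical(c13$members[[1]]$tree$newick, "(1,(3,4))")
  # empty table -> no classes
  empty <- enumerate_frequent_triplets(
    build_lca_tables(lapply(c("(1,(2,3));", "((1,2),3);", "((1,3),2);"), pt)),
    threshold = 2)
  expect_identical(initial_classes(empty), list())
})

test_that("identical collections mine to the single whole tree", {
  for (m in c(1L, 4L)) {
    trees <- lapply(rep("(1,(2,(3,4)));", m), pt)
    res <- mine_mfst(trees, f = 1)
    expect_identical(res$mfst$newick, "(1,(2,(3,4)))")
    expect_true(all(res$mfst$support[[1]] == seq_len(m)))
  }
})

test_that("the rogue-taxon pair yields its three maximal agreement subtrees", {
  res <- mine_mfst(c("(((1,2),(3,4)),5);", "((1,2),((3,4),5));"), f = 1)
  expect_setequal(res$mfst$newick,
                  c("((1,2),(3,4))", "((1,2),5)", "((3,4),5)"))
  expect_true(all(res$mfst$support_count == 2L))
  expect_identical(res$counters[["removed_by_filter"]], 0L)
})

test_that("majority support keeps the better-supported full topology", {
  t1 <- "((1,2),(3,4),5);"
  t2 <- "(1,(2,3),(4,5));"
  res <- mine_mfst(c(t1, t1, t2), f = "0.6")
  expect_identical(res$mfst$newick, cn(t1))
  expect_identical(res$mfst$support[[1]], 1:2)
})

test_that("mining matches the oracle across seeded random collections", {
  set.seed(97)
  cases <- expand.grid(n = c(6, 8), m = c(5, 10), moves = 0:1)
  for (i in seq_len(nrow(cases))) {
    trees <- rcollection(cases$n[i], cases$m[i], moves = cases$moves[i],
                         rogue = i %% 2, seed = 400 + i)
    tal <- fst_tally(trees)
    for (f in c("0.51", "0.75", "1")) {
      expect_matches_oracle(trees, f, tally = tal)
    }
  }
})

test_that("mining matches the oracle on multifurcating and partial-overlap input", {
  set.seed(101)
  trees <- rcollection(8, 6, moves = 1, p_multi = 0.4, seed = 31)
  tal <- fst_tally(trees)
  for (f in c("0.6", "1")) expect_matches_oracle(trees, f, tally = tal)
  # partially overlapping leaf sets: support denominator stays m
  po <- perturb_collection(synth_spec(9, 6, moves_per_tree = 1,
                                      overlap_frac = 0.8, seed = 33))$trees
  for (f in c("0.6", "1")) expect_matches_oracle(po, f)
})

test_that("pruning rules only skip work, never change the output", {
  set.seed(103)
  for (rep in 1:4) {
    trees <- rcollection(8, 6, moves = 1, seed = 500 + rep)
    for (f in c("0.6", "1")) {
      full <- result_keys(mine_mfst(trees, f = f))
      for (rules in list(FALSE, "sibling", "cousin", "pruner",
                         c("sibling", "cousin"))) {
        expect_setequal(result_keys(mine_mfst(trees, f = f, prune = rules)),
                        full)
      }
    }
  }
})

test_that("without pruning each frequent subtree is materialized exactly once", {
  set.seed(107)
  for (rep in 1:3) {
    trees <- rcollection(7, 5, moves = 1, seed = 600 + rep)
    for (f in c("0.6", "1")) {
      th <- threshold_count(length(trees), f)
      res <- mine_mfst(trees, f = f, prune = FALSE)
      expect_identical(res$counters[["fsts_materialized"]],
                       length(brute_force_fsts(trees, threshold = th)))
    }
  }
})

test_that("outputs are pairwise non-displaying and unique per leaf set", {
  set.seed(109)
  trees <- rcollection(8, 5, moves = 2, seed = 700)
  res <- mine_mfst(trees, f = "0.6")
  k <- nrow(res$mfst)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        expect_false(displays(res$mfst$tree[[i]], res$mfst$tree[[j]]))
      }
    }
  }
  leafsets <- vapply(res$mfst$tree, function(t) {
    paste(leaf_set(t), collapse = ".")
  }, character(1))
  expect_identical(anyDuplicated(leafsets), 0L)
})

test_that("tree order does not change the mined set (supports permute)", {
  set.seed(113)
  trees <- rcollection(7, 6, moves = 1, seed = 800)
  perm <- sample(length(trees))
  res1 <- mine_mfst(trees, f = "0.6")
  res2 <- mine_mfst(trees[perm], f = "0.6")
  expect_setequal(res1$mfst$newick, res2$mfst$newick)
  for (i in seq_len(nrow(res1$mfst))) {
    j <- match(res1$mfst$newick[i], res2$mfst$newick)
    expect_setequal(match(res1$mfst$support[[i]], perm),
                    res2$mfst$support[[j]])
  }
})

test_that("config errors are rejected and the node cap guards resources", {
  trees <- c("((1,2),3);", "((1,2),3);")
  expect_error(mine_mfst(trees, f = 0.4), "exceed 1/2")
  expect_error(mine_mfst(c("(1,2);", "(1,2);"), f = 1), "at least 3")
  expect_error(mine_mfst(character(0)), "empty")
  expect_error(mine_mfst(rcollection(8, 4, moves = 0, seed = 1), f = 1,
                         max_nodes = 2L), "max_nodes")
})

test_that("finalize_maximal removes displayed candidates and sorts output", {
  cand <- list(
    list(tree = pt("((1,2),3);"), support = c(TRUE, TRUE)),
    list(tree = pt("((1,2),3,4);"), support = c(TRUE, TRUE))
  )
  fin <- finalize_maximal(cand)
  expect_identical(fin$removed, 1L)
  expect_identical(fin$candidates[[1]]$tree$newick, "((1,2),3,4)")
  # pairwise non-displaying candidates pass through, sorted by size then name
  cand2 <- list(
    list(tree = pt("((1,3),4);"), support = TRUE),
    list(tree = pt("((1,2),(3,4));"), support = TRUE)
  )
  fin2 <- finalize_maximal(cand2)
  expect_identical(fin2$removed, 0L)
  expect_identical(vapply(fin2$candidates, function(c) c$tree$newick, character(1)),
                   c("((1,2),(3,4))", "((1,3),4)"))
  expect_identical(finalize_maximal(list())$candidates, list())
})

test_that("tidy, glance and autoplot summarize a mining result", {
  res <- mine_mfst(c("(((1,2),(3,4)),5);", "((1,2),((3,4),5));"), f = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("newick", "n_leaves", "support_count", "support"))
  gl <- glance(res)
  expect_identical(gl$n_mfst, 3L)
  expect_identical(gl$m, 2L)
  expect_identical(gl$max_leaves, 4L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_output(print(res), "maximal frequent subtrees: 3")
})

test_that("sibling, cousin and pruner-list rules follow their conditions", {
  m <- 3L
  full <- rep(TRUE, m)
  ctx <- phylomfst:::new_mining_ctx(
    tables = build_lca_tables(lapply(rep("((1,2),3,4,5);", 3), pt)),
    triplets = enumerate_frequent_triplets(
      build_lca_tables(lapply(rep("((1,2),3,4,5);", 3), pt)), threshold = 3),
    threshold = 3L, m = m, prune = TRUE, max_nodes = 100L
  )
  mk <- function(nwk, sup = full) fst_record(pt(nwk), sup)
  jn <- function(nwk, type, sup = full) {
    r <- mk(nwk, sup); r$join_type <- type; r
  }

  # sibling case (a): an existing non-cherry join with support containment
  X <- mk("((1,2),3,4);"); Y <- mk("((1,2),3,5);")
  Jxy <- jn("((1,2),3,4,5);", "TYPE1")
  expect_true(phylomfst:::prunes_sibling(X, Y, Jxy, list(), ctx))
  # ... but not when a supporter of Y does not display the join
  Ypart <- mk("((1,2),3,5);", c(TRUE, TRUE, TRUE))
  Jpart <- jn("((1,2),3,4,5);", "TYPE1", c(TRUE, TRUE, FALSE))
  expect_false(phylomfst:::prunes_sibling(X, Ypart, Jpart, list(), ctx))
  # cherry-type joins additionally need every reachable triple pinned:
  # {4,5} absent from the triplet table here, so the check fails
  Jxy2 <- jn("((1,2),3,(4,5));", "TYPE2")
  joins_y <- list("6" = jn("((1,2),3,(5,6));", "TYPE2"))
  expect_false(phylomfst:::prunes_sibling(X, Y, Jxy2, joins_y, ctx))

  # cousin rule: cherry-type T_xy dominates a non-cherry T_yz with nested
  # support; fails on type or support containment
  Jyz1 <- jn("((1,2),3,5,6);", "TYPE1")
  expect_true(phylomfst:::prunes_cousin(Jxy2, Jyz1, ctx))
  expect_false(phylomfst:::prunes_cousin(Jxy2, jn("((1,2),3,(5,6));", "TYPE2"), ctx))
  expect_false(phylomfst:::prunes_cousin(jn("((1,2),3,4,5);", "TYPE1"), Jyz1, ctx))
  Jyz_wide <- jn("((1,2),3,5,6);", "TYPE1", full)
  Jxy_narrow <- jn("((1,2),3,(4,5));", "TYPE2", c(TRUE, TRUE, FALSE))
  expect_false(phylomfst:::prunes_cousin(Jxy_narrow, Jyz_wide, ctx))

  # pruner entry, non-cherry case: only added when the shared support
  # reaches the threshold
  Z <- mk("((1,2),3,6);")
  e <- phylomfst:::pruner_entry_from_sibling(X, Y, Z, Jxy, Jyz1, ctx)
  expect_identical(e$label, 4L)
  expect_true(e$direct)
  Jyz_small <- jn("((1,2),3,5,6);", "TYPE1", c(TRUE, TRUE, FALSE))
  Jxy_small <- jn("((1,2),3,4,5);", "TYPE1", c(FALSE, TRUE, TRUE))
  expect_null(phylomfst:::pruner_entry_from_sibling(X, Y, Z, Jxy_small,
                                                    Jyz_small, ctx))

  # inheritance: labels common to both parents, intersected supports,
  # kept only when the shared support reaches the threshold
  py <- list("9" = list(support = c(TRUE, TRUE, TRUE), direct = TRUE),
             "7" = list(support = c(TRUE, TRUE, FALSE), direct = TRUE))
  pz <- list("9" = list(support = c(TRUE, TRUE, TRUE), direct = TRUE),
             "8" = list(support = full, direct = TRUE))
  inh <- phylomfst:::pruner_inherit(py, pz, full, ctx)
  expect_named(inh, "9")
  expect_false(inh[["9"]]$direct)

  # class check (inspection only): childless classes and the common-label
  # support-equality rule
  mA <- mk("((1,2),3,4,5);"); mA$pruner <- py; mA$pruned <- FALSE
  mB <- mk("((1,2),3,(4,6));"); mB$pruner <- pz; mB$pruned <- FALSE
  chk <- phylomfst:::pruner_class_check(list(mA, mB))
  expect_true(chk$whole)            # both members' supports equal S_cap
  expect_true(all(chk$member_pruned))
  mC <- mk("((1,2),3,(4,7));", c(TRUE, FALSE, TRUE)); mC$pruner <- pz
  chk2 <- phylomfst:::pruner_class_check(list(mA, mC))
  expect_false(chk2$whole)
  expect_identical(chk2$member_pruned, c(TRUE, FALSE))
  expect_true(phylomfst:::has_direct_entry(py))
  expect_false(phylomfst:::has_direct_entry(list(
    "4" = list(support = full, direct = FALSE))))
})
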