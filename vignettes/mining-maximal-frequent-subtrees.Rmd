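---
title: "Mining maximal frequent subtrees in collections of rooted phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining maximal frequent subtrees in collections of rooted phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomfst)
```

## The problem

A phylogenetic analysis rarely produces one tree: bootstrap replicates,
Bayesian posterior samples, or per-gene trees give a *collection* of rooted
trees on (mostly) the same taxa. Consensus summaries such as the
majority-rule tree are fragile in the presence of *rogue taxa* — leaves
whose position wanders between replicates — because they must place every
taxon. Agreement subtrees drop taxa instead: an **agreement subtree (AST)**
is a tree displayed by every tree in the collection (displayed = equal to
the restriction of that tree to the subtree's leaves), a **maximal**
agreement subtree (MXST) is an AST contained in no larger AST, and a
**maximum** agreement subtree (MAST) is an MXST of largest leaf count.
Relaxing "every tree" to "at least a fraction *f*" gives **frequent
subtrees (FSTs)** and **maximal frequent subtrees (MFSTs)**; `phylomfst`
enumerates all MFSTs exactly, for any `f` in (1/2, 1], with the MXST case
as `f = 1`.

Why maximal only? Every FST is contained in some MFST, so the MFST set is a
complete, non-redundant summary; FSTs can outnumber MFSTs exponentially
(restrict a 10-leaf tree to all of its leaf subsets: 968 FSTs, one MFST).
And an MXST other than the MAST — or an MFST at `f < 1` larger than any
MAST — can surface shared structure the MAST misses; the acceptance script
recomputes both phenomena on committed fixtures.

`f` is required to exceed 1/2 because above that threshold at most one
topology on a given leaf set can be frequent, which makes the output
well-defined and the search tractable.

## The enumeration machinery

Trees are rooted, leaf-labeled by integers `1..|L|` (taxon names map to
integers by lexicographic sort), with every internal node of degree at
least two. All candidate generation happens in **canonical form**: each
internal node's children are ordered by *virtual label*, the smallest leaf
label below the child. Two trees are isomorphic exactly when their
canonical serializations are equal, so canonical Newick strings serve as
identities throughout.

The inorder depth-first traversal (IDFT) of a canonical tree linearizes
its leaves; the **prefix** of a tree is what remains after pruning the
last (rightmost) IDFT leaf, and pruning the last or second-to-last leaf of
a canonical tree is again canonical. Trees sharing a prefix form an
**equivalence class** whose shared prefix is the class **core**; classes
form an enumeration tree. Every `k`-leaf frequent subtree `T` is the
**join** of the unique ordered pair `(Tx, Ty)` obtained by pruning its
last and second-to-last leaves; `Tx` and `Ty` live in one class. A join
can attach the new leaf in four ways relative to the rightmost path
(sibling at equal depth, new cherry one level deeper, new node above the
`x`-parent, or re-application of `Ty`'s graft higher up), and which of the
four (if any) an input tree supports is decided in constant time from
three precomputed LCA-depth look-ups on the triple `{r, x, y}` (`r` the
core's rightmost leaf) plus the stored depth of each operand's
rightmost-leaf parent. Support sets (bit-indexed sets of input trees) are
intersected as pairs join, so each join's support is exact.

The recursion is seeded two levels below the triplets: frequent single
leaves, then frequent cherries grouped by their smaller leaf, after which
the triplet classes arise as ordinary joins and no level is special-cased.

## Output rule: exact local maximality

The core of a class with no children (no joins extend it) is a *candidate*
maximal subtree. Rather than trusting the pruning rules to have eliminated
every dominated candidate, the package applies an **exact local maximality
test** at emission: a candidate `C` is output only if no single leaf
outside `C` admits a topology on `L(C) + {leaf}` that displays `C` and is
supported by at least the threshold number of trees (counted directly on
the supporting trees' restrictions). Because any frequent supertree of `C`
restricts to such a one-leaf extension, this test is exact: the emitted
set is precisely the MFST set provided every maximal subtree's class is
*reached*. Pruning therefore only ever needs to be *sound* (never cut a
branch holding a maximal subtree), not complete. A final pairwise display
filter is retained purely as a regression alarm; its removal counter is
reported and is asserted to be zero across the test suite.

## Pruning: what is applied, and why not everything

Branch-and-bound rules decide, from joins among class siblings, that every
subtree in one branch is dominated by (displayed within) another branch:

* **Sibling rule.** `X` prunes sibling `Y` when the join `T_xy` exists,
  every tree supporting `Y`'s core also supports `T_xy`, and either the
  join is not of the "new cherry" type, or — in the cherry case — every
  triple `{x, u, v}` over `Y`'s leaves and the rightmost leaves of `Y`'s
  existing sibling joins is frequent with support containing `Y`'s.
  The second clause is deliberately stronger than checking only the
  `{x, y, z}` triples: trees can agree on `[x,y,a]` and `[x,y,b]` yet
  split on `[x,a,b]`, in which case no frequent supertree pins `x` and the
  weaker rule cuts branches that still hold maximal subtrees (the package
  found desk-scale counterexamples during development). Since descendants
  of `Y` can only ever add the rightmost leaves of `Y`'s sibling joins,
  pinning all those triples makes the rule sound.
* **Cousin rule.** When `T_xy` is a cherry-type join and the sibling join
  `T_yz` is not, with `T_yz`'s support contained in `T_xy`'s, the class of
  `T_yz` is dominated by the class of `T_xy`.
* **Pruner lists.** When a sibling `x` fails to prune a branch outright
  but a frequent triple pins `x` against a join `T_yz` with enough shared
  support, the class of `T_yz` records the entry `(x, support)`. A
  childless class carrying such a *directly seeded* entry is dominated —
  a single pinned extension is enough evidence that a frequent supertree
  displays its core — and is skipped. Entries are also inherited along
  intersections of parent lists, and inherited lists are maintained and
  reported, but they never prune: combining two pinned extensions does not
  pin their mutual placement (the same `[x,a,b]` gap as above), so
  compositional uses (common-label class pruning, inherited childless
  vetoes) can be unsound and are excluded from the decision path.

Two further scope limits, both verified on counterexamples during
development: rule-based pruning presumes binary input trees (a
multifurcating tree can display two different one-leaf extensions of the
same pair of joins, e.g. both `(1,2,4,6)` and `(1,2,6,8)` inside
`(1,2,6,(4,8))`), so collections containing polytomies are enumerated with
pruning disabled — still exact, merely slower; and pruner entries are only
seeded at classes whose core has at least two leaves, where the rightmost
core leaf anchors the triple arguments.

`mine_mfst(..., prune = ...)` exposes the rules individually
(`"sibling"`, `"cousin"`, `"pruner"`, or `FALSE` for none); the test suite
asserts that every setting yields identical output, and that with pruning
off each frequent subtree is materialized exactly once (its unique ordered
pair), matching the brute-force count.

## Support semantics and numeric choices

* `f` is handled as an exact rational (`"0.55"` becomes 11/20); the
  threshold is the smallest integer at least `f * m`, computed in integer
  arithmetic, so no floating-point edge case can shift it.
* With partially overlapping leaf sets, a tree supports a subtree only if
  it contains all its leaves and displays it; the denominator stays the
  full collection size `m`. This keeps "at least `f * m` input trees"
  literal; other readings (per-candidate denominators) exist but are not
  implemented.
* Ties cannot arise in canonical ordering: sibling virtual labels are
  distinct because sibling leaf sets are disjoint (asserted).
* Reported subtrees have at least 3 leaves — the smallest phylogenetically
  informative size; 2-leaf agreements are never reported.
* Output order is deterministic: leaf count descending, then Newick
  string; support sets use 1-based input-tree indices.
* Enumeration is guarded by a configurable `max_nodes` cap with a clear
  error, since the number of frequent subtrees explored has no polynomial
  bound in the output size.

## The synthetic generator

`perturb_collection(synth_spec(...))` emulates the structure of bootstrap
replicate collections: one base topology (uniform random by sequential
leaf attachment; optional per-edge collapse probability for
multifurcations), per-replicate *leaf* prune-and-regraft moves, designated
rogue taxa re-grafted uniformly at random in every replicate, and optional
restriction to a random leaf subset (partial overlap). Leaf (rather than
internal-edge) regrafts are the perturbation unit because they match the
misplaced-taxon failure mode agreement methods target, and they make the
move log exact: the base tree restricted to a replicate's unmoved,
retained leaves is displayed by that replicate, by construction — a
property the tests assert directly.

What the generator does not emulate: branch lengths and realistic
rate heterogeneity, alignment-level resampling, correlated placement of
multiple rogues, or estimation error that perturbs many clades at once.
Passing the oracle-equivalence suite on these collections therefore
demonstrates algorithmic correctness of the enumeration, not robustness
of MFSTs as an inference tool on any particular kind of real data.

## Problem sizes used in validation

The randomized validation grid uses collections of 5–20 trees on 6–10
leaves (54 seeded collections, four support fractions each), small enough
that the brute-force oracle — restriction tallies over every leaf subset,
maximality by pairwise display tests — is itself beyond doubt and the
entire suite runs in minutes on one CPU. The join classifier is checked
against its restriction-based reference on 500 random instances with trees
of up to 12 leaves. The miner itself has no such size limits (the oracle
refuses beyond 16 leaves; the miner's practical range is far larger).

## Known limitations

* `f` must exceed 1/2; mining below majority support would require
  handling multiple frequent topologies per leaf set.
* Rooted trees only; unrooted collections must be rooted consistently
  first. Branch lengths and internal labels are read and discarded.
* The exact emission test costs `O(|L| * m * |T|)` per emitted candidate;
  on large collections with weak pruning (e.g. heavily multifurcating
  input) enumeration can be slow even though it remains exact.
* Memory holds all LCA-depth tables (`m * |L|^2` integers) plus the
  recursion's live classes.
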