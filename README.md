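# phylomfst

Exact enumeration of all **maximal frequent subtrees (MFSTs)** in a
collection of rooted phylogenetic trees — including all **maximal
agreement subtrees (MXSTs)** as the `f = 1` special case.

## The problem

Bootstrap replicates, posterior samples and per-gene trees give a
collection of rooted trees over a common set of taxa. Consensus methods
such as the majority-rule tree must place *every* taxon, which makes them
collapse toward stars when a few "rogue" taxa wander between trees.
Agreement-based summaries drop taxa instead: a subtree `T'` is *displayed*
by a tree `T` when `T'` equals the restriction `T|L(T')` (the minimal
homeomorphic subtree of `T` connecting `L(T')`). For a collection of `m`
trees and a support fraction `f ∈ (1/2, 1]`:

* an **f-frequent subtree (FST)** is displayed by at least `f·m` of the
  input trees;
* a **maximal frequent subtree (MFST)** is an FST that is a subtree of no
  other FST;
* at `f = 1` these are agreement subtrees (ASTs) and maximal agreement
  subtrees (MXSTs); a **MAST** is an MXST of maximum leaf count.

The MFST set is a complete, non-redundant summary of *all* frequent
structure: every FST is contained in some MFST, yet FSTs can outnumber
MFSTs exponentially. MXSTs other than the MAST — and MFSTs at `f < 1`
larger than any MAST — can reveal well-supported structure no MAST shows.

`phylomfst` enumerates the MFST set exactly and non-redundantly: candidate
subtrees are generated once each, in a canonical (virtual-label) form,
by pairwise joins within equivalence classes of a reverse-search
enumeration tree; each join is classified per input tree in constant time
from precomputed LCA-depth tables; support is carried in bit-indexed
support sets; dominated branches are pruned by sibling/cousin/pruner-list
rules; and every emitted candidate passes an exact local maximality test
(no frequent single-leaf extension displays it). A brute-force oracle
(leaf-subset enumeration) ships with the package and anchors the test
suite.

## Worked example

Ten bootstrap-like replicates of an 8-taxon tree in which one rogue taxon
(taxon 2) is re-placed at random in every replicate:

```r
library(phylomfst)

coll <- perturb_collection(synth_spec(n_leaves = 8, m_trees = 10,
                                      n_rogue = 1, seed = 42))
coll$base$newick
#> [1] "(((1,(3,5)),(2,4)),((6,8),7))"
coll$rogues
#> [1] 2

res <- mine_mfst(coll$trees, f = "0.51")
res
#> Maximal frequent subtree mining (MFST mode)
#>   trees: 10   leaf universe: 8   f = 51/100   support threshold: 6
#>   maximal frequent subtrees: 5
#>   (((1,(3,5)),4),((6,8),7));  [7 leaves, support 10/10]
#>   ((2,(3,5)),((6,8),7));  [6 leaves, support 6/10]
#>   ((1,2),((6,8),7));  [5 leaves, support 7/10]
#>   ((2,4),((6,8),7));  [5 leaves, support 7/10]
#>   ((1,(3,5)),2);  [4 leaves, support 6/10]
```

The top MFST is exactly the base tree minus the rogue taxon, displayed by
all ten replicates — structure a majority-rule tree would have blurred.
The remaining MFSTs record the rogue's alternative placements with their
supports. `tidy(res)` returns the same table as a tibble (one row per
subtree, with a list-column of supporting tree indices), `glance(res)`
gives a one-row run summary, `autoplot(res)` plots the size/support
profile, and `write_mfst(res, "out.nwk")` writes Newick.

At `f = 1` the miner returns maximal agreement subtrees. The classic
rogue-taxon pair shows an MXST that no MAST displays:

```r
mine_mfst(c("(((1,2),(3,4)),5);", "((1,2),((3,4),5));"), f = 1)
#> Maximal frequent subtree mining (MXST mode)
#>   trees: 2   leaf universe: 5   f = 1/1   support threshold: 2
#>   maximal frequent subtrees: 3
#>   ((1,2),(3,4));  [4 leaves, support 2/2]
#>   ((1,2),5);  [3 leaves, support 2/2]
#>   ((3,4),5);  [3 leaves, support 2/2]
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/phylomfst.R synth -o coll.nwk --n-leaves 20 --m-trees 50 --rogue 1 --seed 7
Rscript inst/cli/phylomfst.R mine -f 0.75 -o mfst.nwk --report-json run.json coll.nwk
```

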