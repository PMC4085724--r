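Package: phylomfst
Title: Maximal Frequent Subtree Mining for Collections of Rooted Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact enumeration of all maximal frequent subtrees (MFSTs) in a
    collection of rooted leaf-labeled phylogenetic trees, including maximal
    agreement subtrees as the f = 1 special case. Candidate subtrees are
    generated non-redundantly in a canonical (virtual-label) form by pairwise
    joins within equivalence classes of a reverse-search enumeration tree;
    per-tree join types are classified in constant time from precomputed
    LCA-depth tables, support is tracked with bit-indexed support sets, and
    dominated branches are pruned via sibling, cousin and pruner-list rules.
    Includes a brute-force oracle for validation, a deterministic synthetic
    collection generator (bootstrap-replicate-like perturbations, rogue taxa,
    partial leaf overlap), and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
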