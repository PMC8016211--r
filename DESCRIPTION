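Package: rhizogeo
Title: Multilocus Sequence Analysis and Phylogeography of Rhizobia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for phylogeographic analysis of
    bean-nodulating rhizobia from multilocus sequence data: reading and
    concatenating per-locus alignments, nucleotide distances and MLSA-based
    average nucleotide identity, neighbor-joining trees with nonparametric
    bootstrap bipartition supports, maximum-likelihood model fitting and a
    parametric-bootstrap test of gene-tree congruence, reference-anchored
    genospecies assignment, genetic diversity at nucleotide, locus and
    species levels, and spatial association statistics (Mantel and partial
    Mantel tests, principal coordinates analysis, distance-based
    permutational ANOVA, sliding-window diversity curves). Includes a
    synthetic-study generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    geosphere,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
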