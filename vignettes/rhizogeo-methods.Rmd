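---
title: "Methods: multilocus phylogeography of bean-nodulating rhizobia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus phylogeography of bean-nodulating rhizobia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The analysis chain

`rhizogeo` analyses strain collections typed at several housekeeping loci
and one symbiotic locus. The chain is: per-locus alignments are restricted
to a common strain set and concatenated; a tree with bootstrap clade
supports is built per level (concatenated housekeeping genes; the
symbiotic gene separately — symbiotic loci move on plasmids and must never
be pooled with the chromosomal signal); strains are assigned to
genospecies and symbiovars by a reference-anchored clade rule; genetic
diversity is summarized at nucleotide, locus and species levels; and the
association of genetic structure with geography and environment is tested
with Mantel-type statistics, ordination, windowed diversity curves and
distance-based permutational ANOVA. A parametric-bootstrap congruence test
asks whether each gene's own tree fits significantly better than the
multilocus topology — the signature of horizontal transfer.

## Distances and site classification

Sites are classified per column over unambiguous bases only (A/C/G/T):
conserved means a single distinct base, variable at least two,
parsimony-informative at least two bases each carried by at least two
sequences. Gaps and IUPAC ambiguity codes are excluded per column and,
for distances, per pair (pairwise deletion), with complete deletion as an
option; this matches the common behaviour of desktop phylogenetics tools
and keeps single-gap columns from contaminating whole columns. The
p-distance is the proportion of differing sites among comparable ones;
JC69, K2P and T92 corrections use the standard closed forms from the
transition proportion P, transversion proportion Q, and (for T92) the GC
content of the compared pair. A pair whose correction would require the
logarithm of a non-positive number raises a saturation error naming the
pair rather than returning `NaN` — silent non-finite distances corrupt
every downstream stage. ANI is reported as alignment-fraction identity
over the shared MLSA loci ("MLSA-ANI"), not whole-genome ANI, with the
conventional >95% species-membership cutoff.

## Trees, supports and assignment

Trees are built by neighbor joining on the chosen distance; negative
branch-length estimates are clamped to zero with the deficit pushed onto
the adjacent branches. Bootstrap supports resample alignment columns with
replacement (default 100 replicates) and score each internal edge of the
reference tree by the percentage of replicate trees containing the same
bipartition; bipartitions are canonicalized (smaller side, ties broken
toward the side holding the alphabetically first leaf) so supports can be
re-attached to any rooting of the same topology. Rooting for clade logic
is by outgroup when one is configured, midpoint otherwise.

Assignment walks each query leaf rootward and anchors at the first clade
with support above the threshold (default 60%) containing at least one
reference strain; the label is the majority reference species in the
anchor. When the anchor holds several reference species in equal number,
the species nearest to the query by patristic distance wins and the
assignment is flagged ambiguous — distance is the least arbitrary
tie-break available. Queries whose only supported reference-bearing
ancestor is the root are unclustered; maximal supported query-only clades
of two or more such strains are promoted to novel genospecies, named
`novel:1`, `novel:2`, ... in decreasing size order, and the remainder get
deterministic `unclustered:<strain id>` labels. Raising the threshold can
only grow anchors or push queries to unclustered (monotonicity), which
the test suite checks.

## Likelihood layer and the congruence test

Likelihood computations (Felsenstein pruning with pattern compression,
+G as four equal-probability discrete gamma categories, +I as a zero-rate
mixture class, ambiguity codes as partial likelihoods) and optimization
are delegated to `phangorn`; the package adds parameter accounting
(BIC = −2lnL + k ln n, AICc with the small-sample correction, n =
alignment columns), model parsing, and the congruence test. Supported ML
models are JC69, K2P, HKY and GTR, each optionally +G/+I; T92 is
available for distances but not for ML fits, where HKY (which nests T92's
transition bias) stands in.

The congruence test is a SOWH-style parametric bootstrap. For a locus and
a reference topology pruned to the shared taxa, `δ = lnL_free −
lnL_constrained`, with the constrained fit optimizing branch lengths and
model parameters on the fixed reference topology and the free fit adding
NNI search. The null distribution of δ comes from alignments simulated
under the constrained fit, re-analysed identically; the Monte-Carlo
p-value uses the +1 correction `(1 + #{δ* ≥ δ})/(1 + B)` so p = 0 is
impossible. B defaults to 100 (B < 19 is rejected as unable to resolve
the 5% level; the pipeline default uses B = 24 on a 24-taxon subsample
for tractability). The fitting model must accommodate rate heterogeneity:
with a rate-homogeneous model the null simulations are too regular and
the observed free-topology gain on heterogeneous data exceeds the null
even for clonal loci, inflating false alarms. The default is therefore
HKY+G. This is a model-adequacy requirement of the SOWH construction, not
a tuning knob.

## Diversity

Nucleotide diversity π is the mean pairwise p-distance within the group.
Locus diversity is Nei's unbiased haplotype diversity
h = n/(n−1)(1 − Σp²), averaged across loci; haplotypes are exact sequence
identity classes after masking ambiguity characters, so the estimator
reaches exactly 1 for two or three all-distinct strains and 0 for a
monomorphic locus — the boundary behaviour that identifies this estimator
in published per-group tables. Species-level diversity uses Shannon
(natural log) and Gini–Simpson indices over genospecies counts.
Between-group comparisons use a permutation test (strains shuffled
between groups, two-sided, +1-corrected).

## Spatial statistics

Geographic distances are haversine at the mean Earth radius 6371.0088 km.
The Mantel statistic is the Pearson correlation of upper-triangle
distance vectors; significance comes from simultaneous row/column
permutations of one matrix, one-sided (greater) by default because
isolation by distance predicts a positive association — published tables
for these data include negative correlations with large p-values, which
is the behaviour a one-sided test produces; two-sided is a flag away. At
n ≤ 8 all n! relabelings can be enumerated exactly. The partial Mantel
test correlates the residuals of both matrices after regression on the
covariate matrix and permutes the genetic residual matrix. PCoA is Gower
double-centering (−½ J D² J) plus eigendecomposition; negative
eigenvalues are reported but never embedded. The environmental analysis
is sequential (Type-I) distance-based PERMANOVA via `vegan::adonis2`,
with the sum-of-squares column labelled pseudo-χ² as is customary when
reporting distance-based partitioning for these covariates (longitude,
latitude, elevation, soil pH, in that order — order matters under
sequential partitioning).

Sliding-window curves move an 80 km window in 10 km steps across the
range of pairwise geographic separations. Per window the observed value
is the mean genetic distance of randomly selected eligible pairs, and the
null draws pairs irrespective of distance. The faithful default is a
single pair per window, which yields deliberately high-variance curves;
`n_resamples` is exposed because smoother curves are usually wanted.
Windows with no eligible pair are reported absent, never zero. The
species-level pair distance is the 0/1 same-genospecies indicator — the
minimal distance consistent with a species-level analysis.

## The synthetic generator

The generator emulates the structure of the Ethiopian common-bean
rhizobia collections: by default 95 local strains in 8 genospecies with
the two dominant species holding ~70% of strains; four housekeeping loci
of 548, 461, 349 and 784 bp (concatenating to 2142) plus a 465 bp
symbiotic locus; GTR+G sequences (shape 0.5, GC-rich base composition)
on a coalescent genospecies backbone (root-to-tip depth 0.08
substitutions/site) carrying within-genospecies subtrees (depth 0.01);
one reference strain per genospecies as a deeper within-clade lineage,
plus off-panel reference species; two collections over a 400 km region
with soil pH drawn from 4.68–6.44 (current) and 6.0–8.78 (previous).
Horizontal transfer re-grafts flagged strains into donor clades *before*
simulation, so the symbiotic gene tree is genuinely incongruent rather
than a post-hoc sequence swap. Spatial clustering uses
genospecies-specific Gaussian centers with dispersion
extent/(2(1 + λ)); λ = 0 degenerates to a uniform field, giving a clean
null. An optional pH-associated genospecies is confined to collections
whose pH range exceeds a cutoff (default 6.5), reproducing a
composition difference driven by a single clade.

The generator does **not** model recombination within loci, indel
evolution, coalescent demography, or measurement error; divergences
within/between genospecies are cleanly separated by construction. Passing
tests therefore demonstrate that the pipeline recovers structure *when
the MLSA species model holds*; they do not certify behaviour on real data
with intra-locus recombination or poorly separated species.

## Validation problem sizes and numerical choices

The validation harnesses use reduced but representative sizes, chosen
once: assignment accuracy on one 95-strain study with 100 bootstrap
replicates; Mantel size on 30 independent null studies and power on 10
studies at n = 60 with 199 permutations and spatial decay λ = 2 (picked
from a pre-registered λ grid as the smallest value giving saturated
power); congruence behaviour on 5 studies of 40 strains with a 20-taxon
subsample and B = 24; the pH-clade composition test on one 80-strain
study. Optimizer tolerances follow `phangorn` defaults; branch lengths
are bounded to [1e−8, 10]; NJ ties resolve deterministically; every
stochastic stage takes an explicit seed and repeated runs are
byte-identical (asserted in the tests down to the JSON summary).

## Known limitations

- Column trimming coordinates are never inferred; they are explicit
  configuration (`trim_alignment`). Published per-locus site counts that
  depend on undocumented trimming are not reproducible by construction.
- ML model selection excludes T92 (distance-only); HKY is the nesting
  substitute.
- The assignment rule inherits the instability of bootstrap supports near
  the threshold: supports just above/below 60% can flip anchors between
  runs with different replicate counts.
- PERMANOVA is sequential; covariate order changes the partition (by
  design, mirroring the reported analysis style).
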