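# rhizogeo

Phylogeographic analysis of bean-nodulating rhizobia from multilocus
sequence data.

Common bean (*Phaseolus vulgaris*) is nodulated by a diverse set of
*Rhizobium* species whose identity matters for inoculation strategies.
Species boundaries in these bacteria are drawn from housekeeping genes
(multilocus sequence analysis, MLSA), while the symbiotic genes that
control nodulation sit on plasmids and move horizontally between species.
`rhizogeo` implements, as a tested and reusable R pipeline, the analysis
chain used to ask where the genetic structure of such strain collections
comes from: from geography, from soil chemistry, from sampling, or from
horizontal transfer of the symbiosis module. It is aimed at microbial
ecologists and rhizobium systematists working with per-gene alignments and
strain metadata.

## What it computes

- **Multilocus handling** — per-locus FASTA alignments are harmonized to a
  shared strain set and concatenated with recorded locus boundaries; sites
  are classified (conserved / variable / parsimony-informative /
  singleton); pairwise distances are computed as p-distance or with JC69,
  K2P and T92 corrections, and MLSA-based average nucleotide identity
  (ANI%) with the conventional >95% species cutoff.
- **Trees and supports** — neighbor-joining trees; nonparametric bootstrap
  with clade support defined by bipartition recurrence; Newick I/O;
  outgroup or midpoint rooting.
- **Genospecies assignment** — each query strain is assigned to the
  smallest well-supported clade (support > 60% by default) containing at
  least one named reference strain; strains without such a clade form
  novel genospecies or stay unclustered. Genospecies (housekeeping) and
  symbiovars (symbiotic locus) are cross-tabulated, and collection
  compositions are compared with Fisher's exact test.
- **Maximum likelihood and congruence** — Felsenstein-pruning likelihoods
  under JC69/K2P/HKY/GTR with +G and +I (via `phangorn`), model selection
  by BIC/AICc, NNI topology search, sequence simulation, and a
  parametric-bootstrap (SOWH-style) test of whether a gene tree is
  congruent with the multilocus topology — the signature of a horizontally
  transferred locus is a significant likelihood gain
  `δ = lnL_free − lnL_constrained`.
- **Diversity at three levels** — nucleotide diversity
  `π = mean pairwise p-distance`; locus diversity as Nei's unbiased
  haplotype diversity `h = n/(n−1)(1 − Σp_i²)` averaged across loci; and
  species-level Shannon `H′ = −Σ p ln p` and Gini–Simpson `1 − Σp²`
  indices over genospecies counts.
- **Spatial statistics** — haversine distances; Mantel and partial Mantel
  tests (one-sided by default, exact enumeration available at small n);
  principal coordinates analysis by Gower double-centering; sliding-window
  diversity curves (80 km windows, 10 km steps) against a random-distance
  null; and sequential distance-based PERMANOVA over longitude, latitude,
  elevation and soil pH.
- **A synthetic-study generator** — complete studies (genospecies backbone
  tree, within-genospecies subtrees, reference panel, four housekeeping
  loci + one symbiotic locus with optional horizontal transfer,
  genospecies-clustered geography, per-collection soil pH) with known
  ground truth, so every downstream stage can be validated end to end.

## Worked example

Simulate a study emulating two Ethiopian strain collections (60 local
strains in 8 genospecies, no spatial clustering), run the full pipeline,
and score the assignment against ground truth:

```r
library(rhizogeo)
study <- simulate_study(study_config(n_strains = 60, spatial_decay = 0),
                        seed = 42)
run <- run_pipeline(study, pipeline_config(
  bootstrap_reps = 100, mantel_perms = 999,
  congruence = list(enabled = FALSE), seed = 42))
print(run)
evaluate_recovery(run$assignment_hk, study$truth)$assignment_accuracy
```

```
<rhizogeo_run>
  60 local strains, 4 hk loci (2142 concatenated columns)
  genospecies labels: 8; composition p = 0.00684
  Mantel (genetic ~ geographic): nucleotide r = -0.080 (p = 0.901); haplotype r = 0.010 (p = 0.373); species r = -0.003 (p = 0.504)
[1] 1
```

The four loci concatenate to 2142 columns; all 60 strains are assigned to
their true genospecies (accuracy 1.0); and with spatial clustering turned
off the Mantel correlations between genetic and geographic distance are
near zero with large p-values at all three levels — no spurious
isolation-by-distance. The per-genospecies diversity table
(`run$diversity$genospecies`) gives each group's size, nucleotide
diversity π and mean haplotype diversity:

```
              group  n      pi locus
1       R. phaseoli 21 0.01228 0.811
2           R. etli 21 0.00765 0.738
3    R. aethiopicum  5 0.01564 0.925
...
```

Setting `spatial_decay = 2` in the config produces strongly significant
Mantel tests instead; setting `hgt_probability = 0.3` makes the symbiotic
locus fail the congruence test (`congruence_test()`) while the
housekeeping loci pass.

A thin command-line wrapper is installed at
`inst/scripts/rhizogeo.R` (`rhizogeo.R run --config cfg.yaml`,
`rhizogeo.R simulate --out dir`); see `?run_pipeline_yaml` for the YAML
schema.

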