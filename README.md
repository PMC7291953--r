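# pondassembly

Community structure and assembly-process partitioning for amplicon (ZOTU)
count tables from contrasting habitats — built for size-fractionated
microbial eukaryote surveys of Arctic melt ponds (MP) and surface sea water
(SW), and applicable to any two-habitat metacommunity with a rooted
phylogeny of its taxa.

## What it computes

Given a ZOTU-by-sample count table (TSV), a rooted newick phylogeny and
per-sample metadata, the pipeline runs:

1. **Normalisation** — removal of taxa with fewer than 4 total reads,
   rarefaction of every sample to a common depth (single draw, without
   replacement).
2. **Alpha diversity** — richness, Shannon (*H = −Σ pᵢ ln pᵢ*),
   bias-corrected Chao1 (*S₁ = S_obs + F₁(F₁−1)/(2(F₂+1))*), root-inclusive
   Faith PD, rarefaction curves, and compact-letter group comparisons.
3. **Community structure** — Bray–Curtis (*d = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)*) with
   nMDS (Kruskal stress-1), unweighted UniFrac (unique / total branch
   length) with PCoA, ANOSIM (*R = (r̄_between − r̄_within)/(M/2)*), Mantel
   tests against environmental covariates, SIMPER decomposition and
   shared-taxon (Venn) counts.
4. **Assembly partition** — the two-stage null-model framework: weighted
   βMNTD with a taxon-shuffling null gives βNTI = (βMNTD_obs − μ_null)/σ_null;
   pairs with |βNTI| > 2 are heterogeneous (+) or homogeneous (−) selection;
   the rest are classified by the Bray–Curtis Raup–Crick metric
   RC = 2·P(null < obs) − 1 into dispersal limitation (RC > 0.95),
   homogenizing dispersal (RC < −0.95) or ecological drift.

A synthetic metacommunity generator (`scenario_config()` /
`assemble_samples()`) produces two-habitat, three-size-fraction datasets
under known regimes (selection, dispersal limitation, neutral drift, or a
mixed SW-dispersal / MP-drift contrast) with ground truth, so the whole
stack is verifiable without sequencing data.

## Worked example

```r
library(pondassembly)

cfg <- scenario_config(regime = "mixed", seed = 1)   # SW dispersal-limited, MP neutral
sim <- assemble_samples(cfg)
res <- run_analysis(sim$table, sim$tree, sim$metadata,
                    n_null = 499, n_permutations = 999, seed = 8,
                    verbose = FALSE)
print(res)
```

```
pondassembly analysis: 100 taxa x 16 samples (rarefied to 4896 reads)
  ANOSIM habitat: R = 0.1429, p = 0.017
  nMDS stress: 8.75e-05
  Mantel: strongest covariate salinity (r^2 = 0.126)
  Shared taxa: 100 of 100
  Assembly partition (within groups):
  group heterogeneous_selection homogeneous_selection dispersal_limitation
1    MP                   0.000                     0                0.000
2    SW                   0.167                     0                0.833
  homogenizing_dispersal drift n_pairs n_excluded
1                      0     1      28          0
2                      0     0      24          4
```

Reading the partition: within sea water, 83% of sample pairs show more
compositional turnover than the Raup–Crick null allows — dispersal
limitation dominates; within melt ponds every pair sits inside the null
envelope — drift dominates. (The habitat ANOSIM is weak here by design: in
the `mixed` scenario both habitats draw from the same species pool, so they
differ in *process*, not in average composition.) That is exactly the contrast the `mixed`
scenario generates, recovered from counts alone. `plot(res$assembly$MP)`
draws the partition; `res$assembly_pair_stats` holds the per-pair βMNTD,
βNTI, Bray–Curtis and RC values; with `output_dir =` every stage lands on
disk as TSV plus a `manifest.json` recording seed and parameters.

Individual stages are plain functions returning classed S3 objects —
`rarefy()`, `alpha_table()`, `bray_curtis()`, `unweighted_unifrac()`,
`nmds()`, `pcoa()`, `anosim()`, `mantel()`, `simper()`, `shared_taxa()`,
`beta_nti()`, `raup_crick_bray()`, `community_assembly()` — each with
`print`/`summary`/`plot`/`coef` methods where they make sense.

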