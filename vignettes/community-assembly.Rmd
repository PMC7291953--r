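---
title: "Partitioning community assembly processes from amplicon count tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community assembly processes from amplicon count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondassembly)
```

## The question the package answers

Size-fractionated amplicon surveys of microbial eukaryotes in contrasting
habitats — for instance Arctic melt ponds (MP) versus the surface sea water
(SW) they form on — routinely ask two questions: *do the habitats harbor
distinct communities?* and, if so, *which ecological processes assemble
them?* The first is answered with dissimilarity-based ordination and
permutation tests; the second with a two-stage null-model framework that
partitions pairwise community turnover into five processes: heterogeneous
selection, homogeneous selection, dispersal limitation, homogenizing
dispersal, and ecological drift.

`pondassembly` implements the full path from a ZOTU (zero-radius OTU) count
table, a rooted phylogeny of the ZOTUs, and sample metadata to that
partition, together with a synthetic metacommunity generator whose ground
truth makes every stage testable.

## The model

### Stage 1: phylogenetic turnover and selection

For two communities $A$ and $B$ with relative abundances $f$, the weighted
beta mean nearest taxon distance is

$$\beta\mathrm{MNTD} = \frac12\Bigl[\sum_{i \in A} f_{iA}\,
\min_{j \in B} d(i,j) + \sum_{j \in B} f_{jB}\, \min_{i \in A}
d(i,j)\Bigr],$$

where $d$ is the patristic (tip-to-tip branch length) distance. Conspecifics
count: a taxon present in both communities contributes a nearest-taxon
distance of zero, so identical communities score exactly 0.

The null model shuffles taxon identities across the tips of the whole
metacommunity phylogeny — one joint permutation of the patristic matrix per
randomization, shared by every sample pair in that randomization (999
randomizations by default). The beta nearest taxon index is the standardized
effect size

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} -
\overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

$\beta\mathrm{NTI} > +2$ is read as heterogeneous selection (environments
push the pair apart more than chance allows), $\beta\mathrm{NTI} < -2$ as
homogeneous selection. The $\pm 2$ cutoff is the conventional two-standard-
deviation rule of this framework; it is a `bnti_threshold` argument, never a
hard-coded constant. When a pair's null distribution is degenerate (all taxa
mutually equidistant, or both samples supported on exactly the same taxa)
the standard deviation is zero, $\beta$NTI is recorded as `NA` with a
warning, and the pair is excluded from (and counted next to) the partition.

### Stage 2: compositional turnover without selection signal

Pairs with $|\beta\mathrm{NTI}| \le 2$ are passed to the Bray–Curtis based
Raup–Crick metric. Each null replicate reassembles both communities from the
metacommunity: a community that observed $S$ taxa and $N$ reads draws $S$
distinct taxa with probability proportional to occurrence frequency (the
number of samples containing the taxon), then distributes $N$ reads among
the drawn taxa multinomially with probability proportional to metacommunity
relative abundance. With $B_{obs}$ the observed Bray–Curtis value and
$B_{null}^{(r)}$ the replicates,

$$RC = 2\,\frac{\#\{B_{null} < B_{obs}\} + \tfrac12 \#\{B_{null} =
B_{obs}\}}{n_{null}} - 1 \in [-1, 1].$$

$RC > +0.95$: more turnover than the stochastic expectation — dispersal
limitation; $RC < -0.95$: less — homogenizing dispersal; otherwise the pair
is attributed to drift. Ties use an absolute tolerance of $10^{-12}$ on the
Bray–Curtis values. RC is computed on rarefied integer counts so that the
richness and read-total conditioning is comparable across samples.

### Surrounding statistics

Alpha diversity (observed richness, Shannon in natural log by default,
bias-corrected Chao1 $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, root-inclusive Faith
PD), Bray–Curtis and unweighted UniFrac dissimilarities, nMDS (Kruskal
stress-1, monotone regression with primary tie treatment, best of a PCoA
start plus random starts) and PCoA ordination, ANOSIM, Mantel tests, SIMPER,
and shared-taxon (Venn) counts follow their standard definitions; standard
computations are delegated to `vegan`, `ape` and `picante` where those
packages provide them, while ANOSIM, Mantel, SIMPER and UniFrac are
implemented in-package so that exact exhaustive-enumeration p-values and the
decomposition identity (SIMPER contributions sum *exactly* to the mean
between-group Bray–Curtis) are available; the library implementations then
serve as independent cross-checks in the test suite.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_total_count` | 4 | taxa with fewer total reads are removed (denoising-artefact guard) |
| rarefaction `depth` | min sample total | single draw, without replacement (multivariate hypergeometric) |
| `n_null` | 999 | randomizations for both null models (independently configurable) |
| `n_permutations` | 9999 | ANOSIM / Mantel permutations, $p = (k+1)/(n+1)$ |
| `bnti_threshold` | 2 | selection cutoff on the standardized effect size |
| `rc_threshold` | 0.95 | dispersal cutoff on the Raup–Crick scale |

Open conventions are exposed as flags with documented defaults: the Shannon
log base (`base`, natural log by default), the Faith PD root convention
(`include_root = TRUE`, the dominant convention), and single-draw versus
repeated rarefaction (single draw; `rarefaction_curve()` provides the
repeated-draw view when needed).

## Reproducibility and random-number discipline

Every stochastic stage takes one integer seed and derives per-stage,
per-pair streams from it with a fixed affine splitting rule. For RC-bray
each *unordered* sample pair owns its stream, so results are invariant to
pair iteration order and to restricting the computation to a subset of pairs
— `stats(A,B) = stats(B,A)` holds exactly. (Splitting per pair rather than
per pair-and-replicate keeps the same order-invariance while avoiding half a
million re-seedings.) The $\beta$MNTD null permutations form one stream
shared by all pairs, as the model requires. Two runs of `run_analysis()`
with the same inputs and seed write byte-identical TSV artifacts; this is
asserted in the test suite.

The $\beta$MNTD observed-plus-null sweep is the computational core and is
implemented in C++ (the per-pair cost is a dense min-reduction over the
patristic submatrix, repeated for every randomization), as is the RC-bray
null assembler, which draws weighted samples without replacement via
exponential keys — equivalent in distribution to sequential weighted
sampling.

## What the synthetic generator emulates

`scenario_config()` fixes a two-habitat (MP/SW), three-size-fraction
metacommunity: a Yule phylogeny, lognormal pool abundances, a
phylogenetically conserved habitat-preference trait evolved by Brownian
motion, Poisson sequencing depths (mean 5,000), and a salinity covariate at
the habitat means (SW ≈ 29, closed melt ponds ≈ 2.5) plus noise. Regimes:

* **selection** — Gaussian niche filter
  $w_{is} \propto m_i\,e^{-(t_i - e_s)^2 / 2\sigma_w^2}$ with distinct
  habitat optima ($\pm 2$ by default, niche breadth $\sigma_w = 0.5$,
  Brownian rate 1). The minimal selection model with a tunable strength.
* **dispersal_limited** — samples fall into spatial clusters (2 samples per
  cluster by default); each cluster draws neutrally from its own pool subset
  (25% of taxa). Subsets are dealt from whole-pool permutations so clusters
  within a habitat hold complementary taxon sets — the allopatric structure
  the Raup–Crick metric is designed to detect. Fully *independent* uniform
  subsets per sample would coincide generatively with the Raup–Crick null
  itself and are therefore undetectable by construction; the
  `cluster_size = 1` option exists but is documented as such.
* **neutral_drift** — every sample draws from the one shared pool after a
  per-sample lognormal wobble of the expected relative abundances
  (`drift_sigma = 0.15`). The wobble *is* the drift: exact multinomial
  replicates of one pool have *less* turnover than the richness- and
  occupancy-conditioned Raup–Crick null and are classified as homogenizing
  dispersal — which is the ecologically correct reading of perfect panmixia.
* **mixed** — SW samples dispersal-limited, MP samples neutral: the
  qualitative contrast expected between connected sea water and isolated
  melt ponds.

Defaults were chosen once so that each pure regime is recoverable as the
modal class of the partition at the default thresholds (the generator's
reason to exist), and so that magnitudes look like a plausible amplicon
survey: pool abundances span several orders of magnitude
(`lognormal_sigma = 1.5`), per-sample richness is well below pool richness,
and habitat salinity matches the measured ranges of the system the package
models. They are study conditions, not fitting knobs.

What the generator does **not** emulate: sequencing error, chimeras, PCR and
copy-number bias, compositional coupling between size fractions (fraction
labels are structural metadata without a generative effect), temporal
dynamics, and real phylogenetic signal strength. Passing tests therefore
demonstrate that the statistics detect the processes *under the generative
model's assumptions*, not that any particular field dataset is driven by
them.

## Numerical choices

* Bray–Curtis of all-zero samples is undefined; such samples are an error
  naming the sample, and rarefaction drops samples below depth with a
  warning rather than up-sampling.
* PCoA drops negative eigenvalues from the coordinates and reports them
  alongside the positive spectrum.
* nMDS ties are handled by Kruskal's primary approach; non-convergence
  within `max_iter` returns the best configuration with a warning.
* The five partition fractions are computed over classifiable pairs and sum
  to 1 to machine precision; excluded (degenerate-null) pairs are reported
  in `n_excluded`.
* Within-habitat partitions in `run_analysis()` use each habitat's own
  samples as the null metacommunity; the cross-habitat partition uses the
  pooled metacommunity. Pooling across habitats for a within-habitat
  question biases RC upward when the habitats differ strongly.

## Problem sizes used by the tests

The acceptance-style checks run 50 seeded scenarios per regime at 100 taxa,
8 samples per habitat, depth 5,000 and 499 randomizations; oracle
equivalence uses 50 random fixtures of at most 10 taxa and 6 samples;
calibration uses 1,000 neutral simulations at 199 permutations. These sizes
give stable Monte-Carlo margins for the asserted thresholds while keeping a
full run of the suite inside a coffee break on one core.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(regime = "mixed", seed = 1)
sim <- assemble_samples(cfg)
res <- run_analysis(sim$table, sim$tree, sim$metadata,
                    output_dir = "mixed_run", n_null = 499, seed = 1)
print(res)
plot(res$nmds, groups = res$metadata$habitat)
res$assembly_within
```

## Known limitations

* The Raup–Crick null conditions on observed richness and occurrence
  frequencies estimated from the analyzed table itself; with few samples
  those estimates are noisy and RC values are conservative.
* $\beta$NTI assumes phylogenetic signal in the traits under selection;
  selection on phylogenetically random traits will surface as drift or
  dispersal classes.
* The pipeline analyses one rarefaction draw (the survey convention it
  follows); repeated-draw averaging is available only for rarefaction
  curves.
* No per-clade (bin-wise) partition and no abundance-weighted Raup–Crick
  variants are provided.
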