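---
title: "pleioscan: models, design choices and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pleioscan: models, design choices and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

`pleioscan` asks whether candidate loci for local adaptation are unusually
*pleiotropic*, using network connectivity as a phenotype-free proxy for
pleiotropy.  The workflow has three legs:

1. **Find adaptive candidates** in transcriptome-derived SNPs: a
   PCA-differentiation scan and an environmental-association scan flag SNPs
   (and their host genes) whose allele frequencies track geography more
   strongly than the genome-wide background, and sweep statistics
   (θ~π~, θ~W~, Tajima's *D*, normalized Fay & Wu's *H*, a composite
   likelihood ratio against the transcriptome-wide SFS, Hudson's *F*~ST~ and
   *d*~XY~ between range edges) check that the candidates carry hitchhiking
   footprints rather than drift artifacts.
2. **Quantify connectivity**: all-pairs trans-eQTL mapping (which genes'
   SNPs predict other genes' expression) and a signed weighted co-expression
   network (soft-threshold adjacency at power 6, topological overlap,
   average-linkage modules, per-gene connectivity *k*).
3. **Integrate**: Fisher enrichments with bootstrap CIs, standardized
   regressions controlling for segregating sites *S*, expression level and
   variance, 10,000-replicate label-permutation fit tests, and a forward
   Wright–Fisher simulation of a pleiotropic QTL adapting to a displaced
   optimum, which probes *why* pleiotropic loci could be favored during a
   range expansion.

Real data at the scale such studies use (hundreds of thousands of SNPs from
dozens of individuals) are not shippable inside a package, so every stage is
driven by a seeded synthetic generator that plants known truth; the test
suite and `scripts/acceptance.R` measure how well each stage recovers it.

# The synthetic generator

`synth_config()` / `simulate_genotypes()` / `simulate_expression()` emulate
the statistical structure the analysis assumes.  Defaults describe 15
populations of 5 diploids along a 15-degree latitude transect, 2,000 genes
with geometric(mean 30) SNP counts, two ancestral clusters joined by a
logistic admixture gradient, and 5% adaptive genes.

* **Neutral sites** follow a hierarchical Balding–Nichols scheme: a global
  derived-allele frequency from the truncated neutral 1/p law, a per-cluster
  Beta draw with drift `fst_between_clusters` (0.05), and a per-population
  Beta draw with isolation-by-distance drift `ibd_slope` (0.002 per degree of
  latitude from the cluster centre).  Balding–Nichols keeps the generator
  dependency-free and analytically controllable; the neutral-SFS check is
  therefore approximate by design.
* **Adaptive genes**: about 20% of an adaptive gene's sites (at least one)
  are *clinal* — their population frequencies follow the classical sigmoid
  cline shape in latitude with displacement ±`clinal_shift` (0.3) at the
  transect ends, replacing neutral cluster drift (selection, not shared
  ancestry, drives their differentiation), starting from intermediate
  ancestral frequencies (spatially varying selection acts on common standing
  variation, and an intermediate start keeps the whole cline inside [0, 1]).
  The remaining sites are linked neutral sites to which `plant_sweep_sfs()`
  adds the hitchhiking footprint: with probability `1 − exp(−alpha)` a
  site's derived count is redrawn from the boundary-weighted kernel
  `1/(i(n−i))^2` (excess rare and high-frequency-derived variants) and
  reassigned with weights favoring the original carriers, so geography
  survives the spectrum distortion.  Sweeps are planted *locally* (in the
  range-edge populations that the sweep scan later analyses): selective
  sweeps at range edges are local events, and a locally planted footprint is
  what a subset-based scan can actually see.
* **Expression**: each of `n_modules` modules has a latent factor; hub genes
  load at 0.88–0.95, other genes at 0.25–0.7, adaptive genes at 0.65–0.85
  (the planted analogue of the centrality pattern the analysis is designed
  to detect).  Two population-structure axes with gene-varying loadings — a
  north–south gradient and a population-level ancestry factor — emulate the
  two leading expression PCs that the correction step removes; gene-varying
  loadings keep the two axes genuinely rank-two, so removing two PCs does
  not delete a module.  Trans-eQTL sources are adaptive genes with
  probability 0.40 and background genes with probability 0.10 (free design
  knobs chosen to give the desk-scale fixtures usable contrast); each source
  acts through its highest-MAF SNP on 1 + Poisson targets drawn from
  peripheral (non-adaptive, non-hub) genes, with effect ±1.5 per centered
  dosage unit and independent N(0, 0.5²) noise on every gene.
* **Couplings that make the headline patterns testable**: per-gene ancestral
  frequencies are pushed toward rarity in proportion to the gene's loading
  (a purifying-selection proxy — more connected genes carry less diversity),
  and read depth is simulated log-normally and independently of genotype so
  the coverage QC has a true null.
* The `truth` list records outlier genes, clinal sites, hub genes, loadings,
  module assignments, eQTL pairs and the environmental axes, and
  `write_fixture()` emits plain-text VCF/TSV/JSON that round-trip through
  the package readers.

What the generator does **not** emulate: linkage disequilibrium within
genes (sites are exchangeable given their frequencies), read-level noise,
allele-specific expression, cis-regulatory architecture, or the real
study's SNP scale.  Passing tests therefore show that the *methods* recover
*planted* structure of realistic shape and magnitude — not that any
particular biological dataset would yield the same coefficients.

# Variant filtering

`filter_spec()` mirrors a transcriptome SNP-filtering recipe: site quality
≥ 30, genotype quality ≥ 20 and read depth ≥ 6 (both applied as per-genotype
masks, as VCFtools does), heterozygosity < 80% of non-missing genotypes,
missingness < 20%, biallelic SNPs only, and minor allele frequency ≥ 0.05.
The MAF rule belongs to the *scan and eQTL* analyses only; diversity, SFS
and CLR statistics use the full filtered set (`maf_min = 0`), since an MAF
floor would amputate exactly the rare-variant classes those statistics
measure.  Site-level removals are attributed to the first failing rule in
the order quality → heterozygosity → missingness → MAF; a fraction threshold
of 1 disables its rule, so the weakest specification is the identity.

# Diversity and sweep statistics

Genes (transcript contigs) are the unit.  "Span" is the number of callable
sites considered, so θ values are comparable within a run but are not
absolute per-bp rates.  Missing genotypes are deleted pairwise
(site-specific haploid *n*); Tajima's *D* uses the 1989 variance constants
with the rounded mean site-*n*; normalized Fay & Wu's *H* standardizes
θ~π~ − θ~L~ by its neutral variance using Watterson's θ and the unbiased θ²
estimator.  *F*~ST~ is Hudson's estimator in the Bhatia ratio-of-averages
form, chosen for its documented small-sample behavior and isolated behind
the function boundary.

The CLR scan contrasts each gene's unfolded spectrum against the
dataset-wide background SFS.  At a candidate sweep position, a lineage at
distance *d* escapes the sweep with probability `1 − exp(−d/alpha)`, where
`alpha` is the sweep footprint length in bp: larger `alpha` means a
stronger/wider sweep, and `alpha → 0` recovers the background exactly, so
the likelihood ratio is never negative.  Escaped lineages keep a
hypergeometric draw from the background class (at full escape this
reproduces the sample spectrum *exactly*, which makes the nested-limit test
sharp); trapped lineages inherit the sweeping haplotype's allele.  Spectra
are conditioned on polymorphism — invariant-class handling is off because
transcript data lack reliable invariant counts.  The per-gene grid tests
every variable site as the sweep position and 20 log-spaced `alpha` values
chosen so the escape probability at the gene's half-width spans
(0.01, 0.99); ties resolve toward the smallest (weakest, most conservative)
`alpha`.  Escape probabilities are rounded to two significant digits and the
transformed spectra cached, which bounds the cost at O(n³) per distinct
probability.  Distances run along the transcript coordinate, which
understates genomic recombination distance — a stated limitation.

# Selection scans

The PCA-differentiation scan regresses each scaled dosage on K = 4
genotype-PC score vectors, takes the per-axis z-scores, and ranks SNPs by
the robust (median-centered) Mahalanobis distance, rescaled by the genomic
inflation factor λ = median(D)/median(χ²~K~) and referred to χ²~K~.  The
median-based λ is the operative robustness device (no MCD covariance).

The environmental-association scan is a *declared approximation* of ridge
latent-factor mixed models: per SNP and per environmental axis, the linear
model dosage ~ env axis + K latent covariates, where the latent covariates
are genotype PCs orthogonalized against the environmental axes.  The
orthogonalization implements the identifiability convention that structure
collinear with the environment is attributed to the environment — without
it, the latent PCs absorb exactly the latitudinal signal the scan exists to
find.  Per-axis p-values come from the t reference after λ rescaling (exact
under the null); q-values are computed over the pooled (SNP × axis) test
set, because flagging each SNP on its best of four axes with per-axis
q-values would leak FDR by a factor of up to the number of axes.  A SNP's
reported p is its best-axis p — a minimum over axes — so null-uniformity is
a per-axis property, and the calibration tests use single-axis scans.

Storey q-values estimate π₀ on the λ-grid 0.05…0.95 with a cubic smoothing
spline evaluated at the largest grid point; with fewer than 100 p-values the
spline is unstable and π₀ is fixed at 1 (Benjamini–Hochberg behavior).

**Known calibration limit.**  On structured fixtures the Balding–Nichols
background has heavier-than-χ² tails (the rare-frequency drift is strongly
skewed) and part of the drift is genuinely latitude-correlated, so a small
excess of background SNPs crosses q < 0.05 when strong planted signal pulls
π₀ down; the acceptance script reports the resulting empirical FDR
(`empirical_fdr_*`).  On exchangeable null fixtures both scans are fully
calibrated (λ ∈ [0.8, 1.2], uniform p).

# eQTL mapping and the network

`map_eqtl()` tests every SNP × gene pair by streaming SNP blocks with both
sides projected out of the covariate space (exact algebra — the t statistic
equals the full-regression one), pooling Storey q over all tests.
Covariates are the K = 4 admixture proportions with one simplex column
dropped; expression is first residualized on its two leading PCs.  Self
pairs (a SNP against its host gene) are tested by default because transcript
SNPs are coding; `drop_self_pairs` exposes the other counting.  Genes
carrying significant SNPs are eQTLs; their targets are eGenes; the
eGenes-per-eQTL model codes single vs multiple targets and fits a logistic
regression on outlier status with S as covariate, with a Firth-penalized
(Jeffreys-prior) fallback on separation.

The network is the signed WGCNA construction: adjacency
`((1 + cor)/2)^6`, connectivity as diagonal-free row sums, the standard
topological overlap matrix, and average-linkage clustering of 1 − TOM cut at
a merge-height quantile (0.99) with a 30-gene minimum size.  The dynamic
tree cut is deliberately replaced by this static cut: the downstream results
consume only module membership and connectivity, and connectivity is
cut-independent.  Power 6 is taken as given, not re-selected.

**Hub "rank recovery"** is summarized as the Mann–Whitney AUC — the
probability that a planted hub outranks a non-hub in connectivity.  The
Spearman correlation between connectivity and the full loading vector is
also reported, but at 75 individuals it is bounded near 0.85 by irreducible
sampling noise in realized loadings (and pushing noise down does not help:
with little noise *all* in-module correlations saturate and loadings stop
mattering), so the AUC is the informative recovery statistic.

# Integration statistics

Enrichments use two-sided Fisher exact tests with conditional-MLE odds
ratios; percentages carry 95% percentile-bootstrap CIs over genes.  The
regression-permutation test fits stat ~ S + outlier, shuffles only the
labels, and reports the add-one p-value (never exactly zero).  Table-style
diversity ~ connectivity + level + variance models standardize response and
predictors (the implied scale of comparable coefficient magnitudes) and are
run separately for outlier and background subsets.  The connectivity–p-value
trend is summarized by a penalized-spline fit (`mgcv::gam`), the CI of the
linear slope (flat-trend detection), and an interior-mode flag: a fitted
value that rises above or dips below *both* curve endpoints by more than
max(0.1 SD, 5% of the fitted range).

# The forward simulation

`run_replicate()` implements discrete-generation Wright–Fisher dynamics for
a 50 kb region with a 10 kb central genic core (N = 10,000 diploids,
μ = 1.5e−8, r = 5e−8 per site per generation, 10N burn-in).  Mutations are
infinite-sites at continuous positions; transmission draws one parent per
gamete (fitness-proportional after selection onset), Poisson(rL) crossovers
and Poisson(2NLμ) new mutations per generation.  Burn-in mutations are
permanently neutral — only mutations arising after selection onset can be
QTL mutations (10% genic, 1% elsewhere), which also guarantees the
phenotype's initial value of 0.  Each QTL mutation draws an effect vector
over all `n_phen` phenotypes from a multivariate Gaussian with sd 1 and
pairwise covariance 0.1 (0 in the covariance-free variant); phenotypes are
additive over mutation copies; fitness is the doubly-damped Gaussian
`exp(−½ Σ (z_i − z0)² / (2 Vs))` with Vs = 10 (a `standard` singly-damped
form is available for sensitivity analysis).  Selection weights are
computed with a shift so they survive underflow.  The core is compiled
(Rcpp) with a pure-R reference engine kept for cross-checking; both use R's
RNG, so replicates are seed-reproducible.

**Desk scaling.**  The scaled configuration uses N = 200, L = 5 kb and
rates ×50, which preserves the per-site population-scaled rates 4Nμ and
4Nr, with the 10N burn-in (equilibrium diversity scales with N).  The
selection phase is kept at 10,000 generations — the length that preserves
the full-scale protocol's *total mutational opportunity* (15,000 expected
mutations) — because selection coefficients and effect sizes are
deliberately not rescaled, and a phase shortened in proportion to N leaves
most replicates without a single QTL mutation, which makes the reference
class degenerate (IQR exactly 0).

**Normalization and the two trends.**  `run_grid()` summarizes each
(n_phen, z0) class by medians and IQRs and normalizes against the
non-pleiotropic class of the same optimum (subtract its median, divide by
its IQR), so that class sits at exactly 0 with IQR exactly 1.  Two
statistics are normalized: the recorded population **mean fitness**, and
the **log mean-fitness gain** relative to the unadapted phenotype,
`log w̄ − log w(z = 0)`.  The distinction matters: classes with different
`n_phen` start `exp(−n z0²/(4Vs))` apart — at z0 = 10 and n = 20 that is
e⁻⁵⁰ — and since no class can exceed fitness 1 while the single-trait class
adapts essentially to the optimum, the raw-fitness trend across `n_phen` is
negative at every optimum for a purely arithmetic reason.  The adaptive
*benefit* of pleiotropy far from the optimum lives on the gain scale, where
each class is measured against its own starting point; the near-optimum
*cost* of pleiotropy appears directly on the raw scale.  `run_grid` reports
both, and the acceptance script emits both trends
(`fitness_trend_*`, `fitness_gain_trend_*`).

# Problem sizes used by the tests and the acceptance script

Chosen as the package's desk-scale study conditions: the scaled grid runs
n ∈ {1, 5, 10, 20} × z0 ∈ {1, 10} with 30 replicates per class (12 for the
extra master seeds of the direction-consistency checks and the
covariance-free variant); the end-to-end pipeline uses 1,500 genes with
geometric(mean 10) SNP counts and 4 modules; calibration fixtures use
150–600 genes; null permutation calibration uses 200 runs of 200
permutations.  The full-scale simulation parameters remain the defaults of
`sim_config()` and are supported, just not exercised by the routine tests.

# Known limitations

* The generator's sites are exchangeable within a gene given their
  frequencies — no within-gene LD — so the CLR's positional grid is
  exercised, but its spatial decay is not informative about real maps.
* The environmental scan is a latent-factor approximation, not a ridge
  mixed model; its power against signals collinear with unmodeled structure
  differs from the exact algorithm's.
* Genome-scan q-values inherit the heavy drift tail of the structured
  background (see the calibration note above).
* The eGene census misses cis-regulation in intergenic space by
  construction, as any transcript-only design does.
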