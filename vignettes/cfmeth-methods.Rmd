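---
title: "Models and methods behind cfmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmeth)
```

`cfmeth` analyzes whole-genome bisulfite methylomes of cell-free DNA
(cfDNA): mixed DNA shed into plasma mostly by blood cells, with a minor
tumor-derived fraction in cancer patients. This vignette is the package's
account of the underlying models, the parameters that matter, the design
decisions that were genuinely open, and what the synthetic-data validation
does and does not establish.

## The mixture model of plasma methylation

Every quantity in the package rests on one generative picture. A plasma
sample is a mixture over cell types $t = 1, \dots, T$ with proportions
$w$ on the simplex. At CpG site $j$, a molecule from type $t$ is
methylated with probability $M_{jt}$ (the reference methylome), so the
sample's true methylation probability is the linear blend
$p_j = \sum_t w_t M_{jt}$. Bisulfite conversion is imperfect in both
directions: with probability $\varepsilon_+$ an unmethylated cytosine
reads methylated (conversion failure) and with probability
$\varepsilon_-$ a methylated cytosine reads unmethylated
(over-conversion), giving the observed per-read probability

$$p^{obs}_j = p_j (1 - \varepsilon_-) + (1 - p_j)\, \varepsilon_+ .$$

Since non-CpG (CHG/CHH) methylation is essentially absent in human
tissue, the apparent non-CpG level estimates $\varepsilon_+$ directly;
the package's QC and the acceptance script both use this identity.

In cancer samples a tumor fraction $f$ replaces an equal share of every
component with the tumor type: $w^{eff} = (1-f)\,w + f\,e_{tumor}$.
Methylation aberrations (the planted DMRs of the simulator) shift the
*tumor component's* methylation only, so the observed case-minus-control
difference of a DMR is its delta times the mean tumor weight — the
dilution that makes cfDNA methylation analysis hard, reproduced by
construction.

## Synthetic cohorts: what is emulated, and what is not

`simulation_config()` / `simulate_cohort()` generate per-sample call
files, 100-kb bin counts and a serialized ground truth. The defaults are
the study conditions the package targets: a colorectal-cancer-versus-
healthy plasma design of 50 cases and 34 controls; neutrophil-dominated
mixtures (Dirichlet concentrations `c(30, 8, 6, 5, 4, 2)` over
neutrophil/monocyte/CD4 T/CD8 T/B cell/colon for controls, with a lower
neutrophil and higher CD4 share in cases, matching the direction of
reported cfDNA composition shifts in cancer); tumor fractions drawn
uniformly on 0.05–0.3 (cfDNA tumor content is rarely quantified per
sample; this range spans typical detectable disease and is exposed as a
free parameter rather than fitted); mean coverage 30 reads per CpG;
conversion failure 0.008 and over-conversion 0.005, the sub-1% regime of
well-converted libraries as judged by non-CpG levels. The toy genome
(two 5-Mb chromosomes at 1 CpG/kb by default, scaled down further in
tests) keeps full-cohort simulation in seconds; all genomic coordinates
are real in structure (chromosomes, tiling, midpoint assignment), only
shorter.

Coverage is Poisson, not negative binomial: linear (in-vitro
transcription) amplification copies each template independently, so the
overdispersion that PCR compounding produces is deliberately absent from
the default model. The amplification simulator makes this explicit:
linear mode draws copies per molecule as $1 + \text{Poisson}(\mu - 1)$,
exponential mode as $\exp(\mathcal{N}(\log \mu, \sigma))$ — a
heavier-tailed copy distribution at matched mean — and reads sample
molecules proportionally to copy number. The duplication gap between the
two modes is a distributional consequence (collision probability grows
with copy-number inequality), which the test suite verifies by a paired
one-sided Wilcoxon test over 200 replicates.

Per-read simulation uses the binomial equivalence: drawing each read's
source type and methylation state and then flipping by the error rates is
distributionally identical to `rbinom(coverage, p_obs)`, which is what
the generator computes.

Not emulated: fragment-length biology, alignment and mapping artifacts,
read-level sequences, GC-coverage coupling, between-individual reference
variation, and batch effects. Passing tests therefore demonstrate
correctness of the *computations* under the stated generative model, not
robustness to every property of real plasma libraries.

## Region summarization and differential methylation

Region levels are pooled counts: the level of a region is
$\sum_j m_j / \sum_j (m_j + u_j)$ over contained CpGs — the
coverage-weighted mean of site proportions. The weighted (pooled) rather
than unweighted mean was chosen because it is the maximum-likelihood
estimator under binomial sampling and degrades gracefully at low
coverage. Windows default to non-overlapping 3-kb tiles; a sliding step
smaller than the size is supported but the default reading of
genome-wide "windows" is tiles, since downstream tests assume one value
per genomic position. Promoters are TSS &pm; 1 kb, strand recorded but not
used for the interval.

DMR testing pools counts within each group across replicates and applies
the two-sided Fisher exact test per region, then Benjamini–Hochberg.
Pooling ignores between-replicate overdispersion — a documented
limitation shared with the common practice for small cohorts; a
per-sample logistic/beta-binomial test is out of scope. BH was chosen
over less standard q-value estimators because it is conservative,
assumption-light, and exactly testable. Cutoff semantics are kept
distinct: the genome-wide window preset requires a difference *strictly
greater* than 0.15, the promoter preset *at least* 0.12, matching the two
conventions these thresholds are usually quoted with.

## Copy number

Bin counts (100-kb tiles, fragments assigned by midpoint so
boundary-spanning fragments count once) are compared against a *pooled*
panel of normals: all control counts summed, reference proportion
$\pi_b$ = pooled count / pooled total. Pooling (rather than a per-bin
median across normals) follows the synthetic-control construction the
package models and keeps the reference well-defined with as little as one
normal. The copy ratio is $\log_2((c_b/N)/\pi_b)$ with a 0.5-read
pseudocount for empty sample bins (keeping the track dense for PCA
features), missing only where the panel itself is empty. Because both
numerator and denominator are normalized proportions, ratios are exactly
scale-invariant in the sample's total count, and a sample measured
against its own single-sample panel is identically zero — both are unit
tests.

Under the generator, a segment of copy number $c$ at tumor fraction $f$
has expected relative weight $1 + f(c/2 - 1)$; after total-count
normalization the expected log ratio is $\log_2$ of that weight divided
by the genome-wide mean weight. Segmentation is recursive binary
splitting on the maximal two-sample t-statistic, stopping when the best
split's $|t|$ falls below `t_crit` (default 5, conservative enough that a
flat 1000-bin track stays unsegmented) or a child would drop below
`min_bins` (default 10; reduce it for toy genomes with few bins per
chromosome). Binary segmentation was chosen as the simplest defensible
changepoint method; the classifier consumes bin-level ratios, which are
unaffected by this choice. The sample-level rule for declaring a whole
sample "CNA-positive" is left to the user — segment calls are exposed and
any count/fraction rule can be applied on top.

## Deconvolution

Reference CpG markers are individually sparse in low-pass cfDNA, so
marker sites are clustered into "mega sites": hierarchical clustering of
sites on their cell-type profiles, dendrogram cut into `k_groups = 32`
groups, singletons removed, member sites pooled at the read level.
Euclidean distance with complete linkage is the default (the clustering
metric behind a dendrogram cut is rarely stated; both are configurable),
and aggregated reference values are unweighted site means (read-weighted
aggregation is not identifiable from a reference matrix alone).
Aggregation commutes with pooling: the mega-site level of a sample equals
the pooled level over the union of member sites — a tested invariant.

Missing mega sites are imputed by k-NN (k = 10, the conventional default
of the widely used implementation): feature distance is root-mean-square
over jointly observed samples, and the imputed value is the mean of the
k nearest features within the same sample, falling back to the sample
mean. Proportions are then estimated by simplex-constrained least
squares. Instead of the support-vector-regression variant common in
expression deconvolution (whose hyperparameters are rarely reported and
whose solution is not deterministic), the package solves the exact
quadratic program by enumerating active sets: for every support subset an
equality-constrained least-squares problem is solved through the KKT
system (SVD pseudoinverse, so collinear references warn rather than
fail), and the feasible solution with minimal residual is the global
optimum. With at most 14 cell types the enumeration is exact and
microseconds-fast, and it agrees with an iteratively refined simplex grid
search to $10^{-3}$ in the tests. Group differences use the exact
Wilcoxon rank-sum test (normal approximation with tie correction beyond
n = 25 per group) or Welch's t-test.

## Classification

Three feature blocks per sample — window/TSS methylation levels, bin
log2 copy ratios, estimated cell proportions — are combined after
train-only preprocessing: center/scale statistics and PCA loadings are
fitted on training samples and applied unchanged to the test set
(asserted by recomputation in the tests), PCA keeps the minimal prefix of
components reaching 95% cumulative variance with a fixed sign convention,
and one cell type is dropped from the proportions block because the
simplex constraint makes one column exactly redundant. The cohort is
split 1:3 train:test by stratified largest-remainder allocation (the
quoted "1:3 ratio" is read as train:test; the opposite direction is one
configuration flag away, since the source phrasing of such splits is
often ambiguous). Random forest (500 trees, mtry grid) and radial SVM
(cost &times; gamma grid) are tuned by stratified 5-fold cross-validation
maximizing AUC and refitted on the full training set. AUC is the
Mann–Whitney statistic with midrank ties; importance is model-agnostic
permutation importance (mean AUC drop over column permutations), chosen
so the forest and the SVM are ranked on the same scale.

The validation claim is deliberately ordinal: over repeated synthetic
cohorts of 42 cases and 42 controls carrying methylation, copy-number and
composition effects simultaneously, the integrated model's held-out AUC
should not fall below the methylation-only model's on average, and
permuted labels should land in the 95% null band around 0.5. Absolute
AUCs on synthetic cohorts say nothing about clinical performance.

## Numerical choices and degenerate inputs

- Zero-coverage regions, uncovered markers and masked bins propagate as
  `NA`, never as 0; downstream stages drop or impute them explicitly.
- Fisher's test on a region with an empty group returns `NA`; BH
  adjustment passes missing values through untouched.
- Zero-variance features standardize to 0 via a scale-1 guard; PCA caps
  the component count at the matrix rank.
- Deconvolution tolerates rank-deficient references with a warning and
  needs at least two usable features; tiny negative weights from the KKT
  solve are clipped at $-10^{-9}$ and renormalized.
- All stochastic code paths take explicit integer seeds; per-stage seeds
  derive from the global seed by a stable string hash kept in 32-bit
  range, so pipeline reruns are bit-identical (manifests record content
  hashes to prove it).

## Validation problem sizes

The shipped tests and the acceptance script size their simulations for
desk-scale runtimes while keeping each check statistically meaningful:
oracle comparisons on hundreds of random instances; DMR recovery at 200
regions &times; 20 replicates (5v5 samples, 30&times; over three-site
regions, planted &Delta; = 0.4); copy-number recovery on a 100-Mb,
1000-bin genome at $10^6$ reads (copy 3, tumor fraction 0.4, expected
segment ratio $\log_2 1.2$ after normalization); deconvolution at 6
types and ~26–32 mega sites with $\sigma = 0.01$ noise over 100
replicates plus a 10&times;/50&times;/200&times; coverage ladder; classifier
ordering over 20 cohorts of 84 samples on two 1.5-Mb chromosomes; and
200-replicate amplification comparisons. These sizes are the package's
own validation design; scaling any of them up only sharpens the same
checks.

## Known limitations

Pooled-count DMR testing ignores biological replicate variance; copy
ratios assume a diploid-dominant background and report no absolute copy
number or purity; deconvolution accuracy is bounded by the reference
atlas (real marker atlases are inputs, not deliverables, and synthetic
atlases are cleaner than curated ones); the classifier's synthetic
validation cannot certify real-cohort discrimination; and the simulator's
independence assumptions (Poisson coverage, independent sites) understate
the correlation structure of real bisulfite data.
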