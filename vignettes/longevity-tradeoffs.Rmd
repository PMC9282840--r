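---
title: "Methods: PRS trade-off analysis between complex diseases and longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS trade-off analysis between complex diseases and longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
conventions each stage implements, the parameters that matter, what the
synthetic-cohort generator does and does not emulate, and the design choices
made where more than one reasonable convention exists.

## 1. The analysis in one paragraph

A polygenic risk score (PRS) summarizes a GWAS into a per-individual scalar:
a weighted average of counted-allele dosages, weights taken from the GWAS
effect sizes. Regressing a disease PRS on a binary longevity phenotype
(long-lived cases versus middle-aged controls) asks whether the genetic risk
of that disease is depleted or enriched in people who survive to extreme
age. The package implements the full chain — summary-statistic
harmonization, SNP QC, LD clumping and p-value thresholding with
model-selected thresholds, logistic association with Nagelkerke pseudo-R²,
multiple-testing control — and then the dissection layers that make
trade-offs visible: PRSs restricted to annotation sets (cell types and
cell-type groups), PRSs restricted to GWAS significance bins, PRSs with a
candidate region masked out, per-SNP effect-direction panels, and a
multi-PRS classifier of longevity.

## 2. PRS scoring conventions

The score is `PRS_j = sum_i(S_i * G_ij) / M_j`. Two conventions needed
fixing:

* **The denominator.** "Number of alleles included" is read as counting
  both chromosomes: `M_j = 2 x (non-missing SNPs for j)`, the per-allele
  averaging convention of common PRS software. Because the factor is
  constant across individuals scored on the same SNP set (absent
  missingness), it cancels in regression p-values; `mj_mode = "snps"`
  offers the per-SNP denominator for users who prefer it.
* **Missing genotypes** drop out of both the numerator and `M_j` — no mean
  imputation. An individual with no non-missing SNP in the set gets an `NA`
  score rather than a silent zero.

Scores are z-standardized before the logistic fit so coefficients are per
SD of PRS and comparable across traits; standardization does not change
p-values.

## 3. Clumping and the threshold ladder

Clumping visits SNPs by ascending GWAS p (ties broken by chromosome, then
position, making the result independent of input row order). Each
unassigned SNP becomes an index and absorbs unassigned SNPs with r² > 0.1
within ±500 kb. The window is read as a half-width around the index — the
common convention when only "a window of 500 kb" is stated. LD always comes
from the target genotypes, not a reference panel.

The threshold ladder runs from genome-wide significance upward by an order
of magnitude, with the endpoint 1 appended: 5e-8, ..., 5e-1, 1. Best
thresholds such as 0.769 are only reachable with a dense scan, so
`default_ladder(fine = TRUE)` inserts a 5e-5-step grid; it is off by
default because it multiplies the scan cost by roughly 2000 for modest
information gain. Ties for the smallest association p go to the smallest
threshold (parsimony, and it makes the scan deterministic).

## 4. Harmonization rules

Each base-study row is aligned to the target's counted/other alleles with
four outcomes: direct match; swapped match (beta negated); complementary-
strand match (both alleles complemented, then the direct/swap rule); or
exclusion. Palindromic SNPs (A/T, C/G) are excluded by default — after
strand flipping they are indistinguishable from a swap, so their sign is
not identifiable without allele-frequency heuristics we deliberately avoid;
`keep_palindromic = TRUE` rescues them under a same-strand assumption.
SNP ids are the preferred join key, with chromosome+position as the
fallback when the id spaces are disjoint; conflicting duplicate ids are
dropped. Coordinate lift-over is out of scope: inputs must share the build
declared in the pipeline configuration. The harmonization report partitions
the input rows exactly, which the tests assert.

Risk orientation (`orient_to_risk()`) swaps alleles and negates beta for
rows with beta < 0, using the identity that the effect of one allele is
minus the effect of the other. It is idempotent and leaves |beta|, SE and p
untouched; panel classification requires it on the disease side so that
"positive longevity beta" means "the disease risk allele helps survival".

## 5. Association statistics

Logistic regression is fitted by maximum likelihood (IRLS with a tight
convergence tolerance); the Wald p is primary. Under complete separation
the Wald statistic degenerates, so the fit falls back to the
likelihood-ratio p with a warning. Variance explained is Nagelkerke's
pseudo-R² — the default of common PRS tools, hence comparable with
published PRS columns. No covariates enter by default (the PRS regressions
this package mirrors used none); a covariate matrix is accepted and then
enters both the null and full models.

FDR control is Benjamini-Hochberg. The stratified scans correct over a
*declared* family of `sets x traits` tests (e.g. 220 cell types x 16
traits = 3520); when only one trait's scan is in hand, the unobserved tests
are treated as occupying the top ranks, which is conservative and reduces
to plain BH when the family equals the observed count. A Bonferroni flag at
`alpha / family` is reported alongside.

The Hardy-Weinberg filter uses the exact conditional test (sum of
probabilities of heterozygote counts no more probable than observed, given
allele counts), with no mid-p correction — determinism and a simple
enumeration oracle were preferred over the mid-p's slightly better
calibration. HWE is evaluated in controls only when a phenotype is
supplied, since case enrichment at associated SNPs distorts genotype
proportions; the missingness and MAF filters use everyone. All SNP filters
are evaluated on the input matrix and the union of failures removed, so
filter order cannot change the surviving set. The default SNP missingness
cutoff is 0.05 (configurable); sample-level QC is assumed done upstream,
with an optional per-sample missingness flag.

## 6. Stratified scans, masking and LD blocks

Annotation sets are consumed as BED intervals (0-based half-open, converted
internally to 1-based inclusive) or as literal SNP-id lists; sets may
overlap, and group-level sets are unions of their members. Each set is
clumped *within itself* (not genome-wide followed by intersection): this
emulates set-based clumping-and-thresholding tools, whose sets would
otherwise lose their index SNPs to stronger SNPs outside the set. The
set-PRS threshold is fixed at p ≤ 1 — every set SNP surviving clumping
scores — because the stratification, not the thresholding, is the object of
interest; both choices are configurable.

Significance bins are `(0, 5e-8], (5e-8, 1e-7], ..., (1e-2, 5e-2]`; SNPs
above 0.05 never enter a bin. The bins partition the retained SNPs, which
is asserted in tests. Empty bins yield a skipped row rather than an error.

Region masking removes summary-statistic rows inside a 1-based,
endpoint-inclusive region (matching the coordinate style in which such
regions are printed); the bundled `apoe_region()` is
chr19:45,361,224-45,436,657. LD blocks use the D' confidence-interval rule:
a pair is in strong LD when the 90% CI of |D'| (5th/95th percentiles of the
grid-normalized likelihood, grid step 0.005, haplotype frequencies by
likelihood over the unphased 3x3 genotype table with allele frequencies at
their MLEs) has lower bound ≥ 0.70 and upper bound ≥ 0.98, in strong
recombination when the upper bound is < 0.90, and a span is a block when
≥ 95% of its informative pairs are strong. Maximal non-overlapping spans
are taken longest-first with leftmost tie-break, so the result is
deterministic.

## 7. Pleiotropy dissection

Starting from the *disease's* best-PRS SNP set (the anchoring choice when
disease and longevity best PRSs differ), SNPs nominally significant
(p < 0.05, configurable) in both the disease and the longevity summary
statistics are classified by the sign of the longevity beta expressed on
the disease risk allele: panel 1 (risk allele also increases the chance of
longevity) versus panel 2 (risk allele reduces it). Longevity rows reported
on swapped alleles are re-expressed on the disease allele; irreconcilable
allele pairs are an error, not a silent drop. Gene context comes from a
nearest-gene annotator over BED/GFF3 gene intervals — inside a gene gives
that gene at distance 0, otherwise both flanking genes are reported as
`NAME(dist = D)`. Gene-ontology enrichment is intentionally not
reimplemented; `export_panel_genes()` writes plain gene lists for external
enrichment tools.

## 8. The multi-PRS classifier

`model_selection_cv()` compares penalized logistic regression (L1/L2 over a
lambda grid), a linear-kernel SVM, k-nearest neighbours, naive Bayes, a
decision tree and a random forest, each behind a uniform fit/predict
interface — the module is deliberately thin glue around standard libraries,
since the features (the PRSs) are the pipeline's own contribution. Each
candidate runs through repeated stratified k-fold cross-validation
(defaults k = 10) with fold assignments re-randomized every iteration; the
selection metric is mean validation accuracy, with AUC reported alongside.
The winner is refitted on a stratified 80% split and evaluated on the
held-out 20%; both the folds and the final split are re-randomized under
the single seed, and an identical seed reproduces the report exactly. AUC
is computed with a fixed score orientation — letting the AUC routine choose
the favourable direction would bias permutation nulls upward. The reported
pseudo-R² is a calibration value: Nagelkerke R² of a logistic fit of the
held-out labels on the final model's standardized score (this reduces to
the usual model pseudo-R² when the winner is logistic, and remains defined
for families without a likelihood).

A practical note on permutation nulls: a *single* label permutation retains
its chance dataset-level association with the features (of the order of
R² ≈ p/n), which cross-validation faithfully rediscovers in every fold.
Null checks therefore re-permute labels across iterations and average.

## 9. The synthetic cohort: what it emulates, and what it does not

The generator exists so that every downstream stage has inputs with the
statistical structure the analysis assumes.

* **Genotypes** come from a Gaussian copula: per haplotype, a latent
  multivariate normal with AR(1) correlation `within_block_r` inside each
  block, thresholded at the normal quantile of the SNP's allele frequency;
  two haplotypes sum to a genotype. This gives exact Hardy-Weinberg
  proportions and tunable LD with one parameter. Thresholding attenuates
  the correlation: a latent r of 0.9 realizes a mean adjacent-SNP genotype
  r² of about 0.49 for MAFs of 0.3-0.4 (band frozen from a 20-replicate
  Monte-Carlo of the generator). Blocks are spaced 600 kb apart so a 500 kb
  clump window never bridges them.
* **Phenotypes** follow a liability-threshold model: liability is the
  planted per-allele longevity effects times dosage plus standard normal
  noise, and cases are the top `prevalence` fraction by the *empirical*
  liability quantile. Thresholding empirically (rather than at a
  theoretical quantile) mirrors a design that samples fixed numbers of
  long-lived cases and middle-aged controls, and makes the case fraction
  exact by construction; the default prevalence 0.5 gives the balanced
  case/control design.
* **Summary statistics** are simulated directly from planted effects:
  `beta_hat ~ Normal(beta_true, se)` with
  `se = 1 / sqrt(2 N maf (1 - maf))`, `p` the two-sided normal tail of
  `beta_hat / se`. No second cohort is actually GWASed — this is a
  deliberate desk-scale shortcut whose calibration is itself tested (null
  p-values are uniform by a KS check; a logistic refit recovers planted
  directions).

`tradeoff_architecture()` encodes the bidirectional significance gradient:
strong strata at z targets 6.2/6.5/6.9 (510 SNPs, longevity effect -0.3
per allele) and weak strata at z 2.9/2.65/2.4/2.1 (960 SNPs, +0.15). The z
targets and counts were derived from normal tail areas before any test was
run, under two constraints: every significance bin must be populated with
high probability (the (5e-8, 1e-7] bin is only 0.12 z-units wide, so
hundreds of strong SNPs are needed for its expected occupancy to clear
Poisson extinction), and the strata must sit far enough from the 1e-5
boundary (z = 4.42) that estimation noise (z noise has SD 1) cannot leak
enough opposite-effect SNPs across it to flip a boundary bin's direction.
A consequence worth stating plainly: with per-allele liability effects of
0.3 on 510 SNPs the planted heritability is far above anything realistic
for a human trait. The generator is a *mechanism* check — it demonstrates
that the pipeline recovers the direction structure it is pointed at — not a
calibrated model of human polygenic architecture. Passing these tests says
nothing about power at realistic effect sizes, population structure,
relatedness, imputation dosages, or the X chromosome, none of which are
emulated.

`annotation_architecture()` plants two annotation sets with a shared
positive disease effect and opposite longevity effects (±0.15 per allele,
60 SNPs each by default), the structure behind a trait whose cell-type
components disagree about survival.

## 10. Numerical and procedural choices

* `p = 0` in input summary statistics is clamped to the smallest positive
  double with a warning; downstream log-scale work never sees a zero.
* Every stochastic routine takes an explicit integer seed, and fixtures are
  reproduced bit-identically; the pipeline manifest records md5 hashes so
  reruns are verifiable.
* Degenerate inputs error early and namefully: empty SNP sets, constant
  phenotypes, monomorphic loci in D' computation, zero-variance genotype
  vectors in r², impossible heterozygote parities in the HWE test.
* Problem sizes in the tests and acceptance script — cohorts of 150-4000
  individuals, 320-1500 SNPs, 10-20 replicates, 400-1000 null simulations —
  were chosen as the smallest sizes at which the statistical checks have
  comfortable margins; they are package choices, not estimates of any real
  cohort.

## 11. Known limitations

Reference-panel LD, shrinkage/Bayesian PRS weights, genotype imputation,
lift-over, PCA stratification control, survival models, and GO enrichment
are out of scope. The set-based scan emulates the *behaviour* of set-based
clumping-and-thresholding tools (set-restricted clumping, threshold 1), not
any tool's exact defaults, which are not fully published. Real-cohort
headline numbers (best-PRS R² per trait, an AUC near 0.69 for all-PRS
prediction) depend on data that is not redistributable and are therefore
not reproduced here; what the package reproduces is the machinery and its
statistical behaviour under planted truth.
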