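---
title: "Whole-genome prediction and SNP heritability with wgpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome prediction and SNP heritability with wgpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgpred)
```

## The problem

Complex clinical traits — here, asthma-related phenotypes such as lung
function, IgE, bronchodilator response and longitudinal lung-growth
patterns — are polygenic: thousands of variants each contribute a small
effect. Single-marker association studies explain little of the observed
familial aggregation, but *whole-genome prediction* (WGP) sidesteps variant
selection entirely: all genotyped SNPs enter the model, agnostic to prior
association evidence. Two quantities anchor such an analysis. The
narrow-sense SNP heritability `h2` bounds how well any genetic predictor can
do; and the realized prediction accuracy, measured on held-out subjects,
shows how much of that bound a method attains at a given cohort size.

`wgpred` implements the full chain: genotype QC, genomic relatedness matrix
(GRM) construction with functional SNP weighting, GREML variance-component
estimation, G-BLUP/kriging prediction, and evaluation by permutation-tested
AUC — together with a synthetic cohort generator that provides ground truth
for every stage.

## The mixed model

The phenotype vector is modelled as

$$ y \sim N(X\beta,\; \sigma^2_g A + \sigma^2_e I), $$

where `A` is the GRM built from standardized dosages
$z_{ij} = (x_{ij} - 2p_i)/\sqrt{2 p_i (1-p_i)}$ and per-SNP weights $w_i$:
$A = Z \,\mathrm{diag}(w)\, Z^\top / \sum_i w_i$. Under uniform weights this
is the standard GRM whose diagonal averages 1 in a Hardy–Weinberg
population; the normalization by $\sum w$ keeps that convention under every
weighting scheme and makes `A` invariant to rescaling the weight vector.
Assumptions worth keeping in mind: additivity (no dominance or epistasis
terms), effects drawn independently of allele frequency *after*
standardization (the inverse-variance convention), and unrelated subjects —
`A` models distant genomic similarity, not pedigree structure.

### Weighting schemes

Functional priority scores in $[0, 0.12]$ (an eQTL/chromatin "regulatory"
component plus a minor-allele-frequency component) drive three schemes:

* **W1** — weight = total score; zero-score SNPs drop out of `A` entirely.
* **W2** — weight = regulatory component only.
* **NZW** — *subset* to SNPs with non-zero W1 weight, then standard
  inverse-variance weights on the subset.

By default scheme weights *replace* the uniform weight on the standardized
scale (the `1/(2p(1-p))` factor is always present); a `"conjunction"` mode
multiplies in a second inverse-variance factor for users who read the
weighting as acting on raw dosage differences. Replace is the default
because the NZW description ("standard inverse-variance weights" on the
retained set) only makes sense as a contrast to W1/W2 *replacing* them.

### GREML

`greml()` maximizes the restricted likelihood by average-information (AI)
updates, with an EM first step and three safeguards: step-halving when an AI
step would decrease the likelihood, EM fallback when the AI system is
singular, and a component floor of $10^{-6}\,\mathrm{var}(y)$. When a
component is pinned at the floor, the other is polished by a 1-D profile
search — without this, boundary fits stall short of the optimum by EM
crawling. Convergence is declared at $|\Delta \log L| < 10^{-6}$ (max 100
iterations); non-convergence and boundary convergence are reported as
distinct flags, never silently. The SE of `h2` comes from the inverse AI
matrix by the delta method; the `h2 = 0` test is a likelihood-ratio
statistic against the closed-form OLS null, referred to the boundary
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Binary (dichotomized) traits
are analyzed on the observed 0/1 scale; a liability-scale conversion is
deliberately *not* applied by default, matching the convention of reporting
observed-scale estimates alongside continuous traits.

### G-BLUP / kriging prediction

Prediction of a held-out subject is a similarity-weighted sum of the
training phenotypes: with $V = K_{tt} + \lambda I$ and
$\lambda = \sigma^2_e/\sigma^2_g$,
$\hat y_x = K_{xt} V^{-1} (y_t - \mu) + \mu$. The intercept $\mu$ is
estimated by GLS under $V$, which makes the predictor *exactly* the
solution of Henderson's mixed-model equations (the package tests this
against a direct MME solve). When variance components are unavailable or at
the boundary the ridge defaults to 1, i.e. an assumed `h2` of 0.5. A
simpler kriging variant (`kriging_simple_predict`) scores by
kinship-weighted label sums over the `k` nearest training subjects with
weights normalized by $\sum |w|$ — the absolute-value normalization is
chosen because genomic similarities can be negative.

Leave-one-out prediction builds `A` once on the full cohort and predicts
each subject from the other $n-1$. It is computed in closed form from a
single inverse of $K + \lambda I$ via block-inverse (Schur) identities,
including the per-fold GLS intercept; this is algebraically identical to
refitting per subject and is verified against the naive refit at $10^{-10}$.
Building the GRM on the whole cohort (allele frequencies included) mirrors
the study design this package follows; a strict no-leakage analysis can
recompute frequencies per training fold by subsetting before
`compute_grm()`.

### Evaluation

AUC is the Mann–Whitney probability with ties counted half. The convex-hull
AUC is the area under the upper convex hull of the ROC points — the best
operating envelope attainable by randomizing between thresholds; it always
dominates the raw AUC. Significance is a one-sided label-permutation test
with the add-one estimator $p = (1 + \#\{AUC_{perm} \ge AUC_{obs}\})/(B+1)$,
which can never return zero and is at worst super-uniform by $1/(B+1)$. The
repeated-split protocol defaults to 75/25 stratified splits repeated 25
times, reporting mean and SD of the per-repeat AUCs and the *mean* p-value
across repeats — reported that way for comparability even though averaging
p-values is statistically unusual (a combined test such as Fisher's would be
the orthodox alternative). For leave-one-out evaluation the permutation
null permutes labels against the fixed LOO scores, the standard
label-permutation construction; a full re-training permutation would be more
conservative but is quadratic in cost.

## Phenotype derivation

Continuous traits are dichotomized about the mean (`label = 1` above).
Bronchodilator response is `(post − pre)/pre` FEV1. Missing phenotype and
covariate entries are imputed with the column mean (mode for categorical) —
mean imputation biases association toward the null, the conservative
direction. Longitudinal lung-growth patterns are classified from annual
percent-predicted FEV1 series: **NG** (normal growth) when more than half
the observations sit above the 25th percentile of the reference
distribution, **RG** (reduced growth) otherwise; **ED** (early decline) when
a subject followed to at least age 23 shows a relative drop of at least
`decline_threshold` (default 0.05) from a peak attained before the final
visit, after rolling-median smoothing. Composites: ED-All = NG-ED ∪ RG-ED,
RG-All = RG ∪ RG-ED. Two parameters are judgment calls, exposed as
arguments: the "predominately above/below" rule is implemented as a
majority rule (`ng_fraction = 0.5`), and the early-decline magnitude
defaults to a 5% drop — a stand-in where the literature gives no single
number. The percentile reference is an internal synthetic population
(percent-predicted FEV1 ~ Normal(100, 13)), not published reference
equations: classification needs only relative position, and percent-predicted
values are already age/sex/height-normalized.

## The synthetic cohort generator

`sim_config()` defaults describe the cohort the package is designed around:
832 subjects; HWE genotypes with allele frequencies uniform on
[0.05, 0.5] (so simulated SNPs pass the MAF-0.05 and HWE-0.001 filters at
the expected rates); an additive polygenic trait with specified `h2_true`
and causal fraction, effects i.i.d. Gaussian on standardized genotypes (the
same generative model GREML assumes, which is what makes parameter-recovery
tests well-posed); priority scores in [0, 0.12] with 43.1% exact zeros
(259,156 of 455,481 retained — the geometry of the non-zero-weight subset),
causal SNPs over-represented among non-zero scores in proportion to
`priority_informativeness`; demographic covariates with configurable effect
sizes; MCAR missingness (no mechanism being specified, MCAR plus mean
imputation is the null-biased choice); and lung-pattern assignments at
proportions NG 26.56%, NG-ED 20.55%, RG 26.68%, RG-ED 21.27% with the
remainder unclassifiable. Trajectories realize each pattern by
construction: NG level 106% predicted vs RG 84% (either side of the 25th
percentile, 91.2%), a peak at age 19, and for ED patterns a 12% decline to
age 24, plus per-visit Gaussian noise (SD 2% predicted by default; the
trajectory shape and noise parameters are free choices, as no measurement
model is published for these series).

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium (SNPs are independent, so
`m` effective markers here correspond to a much larger genotyped panel),
population stratification (beyond what a user builds manually),
genotype-covariate correlation, informative missingness, and real
percent-predicted reference equations.

## Validation problem sizes

The test suite validates behavior at sizes chosen to finish in minutes on
one CPU while leaving sampling error well inside the asserted bands:
heritability recovery at n = 1000, m = 2000 over 20 replicates (mean
estimate within ±0.05 of the true 0.5, SE-coverage in at least 18/20); null
calibration at n = 500, m = 1000; exact-oracle checks (REML grid search,
MME solve, naive LOO refits, exhaustive AUC enumeration) at n ≤ 50;
prediction-vs-heritability monotonicity at n = 800 over h2 ∈ {0, 0.3, 0.6,
0.9}; and permutation calibration over 400 trials. For the non-zero-weight
comparison the regime n = 1200, m = 4000, h2 = 0.15 with a 20% causal
fraction was fixed after a calibration study: random zero-weighting removes
a proportional share of causal variance, so its paired effect is genuinely
negative and only negligible when the per-dataset signal is weak and
diffuse; this regime is the one where informative weighting measurably
helps while uninformative weighting stays within ±0.01 AUC in expectation.

## Known limitations

Single GRM only (no partitioned or bivariate REML); observed-scale analysis
of binary traits; dense linear algebra, comfortable to n of a few thousand;
PLINK 1 bed/bim/fam and a plain-text dosage dialect, not VCF; the LASSO and
SVM baselines delegate their optimizers to `glmnet` and `e1071` and are
evaluated through the same interface as the GRM methods, not tuned per
trait.
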