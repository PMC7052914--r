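---
title: "Methods: genotype-based radiation pneumonitis risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-based radiation pneumonitis risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiation pneumonitis (RP) is the dose-limiting toxicity of thoracic
radiotherapy. Grade ≥ 2 RP (CTCAE) requires medical intervention, and which
patients develop it is only weakly explained by dosimetric parameters —
two patients receiving near-identical plans can respond very differently.
The working hypothesis behind this package is that much of that variation
is germline: a weighted combination of many common variants, rather than a
single marker, carries the predictive signal.

`rpindex` implements the full modelling pipeline for a **Radiation
Pneumonitis Index (RPI)**: a logistic risk score over selected SNP sites,

$$\mathrm{RPI} = \sigma\!\Big(\beta_0 + \sum_i A_i C_i\Big),
\qquad \sigma(x) = \frac{1}{1+e^{-x}},$$

where $A_i \in \{0,1,2\}$ is the reference-relative dosage of site $i$ and
$C_i$ its fitted coefficient. A patient is classified high-risk when the
RPI strictly exceeds a threshold, 0.5 by default.

## Dosage encoding

Each genotype call is a pair of alleles compared **as literal strings**
against the site's GRCh37-style definition: an allele equal to the designed
alternative (ALT) contributes 1, an allele equal to the reference
("wild-type") contributes 0, and an allele matching *neither* contributes 0.
The site value is the sum over the two alleles, so "WW" → 0, "WA"/"AW" → 1,
"AA" → 2. Allele order and phasing are irrelevant, and no strand flipping or
allele harmonisation is attempted.

One reading of the off-reference rule deserves note: we apply the
per-allele rule, so a call pairing the alternative allele with an
off-reference base encodes as 1, and a call of two off-reference bases as 0.
The alternative reading — one off-reference allele zeroes the whole site —
is not self-consistent with summing two allelic values, so the per-allele
reading is used throughout (and exercised by an exhaustive test over all
allele-pair classes). Off-reference calls mostly arise when scoring a new
cohort against a published coefficient table whose site definitions differ
from the cohort's genotyping assay.

## Quality control

Sites are filtered by five per-site rules, each with its conventional
threshold: mean GenCall score < 0.7 (array call confidence), missingness
> 5%, minor allele frequency < 0.01, exact Hardy–Weinberg test p < 1e-6,
and multi-allelic design (more than one designed ALT). Every statistic is
computed on the *unfiltered* matrix, so filter order cannot change the
surviving set, and a second application removes nothing. MAF and the HWE
test use non-missing calls only; the mean GenCall score is treated as a
per-site quantity (a per-sample reading of the same words is possible, but
per-site is what a site-filter needs). The HWE statistic is the exact
conditional test — the summed probabilities, given the allele counts, of
all heterozygote counts no more probable than the observed one — matching
the default of the standard GWAS toolchain; it is verified in tests against
a direct log-factorial enumeration for every genotype configuration with
up to 30 samples.

## Clinical-factor screening

Non-genetic factors are screened one at a time against the binary grade ≥ 2
endpoint: continuous variables by the Mann–Whitney U test (exact
permutation null for small tie-free samples, normal approximation with tie
and continuity corrections otherwise), categorical variables by the exact
Fisher test. The two-sided Fisher p-value sums the probabilities of all
tables (with the observed margins) whose point probability does not exceed
the observed table's — the convention required to reproduce published
clinical baseline tables. $r \times c$ tables are enumerated exhaustively
with a capacity budget rather than approximated; the table sizes arising in
clinical baseline comparisons enumerate in milliseconds. No multiplicity
adjustment is applied, matching how such tables are conventionally
reported.

## Penalized model

The core fit is an elastic-net logistic regression solved by cyclic
coordinate descent on the IRLS-weighted least-squares surrogate,
implemented in C++ with warm-started descending-lambda paths, sequential
strong-rule screening, and KKT verification of excluded predictors:

$$\min_{\beta_0,\beta}\; -\tfrac1n \ell(\beta_0, \beta)
  + \lambda \sum_j w_j\Big(\alpha|\beta_j| +
  \tfrac{1-\alpha}{2}\beta_j^2\Big).$$

Design columns are standardized internally to unit (1/n-)variance;
coefficients are reported on the input scale. The per-feature penalty
factors $w_j$ are 1 for SNP dosages and 0 for clinical covariates (age,
total dose, fractional dose, V5–V30, MLD when supplied), so covariates are
*exempt from penalization* and always remain in the model, as is the
intercept. Missing dosages are mean-imputed per column (QC caps missingness
at 5% first); constant columns are dropped with a message.

Numerical choices: convergence is declared when the largest weighted
squared coordinate update falls below `thresh` (1e-10 for single fits,
1e-7 for cross-validation paths, 1e-6 inside bootstrap resamples — the
selected-versus-zero pattern is insensitive to the looser tolerances,
which is all the bootstrap stage consumes); fitted probabilities are
clamped to [1e-5, 1-1e-5] as in the reference algorithm; coefficients
within 1e-12 of the soft-threshold boundary are exact zeros; an
unpenalized fit that fails to converge raises a divergence (separation)
error rather than returning drifting coefficients. The solver is tested
against an independent convex-optimization oracle on small instances
across $\alpha \in \{0, 0.5, 1\}$ (coefficients to 1e-5, objective to 1e-8
relative) and satisfies the KKT conditions at tolerance 1e-6.

The mixing parameter defaults to $\alpha = 0.5$: the method is defined as a
combination of lasso and ridge, which fixes only $\alpha \in (0,1)$, and
the midpoint treats the two penalties symmetrically. It is exposed
everywhere.

## Lambda selection and stability selection

$\lambda$ is chosen by 10-fold outcome-stratified cross-validation over a
100-point log-spaced grid from $\lambda_{\max}$ (the null-model gradient
bound, computed after fitting the covariate-only model when covariates are
present) down to $10^{-3}\lambda_{\max}$, scored by validation binomial
deviance. Both the minimum-deviance and the one-standard-error lambda are
reported. The 1-SE rule is the default wherever a lambda decides *which
markers count as present* (inside bootstrap stability selection), since
that stage values sparsity and false-positive control over raw deviance;
the final refit instead defaults to the minimum-deviance lambda on a grid
extended to $10^{-4}\lambda_{\max}$ (the reference-algorithm convention
once $n \gg p$, as on the restricted design), because its job is calibrated
prediction — the 1-SE choice there over-shrinks strong coefficients and
pushes borderline high-risk probabilities below the fixed 0.5 threshold.
The full-data path is fitted first and may
truncate the grid early once the fitted deviance saturates (the reference
algorithm's convention); folds then share the truncated grid exactly.

Marker selection uses bootstrap stability selection: the cohort is
resampled with replacement 500 times (tests and the acceptance script use
100, a documented reduced count), a model is built for each bootstrap
cohort, and a marker counts as *present* when its coefficient is nonzero at
that bootstrap's chosen lambda. Markers present in more than half of all
bootstraps form the final set; covariates take no part in the rule. By
default each bootstrap re-runs cross-validation internally (the literal
reading of building a model per bootstrap cohort); a fast mode fits all
bootstraps at one fixed lambda.

One implementation decision matters greatly here: within a bootstrap
resample, CV folds are assigned at the level of *original* samples, so
duplicate copies of one sample never straddle a training/validation
boundary. Splitting duplicates leaks information, biases the chosen lambda
low by roughly a factor of three in our simulations, and floods the
bootstrap models with false inclusions — with grouped folds the majority
rule recovers planted causal markers essentially without false picks, with
naive folds it does not.

The final model refits the selected markers (plus covariates, still
unpenalized) with a fresh CV-chosen lambda on the restricted design — a
refit, rather than freezing bootstrap-averaged coefficients, because the
selected set is the model being estimated and shrinkage should be
recalibrated to it. An empty selection yields an intercept-only (or
covariate-only) model, not an error. The result is exported as a portable
coefficient table (sites, coefficients, intercept, hyper-parameters,
threshold, covariate effects with training means) that round-trips through
a commented TSV at full precision.

## Scoring and evaluation

Scoring includes the fitted intercept inside the sigmoid: a probability
"from the fitting algorithm" is not defined without it, even where the
score is written as a bare weighted sum. When the model carries covariate
effects, their contribution at the stored training means is folded into the
intercept by default, keeping the score a pure genotype index on a
calibrated probability scale; `covariate_mode = "ignore"` drops them
instead. Neither mode is claimed to be what any particular published model
did — the handling of penalty-exempt covariates at scoring time is
genuinely underdetermined, so both are provided.

Classification is strict (`rpi > threshold`; a score exactly at the
threshold is negative — the tie case is measure-zero but a convention must
be documented and tested). Evaluation reports the confusion counts,
sensitivity TP/(TP+FN) and specificity TN/(TN+FP), unrounded; display
formatting rounds percentages half-up to one decimal. Training/validation
splits are uniform random partitions without outcome stratification
(default 90/28 on a 118-sample cohort), deterministic under a seed.

## The synthetic cohort generator

No genotype data accompany the study this pipeline is modelled on, so the
generator is a first-class module that emulates the *structure* the
analysis assumes: biallelic SNPs with MAFs drawn uniformly on [0.01, 0.5],
genotypes in Hardy–Weinberg proportions (binomial(2, MAF) dosages), a
sparse causal architecture acting additively on the dosage scale through a
logistic outcome model, uniform call missingness (2%), Beta(60, 3) per-site
mean GenCall scores, 1% multi-allelic sites, 0.5% off-reference calls, and
the clinical covariate table with marginals matching published patient
characteristics (median age 60, ~82% smokers, ~34% COPD, ~8.5% prior
surgery, median MLD 11.6 Gy, and so on). Defaults: 118 samples, grade ≥ 2
prevalence targeted at 42.4%, and 39 causal sites with a 2:1
positive-to-negative sign ratio and magnitudes 0.15–0.6 — mirroring the
fitted-model scale reported for this endpoint (39 sites, 25 positive / 14
negative, coefficients ≈ −0.26 to 0.31), since the true generative
architecture is unknown. The intercept is centred so the expected
prevalence hits its target given the MAF spectrum. The default marker count
is a desk-scale 10,000; the array scale (~700,000) is reachable by
argument. Covariates are independent of outcome by default — consistent
with dosimetric factors carrying little predictive signal in this setting —
with an optional effect hook.

Deliberate simplifications: sites are independent (no linkage
disequilibrium), there is no population stratification, and missingness is
uniform rather than clustered. Passing tests on these cohorts therefore
demonstrates correctness of the machinery and recoverability of additive
signal — not performance on real genotyping data, where LD, batch structure
and differential missingness all bite. Multi-allelic sites are planted
outside the causal set so that the QC exclusion cannot silently remove
simulated signal; off-reference calls are injected after the outcome is
drawn so they act purely as encoding noise. An optional switch plants
heterozygote-excess (HWE-violating) sites so the HWE filter has true
positives to catch: with relative excess 0.5 and MAF ≥ 0.3, their exact-test
p-values at n = 2000 are far below the 1e-6 threshold.

## Problem sizes used by the test-suite

Simulation-backed checks run at deliberately modest sizes chosen to make
their statistical expectations sharp yet cheap: planted-marker recovery at
400 samples × 200 sites with 5 causal effects of |coef| ≥ 1.5 and MAF ≥ 0.2
(100 bootstraps, 5 seeds); the null selection control at 200 × 50 over 20
seeded runs; the end-to-end held-out classification property at 400 × 500
with a 300/100 split (60 bootstraps, 2 seeds); exhaustive oracle sweeps for
the exact tests at every configuration with ≤ 30 genotypes (HWE) and every
2×2 table with N ≤ 20 (Fisher).

The end-to-end check expects held-out sensitivity and specificity of at
least 0.8 at the 0.5 threshold, and its planted effects (±3 to ±5 per
allele) are chosen by a ceiling argument rather than realism: under a
logistic outcome model, even classifying with the *true* generative
probabilities cannot beat the Bernoulli noise of labels near p = 0.5, and
with five effects of magnitude ≤ 2 that Bayes ceiling itself sits near
0.75–0.80. High joint sensitivity/specificity is only attainable when the
outcome is nearly deterministic given genotype — which is precisely what
any near-perfect clinical genotype classifier implies about its cohort.
Magnitudes are made heterogeneous because the dosage sum is discrete: with
equal magnitudes one tied cluster of samples can sit exactly on the
decision boundary and flip the sensitivity by thirty points in either
direction.

## Known limitations

* Alleles are compared as given strings; array TOP/BOT versus genomic
  strand conventions must be resolved upstream.
* The r×c Fisher test is exact-by-enumeration and refuses tables beyond its
  budget rather than falling back to an approximation.
* Stability selection with per-bootstrap CV is computationally heavy at
  array scale; the fixed-lambda mode trades literal fidelity for speed.
* The generator's independence assumptions (no LD, no stratification) make
  recovery easier than on real cohorts; headline sensitivities from
  synthetic runs are analogues, not reproductions, of any clinical result.
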