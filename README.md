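# rpindex

Genotype-based prediction of grade ≥ 2 radiation pneumonitis with a
stability-selected elastic net.

## The problem

Radiation pneumonitis (RP) is the dose-limiting toxicity of thoracic
radiotherapy; grade ≥ 2 disease (CTCAE) requires medical intervention.
Dosimetric and clinical factors explain little of the patient-to-patient
variation, so this package models the germline contribution instead: a
**Radiation Pneumonitis Index (RPI)** built from array genotypes,

```
RPI = sigmoid( β₀ + Σᵢ Aᵢ·Cᵢ )
```

where `Aᵢ ∈ {0, 1, 2}` counts the alleles at site `i` matching the
GRCh37-relative alternative allele (alleles matching neither REF nor ALT
count 0), and `Cᵢ` is the site's coefficient from a penalized logistic fit.
Patients with RPI strictly above 0.5 are classified high-risk.

The pipeline, each stage an exported tidyverse-style function:

1. **Genotype I/O and encoding** — VCF (or tabular allele-pair) reading,
   reference-relative 0/1/2 dosage encoding (`read_genotypes()`,
   `encode_cohort()`).
2. **Quality control** — per-site filters: mean GenCall < 0.7, missingness
   > 5%, MAF < 0.01, exact Hardy–Weinberg test p < 1e-6, multi-allelic
   exclusion (`apply_qc()`).
3. **Clinical screening** — exact Fisher tests for categorical factors,
   Mann–Whitney U for continuous ones (`screen_factors()`).
4. **Model fitting** — elastic-net logistic regression by coordinate
   descent (Rcpp) with penalty-exempt clinical covariates, 10-fold
   cross-validated lambda, and 500-bootstrap stability selection keeping
   markers present in more than half of all bootstraps
   (`fit_enet()`, `cv_lambda()`, `stability_select()`, `final_model()`).
5. **Scoring and evaluation** — RPI scores, threshold classification,
   confusion counts with sensitivity/specificity (`score_rpi()`,
   `evaluate_predictions()`), plus a 90/28-style random cohort split
   (`split_cohort()`).
6. **Synthetic cohorts** — a generator emulating the data structure the
   analysis assumes (HWE genotypes, sparse causal logistic outcome,
   missingness, GenCall scores, multi-allelic sites, off-reference calls,
   clinical covariates), so the whole pipeline is testable without any
   genotype download (`synthetic_spec()`, `simulate_cohort()`,
   `write_fixture()`).

Fitted objects have `tidy()` / `glance()` methods and `autoplot()`
visualisations (CV curve, inclusion frequencies, RPI score plot).

## Worked example

Train on a simulated 400-patient cohort with five planted causal sites,
hold out 100 patients:

```r
library(rpindex)

spec <- synthetic_spec(n_samples = 400, n_snps = 500, n_causal = 5,
                       causal_coefficients = c(3, 4, 5, -4, -5),
                       maf_distribution = list(dist = "uniform",
                                               min = 0.2, max = 0.5),
                       seed = 42)
sim <- simulate_cohort(spec)
qc  <- apply_qc(sim$cohort)
qc
#> <qc_result> 500 sites in -> 495 sites out
#>   failed: gencall 0 | missingness 0 | maf 0 | hwe 0 | multiallelic 5

plan <- split_cohort(sim$phenotypes$sample_id, n_train = 300, seed = 42)
ph   <- sim$phenotypes[match(sample_ids(qc$cohort), sim$phenotypes$sample_id), ]
tr   <- ph$sample_id %in% plan$training

design <- build_design(qc$encoded[tr, , drop = FALSE])
st <- stability_select(design, ph$endpoint[tr], n_bootstraps = 100, seed = 42)
st
#> <stability_result> 100 bootstraps (cv lambda): 12 of 495 markers selected at frequency > 0.50

fm <- final_model(design, ph$endpoint[tr], st, seed = 42,
                  variants = qc$cohort$variants)
head(tidy(fm), 4)
#> # A tibble: 4 × 6
#>   site_id   chrom       pos ref   alt   coefficient
#>   <chr>     <chr>     <int> <chr> <chr>       <dbl>
#> 1 snp000030 2      41713737 C     A         -0.612
#> 2 snp000032 2      60449427 T     C         -4.48
#> 3 snp000038 2      78190909 G     A          2.87
#> 4 snp000054 3      25796973 C     G          4.64
```

All five planted sites (true coefficients +3, +4, +5, −4, −5 at
`snp000246`, `snp000038`, `snp000054`, `snp000344`, `snp000032`) are
selected with bootstrap frequencies 0.90–1.00 and recovered with the right
signs; seven weakly weighted extras ride along. Scoring the held-out 100
patients:

```r
sc <- score_rpi(qc$encoded[!tr, , drop = FALSE], fm,
                variants = qc$cohort$variants)
ev <- evaluate_predictions(sc$predicted_class, ph$endpoint[!tr])
ev
#> # A tibble: 1 × 7
#>      tp    fp    tn    fn     n sensitivity specificity
#>   <int> <int> <int> <int> <int>       <dbl>       <dbl>
#> 1    43     7    44     6   100       0.878       0.863
glance(ev)
#> # A tibble: 1 × 2
#>   sensitivity specificity
#>   <chr>       <chr>
#> 1 87.8%       86.3%
```

So on held-out data the RPI classifies 87.8% of the true grade ≥ 2 cases
and 86.3% of the controls correctly at the 0.5 threshold — a synthetic
analogue of the clinical use case, with the caveat that simulated cohorts
lack linkage disequilibrium and population structure (see the methods
vignette, `vignettes/rpi-methods.Rmd`).

A published coefficient table can be applied directly to a new VCF:

```r
model  <- read_coefficients("model.tsv")
cohort <- read_genotypes("patients.vcf")
scores <- score_rpi(encode_cohort(apply_qc(cohort)$cohort), model)
```

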