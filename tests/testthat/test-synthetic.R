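test_that("null model with zero intercept gives ~50% prevalence", {
  spec <- synthetic_spec(n_samples = 100, n_snps = 50, n_causal = 0,
                         intercept = 0, seed = 1)
  sim <- simulate_cohort(spec)
  prev <- mean(sim$phenotypes$endpoint)
  expect_gte(prev, 0.40)
  expect_lte(prev, 0.60)
  expect_equal(sim$phenotypes$endpoint, as.integer(sim$phenotypes$rp_grade >= 2))
})

test_that("zero missing rate yields a fully observed encoded matrix", {
  spec <- synthetic_spec(n_samples = 40, n_snps = 30, n_causal = 0,
                         missing_rate = 0, fraction_multiallelic = 0,
                         fraction_offref = 0, seed = 2)
  enc <- encode_cohort(simulate_cohort(spec)$cohort)
  expect_false(anyNA(enc))
  expect_true(all(enc %in% 0:2))
})

test_that("empirical prevalence matches the simulated linear predictors", {
  spec <- synthetic_spec(n_samples = 2000, n_snps = 200, n_causal = 5,
                         causal_coefficients = c(2, 2, 2, -2, -2),
                         intercept = NULL, seed = 7, missing_rate = 0)
  sim <- simulate_cohort(spec)
  p_true <- sim$truth$probabilities
  mc_se <- sqrt(mean(p_true * (1 - p_true)) / length(p_true))
  expect_lt(abs(mean(sim$phenotypes$endpoint) - mean(p_true)), 4 * mc_se)
})

test_that("per-site allele frequencies converge to the drawn MAFs", {
  spec <- synthetic_spec(n_samples = 2000, n_snps = 100, n_causal = 0,
                         missing_rate = 0, fraction_multiallelic = 0,
                         fraction_offref = 0, seed = 3)
  sim <- simulate_cohort(spec)
  maf <- sim$truth$maf
  emp <- colMeans(sim$truth$dosages) / 2
  se <- sqrt(maf * (1 - maf) / (2 * spec$n_samples))
  expect_true(all(abs(emp - maf) <= 3.89 * se))  # ~1e-4 per-site, 100 sites
})

test_that("with no causal sites, marker-outcome association is at chance level", {
  spec <- synthetic_spec(n_samples = 300, n_snps = 300, n_causal = 0,
                         missing_rate = 0, fraction_multiallelic = 0,
                         fraction_offref = 0, seed = 5)
  sim <- simulate_cohort(spec)
  y <- sim$phenotypes$endpoint
  pvals <- apply(sim$truth$dosages, 2, function(g) {
    tab <- rbind(c(sum(g[y == 1]), 2 * sum(y) - sum(g[y == 1])),
                 c(sum(g[y == 0]), 2 * sum(1 - y) - sum(g[y == 0])))
    fisher_exact(tab)
  })
  # binomial bound at alpha = 0.001 over 300 markers (P(X > 5) ~ 2e-5)
  expect_lte(sum(pvals < 0.001), 5)
})

test_that("identical spec and seed give identical cohorts", {
  spec <- synthetic_spec(n_samples = 30, n_snps = 40, seed = 9,
                         n_causal = 3, causal_coefficients = c(1, -1, 0.5),
                         n_hwe_violating = 2)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$cohort$calls, b$cohort$calls)
  expect_identical(a$cohort$variants, b$cohort$variants)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$probabilities, b$truth$probabilities)
})

test_that("invalid specs fail naming the offending field", {
  expect_error(synthetic_spec(n_causal = 10, n_snps = 5), "n_causal")
  expect_error(synthetic_spec(causal_coefficients = c(1, 2), n_causal = 3),
               "causal_coefficients")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(fraction_offref = -0.1), "fraction_offref")
  expect_error(
    synthetic_spec(maf_distribution = list(dist = "uniform", min = 0, max = 0.6)),
    "maf_distribution")
  expect_error(simulate_cohort(list()), "synthetic_spec")
})

test_that("HWE-violating sites show the planted heterozygote excess", {
  spec <- synthetic_spec(n_samples = 2000, n_snps = 50, n_causal = 0,
                         n_hwe_violating = 5, hwe_het_excess = 0.5,
                         missing_rate = 0, fraction_multiallelic = 0,
                         fraction_offref = 0, seed = 13)
  sim <- simulate_cohort(spec)
  bad <- sim$truth$hwe_violating
  het <- colMeans(sim$truth$dosages == 1)
  maf <- sim$truth$maf
  expected_hw <- 2 * maf * (1 - maf)
  expect_true(all(het[bad] > expected_hw[bad] * 1.2))
})

test_that("fixtures round-trip losslessly and are byte-identical per seed", {
  spec <- synthetic_spec(n_samples = 25, n_snps = 60, n_causal = 2,
                         causal_coefficients = c(1.5, -1.5),
                         fraction_multiallelic = 0.05, fraction_offref = 0.01,
                         seed = 21)
  sim <- simulate_cohort(spec)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- write_fixture(sim, d1)
  back <- read_genotypes(paths$genotypes)
  expect_identical(back$calls, sim$cohort$calls)
  expect_identical(back$variants$site_id, sim$cohort$variants$site_id)
  expect_identical(back$variants$ref, sim$cohort$variants$ref)
  expect_identical(back$variants$alt, sim$cohort$variants$alt)
  expect_identical(is_multiallelic(back), is_multiallelic(sim$cohort))
  ph <- read_phenotypes(paths$phenotypes)
  expect_equal(ph$endpoint, sim$phenotypes$endpoint)
  write_fixture(sim, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "genotypes.vcf"))),
                   unname(tools::md5sum(file.path(d2, "genotypes.vcf"))))
  blocker <- withr::local_tempfile(lines = "not a directory")
  expect_error(suppressWarnings(write_fixture(sim, file.path(blocker, "sub"))),
               "cannot create")
})
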