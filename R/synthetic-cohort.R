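#' Specify a synthetic genotype cohort
#'
#' Defines every parameter of the cohort simulator: sample and marker counts,
#' the minor-allele-frequency (MAF) spectrum, a sparse causal architecture
#' acting additively on the 0/1/2 dosage scale through a logistic outcome
#' model, per-call missingness, per-site array-quality (mean GenCall) scores,
#' and the two data pathologies the downstream pipeline must tolerate:
#' multi-allelic sites and "off-reference" calls carrying an allele that is
#' neither REF nor ALT.
#'
#' Defaults emulate the cohort structure of a thoracic-radiotherapy
#' pharmacogenomic study: 118 patients, grade >= 2 radiation pneumonitis in
#' roughly 42% of them, 39 causal markers with both protective and risk
#' alleles (13 negative / 26 positive effects), and clinical covariates whose
#' marginal distributions match published patient tables but which are, by
#' default, independent of the outcome. The default marker count is a
#' desk-scale 10,000; the array scale (~700,000) is reachable by argument.
#'
#' @param n_samples Number of patients.
#' @param n_snps Number of biallelic SNP sites.
#' @param maf_distribution List describing the per-site MAF draw. Supported:
#'   `list(dist = "uniform", min, max)` (default `[0.01, 0.5]`) and
#'   `list(dist = "beta", shape1, shape2, floor)` (draws truncated to
#'   `(floor, 0.5]`).
#' @param n_causal Number of causal sites.
#' @param causal_coefficients Numeric vector of length `n_causal`: log-odds
#'   effect per alternative allele (dosage coding 0/1/2). `NULL` uses a
#'   default ladder of magnitudes 0.15--0.6 with a 2:1 positive:negative sign
#'   pattern.
#' @param intercept Log-odds baseline. `NULL` centres the linear predictor so
#'   that expected prevalence is `target_prevalence` given the mean of the MAF
#'   distribution.
#' @param target_prevalence Expected outcome prevalence used only when
#'   `intercept` is `NULL`.
#' @param missing_rate Proportion of genotype calls set to missing.
#' @param gencall_mean_distribution List (`dist = "beta"`, `shape1`,
#'   `shape2`): per-site mean GenCall score in `[0, 1]`.
#' @param fraction_multiallelic Proportion of non-causal sites given a second
#'   designed ALT allele.
#' @param fraction_offref Proportion of calls in which one allele is replaced
#'   by a base outside {REF, ALT}; injected after the outcome is drawn so it
#'   acts purely as encoding noise.
#' @param n_hwe_violating Number of sites simulated with excess
#'   heterozygosity (Hardy-Weinberg violation) so the HWE filter has true
#'   positives to catch.
#' @param hwe_het_excess Relative heterozygote excess `e` for violating
#'   sites: P(het) = 2pq(1+e); their MAFs are drawn in `[0.3, 0.5]` so all
#'   genotype probabilities stay valid.
#' @param covariate_effects Optional named list of log-odds effects of
#'   clinical covariates on the outcome (an effect hook; default none, i.e.
#'   covariates independent of outcome).
#' @param seed Integer seed; identical spec + seed gives an identical cohort.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 118L,
                           n_snps = 10000L,
                           maf_distribution = list(dist = "uniform",
                                                   min = 0.01, max = 0.5),
                           n_causal = 39L,
                           causal_coefficients = NULL,
                           intercept = NULL,
                           target_prevalence = 0.424,
                           missing_rate = 0.02,
                           gencall_mean_distribution = list(dist = "beta",
                                                            shape1 = 60,
                                                            shape2 = 3),
                           fraction_multiallelic = 0.01,
                           fraction_offref = 0.005,
                           n_hwe_violating = 0L,
                           hwe_het_excess = 0.5,
                           covariate_effects = NULL,
                           seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", min = 1L)
  n_snps <- assert_count(n_snps, "n_snps", min = 1L)
  n_causal <- assert_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_snps) abort("`n_causal` must not exceed `n_snps`.")
  if (is.null(causal_coefficients) && n_causal > 0L) {
    mags <- seq(0.15, 0.6, length.out = n_causal)
    signs <- rep_len(c(1, 1, -1), n_causal)
    causal_coefficients <- mags * signs
  }
  causal_coefficients <- as.numeric(causal_coefficients %||% numeric(0))
  if (length(causal_coefficients) != n_causal) {
    abort("`causal_coefficients` must have length `n_causal`.")
  }
  if (any(!is.finite(causal_coefficients))) {
    abort("`causal_coefficients` must be finite.")
  }
  assert_scalar_number(missing_rate, "missing_rate", 0, 1, allow_upper_open = TRUE)
  assert_scalar_number(fraction_multiallelic, "fraction_multiallelic", 0, 1,
                       allow_upper_open = TRUE)
  assert_scalar_number(fraction_offref, "fraction_offref", 0, 1,
                       allow_upper_open = TRUE)
  assert_scalar_number(target_prevalence, "target_prevalence", 0, 1)
  n_hwe_violating <- assert_count(n_hwe_violating, "n_hwe_violating")
  if (n_hwe_violating > n_snps) abort("`n_hwe_violating` must not exceed `n_snps`.")
  assert_scalar_number(hwe_het_excess, "hwe_het_excess", 0, 1)
  seed <- assert_count(seed, "seed")
  maf_distribution <- validate_maf_distribution(maf_distribution)
  if (!is.null(intercept)) assert_scalar_number(intercept, "intercept")
  gd <- gencall_mean_distribution
  if (!identical(gd$dist, "beta") || is.null(gd$shape1) || is.null(gd$shape2)) {
    abort("`gencall_mean_distribution` must be list(dist = 'beta', shape1, shape2).")
  }
  if (is.null(intercept)) {
    # centre on the expected dosage contribution: E[dosage] = 2 * E[MAF]
    e_maf <- maf_distribution_mean(maf_distribution)
    intercept <- qlogis(target_prevalence) -
      sum(causal_coefficients) * 2 * e_maf
  }
  structure(
    list(n_samples = n_samples, n_snps = n_snps,
         maf_distribution = maf_distribution, n_causal = n_causal,
         causal_coefficients = causal_coefficients, intercept = intercept,
         missing_rate = missing_rate,
         gencall_mean_distribution = gencall_mean_distribution,
         fraction_multiallelic = fraction_multiallelic,
         fraction_offref = fraction_offref,
         n_hwe_violating = n_hwe_violating, hwe_het_excess = hwe_het_excess,
         covariate_effects = covariate_effects, seed = seed),
    class = "synthetic_spec"
  )
}

validate_maf_distribution <- function(md) {
  if (!is.list(md) || is.null(md$dist)) {
    abort("`maf_distribution` must be a list with a `dist` element.")
  }
  if (md$dist == "uniform") {
    lo <- md$min %||% 0.01
    hi <- md$max %||% 0.5
    if (!(lo > 0 && hi <= 0.5 && lo < hi)) {
      abort("`maf_distribution`: uniform bounds must satisfy 0 < min < max <= 0.5.")
    }
    list(dist = "uniform", min = lo, max = hi)
  } else if (md$dist == "beta") {
    if (is.null(md$shape1) || is.null(md$shape2)) {
      abort("`maf_distribution`: beta needs shape1 and shape2.")
    }
    list(dist = "beta", shape1 = md$shape1, shape2 = md$shape2,
         floor = md$floor %||% 0.01)
  } else {
    abort("`maf_distribution`: unsupported dist (use 'uniform' or 'beta').")
  }
}

maf_distribution_mean <- function(md) {
  if (md$dist == "uniform") (md$min + md$max) / 2
  else min(md$shape1 / (md$shape1 + md$shape2), 0.5)
}

draw_mafs <- function(md, n) {
  if (md$dist == "uniform") {
    runif(n, md$min, md$max)
  } else {
    x <- rbeta(n, md$shape1, md$shape2)
    x <- pmin(pmax(x, md$floor + 1e-6), 0.5)
    x
  }
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat(sprintf("  samples: %d   SNP sites: %d   causal: %d\n",
              x$n_samples, x$n_snps, x$n_causal))
  cat(sprintf("  intercept (log-odds): %.4f   missing rate: %.3f\n",
              x$intercept, x$missing_rate))
  cat(sprintf("  multi-allelic fraction: %.3f   off-reference call fraction: %.3f\n",
              x$fraction_multiallelic, x$fraction_offref))
  cat(sprintf("  HWE-violating sites: %d   seed: %d\n",
              x$n_hwe_violating, x$seed))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate a genotype cohort with phenotypes and ground truth
#'
#' Draws per-site MAFs, genotypes in Hardy-Weinberg proportions
#' (binomial(2, MAF) alternative-allele dosages), a binary grade >= 2
#' pneumonitis outcome from a logistic model on the causal dosages, and the
#' full clinical covariate table. Multi-allelic sites, off-reference calls
#' and missingness are injected after the outcome so they act as pure
#' measurement noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `sim_cohort` with elements
#'   * `cohort` — a [genotype_cohort()] (variant metadata + allele-pair calls),
#'   * `phenotypes` — a tibble, one row per sample (outcome, grades, clinical
#'     and dosimetric covariates),
#'   * `truth` — a `truth_record`: causal site ids and coefficients, the
#'     intercept, per-sample true probabilities, and the pristine dosage
#'     matrix before noise injection.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be created with synthetic_spec().")
  }
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_samples
  p <- spec$n_snps
  sample_ids <- sprintf("S%04d", seq_len(n))
  site_ids <- sprintf("snp%06d", seq_len(p))

  maf <- draw_mafs(spec$maf_distribution, p)

  # site metadata: ordered positions on chromosomes 1..22
  chrom <- sort(sample(1:22, p, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(p), chrom), function(ix) {
    sort(sample.int(2e8, length(ix)))
  }), use.names = FALSE)
  ref <- sample(DNA_BASES, p, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
  names(alt) <- NULL

  # HWE-violating sites: excess heterozygosity, MAF restricted to [0.3, 0.5]
  hwe_sites <- integer(0)
  if (spec$n_hwe_violating > 0L) {
    hwe_sites <- sample.int(p, spec$n_hwe_violating)
    maf[hwe_sites] <- runif(spec$n_hwe_violating, 0.3, 0.5)
  }

  dosage <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), nrow = n,
                   dimnames = list(sample_ids, site_ids))
  if (length(hwe_sites)) {
    e <- spec$hwe_het_excess
    for (j in hwe_sites) {
      q <- maf[j]; pp <- 1 - q
      probs <- c(pp^2 - e * pp * q, 2 * pp * q * (1 + e), q^2 - e * pp * q)
      probs <- pmax(probs, 0); probs <- probs / sum(probs)
      dosage[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    }
  }

  causal_idx <- if (spec$n_causal > 0L) sample.int(p, spec$n_causal) else integer(0)

  covariates <- simulate_covariates(n, sample_ids)

  eta <- rep(spec$intercept, n)
  if (length(causal_idx)) {
    eta <- eta + as.vector(dosage[, causal_idx, drop = FALSE] %*%
                             spec$causal_coefficients)
  }
  if (!is.null(spec$covariate_effects)) {
    for (nm in names(spec$covariate_effects)) {
      if (!nm %in% names(covariates)) {
        abort(sprintf("`covariate_effects`: unknown covariate '%s'.", nm))
      }
      eta <- eta + spec$covariate_effects[[nm]] * as.numeric(covariates[[nm]])
    }
  }
  prob <- plogis(eta)
  y <- rbinom(n, 1L, prob)

  rp_grade <- integer(n)
  rp_grade[y == 1L] <- sample(2:4, sum(y), replace = TRUE, prob = c(0.75, 0.2, 0.05))
  rp_grade[y == 0L] <- sample(0:1, sum(!y), replace = TRUE, prob = c(0.6, 0.4))

  phenotypes <- tibble::tibble(sample_id = sample_ids, rp_grade = rp_grade,
                               endpoint = as.integer(rp_grade >= 2L)) |>
    dplyr::bind_cols(covariates[, setdiff(names(covariates), "sample_id")])

  # allele-pair calls from dosage
  calls <- matrix(NA_character_, n, p, dimnames = list(sample_ids, site_ids))
  for (g in 0:2) {
    idx <- which(dosage == g)
    jj <- (idx - 1L) %/% n + 1L
    calls[idx] <- switch(as.character(g),
      "0" = paste0(ref[jj], "/", ref[jj]),
      "1" = paste0(ref[jj], "/", alt[jj]),
      "2" = paste0(alt[jj], "/", alt[jj]))
  }

  # designed multi-allelic sites (kept off the causal set so the causal
  # architecture survives the multi-allelic QC exclusion)
  alt_alleles <- as.list(alt)
  n_multi <- round(spec$fraction_multiallelic * p)
  multi_sites <- integer(0)
  if (n_multi > 0L) {
    eligible <- setdiff(seq_len(p), causal_idx)
    multi_sites <- sample(eligible, min(n_multi, length(eligible)))
    for (j in multi_sites) {
      alt2 <- sample(setdiff(DNA_BASES, c(ref[j], alt[j])), 1L)
      alt_alleles[[j]] <- c(alt_alleles[[j]], alt2)
      # a few carriers of the second alternative allele
      carriers <- which(runif(n) < 0.05)
      if (length(carriers)) {
        calls[carriers, j] <- paste0(ref[j], "/", alt2)
      }
    }
  }

  # off-reference calls: one allele replaced by a base outside {REF, ALT};
  # injected post-outcome so they are pure encoding noise
  n_offref <- round(spec$fraction_offref * n * p)
  if (n_offref > 0L) {
    cells <- sample.int(n * p, n_offref)
    jj <- (cells - 1L) %/% n + 1L
    for (k in seq_along(cells)) {
      j <- jj[k]
      bad <- sample(setdiff(DNA_BASES, c(ref[j], alt_alleles[[j]])), 1L)
      parts <- strsplit(calls[cells[k]], "/", fixed = TRUE)[[1]]
      parts[sample(1:2, 1L)] <- bad
      calls[cells[k]] <- paste(parts, collapse = "/")
    }
  }

  if (spec$missing_rate > 0) {
    miss <- which(runif(n * p) < spec$missing_rate)
    calls[miss] <- NA_character_
  }

  gd <- spec$gencall_mean_distribution
  mean_gencall <- rbeta(p, gd$shape1, gd$shape2)

  variants <- tibble::tibble(
    site_id = site_ids, chrom = as.character(chrom), pos = as.integer(pos),
    ref = ref, alt = alt_alleles, mean_gencall = mean_gencall
  )
  cohort <- genotype_cohort(variants, calls)

  truth <- structure(
    list(sites = tibble::tibble(site_id = site_ids[causal_idx],
                                coefficient = spec$causal_coefficients),
         intercept = spec$intercept,
         probabilities = setNames(prob, sample_ids),
         maf = setNames(maf, site_ids),
         dosages = dosage,
         prevalence = mean(y),
         hwe_violating = site_ids[hwe_sites],
         multiallelic = site_ids[multi_sites]),
    class = "truth_record")

  structure(list(cohort = cohort, phenotypes = phenotypes, truth = truth),
            class = "sim_cohort")
}

simulate_covariates <- function(n, sample_ids) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tibble::tibble(
    sample_id = sample_ids,
    age = round(clip(rnorm(n, 60, 9), 36, 79)),
    total_dose = round(clip(rnorm(n, 58, 8), 30, 72), 1),
    fractional_dose = round(clip(rnorm(n, 2.5, 0.5), 2, 7), 2),
    v5 = round(clip(rnorm(n, 51, 15), 5, 95), 1),
    v10 = round(clip(rnorm(n, 34, 12), 2, 80), 1),
    v20 = round(clip(rnorm(n, 20, 7), 1, 45), 1),
    v30 = round(clip(rnorm(n, 12, 5), 1, 30), 1),
    mld = round(clip(rnorm(n, 11.6, 3.5), 2, 20), 1),
    surgery = rbinom(n, 1L, 0.085),
    smoker = rbinom(n, 1L, 0.822),
    copd = rbinom(n, 1L, 0.339),
    histology = sample(c("squamous", "adeno", "small_cell", "other"), n,
                       replace = TRUE, prob = c(0.347, 0.161, 0.449, 0.042)),
    stage = sample(c("I-II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.059, 0.729, 0.212)),
    kps = sample(c(70L, 80L, 90L), n, replace = TRUE, prob = c(0.1, 0.4, 0.5))
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  print(x$cohort)
  cat(sprintf("  outcome prevalence: %.3f   causal sites: %d\n",
              mean(x$phenotypes$endpoint), nrow(x$truth$sites)))
  invisible(x)
}
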