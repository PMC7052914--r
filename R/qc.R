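#' Quality-control thresholds
#'
#' The four per-site exclusion filters plus multi-allelic exclusion: a site
#' is dropped when its mean GenCall score is below `min_mean_gencall`, its
#' call missingness exceeds `max_missingness`, its minor allele frequency is
#' below `min_maf`, its exact Hardy-Weinberg test p-value is below
#' `hwe_alpha`, or it carries more than one designed ALT allele.
#'
#' @param min_mean_gencall Minimum per-site mean GenCall score (default 0.7).
#' @param max_missingness Maximum per-site missingness (default 0.05).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level
#'   (default 1e-6).
#' @param exclude_multiallelic Drop sites with more than one designed ALT
#'   (default `TRUE`).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_mean_gencall = 0.7, max_missingness = 0.05,
                          min_maf = 0.01, hwe_alpha = 1e-6,
                          exclude_multiallelic = TRUE) {
  assert_scalar_number(min_mean_gencall, "min_mean_gencall", 0, 1)
  assert_scalar_number(max_missingness, "max_missingness", 0, 1)
  assert_scalar_number(min_maf, "min_maf", 0, 0.5)
  assert_scalar_number(hwe_alpha, "hwe_alpha", 0, 1)
  structure(list(min_mean_gencall = min_mean_gencall,
                 max_missingness = max_missingness, min_maf = min_maf,
                 hwe_alpha = hwe_alpha,
                 exclude_multiallelic = isTRUE(exclude_multiallelic)),
            class = "qc_thresholds")
}

#' Per-site missingness
#'
#' @param x Encoded dosage column (integer vector, `NA` = missing).
#' @return Fraction of missing entries in `[0, 1]`.
#' @export
compute_missingness <- function(x) {
  if (!length(x)) abort("column is empty.")
  mean(is.na(x))
}

#' Minor allele frequency from encoded dosages
#'
#' Computed on non-missing calls only: the alternative-allele frequency is
#' `sum(dosage) / (2 * n_nonmissing)`; the MAF is the smaller of it and its
#' complement.
#'
#' @param x Encoded dosage column in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("MAF undefined: all calls missing.")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the sum of the conditional probabilities of every heterozygote
#' count whose probability does not exceed that of the observed count (the
#' convention of the standard GWAS toolchain). Probabilities are computed by
#' the stable ratio recurrence over the feasible heterozygote counts.
#'
#' @param n_homref,n_het,n_homalt Genotype counts (non-negative, total >= 1).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  counts <- c(n_homref, n_het, n_homalt)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort("genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n < 1) abort("total genotype count must be >= 1.")
  rare <- min(2 * n_homref + n_het, 2 * n_homalt + n_het)
  if (rare == 0) return(1.0)  # monomorphic: a single attainable configuration

  # feasible het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start at the mode-ish midpoint and recurse outward with probability ratios
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1L
  if (mid > rare) mid <- mid - 2L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # going down: het h -> h-2 multiplies by h(h-1) / (4 (hr+1)(ha+1))
  if (i_mid > 1) {
    for (i in seq(i_mid, 2L)) {
      h <- hets[i]
      hr <- (rare - h) / 2            # rare homozygotes at h
      ha <- n - h - hr                # common homozygotes at h
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (ha + 1))
    }
  }
  # going up: het h -> h+2 multiplies by 4 hr ha / ((h+2)(h+1))
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1L)) {
      h <- hets[i]
      hr <- (rare - h) / 2
      ha <- n - h - hr
      probs[i + 1] <- probs[i] * 4 * hr * ha / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

hwe_p_from_dosages <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
}

#' Apply per-site quality control
#'
#' Every filter statistic is computed on the unfiltered cohort (so filter
#' order cannot change the surviving set); a site is removed iff it fails at
#' least one enabled filter. The sample set is untouched. When the mean
#' GenCall filter is enabled but no scores are present, the filter is skipped
#' with a warning.
#'
#' @param cohort A [genotype_cohort()].
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_result`: `cohort` (filtered), `encoded`
#'   (filtered [encode_cohort()] dosage matrix), `report` (per-site tibble
#'   with statistics, verdict and failing filters), and `totals` (excluded
#'   count per filter plus `sites_in` / `sites_out`).
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds()) {
  if (!inherits(cohort, "genotype_cohort")) {
    abort("`cohort` must be a genotype_cohort.")
  }
  if (!inherits(thresholds, "qc_thresholds")) {
    abort("`thresholds` must come from qc_thresholds().")
  }
  v <- cohort$variants
  p <- nrow(v)
  multi <- unname(is_multiallelic(cohort))

  # per-site statistics from calls; dosage statistics on biallelic sites only
  missingness <- colMeans(is.na(cohort$calls))
  maf <- rep(NA_real_, p)
  hwe_p <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    if (multi[j]) next
    dos <- encode_site(cohort$calls[, j], v$ref[j], v$alt[[j]])
    if (all(is.na(dos))) next
    maf[j] <- compute_maf(dos)
    hwe_p[j] <- hwe_p_from_dosages(dos)
  }

  gencall <- if ("mean_gencall" %in% names(v)) v$mean_gencall else rep(NA_real_, p)
  gencall_available <- any(!is.na(gencall))
  fail_gencall <- rep(FALSE, p)
  if (gencall_available) {
    fail_gencall <- !is.na(gencall) & gencall < thresholds$min_mean_gencall
  } else {
    warn("mean GenCall scores absent: GenCall filter skipped.")
  }

  fail_missing <- missingness > thresholds$max_missingness
  fail_maf <- !is.na(maf) & maf < thresholds$min_maf
  fail_maf <- fail_maf | (!multi & is.na(maf))   # all-missing biallelic site
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha
  fail_multi <- if (thresholds$exclude_multiallelic) multi else rep(FALSE, p)

  fails <- unname(cbind(gencall = fail_gencall, missingness = fail_missing,
                        maf = fail_maf, hwe = fail_hwe,
                        multiallelic = fail_multi))
  colnames(fails) <- c("gencall", "missingness", "maf", "hwe", "multiallelic")
  excluded <- unname(rowSums(fails) > 0)
  reasons <- unname(apply(fails, 1, function(f) {
    paste(colnames(fails)[f], collapse = ",")
  }))

  report <- tibble::tibble(
    site_id = v$site_id, missingness = unname(missingness), maf = maf,
    hwe_p = hwe_p, mean_gencall = gencall, multiallelic = multi,
    verdict = ifelse(excluded, "fail", "pass"), reasons = reasons)

  keep <- which(!excluded)
  filtered <- genotype_cohort(v[keep, ], cohort$calls[, keep, drop = FALSE])
  encoded <- encode_cohort(filtered)

  totals <- c(colSums(fails), sites_in = p, sites_out = length(keep))
  structure(list(cohort = filtered, encoded = encoded, report = report,
                 totals = totals, thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<qc_result> %d sites in -> %d sites out\n",
              t[["sites_in"]], t[["sites_out"]]))
  cat(sprintf("  failed: gencall %d | missingness %d | maf %d | hwe %d | multiallelic %d\n",
              t[["gencall"]], t[["missingness"]], t[["maf"]], t[["hwe"]],
              t[["multiallelic"]]))
  invisible(x)
}

#' @rdname apply_qc
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname apply_qc
#' @export
glance.qc_result <- function(x, ...) {
  tibble::as_tibble(as.list(x$totals))
}
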