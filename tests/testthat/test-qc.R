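test_that("missingness and MAF match counting oracles", {
  expect_equal(compute_missingness(c(0L, 1L, 2L, NA)), 0.25)
  expect_equal(compute_missingness(c(0L, 1L, 2L)), 0)
  expect_equal(compute_maf(c(0L, 1L, 2L)), 0.5)
  expect_equal(compute_maf(c(0L, 0L, 0L)), 0)
  expect_equal(compute_maf(c(2L, 2L, 2L, 1L)), 0.125)  # min(7/8, 1/8)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "all calls missing")
  withr::with_seed(2, {
    for (i in 1:25) {
      x <- sample(c(0:2, NA), 40, replace = TRUE)
      expect_equal(compute_missingness(x), sum(is.na(x)) / 40)
      if (any(!is.na(x))) {
        f <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
        expect_equal(compute_maf(x), min(f, 1 - f))
      }
    }
  })
})

test_that("HWE exact test agrees with the enumeration oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)  # monomorphic
  expect_equal(hwe_exact_test(0, 2, 0), hwe_oracle(0, 2, 0))
  withr::with_seed(3, {
    for (i in 1:200) {
      n <- sample(1:30, 1)
      a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
      expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                   tolerance = 1e-12,
                   label = sprintf("counts (%d,%d,%d)", a, b, c))
    }
  })
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), ">= 1")
})

make_qc_cohort <- function(calls_list, gencall = NULL) {
  p <- length(calls_list)
  n <- length(calls_list[[1]])
  variants <- tibble::tibble(
    site_id = sprintf("q%d", seq_len(p)), chrom = "1",
    pos = seq_len(p) * 10L, ref = "A", alt = as.list(rep("G", p)),
    mean_gencall = if (is.null(gencall)) rep(0.95, p) else gencall)
  calls <- do.call(cbind, calls_list)
  rownames(calls) <- sprintf("I%d", seq_len(n))
  genotype_cohort(variants, calls)
}

test_that("each QC filter excludes exactly the offending sites", {
  n <- 200
  good <- rep(c("A/A", "A/G", "G/G"), c(120, 64, 16))        # MAF 0.24, in HWE
  rare <- rep(c("A/A", "A/G"), c(199, 1))                    # MAF 0.0025
  holey <- replace(good, 1:20, NA)                           # 10% missing
  cohort <- make_qc_cohort(list(good, rare, holey),
                           gencall = c(0.95, 0.95, 0.95))
  res <- apply_qc(cohort)
  rep_ <- res$report
  expect_equal(rep_$verdict, c("pass", "fail", "fail"))
  expect_equal(rep_$reasons[2], "maf")
  expect_equal(rep_$reasons[3], "missingness")
  expect_equal(colnames(res$encoded), "q1")

  # low mean GenCall
  cohort2 <- make_qc_cohort(list(good, good), gencall = c(0.95, 0.55))
  res2 <- apply_qc(cohort2)
  expect_equal(res2$report$reasons, c("", "gencall"))

  # all passing: output identical to input
  cohort3 <- make_qc_cohort(list(good, good))
  res3 <- apply_qc(cohort3)
  expect_identical(res3$cohort$calls, cohort3$calls)
  expect_equal(res3$totals[["sites_out"]], 2)
})

test_that("QC is idempotent and order-independent by construction", {
  spec <- synthetic_spec(n_samples = 150, n_snps = 120, n_causal = 0,
                         missing_rate = 0.04, fraction_multiallelic = 0.05,
                         fraction_offref = 0.01, seed = 6,
                         maf_distribution = list(dist = "uniform",
                                                 min = 0.005, max = 0.5))
  sim <- simulate_cohort(spec)
  res1 <- apply_qc(sim$cohort)
  res2 <- apply_qc(res1$cohort)
  expect_identical(res2$cohort$calls, res1$cohort$calls)
  expect_equal(res2$totals[["sites_out"]], res1$totals[["sites_out"]])
  expect_true(all(res2$report$verdict == "pass"))
  # every excluded site lists at least one failing filter
  rep_ <- res1$report
  expect_true(all(nzchar(rep_$reasons[rep_$verdict == "fail"])))
  expect_equal(res1$totals[["sites_in"]] - sum(rep_$verdict == "fail"),
               res1$totals[["sites_out"]])
})

test_that("planted HWE violations are excluded with verified p-values", {
  spec <- synthetic_spec(n_samples = 2000, n_snps = 80, n_causal = 0,
                         n_hwe_violating = 6, hwe_het_excess = 0.5,
                         missing_rate = 0, fraction_multiallelic = 0,
                         fraction_offref = 0, seed = 12)
  sim <- simulate_cohort(spec)
  res <- apply_qc(sim$cohort)
  bad <- sim$truth$hwe_violating
  rep_bad <- res$report[match(bad, res$report$site_id), ]
  # verify the planted p-values with the independent enumeration oracle
  for (sid in bad) {
    g <- sim$truth$dosages[, sid]
    p_oracle <- hwe_oracle(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_lt(p_oracle, 1e-8)
  }
  expect_true(all(rep_bad$verdict == "fail"))
  expect_true(all(grepl("hwe", rep_bad$reasons)))
})

test_that("absent GenCall scores skip that filter with a warning", {
  cohort <- make_qc_cohort(list(rep(c("A/A", "A/G", "G/G"), c(10, 8, 2))))
  cohort$variants$mean_gencall <- NA_real_
  expect_warning(res <- apply_qc(cohort), "GenCall")
  expect_equal(res$report$verdict, "pass")
})

test_that("multi-allelic sites are excluded before encoding", {
  cohort <- tiny_cohort()
  cohort$variants$alt[[2]] <- c("T", "G")
  cohort2 <- genotype_cohort(cohort$variants, cohort$calls)
  res <- apply_qc(cohort2)
  expect_match(res$report$reasons[2], "multiallelic")
  expect_false("s2" %in% colnames(res$encoded))
  expect_s3_class(res$encoded, "encoded_matrix")
})
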