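write_test_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
               lines), path)
  path
}

test_that("VCF GT semantics map to allele pairs, missing and phased calls", {
  path <- write_test_vcf(c(
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "./.", "0|1", "1|1"), collapse = "\t")))
  cohort <- read_genotypes(path)
  expect_equal(unname(cohort$calls[, "rs1"]), c("A/A", "A/G", "G/G"))
  expect_equal(unname(cohort$calls[, "rs2"]), c(NA, "C/T", "T/T"))
  expect_equal(cohort$variants$pos, c(100L, 200L))
})

test_that("multi-allelic ALT fields are preserved as allele lists", {
  path <- write_test_vcf(
    paste(c("2", "50", "rs9", "G", "A,T", ".", "PASS", ".", "GT",
            "0/1", "1/2", "2/2"), collapse = "\t"))
  cohort <- read_genotypes(path)
  expect_identical(cohort$variants$alt[[1]], c("A", "T"))
  expect_true(is_multiallelic(cohort)[["rs9"]])
  expect_equal(unname(cohort$calls[, 1]), c("G/A", "A/T", "T/T"))
  expect_error(encode_cohort(cohort), "multi-allelic")
})

test_that("duplicate site ids are rejected", {
  path <- write_test_vcf(c(
    paste(c("1", "100", "dup", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/0"), collapse = "\t"),
    paste(c("1", "200", "dup", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/0"), collapse = "\t")))
  expect_error(read_genotypes(path), "duplicate site_id")
})

test_that("encoding follows the per-allele reference-relative rule exactly", {
  # exhaustive table over the allele-pair classes for ref=A, alt=G
  cases <- list(
    list("A/A", 0L), list("A/G", 1L), list("G/A", 1L), list("G/G", 2L),
    list("A/T", 0L), list("T/A", 0L),        # ref + off-reference
    list("G/T", 1L), list("T/G", 1L),        # alt + off-reference
    list("T/C", 0L), list("T/T", 0L),        # off-reference only
    list(NA_character_, NA_integer_))
  for (cs in cases) {
    expect_identical(encode_site(cs[[1]], ref = "A", alt = "G"), cs[[2]],
                     label = sprintf("call %s", cs[[1]]))
  }
  # phased separator is equivalent
  expect_identical(encode_site("A|G", "A", "G"), 1L)
  expect_error(encode_site("A/G", "A", c("G", "T")), "QC")
})

test_that("encode_cohort preserves shape, codomain and permutation structure", {
  cohort <- tiny_cohort()
  enc <- encode_cohort(cohort)
  expect_equal(dim(enc), c(4, 3))
  expect_true(all(enc %in% c(0:2, NA)))
  expect_equal(unname(enc[, "s1"]), c(0L, 1L, 2L, 1L))
  expect_identical(enc["P4", "s2"], NA_integer_)
  # row permutation commutes
  perm <- c(3, 1, 4, 2)
  cohort_p <- genotype_cohort(cohort$variants, cohort$calls[perm, ])
  expect_identical(unclass(encode_cohort(cohort_p)),
                   unclass(enc)[perm, ])
  # all-reference cohort encodes to a zero matrix
  zero <- genotype_cohort(cohort$variants[1:2, ],
                          matrix(c("A/A", "A/A", "C/C", "C/C"), 2,
                                 dimnames = list(c("a", "b"), NULL)))
  expect_true(all(encode_cohort(zero) == 0L))
})

test_that("encoded dosages equal simulated truth dosages without noise", {
  spec <- synthetic_spec(n_samples = 50, n_snps = 40, n_causal = 2,
                         causal_coefficients = c(1, -1), missing_rate = 0,
                         fraction_multiallelic = 0, fraction_offref = 0,
                         seed = 4)
  sim <- simulate_cohort(spec)
  enc <- encode_cohort(sim$cohort)
  expect_equal(unclass(enc), sim$truth$dosages, ignore_attr = TRUE)
})

test_that("coefficient tables round-trip exactly, including edge cases", {
  sites <- tibble::tibble(
    site_id = c("RP1", "RP2", "RP37", "RP38"),
    chrom = c("1", "2", "19", "22"), pos = c(123L, 456L, 789L, 101112L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    coefficient = c(-0.2603, -0.25247, 0.279084, 0.305607))
  tab <- coefficient_table(sites, intercept = -0.11, alpha = 0.5,
                           lambda = 0.034, threshold = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(tab, path)
  back <- read_coefficients(path)
  expect_identical(back$sites$coefficient, tab$sites$coefficient)
  expect_identical(back$intercept, tab$intercept)
  expect_identical(back$lambda, tab$lambda)

  # intercept-only table is valid and scores as the intercept alone
  empty <- coefficient_table(tab$sites[0, ], intercept = 0.7)
  write_coefficients(empty, path)
  back <- read_coefficients(path)
  expect_equal(nrow(back$sites), 0)
  enc <- encode_cohort(tiny_cohort())
  sc <- score_rpi(enc, back)
  expect_equal(sc$rpi, rep(plogis(0.7), 4))

  # fuzzed random tables round-trip to full precision
  withr::with_seed(8, {
    for (i in 1:20) {
      k <- sample(0:6, 1)
      rnd <- coefficient_table(
        tibble::tibble(site_id = sprintf("m%d", seq_len(k)),
                       chrom = as.character(sample(1:22, k, TRUE)),
                       pos = sample.int(1e8, k),
                       ref = sample(c("A", "C", "G", "T"), k, TRUE),
                       alt = sample(c("A", "C", "G", "T"), k, TRUE),
                       coefficient = rnorm(k) * 10^sample(-8:4, k, TRUE)),
        intercept = rnorm(1), alpha = runif(1), lambda = rexp(1))
      write_coefficients(rnd, path)
      got <- read_coefficients(path)
      expect_identical(got$sites$coefficient, rnd$sites$coefficient)
      expect_identical(got$intercept, rnd$intercept)
    }
  })
})

test_that("malformed coefficient files are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# intercept=0", "site_id\tchrom\tpos\tref\talt\tcoefficient",
               "m1\t1\t5\tA\tG\tnot_a_number"), path)
  expect_error(read_coefficients(path), "non-numeric coefficient")
  dup <- tibble::tibble(site_id = c("m1", "m1"), chrom = "1", pos = 1L,
                        ref = "A", alt = "G", coefficient = 0.5)
  expect_error(coefficient_table(dup, intercept = 0), "duplicate")
})

test_that("phenotype reading validates endpoint consistency and ranges", {
  path <- withr::local_tempfile()
  ph <- tibble::tibble(sample_id = c("a", "b"), rp_grade = c(0L, 3L),
                       endpoint = c(0L, 1L), v20 = c(20, 25),
                       total_dose = c(60, 55))
  readr::write_tsv(ph, path)
  expect_equal(read_phenotypes(path)$endpoint, c(0L, 1L))
  ph$endpoint <- c(1L, 1L)
  readr::write_tsv(ph, path)
  expect_error(read_phenotypes(path), "inconsistent")
  ph$endpoint <- c(0L, 1L); ph$v20 <- c(20, 120)
  readr::write_tsv(ph, path)
  expect_error(read_phenotypes(path), "v20")
})
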