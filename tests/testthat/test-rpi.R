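test_that("cohort splitting partitions samples deterministically", {
  ids <- sprintf("P%03d", 1:118)
  plan <- split_cohort(ids, n_train = 90, seed = 1)
  expect_length(plan$training, 90)
  expect_length(plan$validation, 28)
  expect_length(intersect(plan$training, plan$validation), 0)
  expect_setequal(c(plan$training, plan$validation), ids)
  expect_identical(split_cohort(ids, 90, seed = 1), plan)
  expect_false(identical(split_cohort(ids, 90, seed = 2)$training,
                         plan$training))
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(5:200, 1); k <- sample(seq_len(n - 1), 1)
      ids_i <- sprintf("s%d", seq_len(n))
      p <- split_cohort(ids_i, k, seed = i)
      expect_length(p$training, k)
      expect_setequal(c(p$training, p$validation), ids_i)
      expect_length(intersect(p$training, p$validation), 0)
    }
  })
  expect_error(split_cohort(ids, 118, seed = 1), "smaller")
  expect_error(split_cohort(c("a", "a", "b"), 1), "unique")
})

scoring_fixture <- function() {
  enc <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("RP1", "RP2")))
  model <- coefficient_table(
    tibble::tibble(site_id = c("RP1", "RP2"), chrom = c("1", "2"),
                   pos = c(10L, 20L), ref = c("A", "C"), alt = c("G", "T"),
                   coefficient = c(-0.2603, 0.305607)),
    intercept = 0)
  list(enc = enc, model = model)
}

test_that("RPI is the sigmoid of the coefficient-weighted dosage sum", {
  f <- scoring_fixture()
  sc <- score_rpi(f$enc, f$model)
  eta <- f$enc %*% c(-0.2603, 0.305607)
  expect_equal(sc$linear_predictor, as.vector(eta))
  expect_equal(sc$rpi, plogis(as.vector(eta)))
  # single-site closed form: dosage 2 at coefficient -0.2603
  one <- score_rpi(f$enc[, "RP1", drop = FALSE],
                   coefficient_table(f$model$sites[1, ], intercept = 0))
  expect_equal(one$rpi[3], plogis(-0.5206))
  # all dosages zero with zero intercept gives exactly 0.5
  zero <- score_rpi(matrix(0L, 2, 1, dimnames = list(c("u", "v"), "RP1")),
                    coefficient_table(f$model$sites[1, ], intercept = 0))
  expect_equal(zero$rpi, c(0.5, 0.5))
  # monotone in the linear predictor
  expect_identical(order(sc$rpi), order(sc$linear_predictor))
})

test_that("scoring is invariant to site order and validates site identity", {
  f <- scoring_fixture()
  sc1 <- score_rpi(f$enc, f$model)
  flipped <- coefficient_table(f$model$sites[2:1, ], intercept = 0)
  sc2 <- score_rpi(f$enc, flipped)
  expect_equal(sc1$rpi, sc2$rpi)
  # missing model site
  bad <- coefficient_table(
    tibble::tibble(site_id = "ABSENT", chrom = "1", pos = 5L, ref = "A",
                   alt = "G", coefficient = 1),
    intercept = 0)
  expect_error(score_rpi(f$enc, bad), "ABSENT")
  # ref/alt mismatch against cohort metadata
  variants <- tibble::tibble(site_id = c("RP1", "RP2"), chrom = c("1", "2"),
                             pos = c(10L, 20L), ref = c("A", "C"),
                             alt = list("C", "T"))
  expect_error(score_rpi(f$enc, f$model, variants = variants), "mismatch")
})

test_that("missing dosages are mean-imputed or rejected per configuration", {
  f <- scoring_fixture()
  enc <- f$enc
  enc[2, 1] <- NA_integer_
  sc <- score_rpi(enc, f$model)
  imputed <- mean(c(0, 2))
  expect_equal(sc$linear_predictor[2],
               imputed * -0.2603 + 0 * 0.305607)
  expect_error(score_rpi(enc, f$model, missing = "error"), "missing")
})

test_that("covariate effects fold into the intercept at training means", {
  f <- scoring_fixture()
  with_cov <- coefficient_table(
    f$model$sites, intercept = -1, covariates = tibble::tibble(
      term = c("age", "mld"), estimate = c(0.02, 0.05), mean = c(60, 11.6)))
  sc_fold <- score_rpi(f$enc, with_cov)
  sc_ignore <- score_rpi(f$enc, with_cov, covariate_mode = "ignore")
  offset <- 0.02 * 60 + 0.05 * 11.6
  expect_equal(sc_fold$linear_predictor, sc_ignore$linear_predictor + offset)
})

test_that("classification at the threshold is strict", {
  expect_equal(classify_rpi(c(0.51, 0.49, 0.5)), c(1L, 0L, 0L))
  f <- scoring_fixture()
  sc <- score_rpi(f$enc, f$model)
  expect_equal(sc$predicted_class, classify_rpi(sc, 0.5))
  # a threshold sweep gives a monotone (non-increasing) positive count
  thr <- seq(0, 1, by = 0.05)
  pos <- vapply(thr, function(t) sum(classify_rpi(sc, t)), integer(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("evaluation reproduces confusion arithmetic and conventions", {
  # 33 positives with 4 false negatives; 57 negatives, none false positive
  truth <- rep(c(1, 0), c(33, 57))
  pred <- c(rep(1, 29), rep(0, 4), rep(0, 57))
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$tp, 29); expect_equal(ev$fn, 4)
  expect_equal(format_percent(ev$sensitivity), "87.9%")
  expect_equal(format_percent(ev$specificity), "100.0%")
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, ev$n)
  # permutation invariance over samples
  perm <- withr::with_seed(4, sample(length(truth)))
  expect_equal(evaluate_predictions(pred[perm], truth[perm]), ev)
  # perfect prediction
  ev2 <- evaluate_predictions(truth, truth)
  expect_equal(c(ev2$sensitivity, ev2$specificity), c(1, 1))
  # undefined sensitivity without positives
  ev3 <- evaluate_predictions(rep(0, 5), rep(0, 5))
  expect_true(is.na(ev3$sensitivity))
  expect_equal(ev3$specificity, 1)
  expect_error(evaluate_predictions(c(1, 0), c(1)), "equal length")
})
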