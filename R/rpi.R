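#' Randomly split a cohort into training and validation sets
#'
#' Uniform random partition without replacement (not stratified by outcome),
#' deterministic under the seed. Default sizes mirror a 90-training /
#' 28-validation split of a 118-patient cohort.
#'
#' @param ids Character vector of sample ids.
#' @param n_train Training-set size (default 90; must be < `length(ids)`).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: `training`, `validation`, `seed`.
#' @export
split_cohort <- function(ids, n_train = 90, seed = 1) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  n_train <- assert_count(n_train, "n_train", min = 1L)
  if (n_train >= length(ids)) {
    abort("`n_train` must be smaller than the number of samples.")
  }
  training <- withr::with_seed(seed, sample(ids, n_train))
  structure(list(training = sort(training),
                 validation = sort(setdiff(ids, training)), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d training / %d validation (seed %d)\n",
              length(x$training), length(x$validation), x$seed))
  invisible(x)
}

#' Compute the Radiation Pneumonitis Index
#'
#' For each sample, `RPI = sigmoid(intercept + sum_i A_i * C_i)` where `A_i`
#' is the encoded 0/1/2 value at selected site `i` and `C_i` its model
#' coefficient. When the model carries penalty-exempt covariate effects,
#' their contribution at the stored training means is folded into the
#' intercept by default (`covariate_mode = "fold"`), keeping the score a pure
#' genotype index on a calibrated probability scale; `"ignore"` drops them.
#'
#' Every model site must be present in the dosage matrix (matching ref/alt
#' when `variants` metadata is supplied); missing dosage entries are
#' mean-imputed per site by default, or rejected with `missing = "error"`.
#'
#' @param encoded Dosage matrix from [encode_cohort()] (samples x sites).
#' @param model A [coefficient_table()].
#' @param variants Optional variant metadata of the scored cohort for
#'   ref/alt consistency checking.
#' @param missing `"impute_mean"` (default) or `"error"`.
#' @param covariate_mode `"fold"` (default) or `"ignore"`.
#' @return Tibble of class `rpi_result`: `sample_id`, `linear_predictor`,
#'   `rpi`, `predicted_class` (1 iff rpi strictly exceeds the model
#'   threshold).
#' @export
score_rpi <- function(encoded, model, variants = NULL,
                      missing = c("impute_mean", "error"),
                      covariate_mode = c("fold", "ignore")) {
  missing <- match.arg(missing)
  covariate_mode <- match.arg(covariate_mode)
  if (!inherits(model, "coefficient_table")) {
    abort("`model` must be a coefficient_table.")
  }
  m <- unclass(encoded)
  storage.mode(m) <- "double"
  absent <- setdiff(model$sites$site_id, colnames(m))
  if (length(absent)) {
    abort(sprintf("model site(s) absent from the dosage matrix: %s",
                  paste(absent, collapse = ", ")))
  }
  if (!is.null(variants) && nrow(model$sites)) {
    v <- tibble::as_tibble(variants)
    i <- match(model$sites$site_id, v$site_id)
    alt1 <- if (is.list(v$alt)) vapply(v$alt[i], `[`, "", 1) else as.character(v$alt[i])
    mism <- which(!is.na(model$sites$ref) &
                    (v$ref[i] != model$sites$ref | alt1 != model$sites$alt))
    if (length(mism)) {
      abort(sprintf("ref/alt mismatch between model and cohort at: %s",
                    paste(model$sites$site_id[mism], collapse = ", ")))
    }
  }
  a <- m[, model$sites$site_id, drop = FALSE]
  if (anyNA(a)) {
    if (missing == "error") {
      abort("missing dosage entries at model sites (missing = 'error').")
    }
    mu <- colMeans(a, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(a), arr.ind = TRUE)
    a[idx] <- mu[idx[, 2]]
  }
  intercept <- model$intercept
  if (covariate_mode == "fold" && !is.null(model$covariates) &&
      nrow(model$covariates)) {
    intercept <- intercept + sum(model$covariates$estimate * model$covariates$mean)
  }
  eta <- intercept + as.vector(a %*% model$sites$coefficient)
  out <- tibble::tibble(sample_id = rownames(m), linear_predictor = eta,
                        rpi = sigmoid(eta),
                        predicted_class = as.integer(sigmoid(eta) > model$threshold))
  attr(out, "threshold") <- model$threshold
  class(out) <- c("rpi_result", class(out))
  out
}

#' Classify RPI scores at a threshold
#'
#' Strict rule: class 1 iff `rpi > threshold`; a score exactly at the
#' threshold is classified negative.
#'
#' @param rpi An `rpi_result` tibble (or numeric vector of scores).
#' @param threshold Probability threshold (default 0.5).
#' @return Integer vector of 0/1 classes.
#' @export
classify_rpi <- function(rpi, threshold = 0.5) {
  scores <- if (is.data.frame(rpi)) rpi$rpi else rpi
  as.integer(scores > threshold)
}

#' Confusion counts, sensitivity and specificity
#'
#' @param predicted Binary 0/1 predictions.
#' @param truth Binary 0/1 ground truth of the same length.
#' @return Tibble of class `evaluation_report` with one row: `tp`, `fp`,
#'   `tn`, `fn`, `n`, `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP). A metric whose denominator is zero is `NA` (not
#'   applicable). Proportions are unrounded; see [format_percent()] for the
#'   display convention.
#' @export
evaluate_predictions <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  if (!all(predicted %in% 0:1) || !all(truth %in% 0:1)) {
    abort("`predicted` and `truth` must be binary 0/1.")
  }
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Display a proportion as a percentage, one decimal place, half-up
#'
#' @param x Proportion in `[0, 1]`.
#' @return Character like `"87.9%"`.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f%%", round_half_up(100 * x, 1)))
}

#' Fit the whole RPI pipeline on an encoded cohort
#'
#' Convenience wrapper chaining quality control, design construction,
#' bootstrap stability selection and the final refit into one call; returns
#' the portable coefficient table plus the intermediate results.
#'
#' @param cohort A [genotype_cohort()].
#' @param phenotypes Phenotype tibble with `sample_id` and `endpoint`.
#' @param covariates Covariate columns included penalty-exempt (default
#'   none).
#' @param thresholds [qc_thresholds()].
#' @param alpha,n_bootstraps,seed,... Passed to [stability_select()].
#' @return List of class `rpi_pipeline`: `qc`, `design`, `stability`,
#'   `model`.
#' @export
rpi_pipeline <- function(cohort, phenotypes, covariates = character(),
                         thresholds = qc_thresholds(), alpha = 0.5,
                         n_bootstraps = 500, seed = 1, ...) {
  ph <- tibble::as_tibble(phenotypes)
  qc <- apply_qc(cohort, thresholds)
  ph <- ph[match(sample_ids(qc$cohort), ph$sample_id), ]
  design <- build_design(qc$encoded, ph, covariates)
  y <- ph$endpoint
  stability <- stability_select(design, y, alpha = alpha,
                                n_bootstraps = n_bootstraps, seed = seed, ...)
  model <- final_model(design, y, stability, alpha = alpha,
                       seed = derive_seed(seed, 0L),
                       variants = qc$cohort$variants)
  structure(list(qc = qc, design = design, stability = stability,
                 model = model), class = "rpi_pipeline")
}
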