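#' Bootstrap stability selection with a majority-inclusion rule
#'
#' The cohort is resampled with replacement `n_bootstraps` times (default
#' 500) and a penalized model is fitted to each bootstrap cohort. A marker is
#' "present" in a bootstrap when its coefficient is nonzero at that
#' bootstrap's chosen lambda; markers present in more than
#' `inclusion_threshold` of all bootstraps form the selected set.
#' Penalty-exempt covariates are always retained and take no part in the
#' selection rule. A bootstrap that draws a single outcome class is redrawn
#' (the event is counted in the result).
#'
#' Two lambda policies are available: `lambda_mode = "cv"` (default,
#' the literal reading of per-bootstrap model building) re-runs k-fold
#' cross-validation inside every bootstrap; `"fixed"` fits each bootstrap at
#' one fixed lambda (`fixed_lambda`), which is much faster.
#'
#' @param x Design matrix or [build_design()] object.
#' @param y Binary 0/1 outcome.
#' @param alpha Elastic-net mixing parameter.
#' @param n_bootstraps Number of bootstrap resamples (default 500).
#' @param inclusion_threshold Selection rule: frequency strictly greater
#'   than this (default 0.5).
#' @param seed Integer seed; the whole procedure is reproducible under it.
#' @param lambda_mode `"cv"` or `"fixed"`.
#' @param lambda_rule `"1se"` (default) or `"min"`: which CV lambda a
#'   bootstrap uses (cv mode).
#' @param fixed_lambda Lambda for `"fixed"` mode.
#' @param n_folds,nlambda,lambda_min_ratio,thresh,maxit Passed to the inner
#'   CV / solver.
#' @param max_redraws Redraw budget for degenerate bootstraps (default 100).
#' @param penalty_factor Per-column penalty factors.
#' @return Object of class `stability_result`: `markers` (tibble: term,
#'   count, frequency, selected), `selected` (character vector),
#'   `n_bootstraps`, `inclusion_threshold`, `n_redraws`, `alpha`, `seed`.
#' @export
stability_select <- function(x, y, alpha = 0.5, n_bootstraps = 500,
                             inclusion_threshold = 0.5, seed = 1,
                             lambda_mode = c("cv", "fixed"),
                             lambda_rule = c("1se", "min"),
                             fixed_lambda = NULL, n_folds = 10,
                             nlambda = 100, lambda_min_ratio = 1e-3,
                             thresh = 1e-6, maxit = 100,
                             max_redraws = 100, penalty_factor = NULL) {
  if (inherits(x, "design_matrix")) {
    penalty_factor <- penalty_factor %||% x$penalty_factor
    x <- x$x
  }
  y <- check_xy(x, y)
  lambda_mode <- match.arg(lambda_mode)
  lambda_rule <- match.arg(lambda_rule)
  if (lambda_mode == "fixed" && is.null(fixed_lambda)) {
    abort("`fixed_lambda` is required when lambda_mode = 'fixed'.")
  }
  n_bootstraps <- assert_count(n_bootstraps, "n_bootstraps", min = 1L)
  pf <- penalty_factor %||% rep(1, ncol(x))
  n <- nrow(x)
  pen_cols <- colnames(x)[pf > 0]

  counts <- setNames(integer(length(pen_cols)), pen_cols)
  n_redraws <- 0L

  withr::with_seed(seed, {
    for (b in seq_len(n_bootstraps)) {
      idx <- sample.int(n, n, replace = TRUE)
      redraw <- 0L
      while (length(unique(y[idx])) < 2 && redraw < max_redraws) {
        idx <- sample.int(n, n, replace = TRUE)
        redraw <- redraw + 1L
      }
      if (length(unique(y[idx])) < 2) {
        abort("could not draw a bootstrap with both outcome classes.")
      }
      n_redraws <- n_redraws + redraw
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      sdb <- apply(xb, 2, stats::sd)
      keep <- sdb > 0
      cv_seed <- derive_seed(seed, b)
      coefs <- if (lambda_mode == "cv") {
        cv <- cv_lambda(xb[, keep, drop = FALSE], yb, alpha = alpha,
                        n_folds = n_folds, seed = cv_seed, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio,
                        penalty_factor = pf[keep], groups = idx,
                        thresh = thresh, maxit = maxit)
        cv_coefficients(cv, lambda_rule)$coefficients
      } else {
        fit <- fit_enet(xb[, keep, drop = FALSE], yb, alpha = alpha,
                        lambda = fixed_lambda, penalty_factor = pf[keep],
                        thresh = thresh, maxit = maxit)
        fit$coefficients
      }
      nz <- names(coefs)[coefs != 0]
      hit <- intersect(nz, pen_cols)
      counts[hit] <- counts[hit] + 1L
    }
  })

  freq <- counts / n_bootstraps
  markers <- tibble::tibble(term = pen_cols, count = unname(counts),
                            frequency = unname(freq),
                            selected = unname(freq > inclusion_threshold))
  structure(list(markers = markers,
                 selected = markers$term[markers$selected],
                 n_bootstraps = n_bootstraps,
                 inclusion_threshold = inclusion_threshold,
                 n_redraws = n_redraws, alpha = alpha, seed = seed,
                 lambda_mode = lambda_mode, lambda_rule = lambda_rule),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d bootstraps (%s lambda): %d of %d markers selected at frequency > %.2f\n",
              x$n_bootstraps, x$lambda_mode, length(x$selected),
              nrow(x$markers), x$inclusion_threshold))
  if (x$n_redraws > 0) cat(sprintf("  degenerate bootstraps redrawn: %d\n", x$n_redraws))
  invisible(x)
}

#' Refit the final model on the stability-selected markers
#'
#' The design is restricted to the selected markers plus the penalty-exempt
#' covariates, lambda is re-chosen by cross-validation on the restricted
#' design, and the model is refitted at that lambda. The result is exported
#' as a portable [coefficient_table()] (with the covariate effects and their
#' training means attached when covariates are present). An empty selection
#' with no covariates yields an intercept-only table, not an error.
#'
#' @param x Design matrix or [build_design()] object.
#' @param y Binary 0/1 outcome.
#' @param stability A [stability_select()] result.
#' @param alpha Elastic-net mixing parameter.
#' @param seed Seed for the restricted-design CV folds.
#' @param variants Optional variant metadata tibble (`site_id`, `chrom`,
#'   `pos`, `ref`, `alt`) used to annotate the coefficient table.
#' @param lambda_rule `"min"` (default) or `"1se"` on the restricted-design
#'   CV. Selection is already settled by the stability rule; the refit's job
#'   is calibrated prediction, for which the minimum-deviance lambda is the
#'   natural choice.
#' @param threshold Classification threshold stored in the table
#'   (default 0.5).
#' @param n_folds,nlambda,lambda_min_ratio,thresh,maxit Solver / CV controls.
#' @return A [coefficient_table()].
#' @export
final_model <- function(x, y, stability, alpha = 0.5, seed = 1,
                        variants = NULL, lambda_rule = c("min", "1se"),
                        threshold = 0.5, n_folds = 10, nlambda = 100,
                        lambda_min_ratio = 1e-4, thresh = 1e-10,
                        maxit = 100) {
  if (inherits(x, "design_matrix")) {
    pf_all <- x$penalty_factor
    x <- x$x
  } else {
    pf_all <- rep(1, ncol(x))
    names(pf_all) <- colnames(x)
  }
  y <- check_xy(x, y)
  lambda_rule <- match.arg(lambda_rule)
  selected <- stability$selected
  cov_cols <- colnames(x)[pf_all == 0]
  keep <- c(selected, cov_cols)

  if (!length(keep)) {
    # null model: intercept only
    return(coefficient_table(empty_sites(), intercept = qlogis(mean(y)),
                             alpha = alpha, lambda = NA_real_,
                             threshold = threshold))
  }
  xr <- x[, keep, drop = FALSE]
  pfr <- pf_all[keep]
  if (!length(selected)) {
    # covariates only: unpenalized logistic fit
    fit <- fit_enet(xr, y, alpha = alpha, lambda = 0, penalty_factor = pfr,
                    thresh = thresh, maxit = maxit)
    lam <- 0
  } else {
    cv <- cv_lambda(xr, y, alpha = alpha, n_folds = n_folds, seed = seed,
                    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                    penalty_factor = pfr, thresh = thresh, maxit = maxit)
    lam <- if (lambda_rule == "1se") cv$lambda_1se else cv$lambda_min
    fit <- fit_enet(xr, y, alpha = alpha, lambda = lam, penalty_factor = pfr,
                    thresh = thresh, maxit = maxit)
  }

  site_coef <- fit$coefficients[selected]
  sites <- annotate_sites(selected, site_coef, variants)
  covariates <- NULL
  if (length(cov_cols)) {
    covariates <- tibble::tibble(term = cov_cols,
                                 estimate = unname(fit$coefficients[cov_cols]),
                                 mean = unname(colMeans(xr[, cov_cols, drop = FALSE])))
  }
  coefficient_table(sites, intercept = fit$intercept, alpha = alpha,
                    lambda = lam, threshold = threshold,
                    covariates = covariates)
}

empty_sites <- function() {
  tibble::tibble(site_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), coefficient = numeric())
}

annotate_sites <- function(site_ids, coefs, variants) {
  if (!length(site_ids)) return(empty_sites())
  out <- tibble::tibble(site_id = site_ids, chrom = NA_character_,
                        pos = NA_integer_, ref = NA_character_,
                        alt = NA_character_, coefficient = unname(coefs))
  if (!is.null(variants)) {
    v <- tibble::as_tibble(variants)
    i <- match(out$site_id, v$site_id)
    out$chrom <- as.character(v$chrom[i])
    out$pos <- as.integer(v$pos[i])
    out$ref <- as.character(v$ref[i])
    alt <- v$alt[i]
    out$alt <- if (is.list(alt)) vapply(alt, function(a) a[1] %||% NA_character_,
                                        character(1)) else as.character(alt)
  }
  out
}
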