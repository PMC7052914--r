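#' 10-fold cross-validated lambda selection
#'
#' Fits the full elastic-net path (warm-started, descending lambda grid) on
#' each training fold and scores binomial deviance on the held-out fold.
#' Folds are stratified by outcome so every training fold contains both
#' classes. Reports the minimum-deviance lambda and the one-standard-error
#' lambda, plus the full-data path fit at every grid point.
#'
#' @param x Design matrix (no missing values) or [build_design()] object.
#' @param y Binary 0/1 outcome.
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param nlambda Lambda grid size (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`
#'   (default 1e-3).
#' @param penalty_factor Per-column penalty factors.
#' @param groups Optional integer vector (one per row) of provenance groups:
#'   rows sharing a group are assigned to the same fold. Used for CV inside
#'   bootstrap resamples, where duplicate copies of one original sample must
#'   not be split across training and validation folds (the split would leak
#'   and bias lambda low).
#' @param thresh,maxit Convergence controls passed to the solver.
#' @return Object of class `enet_cv`: `metrics` (tibble: lambda,
#'   mean_deviance, se_deviance, nonzero), `lambda_min`, `lambda_1se`,
#'   `path` (full-data coefficient matrix on the input scale, features x
#'   lambdas), `intercepts`, `alpha`, `seed`.
#' @export
cv_lambda <- function(x, y, alpha = 0.5, n_folds = 10, seed = 1,
                      nlambda = 100, lambda_min_ratio = 1e-3,
                      penalty_factor = NULL, groups = NULL,
                      thresh = 1e-7, maxit = 100) {
  if (inherits(x, "design_matrix")) {
    penalty_factor <- penalty_factor %||% x$penalty_factor
    x <- x$x
  }
  y <- check_xy(x, y)
  n <- nrow(x)
  if (n < n_folds) abort("`n_folds` must not exceed the sample count.")
  pf <- penalty_factor %||% rep(1, ncol(x))

  lmax <- lambda_max(x, y, alpha = alpha, penalty_factor = pf)
  lambdas <- lambda_grid(lmax, nlambda, lambda_min_ratio)

  # full-data path first, with the usual early truncation once the fitted
  # deviance saturates; folds then share the truncated grid exactly
  std <- standardize_design(x)
  full <- enet_path_std(std$xs, y, lambdas, alpha, pf, thresh,
                        maxit_outer = maxit, maxit_inner = 1e5, fdev = 1e-5)
  lambdas <- lambdas[seq_len(full$nlam_used)]
  beta_full <- sweep(full$beta[, seq_along(lambdas), drop = FALSE], 1,
                     std$sd, "/")
  rownames(beta_full) <- colnames(x)
  b0_full <- full$b0[seq_along(lambdas)] - colSums(beta_full * std$mu)
  nonzero <- colSums(beta_full[pf > 0, , drop = FALSE] != 0)

  folds <- withr::with_seed(seed, {
    if (is.null(groups)) {
      stratified_folds(y, n_folds)
    } else {
      if (length(groups) != n) abort("`groups` must have one entry per row.")
      ug <- unique(groups)
      gy <- y[match(ug, groups)]
      gf <- stratified_folds(gy, n_folds)
      gf[match(groups, ug)]
    }
  })
  for (k in seq_len(n_folds)) {
    if (length(unique(y[folds != k])) < 2) {
      abort("a training fold contains a single outcome class; reduce n_folds.")
    }
  }

  dev <- matrix(NA_real_, n_folds, length(lambdas))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    stdk <- standardize_design(x[tr, , drop = FALSE])
    fit <- enet_path_std(stdk$xs, y[tr], lambdas, alpha, pf, thresh,
                         maxit_outer = maxit, maxit_inner = 1e5)
    beta <- sweep(fit$beta, 1, stdk$sd, "/")
    b0 <- fit$b0 - colSums(beta * stdk$mu)
    eta <- sweep(x[!tr, , drop = FALSE] %*% beta, 2, b0, "+")
    pr <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    yv <- y[!tr]
    dev[k, ] <- -2 * colMeans(yv * log(pr) + (1 - yv) * log(1 - pr))
  }
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2, stats::sd) / sqrt(n_folds)

  i_min <- which.min(mean_dev)
  lambda_min <- lambdas[i_min]
  ok_1se <- mean_dev <= mean_dev[i_min] + se_dev[i_min]
  lambda_1se <- lambdas[which(ok_1se)[1]]  # grid is descending

  structure(list(
    metrics = tibble::tibble(lambda = lambdas, mean_deviance = mean_dev,
                             se_deviance = se_dev, nonzero = nonzero),
    lambda_min = lambda_min, lambda_1se = lambda_1se,
    path = beta_full, intercepts = b0_full, penalty_factor = pf,
    alpha = alpha, n_folds = n_folds, seed = seed),
    class = "enet_cv")
}

stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Extract the fitted model at a chosen lambda from a CV result
#'
#' @param cv An [cv_lambda()] result.
#' @param rule `"1se"` (default) or `"min"`, or a numeric lambda (matched to
#'   the nearest grid point).
#' @return List with `lambda`, `intercept`, `coefficients` (named, input
#'   scale).
#' @export
cv_coefficients <- function(cv, rule = c("1se", "min")) {
  if (is.numeric(rule)) {
    i <- which.min(abs(cv$metrics$lambda - rule))
  } else {
    rule <- match.arg(rule)
    lam <- if (rule == "1se") cv$lambda_1se else cv$lambda_min
    i <- match(lam, cv$metrics$lambda)
  }
  list(lambda = cv$metrics$lambda[i], intercept = cv$intercepts[i],
       coefficients = cv$path[, i])
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf("<enet_cv> %d-fold, alpha=%.2f, %d lambdas\n",
              x$n_folds, x$alpha, nrow(x$metrics)))
  cmin <- cv_coefficients(x, "min"); c1se <- cv_coefficients(x, "1se")
  cat(sprintf("  lambda_min = %.5g (%d nonzero)   lambda_1se = %.5g (%d nonzero)\n",
              x$lambda_min, sum(cmin$coefficients[x$penalty_factor > 0] != 0),
              x$lambda_1se, sum(c1se$coefficients[x$penalty_factor > 0] != 0)))
  invisible(x)
}
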