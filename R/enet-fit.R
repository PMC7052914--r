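#' Build a design matrix from encoded dosages and covariates
#'
#' Columns are the SNP dosage columns followed by the clinical covariate
#' columns. SNP columns get penalty factor 1; covariates get penalty factor 0
#' (penalty-exempt, always retained by the penalty). Missing dosages are
#' mean-imputed per column (site-level QC already caps missingness);
#' constant columns are dropped with a message.
#'
#' @param encoded An [encode_cohort()] dosage matrix (or any numeric matrix
#'   samples x markers).
#' @param phenotypes Optional data frame holding the covariate columns, rows
#'   aligned to `encoded` by `sample_id`.
#' @param covariates Character vector of covariate column names in
#'   `phenotypes` to append unpenalized (default none).
#' @return List of class `design_matrix`: `x`, `penalty_factor`,
#'   `snp_cols`, `covariate_cols`, `dropped`.
#' @export
build_design <- function(encoded, phenotypes = NULL, covariates = character()) {
  x <- unclass(encoded)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  snp_cols <- colnames(x)
  if (length(covariates)) {
    if (is.null(phenotypes)) abort("`phenotypes` needed to pull covariate columns.")
    ph <- tibble::as_tibble(phenotypes)
    missing_cov <- setdiff(covariates, names(ph))
    if (length(missing_cov)) {
      abort(sprintf("covariate column(s) not in `phenotypes`: %s",
                    paste(missing_cov, collapse = ", ")))
    }
    if ("sample_id" %in% names(ph)) {
      if (!setequal(ph$sample_id, rownames(x))) {
        abort("`phenotypes` and `encoded` carry different sample ids.")
      }
      ph <- ph[match(rownames(x), ph$sample_id), ]
    }
    cov_m <- as.matrix(ph[covariates])
    storage.mode(cov_m) <- "double"
    x <- cbind(x, cov_m)
  }
  pf <- c(rep(1, length(snp_cols)), rep(0, length(covariates)))
  names(pf) <- colnames(x)
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    message(sprintf("dropping %d constant column(s): %s%s", length(dropped),
                    paste(utils::head(dropped, 3), collapse = ", "),
                    if (length(dropped) > 3) ", ..." else ""))
    x <- x[, keep, drop = FALSE]
    pf <- pf[keep]
  }
  structure(list(x = x, penalty_factor = pf,
                 snp_cols = intersect(snp_cols, colnames(x)),
                 covariate_cols = intersect(covariates, colnames(x)),
                 dropped = dropped),
            class = "design_matrix")
}

standardize_design <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))  # 1/n variance
  # a column constant in this (sub)sample carries no signal: standardize to
  # the all-zero column, whose coefficient stays exactly 0
  sdev[sdev == 0] <- 1
  list(xs = sweep(sweep(x, 2, mu), 2, sdev, "/"), mu = mu, sd = sdev)
}

check_xy <- function(x, y) {
  if (!is.matrix(x)) abort("`x` must be a numeric matrix.")
  if (anyNA(x)) abort("`x` must not contain missing values (impute upstream).")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) abort("`y` length must match nrow(x).")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  if (nrow(x) < 2) abort("need at least 2 samples.")
  y
}

#' Smallest penalty that zeroes every penalized coefficient
#'
#' Computed from the null-model gradient: the model containing only the
#' intercept and the penalty-exempt covariates is fitted first, and
#' `lambda_max = max_j |<x_j_std, y - p_null>| / (n * alpha * pf_j)` over the
#' penalized columns. For `alpha < 0.001` the mixing parameter is floored at
#' 0.001 for this computation (the pure-ridge path has no finite zeroing
#' penalty).
#'
#' @param x Design matrix (no missing values).
#' @param y Binary outcome vector.
#' @param alpha Elastic-net mixing parameter.
#' @param penalty_factor Per-column penalty factors (default all 1).
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(x, y, alpha = 0.5, penalty_factor = NULL) {
  y <- check_xy(x, y)
  pf <- penalty_factor %||% rep(1, ncol(x))
  std <- standardize_design(x)
  n <- nrow(x)
  if (any(pf == 0)) {
    null_fit <- enet_path_std(std$xs, y, lambdas = 1e30, alpha = alpha, pf = pf,
                              thresh = 1e-10, maxit_outer = 100,
                              maxit_inner = 1e4)
    eta <- null_fit$b0[1] + std$xs %*% null_fit$beta[, 1]
    p0 <- plogis(as.vector(eta))
  } else {
    p0 <- rep(mean(y), n)
  }
  g <- abs(crossprod(std$xs, y - p0)) / n
  a <- max(alpha, 0.001)
  pen <- pf > 0
  max(g[pen] / (a * pf[pen]))
}

#' Log-spaced lambda path
#'
#' @param lmax Largest lambda (typically [lambda_max()]).
#' @param nlambda Number of grid points (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of `lmax`
#'   (default 1e-3).
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(lmax, nlambda = 100, lambda_min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

enet_path_std <- function(xs, y, lambdas, alpha, pf, thresh, maxit_outer,
                          maxit_inner, beta_init = NULL, b0_init = NULL,
                          fdev = 0, devmax = 0.999) {
  p <- ncol(xs)
  beta_init <- beta_init %||% rep(0, p)
  b0_init <- b0_init %||% qlogis(pmin(pmax(mean(y), 1e-5), 1 - 1e-5))
  enet_logistic_path_cpp(xs, y, as.numeric(lambdas), alpha, as.numeric(pf),
                         thresh, as.integer(maxit_outer),
                         as.integer(maxit_inner), as.numeric(beta_init),
                         b0_init, fdev, devmax)
}

#' Fit a penalized logistic model by elastic-net coordinate descent
#'
#' Cyclic coordinate descent on the IRLS-weighted least-squares surrogate.
#' Penalized columns are soft-thresholded with strength
#' `alpha * lambda * penalty_factor` and ridge term
#' `(1 - alpha) * lambda * penalty_factor`; columns with penalty factor 0 and
#' the intercept are updated without shrinkage. The design is standardized
#' internally (mean 0, 1/n-variance 1) and coefficients are returned on the
#' input scale.
#'
#' @param x Design matrix (samples x features, no missing values), or a
#'   [build_design()] object.
#' @param y Binary 0/1 outcome vector.
#' @param alpha Mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength (scalar; >= 0).
#' @param penalty_factor Per-column penalty multipliers (default all 1;
#'   ignored when `x` is a `design_matrix`, which carries its own).
#' @param thresh Convergence threshold on the weighted squared coordinate
#'   update (default 1e-10).
#' @param maxit Maximum IRLS iterations (default 100).
#' @return Object of class `enet_fit`: intercept, named `coefficients`,
#'   `alpha`, `lambda`, `penalty_factor`, `n_iterations`, `converged`,
#'   `objective` (penalized negative log-likelihood, per-observation scale).
#' @export
fit_enet <- function(x, y, alpha = 0.5, lambda, penalty_factor = NULL,
                     thresh = 1e-10, maxit = 100) {
  if (inherits(x, "design_matrix")) {
    penalty_factor <- penalty_factor %||% x$penalty_factor
    x <- x$x
  }
  y <- check_xy(x, y)
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (length(lambda) != 1 || lambda < 0) abort("`lambda` must be a scalar >= 0.")
  pf <- penalty_factor %||% rep(1, ncol(x))
  if (length(pf) != ncol(x) || any(pf < 0)) {
    abort("`penalty_factor` must be non-negative, one per column.")
  }
  std <- standardize_design(x)
  fit <- enet_path_std(std$xs, y, lambdas = lambda, alpha = alpha, pf = pf,
                       thresh = thresh, maxit_outer = maxit,
                       maxit_inner = 1e5)
  if (!fit$converged[1]) {
    if (lambda == 0) {
      abort(paste("unpenalized fit diverged (no convergence at lambda = 0);",
                  "the data are likely separable. Increase lambda."))
    }
    warn(sprintf("fit_enet did not converge in %d IRLS iterations.", maxit))
  }
  beta_std <- fit$beta[, 1]
  beta <- beta_std / std$sd
  intercept <- fit$b0[1] - sum(beta * std$mu)
  structure(list(intercept = intercept,
                 coefficients = setNames(beta, colnames(x)),
                 alpha = alpha, lambda = lambda, penalty_factor = pf,
                 n_iterations = fit$iterations[1],
                 converged = fit$converged[1], objective = fit$objective[1],
                 standardization = list(mu = std$mu, sd = std$sd),
                 beta_std = beta_std, b0_std = fit$b0[1]),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0 & x$penalty_factor > 0)
  cat(sprintf("<enet_fit> alpha=%.2f lambda=%.5g: %d nonzero penalized coefficient(s), objective %.6f%s\n",
              x$alpha, x$lambda, nz, x$objective,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# KKT residual of an enet_fit on the standardized scale; used by tests and
# available for diagnostics. For beta_j != 0 the stationarity residual, for
# beta_j = 0 the amount by which the subgradient bound is violated.
kkt_residual <- function(fit, x, y) {
  std <- fit$standardization
  xs <- sweep(sweep(x, 2, std$mu), 2, std$sd, "/")
  eta <- fit$b0_std + xs %*% fit$beta_std
  pr <- plogis(as.vector(eta))
  g <- -crossprod(xs, y - pr) / nrow(x)   # gradient of (1/n) NLL
  lam <- fit$lambda; a <- fit$alpha; pf <- fit$penalty_factor
  res <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    bj <- fit$beta_std[j]
    if (pf[j] == 0 || bj != 0) {
      res[j] <- abs(g[j] + lam * (1 - a) * pf[j] * bj +
                      lam * a * pf[j] * sign(bj))
    } else {
      res[j] <- max(0, abs(g[j]) - lam * a * pf[j])
    }
  }
  c(res, intercept = abs(sum(y - pr)) / nrow(x))
}
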