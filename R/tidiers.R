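#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per model term (or marker, or site); `glance()`
#' returns a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name rpindex-tidiers
NULL

#' @rdname rpindex-tidiers
#' @export
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)),
                 penalized = c(FALSE, x$penalty_factor > 0))
}

#' @rdname rpindex-tidiers
#' @export
glance.enet_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_nonzero = sum(x$coefficients != 0 & x$penalty_factor > 0),
                 objective = x$objective, n_iterations = x$n_iterations,
                 converged = x$converged)
}

#' @rdname rpindex-tidiers
#' @export
tidy.enet_cv <- function(x, ...) x$metrics

#' @rdname rpindex-tidiers
#' @export
glance.enet_cv <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_folds = x$n_folds,
                 lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
                 nonzero_min = sum(cv_coefficients(x, "min")$coefficients[x$penalty_factor > 0] != 0),
                 nonzero_1se = sum(cv_coefficients(x, "1se")$coefficients[x$penalty_factor > 0] != 0))
}

#' @rdname rpindex-tidiers
#' @export
tidy.stability_result <- function(x, ...) x$markers

#' @rdname rpindex-tidiers
#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(n_bootstraps = x$n_bootstraps,
                 inclusion_threshold = x$inclusion_threshold,
                 n_selected = length(x$selected), n_redraws = x$n_redraws,
                 alpha = x$alpha, lambda_mode = x$lambda_mode)
}

#' @rdname rpindex-tidiers
#' @export
tidy.coefficient_table <- function(x, ...) x$sites

#' @rdname rpindex-tidiers
#' @export
glance.coefficient_table <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$sites), intercept = x$intercept,
                 alpha = x$alpha, lambda = x$lambda, threshold = x$threshold,
                 n_covariates = if (is.null(x$covariates)) 0L else nrow(x$covariates))
}

#' @rdname rpindex-tidiers
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(sensitivity = format_percent(x$sensitivity),
                 specificity = format_percent(x$specificity))
}
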