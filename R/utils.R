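#' @importFrom stats plogis qlogis rbinom rnorm runif rbeta setNames median
#' @importFrom utils head
#' @importFrom rlang abort warn `%||%`
#' @useDynLib rpindex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) stats::plogis(x)

# round half up at `digits` decimals; base round() is half-to-even
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 allow_upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", field))
  }
  hi_ok <- if (allow_upper_open) x < upper else x <= upper
  if (x < lower || !hi_ok) {
    abort(sprintf("`%s` must be in [%s, %s%s; got %s.", field, lower, upper,
                  if (allow_upper_open) ")" else "]", format(x)))
  }
  invisible(x)
}

assert_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", field, min))
  }
  invisible(as.integer(x))
}

# deterministic child seeds (kept below .Machine$integer.max) so that nested
# procedures (CV inside bootstrap) are reproducible without sharing one stream
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}
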