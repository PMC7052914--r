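#' Construct a coefficient table
#'
#' The portable artifact of a fitted model: the selected SNP sites with their
#' log-odds coefficients `C_i`, the model intercept, the elastic-net
#' hyper-parameters used, the classification threshold, and (when the fit
#' included penalty-exempt clinical covariates) the covariate effects with
#' their training means so scoring can fold them into the intercept.
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `coefficient`. May have zero rows (intercept-only model).
#' @param intercept Model intercept (log-odds).
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength (>= 0).
#' @param threshold Classification threshold on the probability scale.
#' @param covariates Optional tibble with columns `term`, `estimate`, `mean`.
#' @return Object of class `coefficient_table`.
#' @export
coefficient_table <- function(sites, intercept, alpha = NA_real_,
                              lambda = NA_real_, threshold = 0.5,
                              covariates = NULL) {
  sites <- tibble::as_tibble(sites)
  req <- c("site_id", "chrom", "pos", "ref", "alt", "coefficient")
  if (!all(req %in% names(sites))) {
    abort(sprintf("`sites` must have columns %s.", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(sites$site_id)) abort("duplicate site_id in coefficient table.")
  if (any(!is.finite(sites$coefficient))) abort("coefficients must be finite.")
  assert_scalar_number(intercept, "intercept")
  if (!is.na(alpha)) assert_scalar_number(alpha, "alpha", 0, 1)
  if (!is.na(lambda) && lambda < 0) abort("`lambda` must be >= 0.")
  assert_scalar_number(threshold, "threshold")
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!all(c("term", "estimate", "mean") %in% names(covariates))) {
      abort("`covariates` must have columns term, estimate, mean.")
    }
  }
  structure(list(sites = sites[req], intercept = intercept, alpha = alpha,
                 lambda = lambda, threshold = threshold,
                 covariates = covariates),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf("<coefficient_table> %d sites, intercept %.5g (alpha=%s, lambda=%s, threshold=%s)\n",
              nrow(x$sites), x$intercept, format(x$alpha), format(x$lambda),
              format(x$threshold)))
  if (!is.null(x$covariates) && nrow(x$covariates)) {
    cat(sprintf("  + %d penalty-exempt covariates\n", nrow(x$covariates)))
  }
  invisible(x)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write / read a coefficient table
#'
#' TSV with columns `site_id`, `chrom`, `pos`, `ref`, `alt`, `coefficient`;
#' the intercept, alpha, lambda and threshold (and any covariate effects)
#' live in a commented `# key=value` header block. Numeric values are written
#' with 17 significant digits, so the round trip is exact.
#'
#' @param table A [coefficient_table()].
#' @param path File path.
#' @return `write_coefficients()` returns `path` invisibly;
#'   `read_coefficients()` returns a `coefficient_table`.
#' @export
write_coefficients <- function(table, path) {
  if (!inherits(table, "coefficient_table")) {
    abort("`table` must be a coefficient_table.")
  }
  con <- file(path, "wb")
  writeLines(c(sprintf("# intercept=%s", fmt_full(table$intercept)),
               sprintf("# alpha=%s", fmt_full(table$alpha)),
               sprintf("# lambda=%s", fmt_full(table$lambda)),
               sprintf("# threshold=%s", fmt_full(table$threshold))), con)
  if (!is.null(table$covariates)) {
    writeLines(sprintf("# covariate\t%s\t%s\t%s", table$covariates$term,
                       fmt_full(table$covariates$estimate),
                       fmt_full(table$covariates$mean)), con)
  }
  writeLines("site_id\tchrom\tpos\tref\talt\tcoefficient", con)
  if (nrow(table$sites)) {
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s\t%s", table$sites$site_id,
                       table$sites$chrom, as.integer(table$sites$pos),
                       table$sites$ref, table$sites$alt,
                       fmt_full(table$sites$coefficient)), con)
  }
  close(con)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_key <- function(key) {
    ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(sprintf("^# %s=", key), "", ln[1])))
  }
  cov_lines <- grep("^# covariate\t", hdr, value = TRUE)
  covariates <- NULL
  if (length(cov_lines)) {
    parts <- strsplit(sub("^# covariate\t", "", cov_lines), "\t", fixed = TRUE)
    covariates <- tibble::tibble(
      term = vapply(parts, `[`, "", 1),
      estimate = as.numeric(vapply(parts, `[`, "", 2)),
      mean = as.numeric(vapply(parts, `[`, "", 3)))
  }
  if (!length(body) || body[1] != "site_id\tchrom\tpos\tref\talt\tcoefficient") {
    abort("coefficient file: missing or malformed column header.")
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(parts) != 6L)) abort("coefficient file: malformed row.")
    coef_chr <- vapply(parts, `[`, "", 6)
    coefficient <- suppressWarnings(as.numeric(coef_chr))
    if (anyNA(coefficient)) {
      abort(sprintf("non-numeric coefficient at data row %d.",
                    which(is.na(coefficient))[1]))
    }
    sites <- tibble::tibble(
      site_id = vapply(parts, `[`, "", 1),
      chrom = vapply(parts, `[`, "", 2),
      pos = as.integer(vapply(parts, `[`, "", 3)),
      ref = vapply(parts, `[`, "", 4),
      alt = vapply(parts, `[`, "", 5),
      coefficient = coefficient)
  } else {
    sites <- tibble::tibble(site_id = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), coefficient = numeric())
  }
  intercept <- get_key("intercept")
  if (is.na(intercept)) abort("coefficient file: missing `# intercept=` header.")
  threshold <- get_key("threshold")
  if (is.na(threshold)) threshold <- 0.5
  coefficient_table(sites, intercept = intercept, alpha = get_key("alpha"),
                    lambda = get_key("lambda"),
                    threshold = threshold, covariates = covariates)
}
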