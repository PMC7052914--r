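#' Reference-relative 0/1/2 dosage encoding
#'
#' Each allele of a call is compared with the GRCh37-style site definition:
#' an allele equal to the designed alternative (ALT) contributes 1, an allele
#' equal to the reference (REF, the "wild type") contributes 0, and an allele
#' matching neither contributes 0. The site value is the sum of the two
#' allelic values, an integer in 0..2; a missing call stays missing. Allele
#' order is irrelevant ("A/G" and "G/A" encode alike), and phased calls are
#' treated like unphased ones upstream.
#'
#' @param call Character vector of allele-pair calls ("A/G"), `NA` = missing.
#' @param ref Reference allele (single string).
#' @param alt Designed alternative allele (single string; the site must be
#'   biallelic).
#' @return Integer vector in `{0, 1, 2, NA}`.
#' @export
encode_site <- function(call, ref, alt) {
  if (length(alt) != 1L) {
    abort("`alt` must be a single allele: run QC (multi-allelic exclusion) first.")
  }
  out <- rep(NA_integer_, length(call))
  ok <- !is.na(call)
  if (any(ok)) {
    parts <- strsplit(call[ok], "[/|]")
    if (any(lengths(parts) != 2L)) abort("calls must be allele pairs like 'A/G'.")
    m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    out[ok] <- (m[, 1] == alt) + (m[, 2] == alt)
  }
  out
}

#' Encode a cohort to a samples x sites dosage matrix
#'
#' Applies [encode_site()] column-wise. All sites must be biallelic
#' (one designed ALT); run [apply_qc()] first to drop multi-allelic sites.
#'
#' @param cohort A [genotype_cohort()].
#' @return An integer matrix of class `encoded_matrix` (samples x sites,
#'   entries 0/1/2 or `NA`).
#' @export
encode_cohort <- function(cohort) {
  if (!inherits(cohort, "genotype_cohort")) {
    abort("`cohort` must be a genotype_cohort.")
  }
  multi <- is_multiallelic(cohort)
  if (any(multi)) {
    abort(sprintf(
      "%d multi-allelic site(s) present (e.g. %s): apply QC before encoding.",
      sum(multi), names(multi)[multi][1]))
  }
  v <- cohort$variants
  out <- matrix(NA_integer_, nrow(cohort$calls), ncol(cohort$calls),
                dimnames = dimnames(cohort$calls))
  for (j in seq_len(nrow(v))) {
    out[, j] <- encode_site(cohort$calls[, j], v$ref[j], v$alt[[j]])
  }
  class(out) <- c("encoded_matrix", class(out))
  out
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d samples x %d sites, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname encode_cohort
#' @param x An `encoded_matrix`.
#' @param ... Unused.
#' @export
tidy.encoded_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    site_id = rep(colnames(x), each = nrow(x)),
    dosage = as.integer(x))
}
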