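#' Construct a genotype cohort
#'
#' A cohort is a variant metadata table plus a samples x sites matrix of
#' literal allele-pair calls ("A/G"; `NA` = missing). Alleles are compared as
#' the strings given; no strand flipping or allele harmonisation is applied.
#'
#' @param variants Tibble with columns `site_id`, `chrom`, `pos`, `ref`,
#'   `alt` (character vector or list-column of designed ALT alleles) and
#'   optionally `mean_gencall` in `[0, 1]`.
#' @param calls Character matrix, rows = samples (rownames = sample ids),
#'   columns = sites in `variants` order.
#' @return Object of class `genotype_cohort`.
#' @export
genotype_cohort <- function(variants, calls) {
  variants <- tibble::as_tibble(variants)
  req <- c("site_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    abort(sprintf("`variants` must have columns %s.", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(variants$site_id)) {
    abort("duplicate site_id in `variants`.")
  }
  if (!is.list(variants$alt)) variants$alt <- as.list(variants$alt)
  if (any(variants$pos < 1)) abort("`pos` must be >= 1 (1-based coordinates).")
  bad <- purrr::map2_lgl(variants$ref, variants$alt, function(r, a) r %in% a)
  if (any(bad)) abort("`ref` allele listed among `alt` alleles.")
  if (!is.matrix(calls) || !is.character(calls)) {
    abort("`calls` must be a character matrix.")
  }
  if (ncol(calls) != nrow(variants)) {
    abort("`calls` must have one column per variant.")
  }
  if (is.null(rownames(calls))) abort("`calls` must have sample ids as rownames.")
  if (anyDuplicated(rownames(calls))) abort("duplicate sample ids.")
  colnames(calls) <- variants$site_id
  structure(list(variants = variants, calls = calls), class = "genotype_cohort")
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat(sprintf("<genotype_cohort> %d samples x %d sites (%d multi-allelic)\n",
              nrow(x$calls), ncol(x$calls), sum(is_multiallelic(x))))
  invisible(x)
}

#' @rdname genotype_cohort
#' @param x A `genotype_cohort`.
#' @export
sample_ids <- function(x) rownames(x$calls)

#' Designed multi-allelic flag per site
#'
#' A site is multi-allelic when its designed ALT list holds more than one
#' allele.
#' @param cohort A `genotype_cohort`.
#' @return Named logical vector over sites.
#' @export
is_multiallelic <- function(cohort) {
  setNames(lengths(cohort$variants$alt) > 1L, cohort$variants$site_id)
}

#' Read genotypes from a VCF or tabular allele-pair file
#'
#' The VCF reader consumes the GT field only; `./.` (or `.`) maps to missing,
#' phased and unphased separators are treated identically, and multi-allelic
#' ALT fields are preserved as allele lists. An `MGC` INFO key, when present,
#' is read as the per-site mean GenCall score. A `DALT` INFO key (written by
#' [write_fixture()]) gives the number of *designed* ALT alleles: extra ALT
#' entries beyond it are alleles observed in calls but not part of the assay
#' design, so the site is not flagged multi-allelic on their account.
#'
#' The `"alleles"` dialect is a TSV with sample rows and site columns holding
#' literal allele pairs ("A/G", "." = missing); it requires a `sites=`
#' metadata TSV (columns `site_id`, `chrom`, `pos`, `ref`, `alt` with
#' comma-separated ALTs, optional `mean_gencall`).
#'
#' @param path File to read.
#' @param format `"vcf"` or `"alleles"`.
#' @param sites Path to the site metadata TSV (alleles dialect only).
#' @return A [genotype_cohort()].
#' @export
read_genotypes <- function(path, format = c("vcf", "alleles"), sites = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "vcf") read_genotypes_vcf(path) else {
    if (is.null(sites)) abort("the alleles dialect needs a `sites` metadata TSV.")
    read_genotypes_alleles(path, sites)
  }
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  site_id <- fix[, "ID"]
  site_id[is.na(site_id) | site_id == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(site_id) | site_id == "."]
  if (anyDuplicated(site_id)) abort("duplicate site_id in VCF.")
  alt_all <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  info <- fix[, "INFO"]
  mgc <- suppressWarnings(as.numeric(sub(".*MGC=([^;]+).*", "\\1", info)))
  mgc[!grepl("MGC=", info)] <- NA_real_
  dalt <- suppressWarnings(as.integer(sub(".*DALT=([^;]+).*", "\\1", info)))
  dalt[!grepl("DALT=", info)] <- NA_integer_
  alt_designed <- purrr::map2(alt_all, dalt, function(a, d) {
    if (is.na(d)) a else a[seq_len(min(d, length(a)))]
  })

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(site_id, names(gt)))
  n_samp <- ncol(gt)
  calls <- matrix(NA_character_, n_samp, nrow(fix),
                  dimnames = list(colnames(gt), site_id))
  for (j in seq_len(nrow(fix))) {
    alleles <- c(fix[j, "REF"], alt_all[[j]])
    g <- gt[j, ]
    ok <- !is.na(g) & !grepl("\\.", g)
    parts <- strsplit(g[ok], "[/|]")
    bad_len <- lengths(parts) != 2L
    if (any(bad_len)) {
      abort(sprintf("malformed GT at site %s (record %d).", site_id[j], j))
    }
    ix <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE) + 1L
    if (any(ix > length(alleles))) {
      abort(sprintf("GT allele index out of range at site %s (record %d).",
                    site_id[j], j))
    }
    calls[ok, j] <- paste0(alleles[ix[, 1]], "/", alleles[ix[, 2]])
  }
  variants <- tibble::tibble(
    site_id = site_id, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
    alt = alt_designed, mean_gencall = mgc)
  genotype_cohort(variants, calls)
}

read_genotypes_alleles <- function(path, sites) {
  meta <- readr::read_tsv(sites, show_col_types = FALSE)
  meta$alt <- strsplit(meta$alt, ",", fixed = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "sample_id") abort("first column must be `sample_id`.")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  m[m == "."] <- NA_character_
  if (!setequal(colnames(m), meta$site_id)) {
    abort("site columns do not match the `sites` metadata.")
  }
  m <- m[, meta$site_id, drop = FALSE]
  genotype_cohort(meta, m)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits `genotypes.vcf` (VCF 4.2 with GT calls, `MGC` = mean GenCall,
#' `DALT` = number of designed ALT alleles), `phenotypes.tsv`, and
#' `truth_sites.tsv` (causal site ids/coefficients plus the intercept as a
#' commented header). Off-reference alleles observed in calls are appended to
#' the record's ALT column (as a variant caller would) and distinguished from
#' designed ALTs via `DALT`, so the files round-trip losslessly through
#' [read_genotypes()]. Identical cohorts produce byte-identical files.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()], or a list with
#'   `cohort` and `phenotypes`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture <- function(sim, dir) {
  cohort <- sim$cohort
  phenotypes <- sim$phenotypes
  if (!identical(sort(sample_ids(cohort)), sort(phenotypes$sample_id))) {
    abort("cohort and phenotypes carry different sample ids.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory: %s", dir))
  paths <- list(genotypes = file.path(dir, "genotypes.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth = file.path(dir, "truth_sites.tsv"))
  write_genotypes_vcf(cohort, paths$genotypes)
  readr::write_tsv(phenotypes, paths$phenotypes)
  if (!is.null(sim$truth)) {
    con <- file(paths$truth, "wb")
    writeLines(sprintf("# intercept=%.17g", sim$truth$intercept), con)
    writeLines("site_id\tcoefficient", con)
    if (nrow(sim$truth$sites)) {
      writeLines(sprintf("%s\t%.17g", sim$truth$sites$site_id,
                         sim$truth$sites$coefficient), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Write a genotype cohort as a VCF 4.2 text file
#'
#' @param cohort A `genotype_cohort`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(cohort, path) {
  v <- cohort$variants
  calls <- cohort$calls
  n <- nrow(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MGC,Number=1,Type=Float,Description=\"Per-site mean GenCall score\">",
    "##INFO=<ID=DALT,Number=1,Type=Integer,Description=\"Number of designed ALT alleles; later ALTs were observed in calls only\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t"))
  body <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    designed <- v$alt[[j]]
    col <- calls[, j]
    seen <- unique(unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE)))
    extra <- setdiff(seen, c(v$ref[j], designed))
    alleles <- c(v$ref[j], designed, extra)
    idx <- setNames(seq_along(alleles) - 1L, alleles)
    gt <- rep("./.", n)
    ok <- !is.na(col)
    parts <- matrix(unlist(strsplit(col[ok], "/", fixed = TRUE)), ncol = 2,
                    byrow = TRUE)
    gt[ok] <- paste0(idx[parts[, 1]], "/", idx[parts[, 2]])
    info <- sprintf("DALT=%d", length(designed))
    if (!is.null(v$mean_gencall) && !is.na(v$mean_gencall[j])) {
      info <- sprintf("%s;MGC=%.6f", info, v$mean_gencall[j])
    }
    body[j] <- paste(c(v$chrom[j], v$pos[j], v$site_id[j], v$ref[j],
                       paste(alleles[-1], collapse = ","), ".", "PASS",
                       info, "GT", gt), collapse = "\t")
  }
  con <- file(path, "wb")  # binary mode: fixed LF endings => byte-identical
  writeLines(c(header, body), con)
  close(con)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Validates the binary endpoint against the pneumonitis grade
#' (`endpoint == (rp_grade >= 2)`), dose non-negativity and percent ranges.
#'
#' @param path TSV with header; must contain `sample_id`, `rp_grade` and/or
#'   `endpoint`.
#' @return Tibble, one row per sample.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(ph)) abort("`sample_id` column required.")
  if ("rp_grade" %in% names(ph)) {
    if (any(ph$rp_grade < 0 | ph$rp_grade > 5)) {
      abort("`rp_grade` must be an integer in 0..5.")
    }
    if (!"endpoint" %in% names(ph)) ph$endpoint <- as.integer(ph$rp_grade >= 2)
    if (any(ph$endpoint != (ph$rp_grade >= 2))) {
      abort("`endpoint` inconsistent with rp_grade >= 2.")
    }
  }
  for (col in intersect(c("v5", "v10", "v20", "v30"), names(ph))) {
    if (any(ph[[col]] < 0 | ph[[col]] > 100, na.rm = TRUE)) {
      abort(sprintf("`%s` must be a percent in [0, 100].", col))
    }
  }
  for (col in intersect(c("total_dose", "fractional_dose", "mld"), names(ph))) {
    if (any(ph[[col]] < 0, na.rm = TRUE)) abort(sprintf("`%s` must be >= 0.", col))
  }
  ph
}
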