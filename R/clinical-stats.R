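#' Exact Fisher test for r x c contingency tables
#'
#' Two-sided exact p-value under the convention that defines the "two-sided"
#' tail as the set of tables (with the observed margins) whose point
#' probability does not exceed that of the observed table, with a relative
#' tolerance of 1e-7 on the comparison. 2 x 2 tables use the hypergeometric
#' distribution directly; larger tables are handled by exhaustive enumeration
#' of all tables with the observed margins (multivariate hypergeometric),
#' guarded by a table-count budget — there is no silent fallback to an
#' approximation.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2
#'   (rows = factor levels, columns = endpoint groups).
#' @param cell_budget Maximum number of tables to enumerate for r x c
#'   tables (default 2e6); exceeding it is an error.
#' @return p-value in `(0, 1]`. A table with a zero row or column margin is
#'   degenerate and returns 1 by convention.
#' @export
fisher_exact <- function(table, cell_budget = 2e6) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    abort("`table` must contain non-negative integer counts.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("`table` must be at least 2 x 2.")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) return(1.0)

  if (nrow(m) == 2 && ncol(m) == 2) {
    # cell (1,1) ranges over the feasible hypergeometric support
    k <- m[1, 1]
    lo <- max(0, cs[1] - rs[2]); hi <- min(rs[1], cs[1])
    support <- lo:hi
    probs <- stats::dhyper(support, rs[1], rs[2], cs[1])
    p_obs <- probs[match(k, support)]
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }
  fisher_exact_rxc(m, rs, cs, cell_budget)
}

fisher_exact_rxc <- function(m, rs, cs, cell_budget) {
  # log point probability of a table with fixed margins:
  #   sum(lfactorial(margins)) - lfactorial(N) - sum(lfactorial(cells))
  log_const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(m))
  logp_obs <- log_const - sum(lfactorial(m))
  tol <- log1p(1e-7)

  r <- nrow(m); cc <- ncol(m)
  n_visited <- 0L
  p_total <- 0

  # enumerate row by row; within a row, cell by cell, tracking remaining
  # column margins; the last row and last cells are forced
  recurse_row <- function(i, col_left, lf_acc) {
    if (i == r) {
      if (any(col_left < 0)) return()
      n_visited <<- n_visited + 1L
      if (n_visited > cell_budget) {
        abort("fisher_exact: table too large to enumerate (cell_budget exceeded).")
      }
      logp <- log_const - lf_acc - sum(lfactorial(col_left))
      if (logp <= logp_obs + tol) p_total <<- p_total + exp(logp)
      return()
    }
    recurse_cell(i, 1L, rs[i], col_left, lf_acc)
  }
  recurse_cell <- function(i, j, row_left, col_left, lf_acc) {
    if (j == cc) {
      if (row_left > col_left[j]) return()
      col_left[j] <- col_left[j] - row_left
      recurse_row(i + 1L, col_left, lf_acc + lfactorial(row_left))
      return()
    }
    upper <- min(row_left, col_left[j])
    for (x in 0:upper) {
      cl <- col_left; cl[j] <- cl[j] - x
      recurse_cell(i, j + 1L, row_left - x, cl, lf_acc + lfactorial(x))
    }
  }
  recurse_row(1L, cs, 0)
  min(1, p_total)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact permutation null when both samples have at
#' most 12 observations and the pooled data are tie-free, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `statistic` (U for the first sample) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Screen clinical factors for association with the grade >= 2 endpoint
#'
#' One test per factor, exactly as clinical baseline tables are screened:
#' continuous factors by the Mann-Whitney U test, categorical factors by the
#' exact Fisher test on the factor x endpoint contingency table. No
#' multiplicity adjustment is applied.
#'
#' @param phenotypes Data frame with an `endpoint` column (0/1) and the
#'   factors to screen.
#' @param factors Character vector of columns to test; defaults to every
#'   column except `sample_id`, `endpoint` and `rp_grade`.
#' @param continuous Character vector naming which of `factors` are
#'   continuous; defaults to the numeric columns with more than 3 distinct
#'   values.
#' @return Tibble with one row per factor: `factor`, `type`, `test`,
#'   `statistic` (U; `NA` for Fisher), `p_value`, per-group summaries and a
#'   degeneracy `note`.
#' @export
screen_factors <- function(phenotypes, factors = NULL, continuous = NULL) {
  ph <- tibble::as_tibble(phenotypes)
  if (!"endpoint" %in% names(ph)) abort("`phenotypes` must have an `endpoint` column.")
  if (anyNA(ph$endpoint)) abort("`endpoint` must be defined for every sample.")
  y <- as.integer(ph$endpoint)
  if (!all(y %in% 0:1)) abort("`endpoint` must be binary 0/1.")
  factors <- factors %||% setdiff(names(ph), c("sample_id", "endpoint", "rp_grade"))
  if (is.null(continuous)) {
    continuous <- factors[vapply(factors, function(f) {
      is.numeric(ph[[f]]) && length(unique(ph[[f]])) > 3
    }, logical(1))]
  }

  rows <- purrr::map(factors, function(f) {
    v <- ph[[f]]
    is_cont <- f %in% continuous
    if (length(unique(v[!is.na(v)])) < 2) {
      return(tibble::tibble(
        factor = f, type = if (is_cont) "continuous" else "categorical",
        test = "none", statistic = NA_real_, p_value = 1,
        group1_summary = NA_character_, group2_summary = NA_character_,
        note = "constant factor (degenerate)"))
    }
    if (is_cont) {
      x1 <- v[y == 1]; x0 <- v[y == 0]
      res <- mann_whitney_u(x1, x0)
      summ <- function(z) sprintf("%s-%s (%s)", format(min(z)), format(max(z)),
                                  format(median(z)))
      tibble::tibble(factor = f, type = "continuous", test = "mann_whitney_u",
                     statistic = res$statistic, p_value = res$p_value,
                     group1_summary = summ(x1), group2_summary = summ(x0),
                     note = NA_character_)
    } else {
      tab <- table(factor(v), factor(y, levels = c(1, 0)))
      p <- fisher_exact(unclass(tab))
      summ <- function(col) paste(sprintf("%s:%d", rownames(tab), tab[, col]),
                                  collapse = " ")
      tibble::tibble(factor = f, type = "categorical", test = "fisher_exact",
                     statistic = NA_real_, p_value = p,
                     group1_summary = summ("1"), group2_summary = summ("0"),
                     note = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}
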