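# Independent oracles, kept deliberately naive and separate from the
# package's implementations.

# Exact HWE test by direct enumeration: log-factorial formula for the
# conditional probability of each heterozygote count given allele counts.
hwe_oracle <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  rare <- min(2 * n_homref + n_het, 2 * n_homalt + n_het)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    ha <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(ha) + h * log(2)
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact 2x2 Fisher by direct enumeration of every table with the observed
# margins, via the log-factorial point-probability formula.
fisher2x2_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (any(rs == 0) || any(cs == 0)) return(1.0)
  logp <- function(a) {
    tab <- c(a, rs[1] - a, cs[1] - a, rs[2] - (cs[1] - a))
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(tab))
  }
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  lp <- vapply(support, logp, numeric(1))
  p <- exp(lp)
  p_obs <- p[match(m[1, 1], support)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Mann-Whitney exact two-sided p by full enumeration of group assignments.
mw_oracle <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (N - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# A tiny hand-built cohort: 4 samples x 3 biallelic sites.
tiny_cohort <- function() {
  variants <- tibble::tibble(
    site_id = c("s1", "s2", "s3"), chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 50L), ref = c("A", "C", "G"),
    alt = list("G", "T", "A"), mean_gencall = c(0.95, 0.9, 0.99))
  calls <- matrix(c("A/A", "A/G", "G/G", "A/G",
                    "C/C", "C/C", "C/T", NA,
                    "G/G", "G/A", "A/A", "G/G"),
                  nrow = 4,
                  dimnames = list(paste0("P", 1:4), NULL))
  genotype_cohort(variants, calls)
}
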