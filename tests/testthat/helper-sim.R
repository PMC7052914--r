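# Small logistic design generator shared across solver tests.
sim_logistic <- function(n, p, beta, seed, intercept = 0, binary_x = FALSE) {
  withr::with_seed(seed, {
    x <- if (binary_x) matrix(rbinom(n * p, 2, 0.3), n)
         else matrix(rnorm(n * p), n)
    colnames(x) <- paste0("x", seq_len(p))
    y <- rbinom(n, 1, plogis(intercept + x %*% c(beta, rep(0, p - length(beta)))))
    list(x = x, y = y)
  })
}
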