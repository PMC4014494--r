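# Independent oracles used across test files.

# Brute-force two-sided signed-rank p-value: enumerate every sign
# assignment of the absolute differences and count positive-rank sums at
# least as extreme as the observed one (two-sided, doubled-tail
# convention).  Exponential in n; usable for n <= 12.
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Short map series for estimator tests.
logistic_series <- function(n, r = 4, x0 = 0.41, n_transient = 100) {
  iterate_map(logistic_map(r, x0), n, n_transient)
}
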