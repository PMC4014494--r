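make_curve <- function(S, eps = 1) {
  structure(data.frame(dn = seq_along(S) - 1L, S = S, n_ref = 50L),
            eps = eps, m = 2L, d = 1L, n_ref_total = 50L,
            class = c("stretching_curve", "data.frame"))
}

test_that("slope fitting recovers exact and piecewise-linear curves", {
  est <- fit_lyapunov(make_curve(c(0, 0.7, 1.4, 2.1)), c(0, 3))
  expect_equal(est$lambda, 0.7)
  expect_equal(est$r_squared, 1)
  expect_length(est$flags, 0)

  flat <- fit_lyapunov(make_curve(rep(-2, 8)), c(1, 7))
  expect_equal(flat$lambda, 0)

  piece <- make_curve(c(seq(0, 2.5, by = 0.5), rep(2.5, 6)))  # bend at dn 5
  est2 <- fit_lyapunov(piece, c(0, 5))
  expect_lt(abs(est2$lambda - 0.5) / 0.5, 0.05)
  expect_error(fit_lyapunov(piece, c(2, 3)), "at least 3")
})

test_that("stretching curves are flat for periodic and reject constant input", {
  per <- rep(c(10, 25, 40, 30, 15), 60)
  cv <- kantz_stretching(per, eps = 2, m = 2, d = 1, t_max = 6)
  expect_lt(diff(range(cv$S)), 1e-6)
  expect_error(kantz_stretching(rep(7, 100), eps = 1), "identical")
  expect_error(estimate_max_lyapunov(rep(7, 200)), "zero variance")
})

test_that("neighbour counts and gates behave", {
  set.seed(1)
  x <- rnorm(300)
  expect_error(kantz_stretching(x, eps = 1e-9), "neighbours")
  cv <- kantz_stretching(x, eps = 2, t_max = 5)
  expect_true(all(cv$n_ref == cv$n_ref[1]))
  expect_gte(cv$n_ref[1], 10)
})

test_that("the Benettin oracle matches analytic exponents", {
  expect_lt(abs(oracle_map_lyapunov(logistic_map(4), 50000) - log(2)), 0.01)
  expect_lt(oracle_map_lyapunov(logistic_map(3.2), 20000), 0)
  ident <- list(f = function(x) x, jac = function(x) matrix(1, 1, 1),
                x0 = 0.5)
  expect_equal(oracle_map_lyapunov(ident, 1000), 0)
})

test_that("estimates are invariant under a constant shift of the series", {
  x <- logistic_series(2000)
  e1 <- estimate_max_lyapunov(x)
  e2 <- estimate_max_lyapunov(x + 1000)
  expect_equal(e1$lambda, e2$lambda, tolerance = 1e-9)
})

test_that("the Theiler window excludes temporal neighbours by default", {
  # strongly autocorrelated signal: temporal neighbours fake convergence,
  # so switching the exclusion off must lower the apparent exponent
  x <- logistic_series(1500)
  xs <- as.numeric(stats::filter(x, rep(1 / 4, 4), sides = 1))
  xs <- xs[!is.na(xs)]
  eps <- popchaos:::default_eps_schedule(xs, 2, 1)[2]
  s_default <- kantz_stretching(xs, eps = eps)       # theiler = d*(m-1)+1
  s_zero <- kantz_stretching(xs, eps = eps, theiler = 0)
  lam_default <- fit_lyapunov(s_default, c(1, 4))$lambda
  lam_zero <- fit_lyapunov(s_zero, c(1, 4))$lambda
  expect_lt(lam_zero, lam_default)
})

test_that("regular dynamics are reported as non-chaotic", {
  sine <- sin(2 * pi * (1:2000) / 40)
  es <- estimate_max_lyapunov(sine)
  expect_lte(es$lambda, 0.05)
  expect_false(is_chaotic(es))
})
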