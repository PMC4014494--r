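make_table <- function(lambda_by_conc, age_class = "total",
                       flagged = FALSE) {
  rows <- do.call(rbind, lapply(names(lambda_by_conc), function(cc) {
    lam <- lambda_by_conc[[cc]]
    data.frame(concentration = as.numeric(cc), age_class = age_class,
               run = seq_along(lam), lambda = lam, flagged = flagged)
  }))
  lyapunov_table(rows)
}

test_that("treatment summaries use mean and n-1 standard deviation", {
  tab <- make_table(list(`0` = c(0.5, 0.5, 0.5), `40` = c(0.2, 0.4)))
  s <- summarize_lyapunov(tab)
  expect_equal(s$mean[s$concentration == 0], 0.5)
  expect_equal(s$sd[s$concentration == 0], 0)
  expect_equal(s$mean[s$concentration == 40], 0.3)
  expect_equal(s$sd[s$concentration == 40], sqrt(0.02), tolerance = 1e-6)
  expect_error(summarize_lyapunov(make_table(list(`0` = 0.1))), "fewer than 2")
})

test_that("signed-rank p-values match hand enumeration and degenerate rules", {
  expect_equal(wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))$p_value, 0.25)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  expect_error(wilcoxon_signed_rank(c(1, 2), c(0, 0)), "at least 3")
  # antisymmetric differences: compare against brute-force enumeration
  a <- c(1.3, -1.3, 0.4, -0.4)
  w <- wilcoxon_signed_rank(a, rep(0, 4))
  expect_equal(w$p_value, brute_force_signed_rank(a))
})

test_that("exact p-values equal brute force for all small samples", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 3 || any(duplicated(abs(d)))) next
    ours <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_true(ours$exact)
    expect_equal(ours$p_value, brute_force_signed_rank(d))
    ref <- stats::wilcox.test(d, alternative = "two.sided")$p.value
    expect_equal(ours$p_value, ref)
  }
})

test_that("the normal approximation agrees with the reference implementation", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(60)
    b <- rnorm(60, 0.2)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               exact = FALSE,
                                               correct = TRUE))$p.value
    expect_false(ours$exact)
    expect_equal(ours$p_value, ref, tolerance = 1e-10)
  }
  # ties force the approximate path even for small n
  tied <- wilcoxon_signed_rank(c(1, 1, 2, 3), c(0, 0, 0, 0))
  expect_false(tied$exact)
})

test_that("rejection rates grow with the shift between paired samples", {
  set.seed(13)
  rates <- vapply(c(0, 0.05, 0.2), function(shift) {
    mean(replicate(150, {
      a <- rnorm(30, sd = 0.05)
      b <- rnorm(30, shift, sd = 0.05)
      wilcoxon_signed_rank(a, b)$p_value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[3], 0.9)
})

test_that("pairwise testing covers all concentration pairs by run pairing", {
  set.seed(14)
  lam <- list(`0` = rnorm(100, 0.5, 0.05), `2.5` = rnorm(100, 0.5, 0.05),
              `5` = rnorm(100, 0.5, 0.05), `10` = rnorm(100, 0.5, 0.05),
              `20` = rnorm(100, 0.5, 0.05), `40` = rnorm(100, 0.3, 0.05))
  pt <- pairwise_tests(make_table(lam))
  expect_identical(nrow(pt$pairs), 15L)          # C(6, 2)
  top <- pt$pairs[pt$pairs$conc_b == 40, "p"]
  expect_true(all(top < 1e-6))

  same <- make_table(list(`0` = c(1, 2, 3), `40` = c(1, 2, 3)))
  expect_true(is.na(pairwise_tests(same)$pairs$p))
})

test_that("threshold detection returns the lowest significant concentration", {
  fake <- function(p) {
    pairs <- data.frame(conc_a = 0, conc_b = c(2.5, 5, 10), p = p, n = 20)
    structure(list(p = NULL, pairs = pairs, age_class = "total",
                   adjust = "none", panel = c(0, 2.5, 5, 10)),
              class = "pairwise_test_matrix")
  }
  expect_true(is.na(detect_threshold(fake(c(0.5, 0.9, 0.2)))$threshold))
  expect_equal(detect_threshold(fake(c(0.5, 0.9, 0.01)))$threshold, 10)
  expect_equal(detect_threshold(fake(c(0.01, 0.02, 0.001)))$threshold, 2.5)
  # monotone in alpha: a stricter level can only raise (or drop) it
  p <- c(0.04, 0.5, 0.001)
  t_loose <- detect_threshold(fake(p), alpha = 0.05)$threshold
  t_strict <- detect_threshold(fake(p), alpha = 0.01)$threshold
  expect_true(t_strict >= t_loose)
})
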