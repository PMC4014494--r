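test_that("transient removal drops exactly the leading samples", {
  x <- seq_len(366)
  expect_length(drop_transient(x, 50), 316)
  expect_identical(drop_transient(x, 50), 51:366)
  expect_identical(drop_transient(x, 0), x)
  expect_error(drop_transient(seq_len(50), 50), "exceed")
})

test_that("autocorrelation is the biased sample estimator", {
  set.seed(1)
  x <- rnorm(300)
  a <- autocorrelation(x, 20)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf) <= 1))
  # hand-computed r(k) with the 1/N denominator
  xc <- x - mean(x)
  r3 <- sum(xc[1:297] * xc[4:300]) / sum(xc^2)
  expect_equal(a$acf[a$lag == 3], r3)

  alt <- rep(c(1, -1), 100)
  expect_lte(autocorrelation(alt, 1)$acf[2], -1 + 1 / 200)

  sine <- sin(2 * pi * (1:2000) / 20)
  as <- autocorrelation(sine, 40)$acf
  expect_gt(as[21], 0.95)                       # lag 20 = full period
  expect_true(as[21] > as[20] && as[21] > as[22])   # local peak at period
  expect_error(autocorrelation(rep(2, 50), 5), "constant")
})

test_that("delay embedding enumerates lagged coordinate vectors exactly", {
  y <- delay_embed(c(1, 2, 3, 4), m = 3, d = 1)
  expect_equal(unclass(y)[, ], matrix(c(1, 2, 2, 3, 3, 4), nrow = 2),
               ignore_attr = TRUE)
  expect_identical(nrow(delay_embed(1:10, m = 2, d = 3)), 7L)
  expect_equal(as.numeric(delay_embed(5:9, m = 1, d = 4)), 5:9)
  expect_error(delay_embed(1:3, m = 4, d = 1), "too short")
})

test_that("embedding count formula and projection hold for random sizes", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    m <- sample(1:4, 1)
    d <- sample(1:5, 1)
    if (n - (m - 1) * d < 1) next
    x <- rnorm(n)
    y <- delay_embed(x, m, d)
    expect_identical(nrow(y), as.integer(n - (m - 1) * d))
    expect_equal(y[, 1], x[seq_len(nrow(y))])
  }
})

test_that("sine autocorrelation is periodic with the signal period", {
  sine <- sin(2 * pi * (1:1500) / 33)
  a <- autocorrelation(sine, 66)$acf
  # local peak within +/- 1 sample of the period
  peak <- 32 + which.max(a[33:35])
  expect_true(a[peak] > a[peak - 2] && a[peak] > a[peak + 2])
  expect_gt(a[peak], 0.9)
})

test_that("embedding scan recommends sensible delays and honours candidates", {
  set.seed(2)
  noise <- rnorm(600)
  expect_identical(scan_embedding(noise)$recommended_d, 1L)
  sine <- sin(2 * pi * (1:800) / 40)
  d_rec <- scan_embedding(sine)$recommended_d
  expect_true(d_rec >= 7 && d_rec <= 11)        # near the quarter period
  one <- scan_embedding(noise, m_candidates = 3, d_candidates = 2)
  expect_identical(unlist(one$best), c(m = 3L, d = 2L))
})
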