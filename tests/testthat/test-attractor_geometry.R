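test_that("recurrence matrices match enumerable cases", {
  const <- recurrence_matrix(delay_embed(rep(3, 10), 2, 1), eps = 0.5)
  expect_true(all(const == 1L))

  inc <- recurrence_matrix(delay_embed(seq(0, 20, by = 2), 1, 1), eps = 1)
  expect_equal(unclass(inc)[, ], diag(1L, 11), ignore_attr = TRUE)

  p5 <- rep(c(0, 10, 20, 30, 40), 8)
  rp <- recurrence_matrix(delay_embed(p5, 2, 1), eps = 2)
  idx <- seq_len(nrow(rp))
  expect_identical(unname(rp == 1L),
                   outer(idx, idx, function(i, j) (i - j) %% 5 == 0))
  expect_error(recurrence_matrix(delay_embed(p5, 2, 1), eps = 0), "positive")
})

test_that("recurrence is symmetric, reflexive and monotone in eps", {
  set.seed(3)
  y <- delay_embed(rnorm(80), 2, 1)
  r1 <- recurrence_matrix(y, eps = 0.4)
  r2 <- recurrence_matrix(y, eps = 1.1)
  expect_identical(unclass(r1), t(unclass(r1)))
  expect_true(all(diag(r1) == 1L))
  expect_true(all(r1 <= r2))
})

test_that("determinism score separates structured from irregular dynamics", {
  const <- recurrence_matrix(delay_embed(rep(3, 12), 2, 1), eps = 0.5)
  expect_equal(determinism_score(const), 1)

  inc <- recurrence_matrix(delay_embed(seq(0, 30, by = 2), 1, 1), eps = 1)
  expect_equal(suppressWarnings(as.numeric(determinism_score(inc))), 0)
  expect_warning(determinism_score(inc), "no off-diagonal")

  p5 <- rep(c(0, 10, 20, 30, 40), 10)
  rp <- recurrence_matrix(delay_embed(p5, 2, 1), eps = 2)
  expect_equal(as.numeric(determinism_score(rp)), 1)

  set.seed(4)
  noise <- rnorm(300)
  sine <- sin(2 * pi * (1:300) / 25)
  yn <- delay_embed(noise, 2, 1)
  ys <- delay_embed(sine, 2, 1)
  det_n <- determinism_score(recurrence_matrix(yn, eps_quantile(yn, 0.1)))
  det_s <- determinism_score(recurrence_matrix(ys, eps_quantile(ys, 0.1)))
  expect_lt(det_n, det_s)
})

test_that("Poincare sections interpolate crossings linearly", {
  y <- structure(rbind(c(-1, 2, 4), c(1, 6, 10)),
                 class = c("embedded_trajectory", "matrix", "array"))
  p <- poincare_section(y, q = 1, cross = 0, direction = "up")
  expect_equal(unclass(p)[1, ], c(4, 7))        # midpoint of the crossing

  above <- structure(cbind(2:6, 1:5, 1:5),
                     class = c("embedded_trajectory", "matrix", "array"))
  empty <- poincare_section(above, q = 1, cross = 0, direction = "up")
  expect_identical(nrow(empty), 0L)
  expect_true(attr(empty, "empty"))
})

test_that("a periodic orbit pierces the section in a tight cluster", {
  sine <- sin(2 * pi * (1:1000) / 40)
  y <- delay_embed(sine, 3, 10)
  p <- poincare_section(y, q = 1, cross = mean(sine), direction = "up")
  expect_gt(nrow(p), 10)
  spread <- max(dist(unclass(p)))
  expect_lt(spread, 0.05 * 2)                   # < 5% of peak-to-peak

  # a discrete period-4 cycle yields at most 4 distinct section points
  p4 <- rep(c(0, 5, 9, 5), 30) + rep(c(0, 0.001, 0, -0.001), 30)
  y4 <- delay_embed(p4, 3, 1)
  s4 <- poincare_section(y4, q = 1, direction = "up")
  expect_lte(nrow(unique(round(unclass(s4), 3))), 4L)
})
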