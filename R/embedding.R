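#' Remove transient dynamics from the start of a series
#'
#' The first `n_cut` samples (default 50 days) are discarded before any
#' nonlinear analysis so that results describe the settled dynamics, not
#' the approach from the seeding conditions.
#'
#' @param x Numeric vector (scalar time series).
#' @param n_cut Number of leading samples to drop; must be shorter than
#'   the series.
#' @return The truncated series, order preserved.
#' @export
drop_transient <- function(x, n_cut = 50L) {
  stopifnot(is.numeric(x), n_cut >= 0)
  if (length(x) <= n_cut) {
    stop("series length (", length(x), ") must exceed n_cut (", n_cut, ")",
         call. = FALSE)
  }
  if (n_cut == 0L) x else x[-seq_len(n_cut)]
}

#' Sample autocorrelation function
#'
#' Biased (1/N-denominator) sample autocorrelation
#' \eqn{r(k) = \sum (x_t - \bar x)(x_{t+k} - \bar x) / \sum (x_t - \bar x)^2},
#' which guarantees `|r(k)| <= 1` and `r(0) = 1`.  Used to assess
#' non-whiteness and periodic components before embedding.
#'
#' @param x Numeric series with positive variance.
#' @param max_lag Largest lag to compute; must be below the series length.
#' @return Data frame with columns `lag` (0..`max_lag`) and `acf`.
#' @export
autocorrelation <- function(x, max_lag = min(length(x) - 1L, 100L)) {
  stopifnot(is.numeric(x), max_lag >= 0, max_lag < length(x))
  if (stats::var(x) == 0) {
    stop("autocorrelation undefined for a constant series", call. = FALSE)
  }
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE,
                  type = "correlation")$acf[, 1, 1]
  data.frame(lag = 0:max_lag, acf = as.numeric(r))
}

#' Time-delay embedding of a scalar series
#'
#' Reconstructs an m-dimensional phase space from a scalar observable by
#' forming lagged coordinate vectors
#' \eqn{y(n) = [x(n), x(n+d), ..., x(n+(m-1)d)]} (Takens' theorem).
#'
#' @param x Numeric series of length at least `(m-1)*d + 1`.
#' @param m Embedding dimension (integer `>= 1`).
#' @param d Delay in samples (integer `>= 1`).
#' @return An `embedded_trajectory`: a numeric matrix with
#'   `length(x) - (m-1)*d` rows and `m` columns, with attributes `m`, `d`.
#' @examples
#' delay_embed(c(1, 2, 3, 4), m = 3, d = 1)
#' @export
delay_embed <- function(x, m = 2L, d = 1L) {
  stopifnot(is.numeric(x), m >= 1, d >= 1)
  m <- as.integer(m); d <- as.integer(d)
  n_vec <- length(x) - (m - 1L) * d
  if (n_vec < 1L) {
    stop("series too short for m = ", m, ", d = ", d,
         " (need at least ", (m - 1L) * d + 1L, " samples)", call. = FALSE)
  }
  y <- vapply(0:(m - 1L), function(k) x[(1L + k * d):(n_vec + k * d)],
              numeric(n_vec))
  y <- matrix(y, nrow = n_vec, ncol = m)
  structure(y, m = m, d = d, class = c("embedded_trajectory", "matrix", "array"))
}

## Internal: first lag at which the ACF has decayed to 1/e (delay heuristic);
## falls back to the largest lag computed if the ACF never decays.
acf_delay_heuristic <- function(x, max_lag = min(length(x) - 1L, 200L)) {
  a <- autocorrelation(x, max_lag)
  hit <- which(a$acf[-1] <= exp(-1))
  if (length(hit)) hit[1] else max_lag
}

## Internal: false-nearest-neighbour fraction (Kennel criterion) by brute
## force on a subsampled trajectory.
fnn_fraction <- function(x, m, d, ratio_tol = 10, n_max = 400L) {
  y <- tryCatch(delay_embed(x, m + 1L, d), error = function(e) NULL)
  if (is.null(y) || nrow(y) < 10L) return(NA_real_)
  if (nrow(y) > n_max) {
    y <- y[round(seq(1L, nrow(y), length.out = n_max)), , drop = FALSE]
  }
  ym <- y[, seq_len(m), drop = FALSE]
  d2 <- as.matrix(stats::dist(ym))
  diag(d2) <- Inf
  nn <- apply(d2, 1L, which.min)
  base <- d2[cbind(seq_len(nrow(y)), nn)]
  extra <- abs(y[, m + 1L] - y[nn, m + 1L])
  ok <- base > 0
  if (!any(ok)) return(0)
  mean(extra[ok] / base[ok] > ratio_tol)
}

#' Scan candidate embedding parameters
#'
#' Advisory report over candidate `(m, d)` pairs: for each pair the
#' false-nearest-neighbour fraction (Kennel criterion) is computed, and
#' for each candidate delay the ACF 1/e-decay heuristic is reported.
#' Candidates are ranked by ascending FNN fraction; ties are broken by
#' smaller `m`, then smaller `d`.  The pipeline itself fixes `m = 2`,
#' `d = 1` for scalar analyses regardless, so this scan documents rather
#' than drives the choice.
#'
#' @param x Numeric series.
#' @param m_candidates,d_candidates Non-empty integer vectors.
#' @return List with `report` (data frame `m`, `d`, `fnn_fraction`,
#'   ranked), `recommended_d` (ACF heuristic), and `acf_delay` per
#'   candidate delay.
#' @export
scan_embedding <- function(x, m_candidates = 1:5, d_candidates = 1:4) {
  stopifnot(length(m_candidates) > 0, length(d_candidates) > 0)
  grid <- expand.grid(m = as.integer(m_candidates),
                      d = as.integer(d_candidates))
  grid$fnn_fraction <- mapply(function(m, d) fnn_fraction(x, m, d),
                              grid$m, grid$d)
  ord <- order(grid$fnn_fraction, grid$m, grid$d)
  report <- grid[ord, , drop = FALSE]
  rownames(report) <- NULL
  list(report = report,
       recommended_d = acf_delay_heuristic(x),
       best = report[1L, c("m", "d")])
}
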