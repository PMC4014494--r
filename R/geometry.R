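#' Recurrence matrix of an embedded trajectory
#'
#' Binary matrix with `R[i, j] = 1` iff the embedded states `y_i` and
#' `y_j` are within distance `eps` of each other.  Diagonal line
#' structures indicate deterministic/periodic dynamics; the threshold is
#' interpreted in absolute state-space units (abundance counts for the
#' simulated series, where `eps = 1` is the resolution of the data).
#'
#' @param traj An [delay_embed()] trajectory (or numeric matrix).
#' @param eps Neighbourhood radius, `> 0`.
#' @param norm `"euclidean"` (default) or `"max"` (supremum norm).
#' @return A `recurrence_matrix`: square 0/1 integer matrix with
#'   attributes `eps` and `norm`.
#' @export
recurrence_matrix <- function(traj, eps = 1, norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  y <- as.matrix(traj)
  if (nrow(y) < 1L) stop("trajectory is empty", call. = FALSE)
  dm <- as.matrix(stats::dist(y, method = if (norm == "max") "maximum"
                                          else "euclidean"))
  r <- matrix(as.integer(dm <= eps), nrow = nrow(dm))
  structure(r, eps = eps, norm = norm,
            class = c("recurrence_matrix", "matrix", "array"))
}

#' Quantile-based recurrence threshold
#'
#' The absolute threshold `eps = 1` used for raw abundance series is
#' scale-sensitive; for cross-treatment or rescaled data a threshold fixed
#' at a percentile of the pairwise distance distribution is provided.
#'
#' @param traj Embedded trajectory.
#' @param q Quantile of the pairwise distances, in (0, 1); default 0.1.
#' @inheritParams recurrence_matrix
#' @return Numeric threshold suitable for [recurrence_matrix()].
#' @export
eps_quantile <- function(traj, q = 0.1, norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  stopifnot(q > 0, q < 1)
  y <- as.matrix(traj)
  if (nrow(y) > 1000L) {
    y <- y[round(seq(1L, nrow(y), length.out = 1000L)), , drop = FALSE]
  }
  d <- stats::dist(y, method = if (norm == "max") "maximum" else "euclidean")
  as.numeric(stats::quantile(d, q))
}

#' Determinism score of a recurrence matrix (RQA DET)
#'
#' Fraction of off-diagonal recurrence points that lie on diagonal line
#' segments of length at least `l_min`.  Deterministic (periodic or
#' strongly patterned) dynamics score near 1, uncorrelated noise near 0;
#' this quantifies the visual "pattern formation" of a recurrence plot.
#'
#' @param R A [recurrence_matrix()].
#' @param l_min Minimum diagonal segment length counted as a line.
#' @return Fraction in `[0, 1]`.  If the matrix has no off-diagonal
#'   recurrences at all the score is 0 and attribute `degenerate` is set.
#' @export
determinism_score <- function(R, l_min = 2L) {
  stopifnot(inherits(R, "recurrence_matrix"), l_min >= 1)
  n <- nrow(R)
  total <- 0L
  in_lines <- 0L
  for (k in seq_len(n - 1L)) {        # upper-triangle offsets; matrix symmetric
    diag_k <- R[cbind(seq_len(n - k), seq_len(n - k) + k)]
    total <- total + sum(diag_k)
    runs <- rle(diag_k)
    ## a recurrent run counts as a line when it reaches l_min or spans
    ## its whole diagonal (a maximal structure cannot be longer)
    keep <- runs$values == 1L &
      (runs$lengths >= l_min | runs$lengths == length(diag_k))
    in_lines <- in_lines + sum(runs$lengths[keep])
  }
  if (total == 0L) {
    warning("no off-diagonal recurrence points; determinism undefined",
            call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  in_lines / total
}

#' Poincare section of an embedded trajectory
#'
#' Intersects the trajectory with the hyper-plane `coordinate q = c`,
#' linearly interpolating the remaining coordinates between the two
#' samples bracketing each crossing.  By default the plane passes through
#' the median of coordinate `q` (a transversal cut through the attractor)
#' and only upward crossings are kept, so one point is produced per cycle
#' of a periodic orbit.
#'
#' @param traj Embedded trajectory with at least 2 points and `>= 2`
#'   coordinates (typically `m = 3`).
#' @param q Index of the sectioning coordinate.
#' @param cross Crossing value `c`; default the median of coordinate `q`.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return A `poincare_section`: matrix of intersection points (one row
#'   per crossing, in time order, `m - 1` columns), with attributes `q`,
#'   `cross`, `direction`.  An empty section (no crossings) is legal and
#'   carries attribute `empty = TRUE`.
#' @export
poincare_section <- function(traj, q = 1L, cross = NULL,
                             direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  y <- as.matrix(traj)
  stopifnot(nrow(y) >= 2L, ncol(y) >= 2L, q >= 1L, q <= ncol(y))
  if (is.null(cross)) cross <- stats::median(y[, q])
  g <- y[, q] - cross
  i <- seq_len(nrow(y) - 1L)
  up <- g[i] < 0 & g[i + 1L] >= 0
  down <- g[i] > 0 & g[i + 1L] <= 0
  hit <- switch(direction, up = up, down = down, both = up | down)
  idx <- which(hit)
  others <- setdiff(seq_len(ncol(y)), q)
  if (length(idx) == 0L) {
    pts <- matrix(numeric(0), ncol = length(others))
    return(structure(pts, q = q, cross = cross, direction = direction,
                     empty = TRUE, class = c("poincare_section", "matrix",
                                             "array")))
  }
  frac <- -g[idx] / (g[idx + 1L] - g[idx])   # linear interpolation in time
  pts <- y[idx, others, drop = FALSE] +
    frac * (y[idx + 1L, others, drop = FALSE] - y[idx, others, drop = FALSE])
  structure(pts, q = q, cross = cross, direction = direction, empty = FALSE,
            class = c("poincare_section", "matrix", "array"))
}
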