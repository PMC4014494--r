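## Distributional statistics over per-run Lyapunov exponents, paired
## signed-rank testing between treatments, and no-effect-threshold
## detection.

#' Assemble a Lyapunov table
#'
#' One record per (concentration, age class, run): the estimated maximal
#' Lyapunov exponent and whether the estimate carried quality flags.
#'
#' @param df Data frame with columns `concentration`, `age_class`, `run`,
#'   `lambda`, `flagged` (logical).
#' @return The validated data frame with class `lyapunov_table`.
#' @export
lyapunov_table <- function(df) {
  need <- c("concentration", "age_class", "run", "lambda", "flagged")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("lyapunov table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[c("concentration", "age_class", "run")])) {
    stop("duplicate (concentration, age_class, run) records", call. = FALSE)
  }
  structure(as.data.frame(df)[need],
            class = c("lyapunov_table", "data.frame"))
}

#' Per-treatment summary of Lyapunov distributions
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' unflagged exponents per (concentration, age class) cell.
#'
#' @param table A [lyapunov_table()].
#' @param strict Error on cells with fewer than 2 valid records (default);
#'   with `strict = FALSE` such cells are dropped, which lets the pipeline
#'   continue when a treatment's estimates were mostly flagged.
#' @return Data frame `concentration`, `age_class`, `mean`, `sd`, `n`,
#'   ordered by concentration.
#' @export
summarize_lyapunov <- function(table, strict = TRUE) {
  stopifnot(inherits(table, "lyapunov_table"))
  valid <- table[!table$flagged & is.finite(table$lambda), , drop = FALSE]
  cells <- unique(valid[c("concentration", "age_class")])
  if (nrow(cells) == 0L) stop("no valid records to summarise", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- valid$concentration == cells$concentration[i] &
      valid$age_class == cells$age_class[i]
    lam <- valid$lambda[sel]
    if (length(lam) < 2L) {
      if (strict) {
        stop("fewer than 2 valid records for concentration ",
             cells$concentration[i], ", class ", cells$age_class[i],
             call. = FALSE)
      }
      return(NULL)
    }
    data.frame(concentration = cells$concentration[i],
               age_class = cells$age_class[i],
               mean = mean(lam), sd = stats::sd(lam), n = length(lam))
  }))
  out[order(out$age_class, out$concentration), , drop = FALSE]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sample paired signed-rank test.  Zero differences are dropped
#' before ranking.  With at most 25 remaining pairs and no ties among the
#' absolute differences, the p-value is exact (full enumeration of the
#' null distribution of the positive-rank sum via subset-sum counting);
#' otherwise a normal approximation with continuity correction and
#' tie-corrected variance is used.
#'
#' @param a,b Equal-length paired numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative refers to the location of `a` relative to `b`).
#' @return List with `p_value`, `statistic` (positive-rank sum `V`),
#'   `n` (pairs after dropping zeros), `exact` (logical).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))$p_value   # 0.25
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "less",
                                                       "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("samples must be paired (equal length)",
                                   call. = FALSE)
  dif <- a - b
  dif <- dif[dif != 0]
  n <- length(dif)
  if (n == 0L) stop("all differences are zero: degenerate test",
                    call. = FALSE)
  if (n < 3L) stop("need at least 3 nonzero differences", call. = FALSE)
  r <- rank(abs(dif))
  v <- sum(r[dif > 0])
  ties <- any(duplicated(abs(dif)))
  if (n <= 25L && !ties) {
    counts <- signed_rank_counts(n)           # counts of V = 0..n(n+1)/2
    tot <- 2^n
    p_le <- cumsum(counts) / tot
    vmax <- n * (n + 1) / 2
    p_lower <- p_le[v + 1L]                                  # P(V <= v)
    p_upper <- 1 - (if (v == 0) 0 else p_le[v])              # P(V >= v)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_lower, p_upper)),
                greater = p_upper,
                less = p_lower)
    return(list(p_value = p, statistic = v, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  z <- v - mu
  cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
               less = -0.5)
  z <- (z - cc) / sigma
  p <- switch(alternative,
              two.sided = min(1, 2 * stats::pnorm(-abs(z))),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(p_value = p, statistic = v, n = n, exact = FALSE)
}

## Internal: exact null distribution of the positive-rank sum for n
## untied pairs -- number of subsets of {1..n} with each possible sum,
## by iterated convolution (dynamic programming).
signed_rank_counts <- function(n) {
  vmax <- n * (n + 1) / 2
  counts <- numeric(vmax + 1)
  counts[1] <- 1
  for (rk in seq_len(n)) {
    shifted <- c(numeric(rk), counts[seq_len(vmax + 1 - rk)])
    counts <- counts + shifted
  }
  counts
}

#' Pairwise signed-rank tests across the concentration panel
#'
#' Tests every unordered pair of concentrations for one age class,
#' pairing observations by run index (valid because ensembles share
#' seeds across concentrations).  Flagged estimates are removed pairwise.
#' Raw p-values are reported by default; Holm adjustment is available.
#'
#' @param table A [lyapunov_table()].
#' @param age_class Which class to test (`"total"`, `"neonates"`,
#'   `"juveniles"`, `"adults"`).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `pairwise_test_matrix`: list with `p` (upper-triangular
#'   matrix indexed by the ordered panel), `pairs` (long data frame with
#'   `conc_a`, `conc_b`, `p`, `n`), `age_class`, `adjust`.  Degenerate
#'   pairs (all differences zero) get `NA` p-values.
#' @export
pairwise_tests <- function(table, age_class = "total",
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "lyapunov_table"))
  sub <- table[table$age_class == age_class, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for age class ", age_class,
                            call. = FALSE)
  panel <- sort(unique(sub$concentration))
  k <- length(panel)
  if (k < 2L) stop("need at least 2 concentrations", call. = FALSE)
  pm <- matrix(NA_real_, k, k, dimnames = list(panel, panel))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ai <- sub[sub$concentration == panel[i] & !sub$flagged, ]
      bj <- sub[sub$concentration == panel[j] & !sub$flagged, ]
      runs <- intersect(ai$run, bj$run)
      x <- ai$lambda[match(runs, ai$run)]
      y <- bj$lambda[match(runs, bj$run)]
      res <- tryCatch(wilcoxon_signed_rank(x, y),
                      error = function(e) list(p_value = NA_real_,
                                               n = length(runs)))
      pm[i, j] <- res$p_value
      rows[[length(rows) + 1L]] <- data.frame(conc_a = panel[i],
                                              conc_b = panel[j],
                                              p = res$p_value, n = res$n)
    }
  }
  pairs <- do.call(rbind, rows)
  if (adjust == "holm") {
    pairs$p <- stats::p.adjust(pairs$p, method = "holm")
    for (r in seq_len(nrow(pairs))) {
      pm[match(pairs$conc_a[r], panel), match(pairs$conc_b[r], panel)] <-
        pairs$p[r]
    }
  }
  structure(list(p = pm, pairs = pairs, age_class = age_class,
                 adjust = adjust, panel = panel),
            class = "pairwise_test_matrix")
}

#' Lowest-effect-concentration from the pairwise test matrix
#'
#' The no-effect threshold is operationalised as the lowest non-control
#' concentration whose Lyapunov distribution differs significantly from
#' the control's (paired signed-rank p below `alpha`); `NA` ("none") when
#' no treatment differs.
#'
#' @param tests A [pairwise_tests()] result whose panel includes the
#'   control (concentration 0).
#' @param alpha Significance level, default 0.05.
#' @return A `threshold_result` list: `threshold` (ug/l or `NA`),
#'   `alpha`, `age_class`, `p_control` (named vector of control-row
#'   p-values).
#' @export
detect_threshold <- function(tests, alpha = 0.05) {
  stopifnot(inherits(tests, "pairwise_test_matrix"), alpha > 0, alpha < 1)
  panel <- tests$panel
  if (!0 %in% panel) stop("control (0) absent from panel", call. = FALSE)
  ctrl <- tests$pairs[tests$pairs$conc_a == 0, , drop = FALSE]
  ctrl <- ctrl[order(ctrl$conc_b), ]
  sig <- ctrl$conc_b[!is.na(ctrl$p) & ctrl$p < alpha]
  structure(list(threshold = if (length(sig)) min(sig) else NA_real_,
                 alpha = alpha, age_class = tests$age_class,
                 p_control = stats::setNames(ctrl$p, ctrl$conc_b)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Lowest-effect concentration (", x$age_class, ", alpha = ", x$alpha,
      "): ", if (is.na(x$threshold)) "none" else paste(x$threshold, "ug/l"),
      "\n", sep = "")
  invisible(x)
}
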