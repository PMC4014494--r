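## Small plain-text exporters for analysis artifacts.

#' Export a recurrence matrix as a sparse coordinate list
#'
#' Writes one `i,j` row per recurrence point (upper triangle including
#' the diagonal; the matrix is symmetric), which keeps files small for
#' sparse plots.
#'
#' @param R A [recurrence_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recurrence_csv <- function(R, path) {
  stopifnot(inherits(R, "recurrence_matrix"))
  idx <- which(unclass(R) == 1L, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  utils::write.csv(data.frame(i = idx[, 1], j = idx[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a Poincare section as CSV
#'
#' Columns `u,v` (plus `w`, ... for higher-dimensional sections), one
#' row per crossing in time order.
#'
#' @param section A [poincare_section()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_poincare_csv <- function(section, path) {
  stopifnot(inherits(section, "poincare_section"))
  pts <- unclass(section)
  attributes(pts) <- attributes(pts)["dim"]
  df <- as.data.frame(pts)
  names(df) <- c("u", "v", "w", "x4", "x5")[seq_len(ncol(df))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an autocorrelation function as CSV (`lag,acf`)
#'
#' @param acf_df An [autocorrelation()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_acf_csv <- function(acf_df, path) {
  stopifnot(is.data.frame(acf_df), all(c("lag", "acf") %in% names(acf_df)))
  utils::write.csv(acf_df[c("lag", "acf")], path, row.names = FALSE)
  invisible(path)
}

#' Export a stretching curve as CSV and an estimate as JSON
#'
#' The curve goes to CSV (`dn,S,n_ref`); the estimate record (lambda,
#' fit range, R^2, eps, flags) to JSON.
#'
#' @param curve A [kantz_stretching()] curve.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stretching_csv <- function(curve, path) {
  stopifnot(inherits(curve, "stretching_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stretching_csv
#' @param est A `lyapunov_estimate`.
#' @export
write_lyapunov_json <- function(est, path) {
  stopifnot(inherits(est, "lyapunov_estimate"))
  jsonlite::write_json(list(lambda = est$lambda,
                            dn_range = est$dn_range,
                            r_squared = est$r_squared,
                            eps = est$eps,
                            flags = as.list(est$flags)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
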