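#' Lagged block of a single series
#'
#' Builds the (n - s) x s matrix of lagged observations of one channel: row
#' r holds `W(s + r - 1), W(s + r - 2), ..., W(r)`, i.e. the s most recent
#' past values available when predicting time `s + r`.
#'
#' @param series numeric vector of length n.
#' @param s lag order, `1 <= s < n`.
#' @return an `(n - s) x s` numeric matrix.
#' @examples
#' lag_block(1:5, 2) # rbind(c(2,1), c(3,2), c(4,3))
#' @export
lag_block <- function(series, s) {
  series <- as.numeric(series)
  n <- length(series)
  s <- as.integer(s)
  if (s < 1L) stop("lag order must be >= 1")
  if (s >= n) stop("series too short for lag order (n = ", n, ", s = ", s, ")")
  stats::embed(series, s + 1L)[, -1L, drop = FALSE]
}

#' Build the MVAR design system for one target channel
#'
#' The design matrix `A` is the horizontal concatenation of the lag blocks
#' of all m channels (m contiguous blocks of s columns, in channel order);
#' the response `y` holds the target channel at the `n - s` predicted times
#' `t = s + 1, ..., n`.
#'
#' @param rec a [recording()].
#' @param s lag order in samples.
#' @param k target channel index (1-based).
#' @return a `design_system`: list with `A` ((n-s) x (m*s) matrix), `y`
#'   (length n-s), `s`, `k`, `m`, `n` and `block_weights` (per-channel
#'   column scalings, all 1 for an unweighted design).
#' @export
build_design <- function(rec, s, k) {
  stopifnot(inherits(rec, "recording"))
  m <- n_channels(rec); n <- n_samples(rec)
  k <- as.integer(k)
  if (k < 1L || k > m) stop("target index k = ", k, " out of range 1..", m)
  blocks <- lapply(seq_len(m), function(i) lag_block(rec$data[i, ], s))
  A <- do.call(cbind, blocks)
  colnames(A) <- as.vector(vapply(seq_len(m), function(i)
    sprintf("%s.l%d", rec$channel_names[i], seq_len(s)), character(s)))
  structure(list(A = A, y = rec$data[k, (s + 1L):n], s = as.integer(s),
                 k = k, m = m, n = n,
                 block_weights = rep(1, m)),
            class = "design_system")
}

#' @export
print.design_system <- function(x, ...) {
  cat(sprintf("<design_system> target k=%d: A %d x %d (m=%d channels, s=%d lags)\n",
              x$k, nrow(x$A), ncol(x$A), x$m, x$s))
  invisible(x)
}

#' Repack per-target coefficient vectors into an m x m x s tensor
#'
#' Entry `a[i, k, l]` is the coefficient of channel i at lag l in the
#' equation predicting channel k, matching the block layout of
#' [build_design()].
#'
#' @param fits list of m `mvar_fit` objects (one per target channel, in
#'   channel order), or a list of plain coefficient vectors of length `m*s`.
#' @param m channel count.
#' @param s lag order.
#' @return numeric array of dimension `c(m, m, s)`.
#' @export
coeffs_to_tensor <- function(fits, m, s) {
  m <- as.integer(m); s <- as.integer(s)
  if (length(fits) != m)
    stop("need one fit per target channel: got ", length(fits), ", expected ", m)
  a <- array(0, dim = c(m, m, s))
  for (k in seq_len(m)) {
    x <- if (inherits(fits[[k]], "mvar_fit")) fits[[k]]$coeffs else as.numeric(fits[[k]])
    if (length(x) != m * s)
      stop("coefficient vector for target ", k, " has length ", length(x),
           ", expected m*s = ", m * s)
    a[, k, ] <- t(matrix(x, nrow = s))  # rows of matrix(x, s): lags; blocks: channels
  }
  a
}

#' Select an MVAR lag order by penalized residual variance
#'
#' Fits the L2 model for each candidate order and scores it with an
#' AIC-style criterion `log(det-free pooled residual variance) +
#' 2 * m^2 * s / n`. A helper only; the pipeline default order is fixed.
#'
#' @param rec a [recording()].
#' @param s_max largest order to consider.
#' @return the selected integer order.
#' @export
select_lag_order <- function(rec, s_max = 8L) {
  m <- n_channels(rec); n <- n_samples(rec)
  score <- vapply(seq_len(s_max), function(s) {
    rv <- vapply(seq_len(m), function(k) fit_l2(build_design(rec, s, k))$resid_var,
                 numeric(1))
    log(mean(rv)) + 2 * m * m * s / n
  }, numeric(1))
  which.min(score)
}
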