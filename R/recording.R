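#' Construct a multichannel recording
#'
#' A `recording` is the basic container of the package: an `m` channels by
#' `n` samples numeric matrix together with its sampling rate and channel
#' names. All downstream operations (band-pass filtering, design-matrix
#' construction, correlation matrices) consume this container.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param srate sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of unique channel
#'   identifiers; defaults to `"ch01"`, `"ch02"`, ...
#'
#' @return an object of class `recording`: a list with elements `data`
#'   (m x n matrix with channel names as rownames), `srate` and
#'   `channel_names`.
#'
#' @details Missing or non-finite values are a hard error: the
#'   autoregressive estimators assume complete series and no imputation is
#'   attempted. Single-channel recordings are allowed so that scalar AR
#'   processes can be represented (the multichannel estimators themselves
#'   are only interesting for m >= 2).
#'
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), srate = 100)
#' rec
#' @export
recording <- function(data, srate, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  m <- nrow(data); n <- ncol(data)
  if (m < 1L || n < 2L)
    stop("recording needs at least 1 channel and 2 samples, got ", m, " x ", n)
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at channel %d, sample %d",
                 bad[1L, 1L], bad[1L, 2L]))
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(m))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != m)
    stop("channel_names has length ", length(channel_names),
         " but recording has ", m, " channels")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  rownames(data) <- channel_names
  structure(list(data = data, srate = as.numeric(srate),
                 channel_names = channel_names),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$srate))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec a [recording()]
#' @return integer scalar
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read a delimited numeric matrix as a recording
#'
#' Reads a CSV/TSV/whitespace-delimited file containing one channel per row
#' (default orientation) and validates it. The delimiter is sniffed from the
#' first line (comma, then tab, then whitespace).
#'
#' @param path path to a delimited text file of numbers, no header.
#' @param srate sampling rate in Hz.
#' @param channel_names optional channel identifiers.
#' @param orientation `"channels"` if rows are channels (default) or
#'   `"samples"` if rows are time samples (the matrix is transposed).
#' @return a [recording()].
#' @export
read_recording <- function(path, srate, channel_names = NULL,
                           orientation = c("channels", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  sep <- if (grepl(",", lines[[1L]])) "," else if (grepl("\t", lines[[1L]])) "\t" else "[[:space:]]+"
  rows <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) > 1L)
    stop(sprintf("ragged rows: row 1 has %d fields but row %d has %d",
                 len[1L], which(len != len[1L])[1L], len[which(len != len[1L])[1L]]))
  num <- lapply(seq_along(rows), function(r) {
    v <- suppressWarnings(as.numeric(rows[[r]]))
    if (anyNA(v)) {
      c0 <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value %s at row %d, column %d",
                   dQuote(rows[[r]][c0]), r, c0))
    }
    v
  })
  mat <- do.call(rbind, num)
  if (orientation == "samples") mat <- t(mat)
  recording(mat, srate = srate, channel_names = channel_names)
}

#' Select (and reorder) channels of a recording
#'
#' @param rec a [recording()].
#' @param keep character vector of channel identifiers; the output rows
#'   follow the order of `keep`.
#' @return a [recording()] with `length(keep)` channels.
#' @export
select_channels <- function(rec, keep) {
  keep <- as.character(keep)
  missing <- setdiff(keep, rec$channel_names)
  if (length(missing) > 0L)
    stop("unknown channel ", paste(missing, collapse = ", "))
  idx <- match(keep, rec$channel_names)
  recording(rec$data[idx, , drop = FALSE], rec$srate, channel_names = keep)
}

#' Frequency band specification
#'
#' @param name band label (e.g. `"gamma"`).
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return a `band_spec` list.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "band_spec")
}

#' The five conventional EEG rhythm bands
#'
#' delta 1--3 Hz, theta 4--7 Hz, alpha 8--13 Hz, beta 14--30 Hz and
#' gamma 31--50 Hz.
#'
#' @return named list of [band_spec()] objects.
#' @export
eeg_bands <- function() {
  list(delta = band_spec("delta", 1, 3),
       theta = band_spec("theta", 4, 7),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 14, 30),
       gamma = band_spec("gamma", 31, 50))
}

# Butterworth band-pass design (transfer-function form) via the analog
# lowpass prototype, lowpass->bandpass transform and bilinear transform.
# `order` is the prototype order; the resulting band-pass has 2*order poles.
butter_bandpass <- function(order, lo, hi, srate) {
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p <- complex(real = -sin(theta), imaginary = cos(theta)) # unit LP prototype
  fs2 <- 2 * srate
  w1 <- fs2 * tan(pi * lo / srate)  # prewarped edges
  w2 <- fs2 * tan(pi * hi / srate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  plp <- p * bw / 2
  root <- sqrt(plp^2 - w0^2)
  pbp <- c(plp + root, plp - root)
  zbp <- rep(0 + 0i, order)               # order zeros at s = 0
  kbp <- bw^order
  zd <- (fs2 + zbp) / (fs2 - zbp)         # bilinear transform
  pd <- (fs2 + pbp) / (fs2 - pbp)
  kd <- Re(kbp * prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(b = Re(poly_from_roots(zd)) * kd, a = Re(poly_from_roots(pd)))
}

poly_from_roots <- function(r) {
  out <- 1 + 0i
  for (ri in r) out <- c(out, 0i) - c(0i, out * ri)
  out
}

# Direct-form IIR filter with zero initial conditions.
iir_filter <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

# Forward-backward (zero-phase) filtering with odd-symmetric edge padding.
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 100L))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass (8 poles after the band
#' transform) forward and backward over each channel, so the output has zero
#' phase distortion: features in the pass band are not shifted in time.
#'
#' @param rec a [recording()].
#' @param band a [band_spec()]; `hi` must lie strictly below the Nyquist
#'   frequency `srate/2`.
#' @param order Butterworth prototype order (default 4).
#' @return a [recording()] of the same shape and sampling rate.
#' @export
bandpass_filter <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  nyq <- rec$srate / 2
  if (band$hi >= nyq)
    stop(sprintf("band edge %g Hz is at or above the Nyquist frequency %g Hz",
                 band$hi, nyq))
  ba <- butter_bandpass(order, band$lo, band$hi, rec$srate)
  out <- t(apply(rec$data, 1L, function(x) filtfilt_ba(ba$b, ba$a, x)))
  recording(out, rec$srate, channel_names = rec$channel_names)
}

#' Remove the per-channel mean of a recording
#'
#' The autoregressive model has no intercept term, so signals are centered
#' before design-matrix construction.
#'
#' @param rec a [recording()].
#' @return a centered [recording()].
#' @export
center_recording <- function(rec) {
  recording(rec$data - rowMeans(rec$data), rec$srate,
            channel_names = rec$channel_names)
}

#' Write a recording to a delimited file
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  utils::write.table(rec$data, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
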