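#' Pearson correlation coefficient of two channels
#'
#' `Cov(u, v) / sqrt(Var(u) Var(v))`; sample vs population normalization
#' cancels in the ratio, so the result matches either convention.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return scalar in `[-1, 1]`.
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 2L) stop("need at least 2 samples")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) stop("zero variance channel")
  stats::cov(u, v) / sqrt(stats::var(u) * stats::var(v))
}

#' Sensor correlation matrix of a recording
#'
#' All pairwise Pearson coefficients `M[i, j]` between channels, the `E`
#' prior used by [fit_scsga()]. Computed per trial on the same (band-
#' filtered, centered) window as the autoregressive fit.
#'
#' @param rec a [recording()].
#' @return an m x m symmetric matrix with unit diagonal (class
#'   `correlation_matrix`), channel names as dimnames.
#' @export
correlation_matrix <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  sds <- apply(rec$data, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero variance channel: ",
         paste(rec$channel_names[sds == 0], collapse = ", "))
  M <- stats::cor(t(rec$data))
  dimnames(M) <- list(rec$channel_names, rec$channel_names)
  structure(M, class = c("correlation_matrix", "matrix"))
}

#' Collapse a coefficient tensor into a directed causality network
#'
#' Edge strength from channel i to channel k aggregates that channel pair's
#' coefficients over lags; the default is the sum of absolute values, the
#' simplest monotone sparsity-preserving collapse. The diagonal
#' (self-causality) is forced to zero.
#'
#' @param tensor an m x m x s array, `tensor[i, k, l]` = coefficient of
#'   channel i at lag l in the equation for channel k
#'   (see [coeffs_to_tensor()]).
#' @param channel_names optional character vector of length m.
#' @param mode `"sum_abs"` (default), `"max_abs"` or `"l2"` over lags.
#' @return a `causality_network`: list with nonnegative m x m matrix `G`
#'   (zero diagonal) and `channel_names`.
#' @export
aggregate_network <- function(tensor, channel_names = NULL,
                              mode = c("sum_abs", "max_abs", "l2")) {
  mode <- match.arg(mode)
  d <- dim(tensor)
  if (length(d) != 3L || d[1L] != d[2L])
    stop("tensor must be m x m x s")
  G <- apply(tensor, c(1L, 2L), switch(mode,
    sum_abs = function(x) sum(abs(x)),
    max_abs = function(x) max(abs(x)),
    l2      = function(x) sqrt(sum(x^2))))
  diag(G) <- 0
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(d[1L]))
  dimnames(G) <- list(channel_names, channel_names)
  structure(list(G = G, channel_names = channel_names),
            class = "causality_network")
}

#' @export
print.causality_network <- function(x, ...) {
  cat(sprintf("<causality_network> %d channels, %d nonzero directed edges\n",
              nrow(x$G), sum(x$G != 0)))
  invisible(x)
}

#' Vectorize per-band causality networks into one feature vector
#'
#' Off-diagonal entries of each network are rastered in fixed row-major
#' order (source channel varying slowest) and the bands concatenated in the
#' declared order, giving `bands * m * (m - 1)` features per trial.
#' Self-edges are excluded.
#'
#' @param nets list of `causality_network` objects (one per band); all must
#'   share channel count and order.
#' @param band_names optional labels used in feature names (defaults to the
#'   list names or `band1`, `band2`, ...).
#' @return named numeric vector; names are `"<band>:<src>-><dst>"`.
#' @export
network_features <- function(nets, band_names = NULL) {
  if (inherits(nets, "causality_network")) nets <- list(nets)
  m <- nrow(nets[[1L]]$G)
  chans <- nets[[1L]]$channel_names
  for (nt in nets) {
    if (nrow(nt$G) != m || !identical(nt$channel_names, chans))
      stop("all networks must share channel count and order")
  }
  if (is.null(band_names))
    band_names <- if (!is.null(names(nets))) names(nets)
                  else sprintf("band%d", seq_along(nets))
  out <- unlist(lapply(seq_along(nets), function(b) {
    v <- numeric(m * (m - 1L)); nm <- character(m * (m - 1L)); p <- 0L
    for (i in seq_len(m)) for (k in seq_len(m)) if (i != k) {
      p <- p + 1L
      v[p] <- nets[[b]]$G[i, k]
      nm[p] <- sprintf("%s:%s->%s", band_names[b], chans[i], chans[k])
    }
    stats::setNames(v, nm)
  }))
  out
}

#' Write a causality network to disk
#'
#' Writes both a dense CSV (channel-name headers) and an edge-list TSV
#' (`source`, `target`, `weight`) containing the nonzero directed edges.
#'
#' @param net a `causality_network`.
#' @param path_csv,path_tsv output paths; either may be `NULL` to skip.
#' @return invisibly, a data.frame of the edge list.
#' @export
write_network <- function(net, path_csv = NULL, path_tsv = NULL) {
  G <- net$G
  if (!is.null(path_csv))
    utils::write.csv(G, path_csv, row.names = TRUE)
  nz <- which(G != 0, arr.ind = TRUE)
  edges <- data.frame(source = net$channel_names[nz[, 1L]],
                      target = net$channel_names[nz[, 2L]],
                      weight = G[nz])
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  if (!is.null(path_tsv))
    utils::write.table(edges, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(edges)
}
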