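#' Specification of a synthetic sparse VAR world
#'
#' Defines the generative model used for end-to-end testing: a stable
#' sparse vector autoregression with Gaussian innovations, optional
#' heavy-amplitude outlier contamination (emulating blink/movement
#' artifacts), and a multi-class structure where classes differ in which
#' directed couplings exist.
#'
#' @param m channels.
#' @param s lag order of the generator.
#' @param n samples kept per trial (after burn-in).
#' @param density fraction of the `m*(m-1)` ordered cross-channel pairs
#'   carrying nonzero coefficients; self-lags are always present.
#' @param coeff_scale magnitude scale of nonzero coefficients (drawn
#'   uniformly from `[0.5, 1] * coeff_scale` with random sign for cross
#'   terms; self terms positive).
#' @param noise_sd innovation standard deviation.
#' @param outlier_frac fraction of time points contaminated per channel, in
#'   `[0, 1)`.
#' @param outlier_amp contamination amplitude, in units of the clean
#'   channel's standard deviation.
#' @param classes number of label classes (for [make_dataset()]).
#' @param trials_per_class trials generated per class.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(m = 8L, s = 2L, n = 400L, density = 0.15,
                            coeff_scale = 0.4, noise_sd = 1,
                            outlier_frac = 0.05, outlier_amp = 10,
                            classes = 3L, trials_per_class = 40L,
                            seed = 20240101L) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (outlier_frac < 0 || outlier_frac >= 1) stop("outlier_frac must be in [0, 1)")
  if (m < 1L || s < 1L || n < 2L) stop("m, s must be >= 1 and n >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (classes < 1L || trials_per_class < 1L) stop("counts must be positive")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(m = as.integer(m), s = as.integer(s), n = as.integer(n),
                 density = density, coeff_scale = coeff_scale,
                 noise_sd = noise_sd, outlier_frac = outlier_frac,
                 outlier_amp = outlier_amp, classes = as.integer(classes),
                 trials_per_class = as.integer(trials_per_class),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Spectral radius of the VAR companion matrix
#'
#' A VAR(s) is stationary iff the spectral radius of its `(m*s) x (m*s)`
#' companion matrix is below 1.
#'
#' @param tensor m x m x s coefficient array, `tensor[i, k, l]` as in
#'   [coeffs_to_tensor()].
#' @return the largest eigenvalue modulus.
#' @export
companion_radius <- function(tensor) {
  m <- dim(tensor)[1L]; s <- dim(tensor)[3L]
  # transition blocks B_l with B_l[k, i] = effect of channel i at lag l on k
  top <- do.call(cbind, lapply(seq_len(s), function(l) t(tensor[, , l])))
  C <- rbind(top, cbind(diag(m * (s - 1L)),
                        matrix(0, m * (s - 1L), m)))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Draw a stable sparse VAR ground truth
#'
#' Chooses a random cross-channel support at the requested density
#' (self-lags always present), draws coefficient magnitudes, and rescales
#' lag-l coefficients by `t^l` (which scales companion eigenvalues exactly
#' by `t`) until the spectral radius is at most 0.95.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional override of `spec$seed`.
#' @return a `ground_truth`: list with `tensor` (m x m x s), logical
#'   `support` (m x m, includes the diagonal), `radius`, `class_id` (NA),
#'   and the spec.
#' @export
sample_sparse_var <- function(spec, seed = spec$seed) {
  restore <- local_rng(seed)
  on.exit(restore())
  m <- spec$m; s <- spec$s
  cross <- which(diag(m) == 0)
  n_edges <- floor(spec$density * length(cross))
  on_edges <- if (n_edges > 0) sample(cross, n_edges) else integer(0)
  support <- matrix(FALSE, m, m)
  support[on_edges] <- TRUE
  diag(support) <- TRUE
  tensor <- array(0, dim = c(m, m, s))
  for (i in seq_len(m)) for (k in seq_len(m)) {
    if (!support[i, k]) next
    mag <- stats::runif(s, 0.5, 1) * spec$coeff_scale
    sgn <- if (i == k) rep(1, s) else sample(c(-1, 1), s, replace = TRUE)
    tensor[i, k, ] <- mag * sgn
  }
  radius <- companion_radius(tensor)
  tries <- 0L
  while (radius > 0.95) {
    tries <- tries + 1L
    if (tries > 100L)
      stop("could not stabilize the VAR in 100 rescalings; lower coeff_scale")
    t_fac <- 0.95 / radius
    for (l in seq_len(s)) tensor[, , l] <- tensor[, , l] * t_fac^l
    radius <- companion_radius(tensor)
  }
  structure(list(tensor = tensor, support = support, radius = radius,
                 class_id = NA_integer_, spec = spec),
            class = "ground_truth")
}

#' Simulate a recording from a VAR ground truth
#'
#' Runs the recursion `W(t) = sum_l B_l W(t - l) + eps(t)` with i.i.d.
#' Gaussian innovations from a zero initial state, discards a 200-sample
#' burn-in (initial-condition influence below 1e-4 at radius 0.95), and
#' returns the next `n` samples.
#'
#' @param gt a `ground_truth` from [sample_sparse_var()].
#' @param spec a [simulation_spec()] (defaults to the one stored in `gt`).
#' @param seed optional override of `spec$seed`.
#' @param srate nominal sampling rate attached to the recording (Hz).
#' @param burn_in samples discarded before the kept window (default 200).
#' @param init optional m x s matrix of initial values (most recent lag in
#'   column s); defaults to the zero state. A nonzero `init` with
#'   `noise_sd = 0` yields the deterministic transient of the model, useful
#'   for exact-regime identifiability checks.
#' @return a [recording()] with `spec$m` channels and `spec$n` samples.
#' @export
simulate_var <- function(gt, spec = gt$spec, seed = spec$seed, srate = 200,
                         burn_in = 200L, init = NULL) {
  restore <- local_rng(seed)
  on.exit(restore())
  m <- spec$m; s <- spec$s
  burn <- as.integer(burn_in)
  n_tot <- spec$n + burn
  B <- lapply(seq_len(s), function(l) t(gt$tensor[, , l]))  # B_l[k, i]
  W <- matrix(0, m, n_tot + s)
  if (!is.null(init)) {
    init <- matrix(init, m, s)
    W[, seq_len(s)] <- init
  }
  eps <- matrix(stats::rnorm(m * n_tot, sd = spec$noise_sd), m, n_tot)
  for (t in (s + 1L):(n_tot + s)) {
    acc <- eps[, t - s]
    for (l in seq_len(s)) acc <- acc + B[[l]] %*% W[, t - l]
    W[, t] <- acc
  }
  recording(W[, (s + burn + 1L):(n_tot + s), drop = FALSE], srate = srate)
}

#' Contaminate a recording with amplitude outliers
#'
#' Replaces `floor(frac * n)` randomly chosen time points per channel with
#' `amp * sd(channel) * (+/- 1)`, emulating blink/movement artifacts. The
#' contaminated indices are recorded for audit in
#' `attr(out, "outlier_index")` (a list, one integer vector per channel).
#'
#' @param rec a [recording()].
#' @param frac fraction of time points contaminated per channel, `[0, 1)`.
#' @param amp amplitude multiplier in clean-channel SD units.
#' @param seed integer seed.
#' @return a [recording()] of the same shape.
#' @export
inject_outliers <- function(rec, frac, amp, seed = 1L) {
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  if (frac == 0) return(rec)
  restore <- local_rng(seed)
  on.exit(restore())
  dat <- rec$data
  n <- ncol(dat)
  n_out <- floor(frac * n)
  audit <- vector("list", nrow(dat))
  for (i in seq_len(nrow(dat))) {
    idx <- sample.int(n, n_out)
    dat[i, idx] <- amp * stats::sd(rec$data[i, ]) *
      sample(c(-1, 1), n_out, replace = TRUE)
    audit[[i]] <- sort(idx)
  }
  out <- recording(dat, rec$srate, channel_names = rec$channel_names)
  attr(out, "outlier_index") <- audit
  out
}

#' Generate a labeled multi-class dataset of VAR trials
#'
#' One ground truth per class, each with its own random coupling support
#' (so classes differ in which directed edges exist, not in noise level);
#' `trials_per_class` independent recordings per class, contaminated with
#' outliers when `spec$outlier_frac > 0`. Per-trial seeds are derived
#' deterministically from `spec$seed`.
#'
#' @param spec a [simulation_spec()] with `classes >= 2`.
#' @return a `sim_dataset`: list with `trials` (list of recordings),
#'   `labels` (integer class ids), `truths` (per-class `ground_truth`) and
#'   the spec.
#' @export
make_dataset <- function(spec) {
  if (spec$classes < 2L) stop("need classes >= 2")
  truths <- lapply(seq_len(spec$classes), function(c) {
    gt <- sample_sparse_var(spec, seed = spec$seed + c)
    gt$class_id <- c
    gt
  })
  trials <- vector("list", spec$classes * spec$trials_per_class)
  labels <- integer(length(trials))
  p <- 0L
  for (c in seq_len(spec$classes)) {
    for (j in seq_len(spec$trials_per_class)) {
      p <- p + 1L
      tseed <- (spec$seed + c * 131071L + j * 257L) %% .Machine$integer.max
      rec <- simulate_var(truths[[c]], spec, seed = tseed)
      if (spec$outlier_frac > 0)
        rec <- inject_outliers(rec, spec$outlier_frac, spec$outlier_amp,
                               seed = tseed + 1L)
      trials[[p]] <- rec
      labels[p] <- c
    }
  }
  structure(list(trials = trials, labels = labels, truths = truths,
                 spec = spec),
            class = "sim_dataset")
}

#' Write a ground truth as JSON
#'
#' @param gt a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  out <- list(tensor = gt$tensor, support = gt$support * 1L,
              radius = gt$radius, class_id = gt$class_id,
              spec = unclass(gt$spec))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
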