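# Shared fixtures: everything is generated in code, no data files.

# Random recording with i.i.d. Gaussian channels.
rand_recording <- function(m, n, seed, srate = 200) {
  set.seed(seed)
  recording(matrix(rnorm(m * n), m, n), srate = srate)
}

# Minimal hand-built design system (bypasses build_design) for solver
# closed-form checks on tiny matrices.
fake_ds <- function(A, y, s = 1L, k = 1L) {
  A <- as.matrix(A)
  structure(list(A = A, y = as.numeric(y), s = as.integer(s),
                 k = as.integer(k), m = ncol(A) %/% s,
                 n = nrow(A) + s, block_weights = rep(1, ncol(A) %/% s)),
            class = "design_system")
}

# Ground truth wrapper around an explicit coefficient tensor.
fixed_ground_truth <- function(tensor, spec) {
  support <- apply(tensor, c(1, 2), function(x) any(x != 0))
  structure(list(tensor = tensor, support = support,
                 radius = companion_radius(tensor), class_id = NA_integer_,
                 spec = spec),
            class = "ground_truth")
}

# Brute-force 1-D minimizer of tau*|x|^(1/2) + (x - z)^2 / 2 (two-stage grid).
grid_half_prox <- function(z, tau) {
  lim <- 2.5 * max(1, abs(z))
  xs <- seq(-lim, lim, by = 1e-3)
  obj <- function(x) tau * sqrt(abs(x)) + 0.5 * (x - z)^2
  x0 <- xs[which.min(obj(xs))]
  xs <- seq(x0 - 2e-3, x0 + 2e-3, by = 1e-7)
  xs[which.min(obj(xs))]
}

# F1 of an estimated edge support against the true cross-channel support.
support_f1 <- function(est, truth) {
  tp <- sum(est & truth)
  2 * tp / (2 * tp + sum(est & !truth) + sum(!est & truth))
}

# Threshold a causality matrix at its 90th percentile (off-diagonal support).
support_at_90pct <- function(G) {
  est <- G > stats::quantile(G, 0.9)
  diag(est) <- FALSE
  est
}

# Linearly separable 2-class, 2-D point cloud (20 points).
separable_toy <- function() {
  set.seed(42)
  X <- rbind(matrix(rnorm(20, mean = 3), 10, 2),
             matrix(rnorm(20, mean = -3), 10, 2))
  feature_set(X, rep(c("a", "b"), each = 10))
}
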