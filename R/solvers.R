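#' Solver configuration
#'
#' Bundles the hyperparameters shared by the iterative MVAR estimators.
#'
#' @param lam penalty strength `lambda >= 0` (L1 for the LASSO, L1/2 for
#'   LAPPS / SC-SGA).
#' @param eta scale `eta > 0` of the L1 fitting loss in LAPPS / SC-SGA; the
#'   loss term is `(1/eta) * ||AX - y||_1`.
#' @param rho ADMM penalty parameter (> 0).
#' @param max_iter iteration cap for iterative solvers.
#' @param tol_abs,tol_rel absolute / relative stopping tolerances.
#' @param seed integer seed for any randomized sub-procedure (cross-validated
#'   lambda selection); the solvers themselves are deterministic.
#' @param weight_mode `"abs"` (default) uses `|M_ik|` as the
#'   sensor-correlation weight, `"signed"` uses `M_ik` itself.
#' @return a `solver_config` list. The penalty exponent p is fixed at 1/2.
#' @export
solver_config <- function(lam = 1, eta = 1, rho = 1, max_iter = 500L,
                          tol_abs = 1e-6, tol_rel = 1e-4, seed = 1L,
                          weight_mode = c("abs", "signed")) {
  weight_mode <- match.arg(weight_mode)
  if (lam < 0) stop("lam must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  if (rho <= 0) stop("rho must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol_abs <= 0 || tol_rel <= 0) stop("tolerances must be > 0")
  structure(list(lam = lam, eta = eta, p = 0.5, rho = rho,
                 max_iter = as.integer(max_iter), tol_abs = tol_abs,
                 tol_rel = tol_rel, seed = as.integer(seed),
                 weight_mode = weight_mode),
            class = "solver_config")
}

#' Soft-thresholding operator
#'
#' Proximal operator of the L1 norm: `sign(z) * max(|z| - tau, 0)`
#' componentwise.
#'
#' @param z numeric vector.
#' @param tau threshold, `tau >= 0`.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(z, tau) {
  if (tau < 0) stop("threshold tau must be >= 0")
  sign(z) * pmax(abs(z) - tau, 0)
}

#' Half-thresholding operator (proximal map of the L1/2 penalty)
#'
#' Componentwise global minimizer of `tau * |x|^(1/2) + (x - z)^2 / 2`.
#' Unlike soft thresholding this map is discontinuous at its threshold: a
#' coordinate is either zeroed or jumps to a value bounded away from zero,
#' which is what makes the L1/2 penalty more aggressively sparse than the
#' L1 norm. The closed form is trigonometric: with `lam = 2 * tau`,
#' `x = (2/3) z (1 + cos((2/3)(pi - phi)))` where
#' `phi = arccos((lam/8) (|z|/3)^(-3/2))` whenever
#' `|z| > (54^(1/3)/4) lam^(2/3)` (equivalently `(3/2) tau^(2/3)`), else 0.
#'
#' @param z numeric vector.
#' @param tau threshold, `tau >= 0`.
#' @return numeric vector of the same length.
#' @export
half_threshold <- function(z, tau) {
  if (tau < 0) stop("threshold tau must be >= 0")
  if (tau == 0) return(z)
  lam <- 2 * tau
  thr <- (54^(1 / 3) / 4) * lam^(2 / 3)
  out <- numeric(length(z))
  idx <- which(abs(z) > thr)
  if (length(idx)) {
    zz <- z[idx]
    phi <- acos(pmin(1, (lam / 8) * (abs(zz) / 3)^(-1.5)))
    out[idx] <- (2 / 3) * zz * (1 + cos((2 / 3) * (pi - phi)))
  }
  out
}

new_mvar_fit <- function(coeffs, ds, method, objective_trace = NULL,
                         converged = TRUE, rank = NULL, extra = list()) {
  coeffs <- zero_snap(as.numeric(coeffs))
  resid <- as.numeric(ds$y - ds$A %*% coeffs)
  structure(c(list(coeffs = coeffs, residuals = resid,
                   resid_var = mean(resid^2), method = method,
                   objective_trace = objective_trace, converged = converged,
                   rank = rank, s = ds$s, k = ds$k, m = ds$m), extra),
            class = "mvar_fit")
}

# coefficients below 1e-10 in magnitude are reported as exact zeros so
# sparsity counts are well defined
zero_snap <- function(x, eps = 1e-10) {
  x[abs(x) < eps] <- 0
  x
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat(sprintf("<mvar_fit:%s> target k=%d, %d coefficients (%d nonzero), resid_var=%.4g%s\n",
              x$method, x$k, length(x$coeffs), sum(x$coeffs != 0), x$resid_var,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Least-squares (L2) MVAR fit
#'
#' Solves `min_X ||y - A X||_2^2` by the normal equations, falling back to
#' the minimum-norm pseudo-inverse solution when `A'A` is singular. This is
#' the classical Granger-causality estimator and the warm start for all
#' iterative solvers.
#'
#' @param ds a `design_system` from [build_design()].
#' @return an `mvar_fit` with `coeffs`, `residuals`, `resid_var` and the
#'   numerical `rank` of A.
#' @export
fit_l2 <- function(ds) {
  sv <- svd(ds$A)
  tol <- max(dim(ds$A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  x <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], ds$y)) / sv$d[pos])
  new_mvar_fit(x, ds, "l2", rank = sum(pos))
}

#' LASSO MVAR fit (cyclic coordinate descent)
#'
#' Solves `min_X ||y - A X||_2^2 + lam * ||X||_1` by cyclic coordinate
#' descent with precomputed Gram/covariance updates. With `lam = 0` this
#' reduces to the least-squares fit.
#'
#' @param ds a `design_system`.
#' @param cfg a [solver_config()]; only `lam` and `max_iter` are used. The
#'   coordinate-wise stopping tolerance is 1e-8 on the largest coefficient
#'   change per sweep.
#' @return an `mvar_fit` with a per-sweep `objective_trace`.
#' @export
fit_lasso <- function(ds, cfg = solver_config()) {
  A <- ds$A; y <- ds$y
  lam <- cfg$lam
  G <- crossprod(A)          # A'A
  b <- crossprod(A, y)[, 1L] # A'y
  d <- diag(G)
  x <- fit_l2(ds)$coeffs
  x[d == 0] <- 0
  obj <- function(x) sum((y - A %*% x)^2) + lam * sum(abs(x))
  trace <- obj(x)
  Gx <- as.numeric(G %*% x)
  converged <- FALSE
  for (it in seq_len(max(cfg$max_iter, 1000L))) {
    delta_max <- 0
    for (j in seq_along(x)) {
      if (d[j] == 0) next
      rj <- b[j] - Gx[j] + d[j] * x[j]   # partial residual correlation
      xj_new <- soft_threshold(rj, lam / 2) / d[j]
      if (xj_new != x[j]) {
        Gx <- Gx + G[, j] * (xj_new - x[j])
        delta_max <- max(delta_max, abs(xj_new - x[j]))
        x[j] <- xj_new
      }
    }
    trace <- c(trace, obj(x))
    if (delta_max < 1e-8) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_lasso: coordinate descent did not converge in ",
            max(cfg$max_iter, 1000L), " sweeps")
  new_mvar_fit(x, ds, "lasso", objective_trace = trace, converged = converged)
}

#' LAPPS MVAR fit: L1 loss with L1/2 penalty via ADMM
#'
#' Approximately minimizes `(1/eta) ||A X - y||_1 + lam * ||X||_{1/2}^{1/2}`.
#' The absolute-value loss damps the influence of outlying samples (each
#' sample contributes linearly, not quadratically), and the nonconvex L1/2
#' penalty drives small coefficients exactly to zero.
#'
#' The splitting introduces `r = A X - y` and iterates
#' \enumerate{
#'   \item `X <- half_threshold(X - (rho/L) A'(A X - y - r + u), lam / L)`
#'     with `L = rho * sigma_max(A)^2` (a linearized proximal step),
#'   \item `r <- soft_threshold(A X - y + u, 1 / (eta * rho))`,
#'   \item `u <- u + A X - y - r` (scaled dual ascent).
#' }
#' Iterations stop when both the primal residual `||A X - y - r||` and the
#' dual residual `rho ||A'(r - r_prev)||` fall below
#' `sqrt(dim) * tol_abs + tol_rel * scale`. The problem is nonconvex, so
#' the iterate is a stationary point, not a certified global minimum; the
#' deterministic least-squares warm start makes the result reproducible.
#'
#' @param ds a `design_system`.
#' @param cfg a [solver_config()].
#' @param x0 optional warm-start coefficient vector (defaults to the L2 fit).
#' @return an `mvar_fit`; `admm_trace` records per-iteration primal/dual
#'   residual norms and objective values.
#' @export
fit_lapps <- function(ds, cfg = solver_config(), x0 = NULL) {
  A <- ds$A; y <- ds$y
  lam <- cfg$lam; eta <- cfg$eta; rho <- cfg$rho
  smax2 <- svd(A, nu = 0, nv = 0)$d[1L]^2
  if (smax2 == 0) return(new_mvar_fit(numeric(ncol(A)), ds, "lapps"))
  L <- rho * smax2
  x <- if (is.null(x0)) fit_l2(ds)$coeffs else as.numeric(x0)
  Ax <- as.numeric(A %*% x)
  r <- Ax - y
  u <- numeric(length(y))
  obj <- function(Ax, x) sum(abs(Ax - y)) / eta + lam * sum(sqrt(abs(x)))
  pr <- du <- ob <- numeric(0)
  converged <- FALSE
  grow <- 0L
  prev_pr <- Inf
  for (it in seq_len(cfg$max_iter)) {
    x <- half_threshold(x - (rho / L) * crossprod(A, Ax - y - r + u)[, 1L],
                        lam / L)
    Ax <- as.numeric(A %*% x)
    r_old <- r
    r <- soft_threshold(Ax - y + u, 1 / (eta * rho))
    u <- u + Ax - y - r
    primal <- sqrt(sum((Ax - y - r)^2))
    dual <- rho * sqrt(sum(crossprod(A, r - r_old)^2))
    pr <- c(pr, primal); du <- c(du, dual); ob <- c(ob, obj(Ax, x))
    eps_pri <- sqrt(length(y)) * cfg$tol_abs +
      cfg$tol_rel * max(sqrt(sum(Ax^2)), sqrt(sum(r^2)), sqrt(sum(y^2)))
    eps_dua <- sqrt(length(x)) * cfg$tol_abs +
      cfg$tol_rel * rho * sqrt(sum(crossprod(A, u)^2))
    if (primal < eps_pri && dual < eps_dua) { converged <- TRUE; break }
    # growth below the scale of y is the normal rise from the warm start
    grow <- if (primal > prev_pr && primal > sqrt(sum(y^2))) grow + 1L else 0L
    if (grow >= 50L)
      stop("fit_lapps: ADMM diverging (primal residual grew for 50 ",
           "consecutive iterations); try a smaller rho or larger eta")
    prev_pr <- primal
  }
  new_mvar_fit(x, ds, "lapps", objective_trace = ob, converged = converged,
               extra = list(admm_trace = list(primal_res = pr, dual_res = du)))
}

#' Scale design-matrix blocks by sensor-correlation weights
#'
#' Injects the Pearson correlation structure of the sensors into the design:
#' for target channel `k = ds$k`, every lag column of predictor channel i is
#' multiplied by the scalar weight `w_i = |M[i, k]|` (or the signed `M[i, k]`
#' when `weight_mode = "signed"`). Channels uncorrelated with the target are
#' thereby suppressed before the sparse fit, acting as a prior on which
#' causal links are plausible.
#'
#' @param ds a `design_system`.
#' @param E an m x m Pearson correlation matrix (see
#'   [correlation_matrix()]).
#' @param weight_mode `"abs"` or `"signed"`.
#' @return a `design_system` with scaled `A` and the applied
#'   `block_weights` recorded (composed with any existing weights).
#' @export
weight_design <- function(ds, E, weight_mode = c("abs", "signed")) {
  weight_mode <- match.arg(weight_mode)
  E <- unclass(E)
  if (!is.matrix(E) || nrow(E) != ds$m || ncol(E) != ds$m)
    stop("correlation matrix is ", paste(dim(E), collapse = " x "),
         " but design has m = ", ds$m, " channels")
  w <- E[, ds$k]
  if (weight_mode == "abs") w <- abs(w)
  scale_cols <- rep(w, each = ds$s)
  ds$A <- sweep(ds$A, 2L, scale_cols, `*`)
  ds$block_weights <- ds$block_weights * w
  ds
}

#' Sensor-correlation weighted sparse Granger fit (SC-SGA)
#'
#' Runs [fit_lapps()] on the correlation-weighted design from
#' [weight_design()], then maps the coefficients back to the original
#' predictor scale (each block multiplied by its weight), so the returned
#' coefficients keep the plain autoregressive interpretation. Channels with
#' zero correlation to the target are forced out of the model entirely.
#'
#' @inheritParams fit_lapps
#' @param E an m x m Pearson correlation matrix of the same channels.
#' @return an `mvar_fit` (method `"scsga"`) with `block_weights` recorded.
#'   `residuals`/`resid_var` are computed from the original-scale design,
#'   which equals the weighted design's fit because the scaling cancels.
#' @export
fit_scsga <- function(ds, E, cfg = solver_config()) {
  wds <- weight_design(ds, E, cfg$weight_mode)
  wfit <- fit_lapps(wds, cfg)
  back <- rep(wds$block_weights, each = ds$s)
  coeffs <- wfit$coeffs * back
  new_mvar_fit(coeffs, ds, "scsga", objective_trace = wfit$objective_trace,
               converged = wfit$converged,
               extra = list(block_weights = wds$block_weights,
                            weighted_coeffs = wfit$coeffs,
                            admm_trace = wfit$admm_trace))
}

#' Choose the L1/2 penalty strength by cross-validated prediction error
#'
#' Splits the design rows into contiguous-free random folds, fits LAPPS (or
#' SC-SGA) on the training rows for each candidate `lam`, and scores the
#' mean absolute prediction error on the held-out rows. Returns the `lam`
#' minimizing the average validation error.
#'
#' @param ds a `design_system`.
#' @param cfg a [solver_config()]; `cfg$seed` fixes the fold shuffle.
#' @param grid candidate penalty values (default a log grid).
#' @param folds number of folds.
#' @param E optional correlation matrix; when given the weighted (SC-SGA)
#'   problem is cross-validated instead.
#' @return the selected `lam` (a scalar from `grid`).
#' @export
select_lambda_cv <- function(ds, cfg = solver_config(),
                             grid = 10^seq(-1, 2, length.out = 7),
                             folds = 5L, E = NULL) {
  if (!is.null(E)) ds <- weight_design(ds, E, cfg$weight_mode)
  nr <- nrow(ds$A)
  rng <- local_rng(cfg$seed)
  fold_id <- sample(rep_len(seq_len(folds), nr))
  rng()
  err <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sub <- ds
    sub$A <- ds$A[tr, , drop = FALSE]; sub$y <- ds$y[tr]
    x0 <- fit_l2(sub)$coeffs
    for (g in seq_along(grid)) {
      cfg_g <- cfg; cfg_g$lam <- grid[g]
      fit <- fit_lapps(sub, cfg_g, x0 = x0)
      pred <- ds$A[!tr, , drop = FALSE] %*% fit$coeffs
      err[g, f] <- mean(abs(ds$y[!tr] - pred))
    }
  }
  grid[which.min(rowMeans(err))]
}

# Run `code` under a temporary RNG state seeded with `seed`; returns a
# restorer function. Keeps package functions from disturbing the caller's
# RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
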