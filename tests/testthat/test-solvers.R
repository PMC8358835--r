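test_that("soft_threshold matches its definition", {
  expect_equal(soft_threshold(c(2, -0.5), 1), c(1, 0))
  z <- c(-3, 0.2, 0, 5)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(rep(0, 4), 3), rep(0, 4))
  expect_error(soft_threshold(1, -0.1), ">= 0")
})

test_that("half_threshold solves the scalar L1/2 proximal problem", {
  expect_equal(half_threshold(0, 1), 0)
  z <- c(-1.3, 0.4, 2)
  expect_equal(half_threshold(z, 0), z)
  # frozen from the two-stage grid oracle (grid_half_prox(1, 0.2))
  expect_equal(half_threshold(1, 0.2), grid_half_prox(1, 0.2), tolerance = 1e-6)
  expect_equal(half_threshold(1, 0.2), 0.8942525, tolerance = 1e-6)
  # small inputs are zeroed, with a jump (no continuum of tiny outputs)
  expect_equal(half_threshold(0.3, 0.2), 0)
  expect_error(half_threshold(1, -1), ">= 0")
})

test_that("fit_l2 recovers exact models and tolerates singular designs", {
  # noiseless AR(1): W(t) = 0.5 W(t-1), W(1) = 1
  spec <- simulation_spec(m = 1, s = 1, n = 20, noise_sd = 0,
                          outlier_frac = 0, seed = 1)
  gt <- fixed_ground_truth(array(0.5, c(1, 1, 1)), spec)
  rec <- simulate_var(gt, seed = 1, burn_in = 0, init = matrix(1, 1, 1))
  fit <- fit_l2(build_design(rec, 1, 1))
  expect_equal(fit$coeffs, 0.5, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-12)

  # duplicated columns: minimum-norm solution, no error
  set.seed(3)
  A <- matrix(rnorm(20), 10, 2)
  A <- cbind(A, A[, 1])
  y <- rnorm(10)
  fit2 <- fit_l2(fake_ds(A, y, s = 1))
  expect_equal(fit2$rank, 2)
  expect_equal(fit2$coeffs[1], fit2$coeffs[3])  # min-norm splits evenly

  # closed-form normal-equations oracle on a random full-rank system
  rec3 <- rand_recording(5, 200, seed = 7)
  ds3 <- build_design(rec3, 3, 2)
  oracle <- unname(solve(crossprod(ds3$A), crossprod(ds3$A, ds3$y))[, 1])
  expect_equal(fit_l2(ds3)$coeffs, oracle, tolerance = 1e-8)
})

test_that("fit_lasso satisfies its closed forms and reduction limits", {
  rec <- rand_recording(3, 100, seed = 5)
  ds <- build_design(rec, 2, 1)

  # lambda = 0 reduces to least squares
  f0 <- fit_lasso(ds, solver_config(lam = 0))
  expect_equal(f0$coeffs, fit_l2(ds)$coeffs, tolerance = 1e-6)

  # one-column single-row closed form: X = soft_threshold(A'y, lam/2) / A'A
  f1 <- fit_lasso(fake_ds(matrix(1, 1, 1), 2), solver_config(lam = 2))
  expect_equal(f1$coeffs, 1)

  # null-solution bound
  lam_max <- 2 * max(abs(crossprod(ds$A, ds$y)))
  fnull <- fit_lasso(ds, solver_config(lam = lam_max))
  expect_equal(fnull$coeffs, rep(0, ncol(ds$A)))

  # objective non-increasing per sweep
  fmid <- fit_lasso(ds, solver_config(lam = 5))
  expect_true(all(diff(fmid$objective_trace) <= 1e-10))
})

test_that("lasso sparsity is non-decreasing in lambda", {
  rec <- rand_recording(4, 150, seed = 11)
  ds <- build_design(rec, 2, 1)
  lam_grid <- exp(seq(log(0.01), log(500), length.out = 10))
  nz <- vapply(lam_grid, function(l)
    sum(fit_lasso(ds, solver_config(lam = l))$coeffs != 0), integer(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("fit_lapps honors fixed points, feasibility and the separable oracle", {
  # all-zero response: zero solution
  z <- fit_lapps(fake_ds(matrix(rnorm(20), 10, 2), rep(0, 10)),
                 solver_config(lam = 1))
  expect_equal(z$coeffs, c(0, 0))

  # y in the span of a sparse X with negligible penalty is reproduced
  set.seed(21)
  A <- matrix(rnorm(200), 50, 4)
  x_true <- c(1.5, 0, -2, 0)
  y <- as.numeric(A %*% x_true)
  f <- fit_lapps(fake_ds(A, y, s = 1), solver_config(lam = 1e-8, max_iter = 2000))
  expect_lt(sum(abs(A %*% f$coeffs - y)) / sum(abs(y)), 1e-3)

  # identity design: solution separates into per-coordinate problems
  # min (1/eta)|x - y_i| + lam * sqrt(|x|), solved by a brute-force grid;
  # y values chosen outside the narrow band where the nonconvex problem has
  # two competing local minima and ADMM may settle on the zero basin
  yid <- c(2, 0.2, -1.2, 0.05)
  cfg <- solver_config(lam = 0.6, eta = 1, max_iter = 3000, tol_abs = 1e-9,
                       tol_rel = 1e-7)
  fid <- fit_lapps(fake_ds(diag(4), yid, s = 1), cfg)
  oracle <- vapply(yid, function(yi) {
    xs <- seq(-3, 3, by = 1e-4)
    xs[which.min(abs(xs - yi) / cfg$eta + cfg$lam * sqrt(abs(xs)))]
  }, numeric(1))
  expect_equal(fid$coeffs, oracle, tolerance = 1e-3)

  # ADMM residual norms are recorded every iteration
  expect_true(all(fid$admm_trace$primal_res >= 0))
  expect_identical(length(fid$admm_trace$primal_res),
                   length(fid$admm_trace$dual_res))
})

test_that("weight_design scales predictor blocks by target correlation", {
  rec <- rand_recording(2, 60, seed = 13)
  ds <- build_design(rec, 2, 1)

  E1 <- matrix(1, 2, 2)
  expect_equal(weight_design(ds, E1)$A, ds$A)

  Eh <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  w <- weight_design(ds, Eh)
  expect_equal(w$A[, 1:2], ds$A[, 1:2])
  expect_equal(w$A[, 3:4], 0.5 * ds$A[, 3:4])
  expect_equal(w$block_weights, c(1, 0.5))

  E0 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(unname(weight_design(ds, E0)$A[, 3:4]),
               matrix(0, nrow(ds$A), 2))

  expect_error(weight_design(ds, matrix(1, 3, 3)), "m = 2")
})

test_that("fit_scsga reduces to fit_lapps under unit weights and preserves support under uniform ones", {
  spec <- simulation_spec(outlier_frac = 0)
  gt <- sample_sparse_var(spec)
  rec <- center_recording(simulate_var(gt))
  cfg <- solver_config(lam = 3, seed = 7)
  E1 <- matrix(1, spec$m, spec$m)
  Ec <- matrix(0.9, spec$m, spec$m); diag(Ec) <- 1
  for (k in c(1, 4)) {
    ds <- build_design(rec, spec$s, k)
    fl <- fit_lapps(ds, cfg)
    expect_equal(fit_scsga(ds, E1, cfg)$coeffs, fl$coeffs, tolerance = 1e-6)
    # uniform off-diagonal correlation: same support after back-scaling
    expect_identical(fit_scsga(ds, Ec, cfg)$coeffs != 0, fl$coeffs != 0)
  }
})

test_that("correlation weighting suppresses uncorrelated high-amplitude channels", {
  set.seed(99)
  n <- 300
  target <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
  noise <- 50 * rnorm(n)   # large spurious amplitude, no coupling
  other <- as.numeric(stats::arima.sim(list(ar = 0.4), n))
  rec <- center_recording(recording(rbind(target, noise, other), 200))
  E <- correlation_matrix(rec)
  expect_lt(abs(E[2, 1]), 0.1)
  ds <- build_design(rec, 2, 1)
  cfg <- solver_config(lam = 5, seed = 1)
  f_sc <- fit_scsga(ds, E, cfg)
  f_la <- fit_lapps(ds, cfg)
  expect_equal(f_sc$coeffs[3:4], c(0, 0))  # noise-channel block zeroed
  expect_lte(sum(abs(f_sc$coeffs[3:4])), sum(abs(f_la$coeffs[3:4])))
})

test_that("the L1 loss resists outliers better than least squares", {
  # single-seed version of the acceptance sweep
  spec <- simulation_spec()
  gt <- sample_sparse_var(spec)
  rec <- simulate_var(gt, seed = spec$seed + 1)
  rec <- inject_outliers(rec, spec$outlier_frac, spec$outlier_amp,
                         seed = spec$seed + 2)
  rec <- center_recording(rec)
  fits2 <- lapply(seq_len(spec$m), function(k) fit_l2(build_design(rec, spec$s, k)))
  cfg <- solver_config(lam = 3, seed = 1)
  fitsL <- lapply(seq_len(spec$m), function(k) fit_lapps(build_design(rec, spec$s, k), cfg))
  rmse <- function(fits) sqrt(mean((coeffs_to_tensor(fits, spec$m, spec$s) - gt$tensor)^2))
  expect_lt(rmse(fitsL), rmse(fits2))
})

test_that("solver_config validates its fields", {
  expect_error(solver_config(lam = -1), "lam")
  expect_error(solver_config(eta = 0), "eta")
  expect_error(solver_config(rho = -2), "rho")
  expect_identical(solver_config()$p, 0.5)
})
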