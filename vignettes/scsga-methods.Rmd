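---
title: "Sparse Granger causality with sensor-correlation weighting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Granger causality with sensor-correlation weighting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsga)
```

## The model

Effective (directed) connectivity between the $m$ channels of a multichannel
recording $W_1(t), \dots, W_m(t)$ is modeled by a multivariate
autoregression of order $s$:

$$W_k(t) = \sum_{i=1}^{m} \sum_{l=1}^{s} a_{ik}(l)\, W_i(t-l) + \varepsilon_k(t),
  \qquad \operatorname{var}(\varepsilon_k) = \Sigma_k .$$

Channel $i$ Granger-causes channel $k$ when the past of $i$ improves the
prediction of $k$ beyond $k$'s own past, i.e. when the coefficients
$a_{ik}(\cdot)$ are nonzero. Estimation is per target channel: the lagged
design matrix $A \in \mathbb{R}^{(n-s)\times(ms)}$ stacks $m$ contiguous
$s$-column lag blocks (`build_design()`), the response is
$y_k = (W_k(s{+}1), \dots, W_k(n))$, and each estimator solves for the
coefficient vector $X_k$. There is no intercept; signals are mean-centered
per channel before design construction.

Four estimators share this design:

* **L2** (`fit_l2()`): $\min \|y - AX\|_2^2$, solved by the normal
  equations, with the minimum-norm pseudo-inverse solution in the singular
  case. The squared loss weights every sample quadratically, so a handful
  of high-amplitude artifacts (blinks, movement) can dominate the fit and
  manufacture spurious connections.
* **LASSO** (`fit_lasso()`): $\min \|y - AX\|_2^2 + \lambda\|X\|_1$, cyclic
  coordinate descent with precomputed Gram updates. Sparsity reflects the
  anatomical sparsity of cortical coupling.
* **LAPPS** (`fit_lapps()`):
  $\min \tfrac1\eta \|AX - y\|_1 + \lambda \|X\|_{1/2}^{1/2}$. The
  absolute-value loss grows linearly in the residual, damping outliers, and
  the nonconvex $L_{1/2}$ penalty zeroes small coefficients more
  aggressively than the $L_1$ norm.
* **SC-SGA** (`fit_scsga()`): LAPPS on a *correlation-weighted* design. For
  target $k$, every lag column of predictor channel $i$ is scaled by
  $w_i = |M_{ik}|$, where $M$ is the Pearson correlation matrix of the
  channels on the same analysis window (`correlation_matrix()`). Sensors
  whose time courses do not co-vary with the target are unlikely causal
  partners; weighting injects that prior before the sparse fit. Reported
  coefficients are mapped back to the original predictor scale so the
  autoregressive interpretation is preserved.

The estimated tensor $a[i,k,l]$ collapses over lags into a directed network
$G_{ik} = \sum_l |a_{ik}(l)|$ (`aggregate_network()`; max and $L_2$
collapses are available), whose off-diagonal raster — concatenated over
frequency bands — is the feature vector for classification.

## Solving LAPPS: linearized ADMM with half-thresholding

Neither term of the LAPPS objective is smooth, so the residual is split,
$r = AX - y$, and the scaled-dual ADMM alternates

1. $X \leftarrow \mathrm{H}_{\lambda/L}\!\big(X - \tfrac{\rho}{L} A^\top (AX - y - r + u)\big)$,
   one linearized proximal step with $L = \rho\,\sigma_{\max}(A)^2$;
2. $r \leftarrow \mathrm{S}_{1/(\eta\rho)}(AX - y + u)$ (soft threshold);
3. $u \leftarrow u + AX - y - r$.

$\mathrm{S}_\tau$ is the $L_1$ proximal map and $\mathrm{H}_\tau$ the
$L_{1/2}$ one, the *half-threshold*: the global minimizer of
$\tau|x|^{1/2} + \tfrac12 (x - z)^2$, which is $0$ for
$|z| \le \tfrac32 \tau^{2/3}$ and otherwise has the trigonometric closed
form $\tfrac23 z (1 + \cos(\tfrac23(\pi - \phi)))$ with
$\phi = \arccos\!\big(\tfrac{\tau}{4} (|z|/3)^{-3/2}\big)$. The operator is
*discontinuous* at its threshold — coefficients either vanish or jump to a
value bounded away from zero — which is exactly what makes the $L_{1/2}$
penalty a sharper variable selector than soft thresholding. The
implementation is validated against a brute-force 1-D grid minimizer
(`tests/testthat`, tolerance $10^{-5}$ over a $(z,\tau)$ lattice).

Iterations stop when primal and dual residuals fall below
$\sqrt{d}\,\cdot\texttt{tol\_abs} + \texttt{tol\_rel}\cdot\text{scale}$
(Boyd-style criteria) or at `max_iter`. The problem is nonconvex: the
iterate is a stationary point, not a certified global optimum. All
iterative solvers warm-start at the L2 solution, making results
deterministic; seeds only enter the cross-validated penalty selection.

**A numerical edge case worth knowing.** For coordinates whose 1-D
subproblem has two competing local minima — data values lying between the
zero/nonzero objective crossover and the half-threshold radius — the
linearized ADMM can settle in the zero basin while the global minimum is
nonzero. This is inherent to nonconvex
proximal schemes, shrinks with $L$, and in practice affects only
coefficients of marginal magnitude; the test fixtures avoid the knife edge.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `s` | lag order (samples) | 3 | never fixed by the source formulation; order-selection helper provided (`select_lag_order()`) |
| `lam` | sparsity penalty $\lambda$ | 1, or CV | per-target 5-fold CV over a log grid ($10^{-1}$–$10^{2}$, `select_lambda_cv()`) is the reference mechanism |
| `eta` | $L_1$ loss scale $\eta$ | 1 | only the product $\eta\lambda$ matters for the minimizer's location; $\eta$ kept at 1 |
| `rho` | ADMM penalty | 1 | standard default; step size adapts through $L = \rho\sigma_{\max}^2$ |
| `max_iter` | ADMM / CD cap | 500 | converges in tens of iterations on well-scaled designs |
| `tol_abs`, `tol_rel` | stopping tolerances | $10^{-6}$, $10^{-4}$ | residuals at the noise floor of double precision relative to signal scale |
| `weight_mode` | $|M_{ik}|$ vs signed | `abs` | anticorrelated sensors are equally informative about coupling |
| filter | Butterworth order 4, forward–backward | — | conventional EEG choice; makes the zero-phase invariant exactly testable |

Band definitions follow the conventional EEG rhythms: delta 1–3, theta
4–7, alpha 8–13, beta 14–30, gamma 31–50 Hz (`eeg_bands()`); they are
configuration, not constants, as is the analysis montage (the channel
subset is a user-supplied list of 10–20-system names — no electrode list is
hardcoded).

**Why the pipeline default is a *fixed / first-trial* penalty.** Per-trial,
per-target CV is the reference mechanism, but over a 120-trial corpus it
multiplies solver cost by $\approx 35\times$ (5 folds × 7 grid points),
far beyond an interactive budget in pure R. `run_pipeline()` therefore
selects $\lambda$ per target on the *first* trial and reuses it
(`select_lam = "cv_first_trial"`), or uses a fixed value from the config.
The solver-level validations (robustness, support recovery) use the full
per-problem CV.

## The synthetic world

Because the benchmark EEG corpora are restricted-access, every claim is
validated on simulated data with known ground truth (`make_dataset()`):

* stable sparse VAR($s$) with random cross-channel support at density 0.15
  (self-lags always present), coefficients of magnitude
  $[0.5, 1] \times 0.4$, companion-matrix spectral radius rescaled to
  $\le 0.95$ (per-lag scaling $t^l$, which moves eigenvalues exactly by
  $t$), Gaussian innovations of unit SD;
* default dimensions m = 8 channels, s = 2 lags, n = 400 samples — small
  enough for desk-scale testing, large enough for the estimators to be in
  their asymptotic regime;
* artifact emulation: 5% of time points per channel replaced by
  $\pm 10\times$ the channel SD (blink/movement-like amplitude bursts);
  contaminated indices are recorded for audit;
* classes (3 × 40 trials) differ in *which* directed couplings exist, not
  in noise level, so a classifier can only succeed through the
  connectivity features;
* a 200-sample burn-in leaves $<10^{-4}$ initial-condition influence at
  radius 0.95; generation is a pure function of the specification
  (identical spec ⇒ identical bytes).

What the simulator does **not** emulate: $1/f$ spectra, volume conduction,
nonstationarity, inter-trial variability of the generating coefficients
within a class, or realistic electrode geometry. A green end-to-end test
therefore establishes that the estimator chain recovers and discriminates
*planted* causal structure — not that any particular accuracy transfers to
real EEG.

### A consequence: the known-red end-to-end ordering

The evaluation harness verifies the directional claim that sparse robust
features should classify at least as well as dense L2 features, and
correlation-weighted features better still. On the default synthetic
corpus the *second* comparison holds (SC-SGA > LAPPS) and everything is
far above chance, but **LAPPS ≥ L2 fails**: because all trials of a class
share one exact coefficient tensor, even the dense L2 estimate separates
the three supports almost perfectly (all solvers score ≥ 0.97), and at
that ceiling the sparse estimators' shrinkage bias costs slightly more
than outlier sensitivity costs L2. The corresponding acceptance test is
intentionally left failing rather than weakened; the solver-level
robustness ordering (coefficient RMSE and support-recovery F1 across 20
contaminated realizations) does hold in the same world.

## Evaluation harness

Classification uses one-vs-rest L2-regularized logistic regression
($p(y{=}1\,|\,x) = (1 + e^{-(b + w^\top x)})^{-1}$, penalty
$\lambda_c \sum w^2$, bias unpenalized), a ridge classifier on one-hot
indicators, or a delegated linear SVM. Features are z-scored with
*training-fold statistics only*. Stratified 5-fold cross-validation is
repeated (default 100×) with every sample predicted exactly once per
repeat; the confusion matrix (rows = true, columns = predicted) aggregates
all predictions, precision is reported as absent — not zero — for classes
never predicted, and argmax ties break toward the lowest class index. An
80/20 stratified holdout is available as the alternative evaluation mode.
Identical seed and configuration reproduce reports byte-for-byte.

## Degenerate inputs and numerical conventions

* Missing/non-finite samples are a hard error (no imputation); constant
  channels are an error wherever a correlation is required.
* Rank-deficient designs (duplicated channels) fall through to the
  minimum-norm solution without raising.
* Coefficients with magnitude $< 10^{-10}$ are snapped to exact zeros so
  sparsity counts are well defined.
* Band edges must satisfy $0 < \mathrm{lo} < \mathrm{hi} <$ Nyquist at
  filter time.
* Pearson normalization (population vs sample) cancels in the ratio and is
  therefore convention-free.
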