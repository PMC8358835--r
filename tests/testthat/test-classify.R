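test_that("logistic regression separates a separable toy and respects symmetry", {
  toy <- separable_toy()
  model <- fit_logistic_l2(toy, reg_strength = 0.01)
  expect_equal(mean(predict(model, toy$X) == as.character(toy$labels)), 1.0)

  # extreme penalty: weights collapse, predictions fall to the majority class
  skew <- feature_set(toy$X, c(rep("a", 13), rep("b", 7)))
  heavy <- fit_logistic_l2(skew, reg_strength = 1e6)
  expect_lt(max(abs(heavy$weights)), 1e-3)
  expect_identical(unique(predict(heavy, toy$X)), "a")

  # flipping labels mirrors the per-class weights
  flipped <- feature_set(toy$X, ifelse(toy$labels == "a", "b", "a"))
  mf <- fit_logistic_l2(flipped, reg_strength = 0.01)
  expect_equal(mf$weights["a", ], model$weights["b", ], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(predict(mf, toy$X),
               ifelse(predict(model, toy$X) == "a", "b", "a"))

  expect_error(fit_logistic_l2(feature_set(toy$X, rep("a", 20))), "2 classes")
})

test_that("ridge classifier matches least squares at zero penalty", {
  toy <- separable_toy()
  model <- fit_ridge(toy, reg_strength = 0.1)
  expect_equal(mean(predict(model, toy$X) == as.character(toy$labels)), 1.0)

  m0 <- fit_ridge(toy, reg_strength = 0)
  # unpenalized one-hot least-squares oracle with explicit intercept
  X1 <- cbind(1, toy$X)
  Y <- cbind(a = as.numeric(toy$labels == "a"), b = as.numeric(toy$labels == "b"))
  W <- solve(crossprod(X1), crossprod(X1, Y))
  expect_equal(unname(m0$weights), unname(t(W[-1, ])), tolerance = 1e-8)
  expect_equal(unname(m0$bias), unname(W[1, ]), tolerance = 1e-8)

  # duplicating every sample leaves the model unchanged
  dup <- feature_set(rbind(toy$X, toy$X), c(toy$labels, toy$labels))
  md <- fit_ridge(dup, reg_strength = 0)
  expect_equal(md$weights, m0$weights, tolerance = 1e-8)
})

test_that("confusion_and_metrics reproduces hand-computed values", {
  rep <- confusion_and_metrics(c("+", "+", "-", "-"), c("+", "-", "-", "-"))
  expect_equal(unname(rep$confusion),
               rbind(c(1, 1), c(0, 2)))  # classes in radix order: "+", "-"
  expect_equal(rep$precision[["+"]], 1.0)
  expect_equal(rep$recall[["+"]], 0.5)
  expect_equal(rep$accuracy, 0.75)

  # perfect prediction
  perf <- confusion_and_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perf$accuracy, 1.0)
  expect_equal(unname(diag(perf$confusion)), c(2, 1))

  # degenerate: everything predicted one class -> other precision absent
  deg <- confusion_and_metrics(c("a", "b", "b"), c("a", "a", "a"))
  expect_true(is.na(deg$precision[["b"]]))
  expect_equal(deg$precision[["a"]], 1 / 3)

  expect_error(confusion_and_metrics(c("a"), c("a", "b")), "length")
})

test_that("metrics recomputed from the stored confusion match the scalars", {
  set.seed(31)
  truth <- sample(letters[1:3], 60, replace = TRUE)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  rep <- confusion_and_metrics(truth, pred)
  cm <- rep$confusion
  expect_equal(rep$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(rep$recall), unname(diag(cm) / rowSums(cm)))
  expect_equal(rowSums(cm), table(factor(truth))[rownames(cm)],
               ignore_attr = TRUE)
})

test_that("cross_validate partitions, stratifies and reproduces from seed", {
  set.seed(37)
  X <- matrix(rnorm(10 * 3), 10, 3)
  fs <- feature_set(X, rep(c("a", "b"), each = 5))
  r1 <- cross_validate(fs, folds = 5, repeats = 1, seed = 123)
  # every sample predicted exactly once per repeat
  expect_equal(sum(r1$confusion), 10)
  expect_equal(unname(rowSums(r1$confusion)), c(5, 5))
  r2 <- cross_validate(fs, folds = 5, repeats = 1, seed = 123)
  expect_identical(r1, r2)

  expect_error(cross_validate(feature_set(X, c(rep("a", 9), "b")), folds = 5),
               "fewer than folds")
})

test_that("label-shuffled data scores at chance level", {
  set.seed(41)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  labels <- rep(c("a", "b", "c"), each = n / 3)  # independent of X
  rep <- cross_validate(feature_set(X, labels), folds = 5, repeats = 20,
                        seed = 7)
  chance <- 1 / 3
  band <- 3 * sqrt(chance * (1 - chance) / n)
  expect_lt(abs(rep$mean_sd[["mean"]] - chance), band)
})

test_that("holdout evaluation stratifies an 80/20 split", {
  set.seed(43)
  X <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  fs <- feature_set(X, rep(c("a", "b"), each = 20))
  rep <- evaluate_holdout(fs, seed = 5)
  expect_equal(sum(rep$confusion), 8)          # 20% of 40
  expect_equal(unname(rowSums(rep$confusion)), c(4, 4))
  expect_equal(rep$accuracy, 1.0)
})

test_that("the svm backend is delegated or clearly absent", {
  toy <- separable_toy()
  if (requireNamespace("e1071", quietly = TRUE)) {
    model <- fit_svm(toy)
    expect_equal(mean(predict(model, toy$X) == as.character(toy$labels)), 1.0)
  } else {
    expect_error(fit_svm(toy), "e1071")
  }
})
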