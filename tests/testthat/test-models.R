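# The regression families behind the uniform fit/predict surface.

make_xy <- function(n = 300, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("c", 1:p)))
  list(X = X, y = 2 * X[, 1] - X[, 2])
}

test_that("unknown families and hyperparameters are rejected", {
  expect_error(regressor_spec("deep_transformer"), "arg")
  expect_error(regressor_spec("linear_least_squares", list(eta = 1)),
               "unknown hyperparameter")
})

test_that("the linear family solves exact least squares", {
  d <- make_xy()
  fit <- fit_regressor(regressor_spec("linear_least_squares"), d$X, d$y)
  expect_lt(mean((predict(fit, d$X) - d$y)^2), 1e-10)
  cf <- fit$model$coefficients
  expect_equal(unname(cf[c("c1", "c2")]), c(2, -1), tolerance = 1e-6)
})

test_that("every family reproduces a constant target with zero MSE", {
  d <- make_xy(n = 80)
  y <- rep(3.5, 80)
  for (fam in c("gradient_boosted_trees", "classic_gradient_boosting",
                "linear_least_squares", "support_vector",
                "multilayer_perceptron")) {
    fit <- fit_regressor(regressor_spec(fam), d$X, y)
    expect_equal(mean((predict(fit, d$X) - y)^2), 0, label = fam)
  }
})

test_that("boosted trees capture an axis-aligned step almost exactly", {
  set.seed(5)
  X <- matrix(rnorm(1000 * 4), 1000, 4)
  y <- ifelse(X[, 2] > 0.3, 2, -1)
  for (fam in c("gradient_boosted_trees", "classic_gradient_boosting")) {
    fit <- fit_regressor(regressor_spec(fam, list(nrounds = 50)), X, y)
    expect_gt(cor(predict(fit, X), y), 0.99)
  }
})

test_that("prediction enforces the training fingerprint", {
  d <- make_xy()
  fit <- fit_regressor(regressor_spec("linear_least_squares"), d$X, d$y)
  expect_error(predict(fit, d$X[, 1:3]), "expects 5 columns")
  Xren <- d$X; colnames(Xren) <- paste0("z", 1:5)
  expect_error(predict(fit, Xren), "column names")
  expect_length(predict(fit, d$X[1, , drop = FALSE]), 1)
})

test_that("permuting prediction rows permutes predictions identically", {
  d <- make_xy(n = 120)
  fit <- fit_regressor(fast_tree_spec(nrounds = 30), d$X, d$y)
  perm <- sample(120)
  expect_identical(predict(fit, d$X)[perm],
                   predict(fit, d$X[perm, , drop = FALSE]))
})

test_that("identical seeds reproduce identical predictions", {
  d <- make_xy(n = 200, p = 8)
  y <- d$y + rnorm(200, sd = 0.2)
  for (fam in c("gradient_boosted_trees", "linear_least_squares")) {
    hp <- if (fam == "gradient_boosted_trees")
      list(nrounds = 40, subsample = 0.8) else list()
    p1 <- predict(fit_regressor(regressor_spec(fam, hp, seed = 7), d$X, y),
                  d$X)
    p2 <- predict(fit_regressor(regressor_spec(fam, hp, seed = 7), d$X, y),
                  d$X)
    expect_identical(p1, p2, label = fam)
  }
  for (fam in c("support_vector", "multilayer_perceptron")) {
    p1 <- predict(fit_regressor(regressor_spec(fam, seed = 7), d$X, y), d$X)
    p2 <- predict(fit_regressor(regressor_spec(fam, seed = 7), d$X, y), d$X)
    expect_equal(p1, p2, tolerance = 1e-10, label = fam)
  }
})

test_that("grid search maximizes validation PCC with deterministic ties", {
  set.seed(11)
  X <- matrix(rnorm(600 * 3), 600, 3)
  y <- X[, 1] * X[, 2] + rnorm(600, sd = 0.1)  # pure interaction target
  tr <- list(X = X[1:400, ], y = y[1:400])
  va <- list(X = X[401:600, ], y = y[401:600])
  spec <- fast_tree_spec(nrounds = 100)
  one <- grid_search(spec, list(max_depth = 3), tr, va)
  expect_equal(one$best_spec$hyperparameters$max_depth, 3)
  # depth-1 stumps are additive and cannot represent the interaction
  gs <- grid_search(spec, list(max_depth = c(1, 4)), tr, va)
  expect_equal(gs$best_spec$hyperparameters$max_depth, 4)
  expect_gt(diff(range(gs$table$validation_pcc)), 0.2)
  # identical points: the first in lexicographic order wins
  tie <- grid_search(spec, list(nrounds = c(40, 40)), tr, va)
  expect_equal(which(tie$table$validation_pcc ==
                       max(tie$table$validation_pcc))[1], 1)
  expect_error(grid_search(spec, list(), tr, va), "empty grid")
})
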