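# Uniform train/predict interface over the benchmarked regression families.

REGRESSOR_FAMILIES <- c("gradient_boosted_trees", "classic_gradient_boosting",
                        "linear_least_squares", "support_vector",
                        "multilayer_perceptron")

default_hyperparameters <- function(family) {
  switch(family,
    gradient_boosted_trees = list(nrounds = 300L, max_depth = 6L, eta = 0.05,
                                  subsample = 1.0, colsample_bytree = 1.0,
                                  min_child_weight = 1),
    classic_gradient_boosting = list(nrounds = 100L, max_depth = 3L,
                                     shrinkage = 0.1, subsample = 1.0),
    linear_least_squares = list(),
    support_vector = list(kernel = "radial", cost = 1, epsilon = 0.1,
                          gamma = NA),
    multilayer_perceptron = list(hidden = 32L, maxit = 200L, decay = 1e-4,
                                 chunk_iters = 50L, patience = 3L))
}

#' Specify a regression model
#'
#' @param family One of `"gradient_boosted_trees"` (xgboost),
#'   `"classic_gradient_boosting"` (stagewise least-squares boosting over
#'   rpart trees), `"linear_least_squares"`, `"support_vector"` (epsilon-SVR)
#'   or `"multilayer_perceptron"` (single hidden layer).
#' @param hyperparameters Named list overriding the family defaults; unknown
#'   names are rejected.
#' @param seed Integer seed routed to every stochastic component of the fit.
#' @return Object of class `regressor_spec`.
#' @export
regressor_spec <- function(family, hyperparameters = list(), seed = 0L) {
  family <- match.arg(family, REGRESSOR_FAMILIES)
  defaults <- default_hyperparameters(family)
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown) > 0)
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(family = family, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Fit a regression model
#'
#' All families minimize mean squared error on the training pairs; identical
#' `(spec, X, y)` (including the seed) reproduce identical predictions. The
#' fitted handle records a fingerprint of the training design (gene count,
#' column count, column names) and `predict` refuses matrices that do not
#' match it.
#'
#' @param spec A [regressor_spec()].
#' @param X Numeric design matrix (e.g. a [flatten()] result); rows align
#'   with `y`.
#' @param y Numeric label vector.
#' @param validation Optional `list(X=, y=)` used for the multilayer
#'   perceptron's early stopping; ignored by other families.
#' @return Object of class `trained_regressor`.
#' @export
fit_regressor <- function(spec, X, y, validation = NULL) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(X)
  if (length(y) == 0) stop("y has length 0")
  if (nrow(X) != length(y))
    stop("rows of X (", nrow(X), ") do not align with y (", length(y), ")")
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  # A constant target carries no signal: every family's MSE minimizer is
  # the constant itself, so short-circuit to an exact constant model.
  model <- if (stats::sd(y) == 0) {
    structure(list(value = y[1]), class = "constant_model")
  } else switch(spec$family,
    gradient_boosted_trees = fit_xgb(X, y, hp, spec$seed),
    classic_gradient_boosting = fit_classic_gbm(X, y, hp, spec$seed),
    linear_least_squares = fit_linear(X, y),
    support_vector = fit_svr(X, y, hp),
    multilayer_perceptron = fit_mlp(X, y, hp, spec$seed, validation))
  structure(
    list(model = model, spec = spec,
         fingerprint = list(n_genes = nrow(X), n_cols = ncol(X),
                            col_names = colnames(X)),
         column_map = attr(X, "column_map")),
    class = "trained_regressor")
}

fit_xgb <- function(X, y, hp, seed) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = hp$max_depth,
                  eta = hp$eta, subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree,
                  min_child_weight = hp$min_child_weight,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(unclass_matrix(X), label = y),
    nrounds = hp$nrounds, verbose = 0)
}

# Stagewise least-squares gradient boosting: each round fits a shallow
# regression tree to the current residuals and adds a shrunken copy.
fit_classic_gbm <- function(X, y, hp, seed) {
  df <- as.data.frame(unclass_matrix(X))
  names(df) <- paste0("V", seq_len(ncol(X)))
  ctl <- rpart::rpart.control(maxdepth = hp$max_depth, cp = 0, xval = 0,
                              minsplit = 20, maxsurrogate = 0,
                              usesurrogate = 0, maxcompete = 0)
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", hp$nrounds)
  n <- length(y)
  for (m in seq_len(hp$nrounds)) {
    rows <- if (hp$subsample < 1)
      sample.int(n, floor(hp$subsample * n)) else seq_len(n)
    df$.resid <- y - pred
    tr <- rpart::rpart(.resid ~ ., data = df[rows, , drop = FALSE],
                       method = "anova", control = ctl)
    pred <- pred + hp$shrinkage * rpart_predict(tr, df)
    trees[[m]] <- tr
  }
  list(f0 = f0, shrinkage = hp$shrinkage, trees = trees)
}

rpart_predict <- function(tree, df) unname(stats::predict(tree, newdata = df))

fit_linear <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, unclass_matrix(X)), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0  # aliased columns contribute nothing
  list(coefficients = cf)
}

fit_svr <- function(X, y, hp) {
  gamma <- if (is.na(hp$gamma)) 1 / ncol(X) else hp$gamma
  e1071::svm(x = unclass_matrix(X), y = y, type = "eps-regression",
             kernel = hp$kernel, cost = hp$cost, epsilon = hp$epsilon,
             gamma = gamma, scale = FALSE)
}

# Single-hidden-layer perceptron; with a validation set the fit proceeds in
# warm-started chunks and stops once validation PCC stops improving.
fit_mlp <- function(X, y, hp, seed, validation = NULL) {
  Xu <- unclass_matrix(X)
  args <- list(x = Xu, y = y, size = hp$hidden, linout = TRUE,
               decay = hp$decay, trace = FALSE, MaxNWts = 1e6)
  if (is.null(validation)) {
    return(do.call(nnet::nnet, c(args, list(maxit = hp$maxit))))
  }
  Xv <- unclass_matrix(as.matrix(validation$X))
  best <- NULL; best_pcc <- -Inf; bad <- 0L; wts <- NULL
  iters <- 0L
  while (iters < hp$maxit && bad < hp$patience) {
    step_args <- c(args, list(maxit = hp$chunk_iters))
    if (!is.null(wts)) step_args$Wts <- wts
    net <- do.call(nnet::nnet, step_args)
    wts <- net$wts
    iters <- iters + hp$chunk_iters
    pcc <- suppressWarnings(stats::cor(validation$y, stats::predict(net, Xv)))
    if (!is.na(pcc) && pcc > best_pcc) {
      best_pcc <- pcc; best <- net; bad <- 0L
    } else bad <- bad + 1L
  }
  if (is.null(best)) net else best
}

unclass_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  oldClass(X) <- NULL
  attr(X, "column_map") <- NULL
  X
}

#' Predict from a trained regressor
#'
#' @param object A `trained_regressor`.
#' @param newdata Design matrix with the same columns (count and names) as
#'   the training matrix.
#' @param ... Unused.
#' @return Numeric prediction vector, one value per row.
#' @export
predict.trained_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  fp <- object$fingerprint
  if (ncol(X) != fp$n_cols)
    stop("column mismatch: model expects ", fp$n_cols, " columns, got ",
         ncol(X))
  if (!is.null(fp$col_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), fp$col_names))
    stop("column names differ from the training design matrix")
  if (inherits(object$model, "constant_model"))
    return(rep(object$model$value, nrow(X)))
  Xu <- unclass_matrix(X)
  out <- switch(object$spec$family,
    gradient_boosted_trees =
      stats::predict(object$model, xgboost::xgb.DMatrix(Xu)),
    classic_gradient_boosting = {
      df <- as.data.frame(Xu)
      names(df) <- paste0("V", seq_len(ncol(Xu)))
      p <- rep(object$model$f0, nrow(Xu))
      for (tr in object$model$trees)
        p <- p + object$model$shrinkage * rpart_predict(tr, df)
      p
    },
    linear_least_squares =
      drop(cbind(1, Xu) %*% object$model$coefficients),
    support_vector = unname(stats::predict(object$model, Xu)),
    multilayer_perceptron = drop(stats::predict(object$model, Xu)))
  unname(as.numeric(out))
}

#' Grid search maximizing validation PCC
#'
#' Evaluates every point of the hyperparameter grid by Pearson correlation
#' on a held-out validation set and returns the maximizer. Grid points are
#' enumerated in deterministic lexicographic order over the name-sorted
#' hyperparameters; ties keep the first point.
#'
#' @param spec Base [regressor_spec()] (family and seed).
#' @param grid Named list of hyperparameter value vectors.
#' @param train `list(X=, y=)` training pair.
#' @param val `list(X=, y=)` validation pair (gene set disjoint from
#'   training).
#' @return List with `best_spec` and `table` (one row per grid point with
#'   its validation PCC).
#' @export
grid_search <- function(spec, grid, train, val) {
  if (length(grid) == 0 || prod(lengths(grid)) == 0) stop("empty grid")
  grid <- grid[sort(names(grid))]
  points <- expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  points <- points[, sort(names(points)), drop = FALSE]
  pcc <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    hp <- as.list(points[i, , drop = FALSE])
    cand <- regressor_spec(spec$family,
                           utils::modifyList(spec$hyperparameters, hp),
                           seed = spec$seed)
    fit <- fit_regressor(cand, train$X, train$y)
    pcc[i] <- suppressWarnings(
      stats::cor(val$y, stats::predict(fit, val$X)))
  }
  best <- which.max(pcc)  # first maximum wins ties
  hp <- as.list(points[best, , drop = FALSE])
  list(best_spec = regressor_spec(
         spec$family, utils::modifyList(spec$hyperparameters, hp),
         seed = spec$seed),
       table = cbind(points, validation_pcc = pcc))
}
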