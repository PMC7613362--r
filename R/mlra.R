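#' The supported machine-learning regression algorithms
#'
#' Fixed label order; the order also breaks ties whenever two algorithms
#' score equally in a cross-validated comparison.
#'
#' @return Character vector of algorithm labels.
#' @export
mlra_algorithms <- function() {
  c("OLS", "RT", "MLP", "SVR", "KRR", "GPR")
}

#' RBF kernel bandwidth heuristic
#'
#' Estimates the bandwidth `gamma` of the radial basis function kernel
#' `k(x, y) = exp(-gamma * ||x - y||^2)` as the reciprocal of the median
#' squared Euclidean distance between up to `max_pairs` randomly chosen
#' distinct row pairs.
#'
#' @param features Numeric matrix or data frame (rows = samples).
#' @param seed Integer seed for the pair subsample.
#' @param max_pairs Maximum number of random pairs examined.
#' @return Scalar `gamma` > 0.
#' @export
#' @examples
#' rbf_width_heuristic(rbind(c(0, 0), c(3, 4)))  # 1 / 25
rbf_width_heuristic <- function(features, seed = 1, max_pairs = 500) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2) abort("at least two rows are required")
  pairs <- with_seed(seed, {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    cbind(i, j)
  })
  d2 <- rowSums((X[pairs[, 1], , drop = FALSE] -
                   X[pairs[, 2], , drop = FALSE])^2)
  d2 <- d2[d2 > 0]  # distinct rows only
  if (length(d2) == 0) {
    # the random pairs may all coincide on tiny inputs; fall back to the
    # full set of distinct pairs before giving up
    d2 <- as.numeric(stats::dist(X))^2
    d2 <- d2[d2 > 0]
    if (length(d2) == 0) abort("all feature rows are identical")
  }
  1 / median(d2)
}

# --- internal helpers --------------------------------------------------------

feature_scaling <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center, `-`), 2, scaling$scale, `/`)
}

cv_fold_ids <- function(n, folds, seed) {
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

# grid search by k-fold CV over a single hyperparameter; `fit` and `pred`
# close over everything but the tuned value
tune_by_cv <- function(X, y, grid, folds, seed, fit, pred) {
  ids <- cv_fold_ids(nrow(X), folds, seed)
  scores <- map_dbl(grid, function(g) {
    errs <- map_dbl(seq_len(folds), function(f) {
      tr <- ids != f
      m <- fit(X[tr, , drop = FALSE], y[tr], g)
      rmse(pred(m, X[!tr, , drop = FALSE]), y[!tr])
    })
    mean(errs)
  })
  list(best = grid[which.min(scores)],
       table = tibble(value = grid, cv_rmse = scores))
}

# --- fitting -----------------------------------------------------------------

#' Fit an inversion regressor
#'
#' Trains one of six regression algorithms to map band reflectances (plus
#' optional extra features) to LAI, with the tuning scheme each algorithm
#' needs:
#'
#' * `OLS` - multivariate linear least squares, no tuning.
#' * `RT` - random forest, 500 trees, `max(1, floor(p/3))` candidate
#'   features per split.
#' * `MLP` - single hidden layer of `p + 1` logistic units, linear output,
#'   standardised inputs, seeded initialisation, at most 1000 iterations.
#' * `SVR` - RBF-kernel support vector regression, `epsilon = 0.1`,
#'   bandwidth from [rbf_width_heuristic()], cost tuned over
#'   `{0.1, 1, 10, 100}` by k-fold cross-validation.
#' * `KRR` - RBF-kernel ridge regression, ridge penalty tuned over
#'   `{1e-4, 1e-3, 1e-2, 1e-1, 1}`.
#' * `GPR` - Gaussian process regression with RBF kernel, observation-noise
#'   variance tuned over `{1e-4, 1e-3, 1e-2, 1e-1}`.
#'
#' Kernel and neural methods standardise features with training means and
#' standard deviations. Fitting is deterministic under a fixed `seed`.
#'
#' @param features Tibble/matrix of training features.
#' @param targets Numeric target vector (LAI, m2/m2).
#' @param algorithm One of [mlra_algorithms()].
#' @param folds Cross-validation folds for tuning (>= 2).
#' @param seed Integer seed (folds, multi-starts, forest growth).
#' @param test_features,test_targets Optional held-out set; when supplied the
#'   model's `test_rmse` is filled in.
#' @return An object of class `lai_inverter`.
#' @export
fit_inverter <- function(features, targets, algorithm = "GPR", folds = 5,
                         seed = 1, test_features = NULL, test_targets = NULL) {
  algorithm <- match.arg(algorithm, mlra_algorithms())
  X <- as.matrix(features)
  y <- as.numeric(targets)
  check_finite(X, "features")
  check_finite(y, "targets")
  if (nrow(X) != length(y)) abort("features and targets are not aligned")

  scaling <- feature_scaling(X)
  Xs <- apply_scaling(X, scaling)
  p <- ncol(X)
  tuning <- NULL

  model <- switch(
    algorithm,
    OLS = {
      fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
      list(coef = fit$coefficients)
    },
    RT = {
      dat <- data.frame(X, check.names = FALSE)
      dat$.lai <- y
      ranger::ranger(
        dependent.variable.name = ".lai", data = dat,
        num.trees = 500, mtry = max(1, floor(p / 3)),
        seed = seed, num.threads = 1
      )
    },
    MLP = {
      with_seed(seed, nnet::nnet(
        Xs, y, size = p + 1, linout = TRUE, maxit = 1000,
        trace = FALSE, MaxNWts = 5000
      ))
    },
    SVR = {
      gamma <- rbf_width_heuristic(Xs, seed = derive_seed(seed, "gamma"))
      tuned <- tune_by_cv(
        Xs, y, grid = c(0.1, 1, 10, 100), folds = folds,
        seed = derive_seed(seed, "cv"),
        fit = function(Xtr, ytr, cost) {
          e1071::svm(Xtr, ytr, type = "eps-regression", kernel = "radial",
                     gamma = gamma, epsilon = 0.1, cost = cost, scale = FALSE)
        },
        pred = function(m, Xte) as.numeric(predict(m, Xte))
      )
      tuning <- tuned$table
      list(
        svm = e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                         gamma = gamma, epsilon = 0.1, cost = tuned$best,
                         scale = FALSE),
        gamma = gamma, cost = tuned$best
      )
    },
    KRR = {
      gamma <- rbf_width_heuristic(Xs, seed = derive_seed(seed, "gamma"))
      krr_fit <- function(Xtr, ytr, lambda) {
        K <- rbf_kernel(Xtr, Xtr, gamma)
        ybar <- mean(ytr)
        alpha <- solve(K + diag(lambda, nrow(K)), ytr - ybar)
        list(X = Xtr, alpha = alpha, ybar = ybar)
      }
      krr_pred <- function(m, Xte) {
        drop(rbf_kernel(Xte, m$X, gamma) %*% m$alpha) + m$ybar
      }
      tuned <- tune_by_cv(Xs, y, grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                          folds = folds, seed = derive_seed(seed, "cv"),
                          fit = krr_fit, pred = krr_pred)
      tuning <- tuned$table
      c(krr_fit(Xs, y, tuned$best), list(gamma = gamma, lambda = tuned$best))
    },
    GPR = {
      # exact GP regression posterior mean; written out directly because the
      # noise-variance grid extends below what packaged GP fitters accept
      gamma <- rbf_width_heuristic(Xs, seed = derive_seed(seed, "gamma"))
      gpr_fit <- function(Xtr, ytr, noise_var) {
        K <- rbf_kernel(Xtr, Xtr, gamma)
        ybar <- mean(ytr)
        alpha <- solve(K + diag(noise_var, nrow(K)), ytr - ybar)
        list(X = Xtr, alpha = alpha, ybar = ybar)
      }
      gpr_pred <- function(m, Xte) {
        drop(rbf_kernel(Xte, m$X, gamma) %*% m$alpha) + m$ybar
      }
      tuned <- tune_by_cv(Xs, y, grid = c(1e-4, 1e-3, 1e-2, 1e-1),
                          folds = folds, seed = derive_seed(seed, "cv"),
                          fit = gpr_fit, pred = gpr_pred)
      tuning <- tuned$table
      c(gpr_fit(Xs, y, tuned$best), list(gamma = gamma,
        noise_var = tuned$best))
    }
  )

  out <- structure(
    list(
      algorithm = algorithm,
      model = model,
      feature_names = colnames(X),
      scaling = scaling,
      tuning = tuning,
      folds = folds,
      seed = seed,
      n_train = nrow(X),
      test_rmse = NA_real_
    ),
    class = "lai_inverter"
  )
  if (!is.null(test_features)) {
    out$test_rmse <- rmse(predict_lai(out, test_features), test_targets)
  }
  out
}

#' Predict LAI from band features
#'
#' Applies a fitted inverter to new feature rows. Feature columns must match
#' the training order exactly. Negative predictions are preserved (clamping
#' would bias winter retrievals) but their count is attached as the
#' `n_negative` attribute.
#'
#' @param model A `lai_inverter` from [fit_inverter()].
#' @param features Tibble/matrix with the training feature columns.
#' @return Numeric vector of LAI predictions with attribute `n_negative`.
#' @export
predict_lai <- function(model, features) {
  stopifnot(inherits(model, "lai_inverter"))
  X <- as.matrix(features)
  if (is.null(colnames(X)) ||
      !identical(colnames(X), model$feature_names)) {
    abort("feature columns do not match the training feature order")
  }
  Xs <- apply_scaling(X, model$scaling)
  pred <- switch(
    model$algorithm,
    OLS = drop(cbind(1, X) %*% model$model$coef),
    RT = predict(model$model, data.frame(X, check.names = FALSE),
                 num.threads = 1)$predictions,
    MLP = drop(predict(model$model, Xs)),
    SVR = as.numeric(predict(model$model$svm, Xs)),
    KRR = drop(rbf_kernel(Xs, model$model$X, model$model$gamma) %*%
                 model$model$alpha) + model$model$ybar,
    GPR = drop(rbf_kernel(Xs, model$model$X, model$model$gamma) %*%
                 model$model$alpha) + model$model$ybar
  )
  pred <- unname(pred)
  attr(pred, "n_negative") <- sum(pred < 0)
  pred
}

#' @export
print.lai_inverter <- function(x, ...) {
  cat("<lai_inverter> ", x$algorithm, ", ", x$n_train, " training rows, ",
      length(x$feature_names), " features\n", sep = "")
  if (!is.na(x$test_rmse)) cat("  test RMSE:", format(x$test_rmse), "\n")
  invisible(x)
}

#' @rdname fit_inverter
#' @param x A `lai_inverter`.
#' @param ... Unused.
#' @export
tidy.lai_inverter <- function(x, ...) {
  if (x$algorithm == "OLS") {
    return(tibble(term = names(x$model$coef), estimate = unname(x$model$coef)))
  }
  if (is.null(x$tuning)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  mutate(x$tuning, term = paste0(tolower(x$algorithm), "_tuning"),
         .before = 1)
}

#' @rdname fit_inverter
#' @export
glance.lai_inverter <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    n_train = x$n_train,
    n_features = length(x$feature_names),
    folds = x$folds,
    test_rmse = x$test_rmse
  )
}
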