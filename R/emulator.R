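#' Fit a per-band emulator of a canopy reflectance model
#'
#' Replaces an expensive radiative-transfer model by a regression surrogate:
#' one regressor per spectral band, each trained on (parameter, clean band
#' reflectance) pairs. Every candidate algorithm is scored by fold-averaged
#' held-out RMSE in a k-fold cross-validation and the band's winner is the
#' algorithm with the lowest CV RMSE; ties go to the earlier algorithm in
#' [mlra_algorithms()] order. Emulation targets clean (noise-free) spectra —
#' noise is a property of the training database, applied downstream.
#'
#' For the kernel algorithms (KRR, GPR) all bands share the parameter matrix,
#' so their cross-validation is evaluated in a batched path that factorises
#' each regularised kernel matrix once and solves all bands as multiple
#' right-hand sides; results are deterministic under `seed`.
#'
#' @param params Parameter tibble (the RTM inputs; rows = samples).
#' @param bands Tibble of clean band reflectances aligned with `params`.
#' @param algorithms Candidate algorithm labels (subset of
#'   [mlra_algorithms()]). The default combines the linear benchmark, the
#'   random forest and kernel ridge regression, which carries smooth
#'   multi-parameter response surfaces at desk-scale cost.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed.
#' @return Object of class `rtm_emulator`: per-band fitted regressor, winning
#'   algorithm label and CV RMSE, plus a manifest.
#' @export
fit_emulator <- function(params, bands, algorithms = c("OLS", "RT", "KRR"),
                         folds = 5, seed = 1) {
  algorithms <- match.arg(algorithms, mlra_algorithms(), several.ok = TRUE)
  # keep the fixed tie-break order regardless of user-supplied order
  algorithms <- intersect(mlra_algorithms(), algorithms)
  X <- as_tibble(params)
  B <- as_tibble(bands)
  if (nrow(X) != nrow(B)) abort("params and bands are not aligned")
  if (nrow(X) < 50) abort("at least 50 rows are required to fit an emulator")
  if (folds < 2 || nrow(X) < folds) {
    abort("fewer rows than cross-validation folds")
  }
  ids <- cv_fold_ids(nrow(X), folds, seed = derive_seed(seed, "folds"))
  kernel_algs <- intersect(algorithms, c("KRR", "GPR"))
  other_algs <- setdiff(algorithms, kernel_algs)

  # CV scores per band for the non-kernel algorithms
  cv_other <- map(setNames(other_algs, other_algs), function(alg) {
    map_dbl(setNames(names(B), names(B)), function(band) {
      y <- B[[band]]
      errs <- map_dbl(seq_len(folds), function(f) {
        tr <- ids != f
        m <- fit_inverter(X[tr, , drop = FALSE], y[tr], alg, folds = folds,
                          seed = derive_seed(seed, band, alg, f))
        rmse(predict_lai(m, X[!tr, , drop = FALSE]), y[!tr])
      })
      mean(errs)
    })
  })
  cv_kernel_full <- map(setNames(kernel_algs, kernel_algs), function(alg) {
    kernel_emulator_cv(X, B, ids, folds, alg, seed)
  })
  cv_kernel <- map(cv_kernel_full, "cv")
  cv_all <- c(cv_other, cv_kernel)[algorithms]

  winners <- map_chr(setNames(names(B), names(B)), function(band) {
    algorithms[which.min(map_dbl(cv_all, ~ .x[[band]]))]
  })

  models <- vector("list", ncol(B))
  names(models) <- names(B)
  for (alg in unique(winners)) {
    won <- names(winners)[winners == alg]
    if (alg %in% c("KRR", "GPR")) {
      models[won] <- kernel_emulator_fit(
        X, B[won], alg,
        best_reg = cv_kernel_full[[alg]]$best_reg[won],
        folds = folds, seed = seed
      )
    } else {
      for (band in won) {
        models[[band]] <- fit_inverter(X, B[[band]], alg, folds = folds,
                                       seed = derive_seed(seed, band, alg))
      }
    }
  }

  resid_sd <- map_dbl(setNames(names(B), names(B)), function(band) {
    sd(predict_lai(models[[band]], X) - B[[band]])
  })

  structure(
    list(
      bands = names(B),
      models = models,
      winners = winners,
      cv_rmse = map_dbl(setNames(names(B), names(B)),
                        ~ min(map_dbl(cv_all, function(a) a[[.x]]))),
      cv_table = cv_all,
      resid_sd = resid_sd,
      param_names = names(X),
      folds = folds,
      seed = seed,
      n = nrow(X)
    ),
    class = "rtm_emulator"
  )
}

# regularisation grids of the two kernel regressors (shared with fit_inverter)
kernel_reg_grid <- function(algorithm) {
  if (algorithm == "KRR") c(1e-4, 1e-3, 1e-2, 1e-1, 1) else
    c(1e-4, 1e-3, 1e-2, 1e-1)
}

# batched k-fold CV of a kernel regressor over all bands at once: one
# Cholesky per (fold, regularisation) solved against all band targets
kernel_emulator_cv <- function(X, B, ids, folds, algorithm, seed) {
  Y <- as.matrix(B)
  grid <- kernel_reg_grid(algorithm)
  sq_err <- matrix(0, nrow = length(grid), ncol = ncol(Y))
  n_acc <- 0
  for (f in seq_len(folds)) {
    tr <- ids != f
    scaling <- feature_scaling(as.matrix(X)[tr, , drop = FALSE])
    Xtr <- apply_scaling(as.matrix(X)[tr, , drop = FALSE], scaling)
    Xte <- apply_scaling(as.matrix(X)[!tr, , drop = FALSE], scaling)
    gamma <- rbf_width_heuristic(Xtr, seed = derive_seed(seed, "gamma", f))
    K <- rbf_kernel(Xtr, Xtr, gamma)
    Kte <- rbf_kernel(Xte, Xtr, gamma)
    ybar <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ybar)
    for (g in seq_along(grid)) {
      alpha <- solve(K + diag(grid[g], nrow(K)), Yc)
      pred <- sweep(Kte %*% alpha, 2, ybar, `+`)
      sq_err[g, ] <- sq_err[g, ] + colSums((pred - Y[!tr, , drop = FALSE])^2)
    }
    n_acc <- n_acc + sum(!tr)
  }
  cv_rmse_by_reg <- sqrt(sq_err / n_acc)
  list(
    cv = setNames(apply(cv_rmse_by_reg, 2, min), colnames(Y)),
    best_reg = setNames(grid[apply(cv_rmse_by_reg, 2, which.min)],
                        colnames(Y)),
    by_reg = cv_rmse_by_reg
  )
}

# final kernel fits for the bands an algorithm won, with the regularisation
# already selected by the batched CV; one factorisation per distinct value,
# solved for all its bands together. Returns `lai_inverter` objects so
# prediction goes through the common path.
kernel_emulator_fit <- function(X, B, algorithm, best_reg, folds, seed) {
  Xm <- as.matrix(X)
  scaling <- feature_scaling(Xm)
  Xs <- apply_scaling(Xm, scaling)
  gamma <- rbf_width_heuristic(Xs, seed = derive_seed(seed, "gamma"))
  K <- rbf_kernel(Xs, Xs, gamma)
  out <- vector("list", ncol(B))
  names(out) <- names(B)
  for (reg in unique(best_reg)) {
    bands <- names(best_reg)[best_reg == reg]
    Y <- as.matrix(B[bands])
    ybar <- colMeans(Y)
    alpha <- solve(K + diag(reg, nrow(K)), sweep(Y, 2, ybar))
    for (b in bands) {
      mdl <- list(X = Xs, alpha = alpha[, b], ybar = ybar[[b]],
                  gamma = gamma)
      mdl[[if (algorithm == "KRR") "lambda" else "noise_var"]] <- reg
      out[[b]] <- structure(
        list(algorithm = algorithm, model = mdl,
             feature_names = colnames(Xm), scaling = scaling,
             tuning = NULL, folds = folds, seed = seed,
             n_train = nrow(Xm), test_rmse = NA_real_),
        class = "lai_inverter"
      )
    }
  }
  out
}

#' Predict band reflectances with an emulator
#'
#' @param emulator An `rtm_emulator` from [fit_emulator()].
#' @param params Parameter tibble with the training parameter columns.
#' @return Tibble of predicted band reflectances, rows aligned with `params`.
#' @export
emulate_bands <- function(emulator, params) {
  stopifnot(inherits(emulator, "rtm_emulator"))
  X <- as_tibble(params)
  if (!identical(names(X), emulator$param_names)) {
    abort("parameter columns do not match the emulator's training columns")
  }
  out <- map(emulator$models, function(m) {
    p <- predict_lai(m, X)
    attributes(p) <- NULL
    p
  })
  as_tibble(out)
}

#' @export
print.rtm_emulator <- function(x, ...) {
  cat("<rtm_emulator> ", length(x$bands), " bands, ", x$n,
      " training samples\n", sep = "")
  cat("  winners: ", paste0(x$bands, "=", x$winners, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_emulator
#' @param x An `rtm_emulator`.
#' @param ... Unused.
#' @export
glance.rtm_emulator <- function(x, ...) {
  tibble(
    band = x$bands,
    winner = unname(x$winners),
    cv_rmse = unname(x$cv_rmse),
    resid_sd = unname(x$resid_sd),
    n = x$n
  )
}
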