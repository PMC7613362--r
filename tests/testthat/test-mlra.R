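test_that("RBF bandwidth heuristic matches its contract", {
  # two rows at distance d -> gamma = 1/d^2
  expect_equal(rbf_width_heuristic(rbind(c(0, 0), c(3, 4))), 1 / 25)
  # standard normal features: median squared distance ~ 2p
  set.seed(1)
  Z <- matrix(rnorm(5000), 1000, 5)
  expect_equal(rbf_width_heuristic(Z, seed = 2), 0.1, tolerance = 0.3)
  # duplicated rows are filtered out
  X <- rbind(c(0, 0), c(3, 4))
  expect_equal(rbf_width_heuristic(rbind(X, X, X), seed = 3), 1 / 25)
  expect_error(rbf_width_heuristic(matrix(1, 5, 2)), "identical")
})

test_that("standardisation round-trips", {
  X <- matrix(rnorm(200), 50, 4)
  sc <- hylai:::feature_scaling(X)
  Xs <- hylai:::apply_scaling(X, sc)
  back <- sweep(sweep(Xs, 2, sc$scale, `*`), 2, sc$center, `+`)
  expect_lt(max(abs(back - X)), 1e-10)
})

test_that("OLS is exact on linear targets and constant on constant targets", {
  set.seed(2)
  X <- tibble::as_tibble(matrix(runif(300), 100, 3, dimnames =
                                  list(NULL, c("a", "b", "c"))))
  y <- 2 + 3 * X$a - 1.5 * X$b + 0.2 * X$c
  m <- fit_inverter(X, y, "OLS", test_features = X, test_targets = y)
  expect_lte(m$test_rmse, 1e-8)
  yc <- rep(4.2, 100)
  mc <- fit_inverter(X, yc, "OLS")
  expect_equal(unname(predict_lai(mc, X[1:5, ])), rep(4.2, 5),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("the MLP hidden layer has one more unit than the feature count", {
  db <- fx_turbid_db()
  tr <- assemble_features(db, "MSI", use_sza = TRUE, split = "train")
  m <- fit_inverter(tr$features[1:200, ], tr$target[1:200], "MLP", seed = 1)
  # nnet records the architecture as (inputs, hidden, outputs)
  expect_equal(m$model$n, c(11, 12, 1))
})

test_that("fit-predict is deterministic under a fixed seed", {
  db <- fx_turbid_db()
  tr <- assemble_features(db, "MSI", use_sza = FALSE, split = "train")
  te <- assemble_features(db, "MSI", use_sza = FALSE, split = "test")
  idx <- 1:250
  for (alg in mlra_algorithms()) {
    m1 <- fit_inverter(tr$features[idx, ], tr$target[idx], alg, seed = 42)
    m2 <- fit_inverter(tr$features[idx, ], tr$target[idx], alg, seed = 42)
    expect_identical(predict_lai(m1, te$features),
                     predict_lai(m2, te$features))
  }
})

test_that("kernel methods beat the linear benchmark on the nonlinear
           band-LAI map", {
  db <- fx_turbid_db()
  tr <- assemble_features(db, "MSI", use_sza = TRUE, split = "train")
  te <- assemble_features(db, "MSI", use_sza = TRUE, split = "test")
  scores <- purrr::map_dbl(
    setNames(c("OLS", "SVR", "KRR", "GPR"), c("OLS", "SVR", "KRR", "GPR")),
    function(alg) {
      fit_inverter(tr$features, tr$target, alg, seed = 7,
                   test_features = te$features,
                   test_targets = te$target)$test_rmse
    })
  expect_true(all(scores[c("SVR", "KRR", "GPR")] <= scores["OLS"]))
})

test_that("prediction enforces the training feature contract", {
  X <- tibble::tibble(a = runif(60), b = runif(60))
  m <- fit_inverter(X, runif(60), "OLS")
  expect_error(predict_lai(m, tibble::tibble(b = runif(3), a = runif(3))),
               "feature columns")
  # negative predictions preserved but counted
  y <- -5 + 0 * X$a
  mneg <- fit_inverter(X, y, "OLS")
  p <- predict_lai(mneg, X)
  expect_true(all(p < 0))
  expect_equal(attr(p, "n_negative"), 60L)
})

test_that("the random forest reproduces its own training rows within the
           out-of-bag spread", {
  db <- fx_turbid_db()
  tr <- assemble_features(db, "MSI", use_sza = FALSE, split = "train")
  idx <- 1:400
  m <- fit_inverter(tr$features[idx, ], tr$target[idx], "RT", seed = 3)
  oob_rmse <- sqrt(m$model$prediction.error)
  p <- predict_lai(m, tr$features[idx, ])
  expect_lt(sqrt(mean((p - tr$target[idx])^2)), oob_rmse)
})

test_that("tidy and glance methods expose fits in broom style", {
  X <- tibble::tibble(a = runif(60), b = runif(60))
  y <- 1 + X$a
  m <- fit_inverter(X, y, "OLS", test_features = X, test_targets = y)
  td <- tidy(m)
  expect_tibble(td)
  expect_equal(td$term, c("(Intercept)", "a", "b"))
  gl <- glance(m)
  expect_equal(gl$algorithm, "OLS")
  expect_equal(gl$n_train, 60L)
  mk <- fit_inverter(X, y + X$b^2, "KRR", seed = 1)
  expect_true(nrow(tidy(mk)) == 5)  # one row per ridge-penalty candidate
})
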