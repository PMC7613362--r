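test_that("the factorial grid enumerates every feature combination", {
  expect_equal(nrow(build_grid()), 960L)
  one <- build_grid(feature_domains(prior = "free", rtm = "GEOM",
                                    sigma_ai = 0, sigma_mi = 0,
                                    sza = TRUE, mlra = "RT"))
  expect_equal(nrow(one), 1L)
  three <- build_grid(feature_domains(mlra = c("OLS", "RT", "KRR")))
  expect_equal(nrow(three), 480L)
  expect_equal(dplyr::n_distinct(build_grid()$id), 960L)
  # ensemble sizes: every level of a feature covers grid_size / n_levels
  g <- build_grid()
  expect_true(all(table(g$sigma_ai) == 240))
  expect_true(all(table(g$mlra) == 160))
  expect_error(build_grid(feature_domains(mlra = character(0))), "empty")
})

test_that("feature ensemble statistics summarise levels as in the
           assessment table", {
  toy <- tibble::tibble(
    prior = c("free", "free", "prior", "prior"),
    rtm = "GEOM", sigma_ai = 0, sigma_mi = 0, sza = FALSE, mlra = "RT",
    val_rmse = c(1, 2, 3, 4)
  )
  st <- feature_ensemble_stats(toy, "prior")
  expect_equal(st$median_rmse[st$level == "free"], 1.5)
  expect_equal(st$median_rmse[st$level == "prior"], 3.5)
  expect_equal(st$delta_rmse[st$level == "prior"], 2.0)
  expect_equal(st$delta_rmse[st$level == "free"], 0)
  # identical results across levels: all deltas zero
  flat <- dplyr::mutate(toy, val_rmse = 2)
  expect_true(all(feature_ensemble_stats(flat, "prior")$delta_rmse == 0))
  expect_error(feature_ensemble_stats(toy, "banana"), "unknown feature")
})

test_that("the paired test flags a consistent binary-feature effect", {
  base <- tidyr::expand_grid(
    prior = c("free", "prior"), rtm = c("TURBID", "GEOM"),
    sigma_ai = c(0, 0.05), sigma_mi = c(0, 0.1, 0.2), mlra = "RT"
  )  # 24 pairs
  set.seed(3)
  base$val0 <- runif(nrow(base), 1, 2)
  paired <- dplyr::bind_rows(
    dplyr::mutate(base, sza = FALSE, val_rmse = val0),
    dplyr::mutate(base, sza = TRUE, val_rmse = val0 - 0.1)
  )
  out <- paired_feature_test(paired, "sza")
  expect_equal(out$n_pairs, 24L)
  expect_lt(out$p_value, 0.01)
  expect_equal(out$statistic, 0)   # all differences share one sign
  expect_equal(out$median_diff, -0.1)
  # identical pairs: undefined, reported as missing
  same <- dplyr::bind_rows(
    dplyr::mutate(base, sza = FALSE, val_rmse = val0),
    dplyr::mutate(base, sza = TRUE, val_rmse = val0)
  )
  out2 <- paired_feature_test(same, "sza")
  expect_true(is.na(out2$p_value))
  expect_error(paired_feature_test(paired, "mlra"), "two levels")
})

test_that("the interaction scan ranks the feature that modulates RMSE", {
  toy <- tidyr::expand_grid(
    prior = c("free", "prior"), rtm = c("TURBID", "GEOM"),
    sigma_ai = c(0, 0.05), sigma_mi = 0, sza = FALSE,
    mlra = c("OLS", "RT")
  )
  # rtm shifts RMSE by 1.0, but only within the free prior level
  toy$val_rmse <- 1 + ifelse(toy$prior == "free" & toy$rtm == "GEOM", 1, 0)
  sc <- interaction_scan(toy, "prior")
  expect_equal(sc$with[1], "rtm")
  expect_equal(sc$score[1], 1.0)
  expect_true(all(sc$score >= 0))
  # a flat grid scores zero everywhere
  flat <- dplyr::mutate(toy, val_rmse = 1.3)
  expect_true(all(interaction_scan(flat, "prior")$score == 0))
})

test_that("realisations run end to end, deterministically", {
  w <- fx_world()
  ref <- fx_reference()
  cfg <- grid_config(n_train = 150, n_test = 50, seed = 99)
  sp <- build_grid(feature_domains(prior = "free", rtm = "TURBID",
                                   sigma_ai = 0.05, sigma_mi = 0,
                                   sza = TRUE, mlra = "OLS"))
  r1 <- run_realisation(sp, w, ref, cfg)
  r2 <- run_realisation(sp, w, ref, cfg)
  expect_identical(r1$val_rmse, r2$val_rmse)
  expect_identical(r1$series[[1]], r2$series[[1]])
  expect_gte(r1$val_rmse, 0)
  expect_equal(r1$n_dates, nrow(r1$series[[1]]))
  expect_tibble(r1$plot_bias[[1]])
  # the reported R2 is consistent with rescoring the exported series
  s <- r1$series[[1]]
  expect_equal(r1$val_r2, score_series(s$pred, s$ref)$r2)
})

test_that("the best-realisation report returns the grid minimum", {
  res <- fx_grid_results()
  expect_equal(nrow(res), 24L)
  rep <- best_report(res)
  expect_equal(rep$best$val_rmse, min(res$val_rmse))
  expect_tibble(rep$series)
  # matched-training cells sit well below the catastrophic mismatched ones
  expect_lt(rep$best$val_rmse, 0.1 * max(res$val_rmse))
  gl <- glance(res)
  expect_equal(gl$n_realisations, 24L)
  expect_equal(gl$best_rmse, rep$best$val_rmse)
})

test_that("noise-free training produces the unstable tail of the ensemble", {
  res <- fx_grid_results()
  st <- feature_ensemble_stats(res, "sigma_ai")
  med0 <- st$median_rmse[st$level == "0"]
  med5 <- st$median_rmse[st$level == "0.05"]
  expect_lt(med5, med0)
  expect_equal(res$sigma_ai[which.max(res$val_rmse)], 0)
})

test_that("grid results persist to CSV", {
  res <- fx_grid_results()
  dir <- withr::local_tempdir()
  write_grid_results(res, dir)
  back <- utils::read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(back), nrow(res))
  expect_true(file.exists(file.path(dir, "summary.csv")))
})
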