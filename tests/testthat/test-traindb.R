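test_that("Latin hypercube samples stratify every varying parameter", {
  rng <- param_ranges("free", "TURBID")
  n <- 10
  s <- lhs_sample(n, rng, seed = 4)
  # exactly one sample per equal-width stratum for a uniform marginal
  for (p in rng$param) {
    lo <- rng$lower[rng$param == p]
    up <- rng$upper[rng$param == p]
    bins <- floor((s[[p]] - lo) / (up - lo) * n)
    expect_setequal(bins, 0:(n - 1))
  }
  expect_identical(lhs_sample(n, rng, seed = 4), s)
  expect_false(identical(lhs_sample(n, rng, seed = 5), s))
  expect_error(
    lhs_sample(5, tibble::tibble(param = "x", lower = 1, upper = 0,
                                 fixed = NA_real_)),
    "lower > upper")
})

test_that("prior-mode sampling pins the stable constituents", {
  s <- lhs_sample(50, param_ranges("prior", "GEOM"), seed = 9)
  expect_true(all(s$n == 1.27))
  expect_true(all(s$car == 8.60))
  expect_true(all(s$cw == 0.0053))
  expect_true(all(s$cm == 0.00263))
  expect_gt(dplyr::n_distinct(s$cab), 1)
  expect_gt(dplyr::n_distinct(s$crown_diameter), 1)
})

test_that("LHS marginals are flat at database scale", {
  rng <- param_ranges("free", "TURBID")
  s <- lhs_sample(2500, rng, seed = 21)
  for (p in c("cab", "lai", "theta_s")) {
    lo <- rng$lower[rng$param == p]
    up <- rng$upper[rng$param == p]
    counts <- table(cut(s[[p]], breaks = seq(lo, up, length.out = 11)))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("barren injection zeroes the right rows, reproducibly", {
  rng <- param_ranges("free", "TURBID")
  s <- lhs_sample(2500, rng, seed = 2)
  b <- inject_barren(s, 0.30, seed = 8)
  expect_equal(sum(b$barren), 750L)
  expect_true(all(b$lai[b$barren] == 0))
  expect_true(all(b$cab[b$barren] == 0 & b$cbrown[b$barren] == 0))
  expect_true(all(b$n[b$barren] > 0))  # structure index untouched
  expect_identical(inject_barren(s, 0.30, seed = 8), b)
  expect_identical(inject_barren(s, 0)[names(s)], s)
  expect_true(all(inject_barren(s, 1)$lai == 0))
})

test_that("noise contamination follows the two-component Gaussian law", {
  clean <- tibble::tibble(B4 = rep(0.5, 1e5), B8A = rep(0.5, 1e5))
  expect_identical(apply_noise(clean, 0, 0, seed = 1), clean)
  noisy <- apply_noise(clean, sigma_mi = 0.2, sigma_ai = 0.05, seed = 3)
  d <- noisy$B4 - clean$B4
  # E[rho'] = rho, Var = rho^2 sMI^2 + sAI^2 (within 5% at 1e5 draws)
  expect_lt(abs(mean(d)), 0.002)
  expect_equal(var(d), 0.5^2 * 0.04 + 0.0025, tolerance = 0.05)
  # per-band independence: band draws differ
  expect_gt(sd(noisy$B4 - noisy$B8A), 0.01)
  # shared-draw mode applies one pair per row
  sh <- apply_noise(tibble::tibble(a = rep(0.4, 10), b = rep(0.4, 10)),
                    0.1, 0.02, seed = 2, shared_draw = TRUE)
  expect_equal(sh$a, sh$b)
  expect_error(apply_noise(clean, -0.1, 0), ">= 0")
})

test_that("hand-substituted noise case: rho 0.4, eps_mi 0.1, eps_ai 0.02", {
  expect_equal(0.4 + 0.4 * 0.1 + 0.02, 0.46)
})

test_that("database assembly exposes the right features and targets", {
  db <- build_training_db(n_train = 100, n_test = 30, rtm = "GEOM",
                          sigma_ai = 0.05, sensors = c("MSI", "ETM+"),
                          seed = 12)
  msi <- assemble_features(db, "MSI", use_sza = TRUE)
  expect_equal(ncol(msi$features), 11L)  # 10 bands + sza
  etm <- assemble_features(db, "ETM+", use_sza = FALSE)
  expect_equal(ncol(etm$features), 6L)
  expect_true(all(msi$target[db$params$barren] == 0))
  expect_equal(sum(db$params$split == "train"), 100L)
  expect_error(assemble_features(db, "OLI"), "not built")
  # same config + seed regenerates identically
  db2 <- build_training_db(n_train = 100, n_test = 30, rtm = "GEOM",
                           sigma_ai = 0.05, sensors = c("MSI", "ETM+"),
                           seed = 12)
  expect_identical(db$params, db2$params)
  expect_identical(db$noisy, db2$noisy)
})

test_that("training databases persist as CSV + JSON manifest", {
  db <- build_training_db(n_train = 60, n_test = 20, sensors = "MSI",
                          sigma_ai = 0.05, seed = 5)
  dir <- withr::local_tempdir()
  write_training_db(db, dir)
  expect_true(file.exists(file.path(dir, "params.csv")))
  expect_true(file.exists(file.path(dir, "noisy_MSI.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$sigma_ai, 0.05)
  expect_equal(man$band_order$MSI,
               names(db$clean$MSI))
})
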