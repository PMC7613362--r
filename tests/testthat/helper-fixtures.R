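# Shared fixtures, built once per test run and cached. Heavy objects (the
# synthetic world, the scaled realisation grid) are reused across test files
# so the suite stays desk-scale.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# noisy synthetic world under default study conditions (GEOM truth,
# sigma_obs = 0.05), used by the realisation-level tests
fx_world <- function() {
  fixture("world", function() build_world(seed = 101))
}

fx_reference <- function() {
  fixture("reference", function() build_reference(fx_world())$series)
}

# scaled-down factorial grid: 2 RTMs x 2 sigma_AI x 2 sigma_MI x 3 MLRAs,
# training databases of 500 + 100 rows
fx_grid_spec <- function() {
  build_grid(feature_domains(
    prior = "free", rtm = c("TURBID", "GEOM"),
    sigma_ai = c(0, 0.05), sigma_mi = c(0, 0.10),
    sza = FALSE, mlra = c("OLS", "RT", "KRR")
  ))
}

fx_grid_config <- function() {
  grid_config(n_train = 500, n_test = 100, seed = 707)
}

fx_grid_results <- function() {
  fixture("grid_results", function() {
    run_grid(fx_grid_spec(), fx_world(), fx_reference(), fx_grid_config())
  })
}

# small noiseless TURBID database shared by the MLRA ordering tests
fx_turbid_db <- function() {
  fixture("turbid_db", function() {
    build_training_db(n_train = 800, n_test = 200, rtm = "TURBID",
                      sensors = "MSI", seed = 313)
  })
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
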