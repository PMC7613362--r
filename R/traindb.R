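#' Parameter ranges for a training database
#'
#' Assembles the per-parameter bounds (or fixed values) that a training
#' database is sampled from. Under the `free` option every leaf constituent,
#' LAI and the sun zenith angle vary over their literature ranges; under the
#' `prior` option the seasonally stable constituents (structure index,
#' carotenoids, water, dry matter) are pinned to their field best estimates
#' while chlorophyll and brown pigment stay free. The crown-explicit
#' surrogate additionally varies the crown diameter (5-9 m) in both modes.
#'
#' @param prior `"free"` or `"prior"`.
#' @param rtm `"TURBID"` or `"GEOM"`.
#' @param prior_summary Optional [summarize_season_prior()] result; its fixed
#'   values override the shipped best estimates in `prior` mode.
#' @return Tibble with columns `param`, `lower`, `upper`, `fixed` (`NA` for
#'   varying parameters).
#' @export
param_ranges <- function(prior = c("free", "prior"), rtm = c("TURBID", "GEOM"),
                         prior_summary = NULL) {
  prior <- match.arg(prior)
  rtm <- match.arg(rtm)
  ranges <- bind_rows(
    leaf_free_bounds(),
    tribble(
      ~param,    ~lower, ~upper,
      "lai",      0,      8,
      "theta_s",  27.5,   80
    )
  ) |>
    mutate(fixed = NA_real_)
  if (rtm == "GEOM") {
    ranges <- bind_rows(ranges,
                        tibble(param = "crown_diameter", lower = 5, upper = 9,
                               fixed = NA_real_))
  }
  if (prior == "prior") {
    fixed_vals <- leaf_best_estimates()
    if (!is.null(prior_summary)) {
      fx <- prior_summary[prior_summary$fixed, ]
      fixed_vals[fx$param] <- fx$value
    }
    hit <- match(ranges$param, names(fixed_vals))
    ranges$fixed <- ifelse(is.na(hit), ranges$fixed,
                           unname(fixed_vals)[hit])
  }
  ranges
}

#' Latin hypercube sample of canopy parameters
#'
#' Draws a stratified uniform Latin hypercube over the varying parameters:
#' for each parameter, exactly one sample falls in each of the `n`
#' equal-probability strata. Fixed parameters are constant columns.
#'
#' @param n Number of samples.
#' @param ranges Tibble from [param_ranges()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Tibble with one column per parameter and `n` rows.
#' @export
#' @examples
#' lhs_sample(5, param_ranges("free", "TURBID"), seed = 1)
lhs_sample <- function(n, ranges, seed = 1) {
  if (n < 1) abort("`n` must be >= 1")
  if (any(ranges$lower > ranges$upper)) abort("invalid ranges: lower > upper")
  varying <- is.na(ranges$fixed)
  d <- sum(varying)
  u <- with_seed(seed, lhs::randomLHS(n, max(d, 1)))
  out <- matrix(NA_real_, nrow = n, ncol = nrow(ranges),
                dimnames = list(NULL, ranges$param))
  j <- 0
  for (i in seq_len(nrow(ranges))) {
    if (varying[i]) {
      j <- j + 1
      out[, i] <- ranges$lower[i] + u[, j] * (ranges$upper[i] - ranges$lower[i])
    } else {
      out[, i] <- ranges$fixed[i]
    }
  }
  as_tibble(as.data.frame(out))
}

#' Convert part of a parameter table to barren (winter) conditions
#'
#' A fraction of the sampled canopy states is converted to leaf-off winter
#' conditions: LAI and all leaf constituent contents are set to 0 (the
#' structure index, a property of leaf anatomy rather than abundance, keeps
#' its sampled value). Rows are chosen uniformly at random, reproducibly by
#' seed.
#'
#' @param params Parameter tibble from [lhs_sample()].
#' @param fraction Fraction of rows to convert, in `[0, 1]` (default 0.30).
#' @param seed Integer seed.
#' @return The parameter tibble with `round(fraction * n)` barren rows and a
#'   logical `barren` column.
#' @export
inject_barren <- function(params, fraction = 0.30, seed = 1) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1]")
  n <- nrow(params)
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  params$barren <- FALSE
  params$barren[idx] <- TRUE
  chem <- intersect(c("cab", "car", "cw", "cm", "cbrown", "lai"), names(params))
  params[idx, chem] <- 0
  params
}

#' Contaminate band reflectances with Gaussian noise
#'
#' Applies the two-component noise model used to regularise training
#' databases: `rho' = rho + rho * e_MI + e_AI` with multiplicative
#' wavelength-independent noise `e_MI ~ N(0, sigma_mi)` (relative units) and
#' additive wavelength-independent noise `e_AI ~ N(0, sigma_ai)` (reflectance
#' units). "Wavelength-independent" refers to the standard deviations not
#' varying across bands; by default the noise terms are drawn independently
#' per row and per band (`shared_draw = TRUE` draws one pair of terms per
#' row instead). No clipping is applied: clipping would bias the noise
#' distribution.
#'
#' @param bands Tibble/matrix of clean band reflectances.
#' @param sigma_mi,sigma_ai Noise standard deviations (>= 0).
#' @param seed Integer seed.
#' @param shared_draw Draw one noise pair per row shared across bands.
#' @return Tibble of contaminated band reflectances, same shape as `bands`.
#' @export
#' @examples
#' apply_noise(tibble::tibble(B4 = 0.05, B8A = 0.4), 0.1, 0.05, seed = 1)
apply_noise <- function(bands, sigma_mi, sigma_ai, seed = 1,
                        shared_draw = FALSE) {
  if (sigma_mi < 0 || sigma_ai < 0) abort("noise sigmas must be >= 0")
  mat <- as.matrix(bands)
  check_finite(mat, "bands")
  if (sigma_mi == 0 && sigma_ai == 0) return(as_tibble(bands))
  n <- nrow(mat)
  p <- ncol(mat)
  noisy <- with_seed(seed, {
    if (shared_draw) {
      e_mi <- rnorm(n, 0, sigma_mi)
      e_ai <- rnorm(n, 0, sigma_ai)
      mat + mat * e_mi + e_ai
    } else {
      e_mi <- matrix(rnorm(n * p, 0, sigma_mi), n, p)
      e_ai <- matrix(rnorm(n * p, 0, sigma_ai), n, p)
      mat + mat * e_mi + e_ai
    }
  })
  out <- as_tibble(as.data.frame(noisy))
  names(out) <- colnames(mat)
  out
}

#' Build a complete training database
#'
#' Runs the full database pipeline for one workflow realisation: Latin
#' hypercube sampling under free or prior ranges, barren injection, forward
#' simulation of every requested sensor's bands with the chosen canopy
#' surrogate, noise contamination, and a seeded train/test split.
#'
#' @param n_train,n_test Split sizes (the database holds
#'   `n_train + n_test` rows; one LHS is shared by all sensors so that
#'   realisations stay comparable across sensors).
#' @param prior,rtm Passed to [param_ranges()].
#' @param sigma_mi,sigma_ai Noise levels for [apply_noise()] (applied to both
#'   splits).
#' @param sensors Character vector of sensor names.
#' @param barren_fraction Fraction of leaf-off rows.
#' @param prior_summary Optional seasonal prior summary.
#' @param geom Scene geometry constants.
#' @param seed Integer master seed for sampling, barren choice, noise and
#'   split.
#' @return An object of class `training_db`: list with `params` (including
#'   `barren` and `split` columns), `clean` and `noisy` (named lists of band
#'   tibbles per sensor) and a `manifest` recording ranges, seeds, noise and
#'   column order.
#' @export
build_training_db <- function(n_train = 2500, n_test = 500,
                              prior = "free", rtm = "TURBID",
                              sigma_mi = 0, sigma_ai = 0,
                              sensors = c("MSI", "ETM+", "OLI"),
                              barren_fraction = 0.30, prior_summary = NULL,
                              geom = scene_geometry(), seed = 1) {
  n <- n_train + n_test
  ranges <- param_ranges(prior, rtm, prior_summary)
  params <- lhs_sample(n, ranges, seed = derive_seed(seed, "lhs"))
  params <- inject_barren(params, barren_fraction,
                          seed = derive_seed(seed, "barren"))
  split <- rep("test", n)
  split[with_seed(derive_seed(seed, "split"), sample.int(n, n_train))] <- "train"
  params$split <- split

  clean <- map(setNames(sensors, sensors), function(s) {
    rtm_bands(params, rtm = rtm, sensor = s, geom = geom)
  })
  noisy <- imap(clean, function(b, s) {
    apply_noise(b, sigma_mi, sigma_ai, seed = derive_seed(seed, "noise", s))
  })

  structure(
    list(
      params = params,
      clean = clean,
      noisy = noisy,
      manifest = list(
        prior = prior, rtm = rtm, sigma_mi = sigma_mi, sigma_ai = sigma_ai,
        n_train = n_train, n_test = n_test,
        barren_fraction = barren_fraction, sensors = sensors,
        ranges = ranges, seed = seed,
        band_order = map(clean, names)
      )
    ),
    class = "training_db"
  )
}

#' @export
print.training_db <- function(x, ...) {
  m <- x$manifest
  cat("<training_db> ", m$rtm, "/", m$prior,
      "  n = ", nrow(x$params),
      " (train ", m$n_train, " / test ", m$n_test, ")\n", sep = "")
  cat("  sensors: ", paste(m$sensors, collapse = ", "),
      "   sigma_MI = ", m$sigma_mi, ", sigma_AI = ", m$sigma_ai, "\n", sep = "")
  invisible(x)
}

#' Assemble the feature matrix and target for one sensor
#'
#' Extracts the learning problem of one sensor from a training database: the
#' noise-contaminated band reflectances (plus, optionally, the sun zenith
#' angle as an extra feature column `sza`) and the LAI target.
#'
#' @param db A `training_db` from [build_training_db()].
#' @param sensor Sensor name present in the database.
#' @param use_sza Include the sun zenith angle as a feature.
#' @param split `"train"`, `"test"` or `"all"`.
#' @return List with `features` (tibble, fixed column order recorded by
#'   name), `target` (numeric LAI vector) and `sensor`.
#' @export
assemble_features <- function(db, sensor, use_sza = FALSE, split = "all") {
  stopifnot(inherits(db, "training_db"))
  if (!sensor %in% names(db$noisy)) {
    abort(paste0("database was not built for sensor ", sensor))
  }
  keep <- if (split == "all") rep(TRUE, nrow(db$params)) else
    db$params$split == split
  features <- db$noisy[[sensor]][keep, , drop = FALSE]
  if (use_sza) features$sza <- db$params$theta_s[keep]
  list(features = features, target = db$params$lai[keep], sensor = sensor)
}
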