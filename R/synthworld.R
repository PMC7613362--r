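#' Configuration of the synthetic forest world
#'
#' Defines the study conditions of the synthetic deciduous-forest year that
#' every pipeline stage can be exercised against: five plots with known peak
#' LAI (one plot markedly sparser, reflecting a younger, denser-stemmed
#' stand), a constant wood area index, a double-logistic phenology (fast
#' spring flush, slower autumn fall), seasonal leaf chemistry with stable
#' structural constituents and senescing chlorophyll/brown pigment, sensor
#' observation calendars thinned by cloud cover, and noise levels of the
#' simulated field instruments.
#'
#' @param plots Tibble with one row per plot: `plot`, `lai_max` (m2/m2),
#'   `crown_diameter` (m), `n_scan_positions`, `n_traps`.
#' @param wai Wood area index, m2/m2 (constant over the year).
#' @param t_flush,t_fall Day-of-year midpoints of leaf flush and leaf fall.
#' @param k_flush,k_fall Logistic rates (1/day); the flush default spans
#'   10-90% in ~12.6 days.
#' @param cab_peak Plateau chlorophyll content, ug/cm2.
#' @param sigma_obs Additive Gaussian observation noise per band
#'   (reflectance units) on the simulated satellite observations.
#' @param clear_sky Named clear-sky probabilities per sensor.
#' @param sigma_tls Lognormal noise sd of the TLS gap fractions.
#' @param litter_cv Coefficient of variation of per-trap seasonal litter
#'   mass.
#' @param sla Specific leaf area, cm2/g.
#' @param trap_area Litter-trap surface area, m2.
#' @param latitude Site latitude, degrees north.
#' @param overpass_hour Local solar time of the morning overpasses.
#' @return A list of class `world_config`.
#' @export
world_config <- function(
    plots = tibble(
      plot = c("A", "B", "C", "D", "E"),
      lai_max = c(6.1, 5.9, 5.0, 3.2, 5.9),
      crown_diameter = c(7, 7.5, 6.5, 5.5, 8),
      n_scan_positions = 5,
      n_traps = 5
    ),
    wai = 0.6,
    t_flush = 128, t_fall = 315,
    k_flush = 0.35, k_fall = 0.12,
    cab_peak = 40,
    sigma_obs = 0.05,
    clear_sky = c("MSI" = 0.33, "ETM+" = 0.17, "OLI" = 0.16),
    sigma_tls = 0.03,
    litter_cv = 0.08,
    sla = 200,
    trap_area = 0.79,
    latitude = 52.2525,
    overpass_hour = 10.5) {
  stopifnot(all(plots$lai_max > 0), all(plots$lai_max <= 8), wai >= 0,
            t_fall > t_flush, all(clear_sky >= 0), all(clear_sky <= 1))
  structure(
    list(plots = plots, wai = wai, t_flush = t_flush, t_fall = t_fall,
         k_flush = k_flush, k_fall = k_fall, cab_peak = cab_peak,
         sigma_obs = sigma_obs, clear_sky = clear_sky,
         sigma_tls = sigma_tls, litter_cv = litter_cv, sla = sla,
         trap_area = trap_area, latitude = latitude,
         overpass_hour = overpass_hour),
    class = "world_config"
  )
}

# closed-form truth curves (day may exceed 365, e.g. a January litter pickup)
phenology_lai <- function(day, lai_max, config) {
  lai_max * pmax(
    logistic(config$k_flush * (day - config$t_flush)) -
      logistic(config$k_fall * (day - config$t_fall)),
    0
  )
}

#' Daily truth LAI trajectories
#'
#' Double-logistic phenology per plot:
#' `LAI(t) = LAI_max * [logistic(k1 (t - t_flush)) - logistic(k2 (t - t_fall))]+`.
#'
#' @param config A [world_config()].
#' @param days Days of year to evaluate.
#' @return Tibble `plot`, `day`, `lai`.
#' @export
gen_phenology <- function(config, days = 1:365) {
  if (config$t_fall <= config$t_flush) {
    abort("leaf fall must come after leaf flush")
  }
  expand_grid(plot = config$plots$plot, day = days) |>
    left_join(config$plots[c("plot", "lai_max")], by = "plot") |>
    mutate(lai = phenology_lai(.data$day, .data$lai_max, config)) |>
    select("plot", "day", "lai")
}

#' Daily truth leaf chemistry
#'
#' The structural constituents (N, Car, Cw, Cm) are constant at the field
#' best estimates; chlorophyll rises with the flush to its plateau and drops
#' by more than half during senescence; brown pigment ramps from 0 to 0.6
#' across senescence.
#'
#' @inheritParams gen_phenology
#' @return Tibble `day`, `n`, `cab`, `car`, `cw`, `cm`, `cbrown`.
#' @export
gen_chem_season <- function(config, days = 1:365) {
  best <- leaf_best_estimates()
  tibble(
    day = days,
    n = best[["n"]], car = best[["car"]], cw = best[["cw"]],
    cm = best[["cm"]],
    cab = config$cab_peak *
      logistic(config$k_flush * (days - config$t_flush)) *
      (1 - 0.55 * logistic(0.15 * (days - (config$t_fall - 20)))),
    cbrown = 0.6 * logistic(0.1 * (days - (config$t_fall - 10)))
  ) |>
    select("day", "n", "cab", "car", "cw", "cm", "cbrown")
}

# sun zenith angle (degrees) from day of year, latitude and local solar hour
solar_zenith <- function(day, latitude, hour = 10.5) {
  decl <- -23.44 * cos(2 * pi * (day + 10) / 365.25)
  h <- (hour - 12) * 15
  cosz <- sin(latitude * pi / 180) * sin(decl * pi / 180) +
    cos(latitude * pi / 180) * cos(decl * pi / 180) * cos(h * pi / 180)
  acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

#' Observation calendar of one sensor
#'
#' Builds the overpass dates of a sensor over one year (two orbits each: a
#' combined 5-day cadence for MSI, two 16-day tracks one week apart for each
#' Landsat mission), computes the sun zenith angle at the morning overpass
#' from latitude and solar declination (clipped to the 27.5-80 degree
#' training range), and draws per-date usability as Bernoulli trials with
#' the sensor's clear-sky probability.
#'
#' @param config A [world_config()].
#' @param sensor Sensor name.
#' @param seed Integer seed for the cloud draws.
#' @return Tibble `day`, `theta_s`, `usable`.
#' @export
gen_calendar <- function(config, sensor, seed = 1) {
  days <- switch(
    match.arg(sensor, c("MSI", "ETM+", "OLI")),
    "MSI" = seq(3, 365, by = 5),
    "ETM+" = sort(c(seq(5, 365, by = 16), seq(12, 365, by = 16))),
    "OLI" = sort(c(seq(13, 365, by = 16), seq(20, 365, by = 16)))
  )
  p_clear <- unname(config$clear_sky[[sensor]])
  usable <- with_seed(seed, runif(length(days)) < p_clear)
  tibble(
    day = days,
    theta_s = pmin(pmax(solar_zenith(days, config$latitude,
                                     config$overpass_hour), 27.5), 80),
    usable = usable
  )
}

#' Simulated satellite observations of the synthetic world
#'
#' For every usable calendar date and plot, evaluates the truth canopy state
#' (phenology LAI, seasonal chemistry, overpass sun angle, plot crown
#' diameter) with the chosen reflectance surrogate, convolves to the sensor's
#' bands and adds independent additive Gaussian observation noise per band.
#'
#' @param config A [world_config()].
#' @param sensor Sensor name.
#' @param rtm Truth surrogate; the crown-explicit `"GEOM"` default makes
#'   homogeneous-model training face realistic structural mismatch.
#' @param calendar Optional precomputed [gen_calendar()] table.
#' @param sigma_obs Override of the configured observation noise.
#' @param geom Scene geometry constants.
#' @param seed Integer seed (cloud draws via the calendar, then noise).
#' @return Tibble `plot`, `day`, `sensor`, `theta_s`, `usable` and one column
#'   per band.
#' @export
gen_observations <- function(config, sensor, rtm = "GEOM", calendar = NULL,
                             sigma_obs = NULL, geom = scene_geometry(),
                             seed = 1) {
  if (is.null(calendar)) {
    calendar <- gen_calendar(config, sensor, seed = derive_seed(seed, "cal"))
  }
  sigma_obs <- if (is.null(sigma_obs)) config$sigma_obs else sigma_obs
  cal <- calendar[calendar$usable, ]
  if (nrow(cal) == 0) {
    abort(paste0("no usable observations in the ", sensor, " calendar"))
  }
  chem <- gen_chem_season(config, days = cal$day)
  obs <- expand_grid(plot = config$plots$plot, idx = seq_len(nrow(cal))) |>
    mutate(day = cal$day[.data$idx], theta_s = cal$theta_s[.data$idx]) |>
    left_join(config$plots[c("plot", "lai_max", "crown_diameter")],
              by = "plot") |>
    mutate(lai = phenology_lai(.data$day, .data$lai_max, config))
  params <- obs |>
    mutate(
      n = chem$n[.data$idx], cab = chem$cab[.data$idx],
      car = chem$car[.data$idx], cw = chem$cw[.data$idx],
      cm = chem$cm[.data$idx], cbrown = chem$cbrown[.data$idx]
    ) |>
    select("n", "cab", "car", "cm", "cw", "cbrown", "lai", "theta_s",
           "crown_diameter")
  bands <- rtm_bands(params, rtm = rtm, sensor = sensor, geom = geom)
  if (sigma_obs > 0) {
    bands <- apply_noise(bands, sigma_mi = 0, sigma_ai = sigma_obs,
                         seed = derive_seed(seed, "obsnoise", sensor))
  }
  bind_cols(
    obs |> mutate(sensor = sensor, usable = TRUE) |>
      select("plot", "day", "sensor", "theta_s", "usable"),
    bands
  ) |>
    arrange(.data$day, .data$plot)
}

# 28 TLS field visits, denser during flush and senescence
tls_visit_days <- function() {
  c(15, 46, 74, 100, 110, 118, 124, 130, 136, 142, 150, 160,
    175, 190, 205, 220, 235, 250, 265, 280, 290, 298, 306, 314,
    322, 330, 345, 360)
}

#' Simulated TLS gap-fraction records
#'
#' For each of 28 field visits and each plot, the hinge-angle gap fraction
#' consistent with the truth plant area (leaf plus wood):
#' `P_gap = exp(-(LAI + WAI) / 1.1) * exp(eps)`, `eps ~ N(0, sigma_tls)`,
#' clipped to `(0, 1]`.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return Tibble `plot`, `day`, `gap`.
#' @export
gen_tls <- function(config, seed = 1) {
  days <- tls_visit_days()
  truth <- gen_phenology(config, days = days)
  eps <- with_seed(derive_seed(seed, "tls"),
                   rnorm(nrow(truth), 0, config$sigma_tls))
  truth |>
    mutate(gap = pmin(exp(-(.data$lai + config$wai) / 1.1) * exp(eps), 1)) |>
    select("plot", "day", "gap")
}

# litter pickup days: one early-summer check, then concentrated in autumn,
# with a final pickup the following January (day > 365)
litter_collection_days <- function() {
  c(153, 225, 281, 295, 316, 337, 375)
}

#' Simulated litter-trap records
#'
#' Per plot, each of the five traps collects a total seasonal dry leaf mass
#' consistent with the plot's peak LAI and the specific leaf area
#' (`mass = LAI_max * area / (SLA * 1e-4)`), perturbed by a trap-level
#' relative error. The total is split across the seven collections
#' proportionally to the truth LAI decline between pickup dates.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return Tibble `plot`, `trap`, `day`, `mass`, `sla`, `area`.
#' @export
gen_littertraps <- function(config, seed = 1) {
  days <- litter_collection_days()
  edges <- c(1, days)
  out <- map(seq_len(nrow(config$plots)), function(i) {
    pl <- config$plots[i, ]
    lai_edges <- phenology_lai(edges, pl$lai_max, config)
    decline <- pmax(-diff(lai_edges), 0)
    w <- if (sum(decline) > 0) decline / sum(decline) else
      rep(1 / length(days), length(days))
    total <- pl$lai_max * config$trap_area / (config$sla * 1e-4)
    delta <- with_seed(derive_seed(seed, "litter", pl$plot),
                       rnorm(pl$n_traps, 0, config$litter_cv))
    expand_grid(trap = seq_len(pl$n_traps), day = days) |>
      mutate(
        plot = pl$plot,
        mass = total * (1 + delta[.data$trap]) * w[match(.data$day, days)],
        sla = config$sla, area = config$trap_area
      )
  }) |>
    list_rbind()
  out[c("plot", "trap", "day", "mass", "sla", "area")]
}

#' Build a complete synthetic world
#'
#' Generates all components of the synthetic year in one call: daily truth
#' (LAI, chemistry), per-sensor observation tables, TLS and litter-trap
#' records, and a manifest tracing every table to the configuration and
#' master seed. Regeneration with the same configuration and seed is
#' identical.
#'
#' @param config A [world_config()].
#' @param rtm Truth reflectance surrogate (`"GEOM"` by default).
#' @param sensors Sensors to observe with.
#' @param seed Master seed.
#' @param sigma_obs Optional observation-noise override.
#' @return List of class `synth_world`.
#' @export
build_world <- function(config = world_config(), rtm = "GEOM",
                        sensors = c("MSI", "ETM+", "OLI"), seed = 1,
                        sigma_obs = NULL) {
  observations <- map(setNames(sensors, sensors), function(s) {
    gen_observations(config, s, rtm = rtm, sigma_obs = sigma_obs,
                     seed = derive_seed(seed, "obs", s))
  })
  structure(
    list(
      config = config,
      truth_lai = gen_phenology(config),
      truth_chem = gen_chem_season(config),
      observations = observations,
      tls = gen_tls(config, seed = derive_seed(seed, "tls")),
      litter = gen_littertraps(config, seed = derive_seed(seed, "litter")),
      manifest = list(rtm = rtm, sensors = sensors, seed = seed,
                      sigma_obs = if (is.null(sigma_obs)) config$sigma_obs
                                  else sigma_obs)
    ),
    class = "synth_world"
  )
}

#' @export
print.synth_world <- function(x, ...) {
  n_obs <- sum(map_dbl(x$observations, nrow))
  cat("<synth_world> ", nrow(x$config$plots), " plots, truth RTM ",
      x$manifest$rtm, "\n", sep = "")
  cat("  ", n_obs, " usable plot-observations across ",
      length(x$observations), " sensors; ", nrow(x$tls),
      " TLS records; ", nrow(x$litter), " litter records\n", sep = "")
  invisible(x)
}

#' Build the validation reference series of a synthetic world
#'
#' Runs the full reference pipeline on the world's field records: gap
#' fractions to PAI, litter traps to plot seasonal LAI, TLS calibration to
#' the litter totals.
#'
#' @param world A `synth_world`.
#' @param range_denominator Passed to [calibrate_tls()].
#' @return List with `series` (the calibrated per-plot LAI series),
#'   `litter` (per-plot litter LAI and SEM).
#' @export
build_reference <- function(world, range_denominator = FALSE) {
  pai <- world$tls |>
    mutate(pai = pai_from_gap(.data$gap), date = .data$day) |>
    select("plot", "date", "pai")
  litter <- littertrap_lai(world$litter)
  series <- calibrate_tls(pai, litter,
                          range_denominator = range_denominator)
  list(series = series, litter = litter)
}
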