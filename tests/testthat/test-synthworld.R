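test_that("phenology follows the double-logistic with plot-specific peaks", {
  cfg <- world_config()
  ph <- gen_phenology(cfg)
  peaks <- ph |> dplyr::group_by(plot) |>
    dplyr::summarise(peak = max(lai)) |>
    dplyr::left_join(cfg$plots[c("plot", "lai_max")], by = "plot")
  expect_true(all(peaks$peak >= 0.98 * peaks$lai_max))
  expect_equal(peaks$peak[peaks$plot == "D"], 3.2, tolerance = 0.02)
  # midwinter bare canopy
  w15 <- ph[ph$day == 15, ]
  expect_true(all(w15$lai <= 0.05 * peaks$lai_max))
  expect_error(world_config(t_flush = 300, t_fall = 200), "t_fall")
})

test_that("leaf chemistry season: stable structure, senescing pigments", {
  cfg <- world_config()
  ch <- gen_chem_season(cfg)
  expect_true(all(ch$n == 1.27))
  expect_true(all(ch$car == 8.60))
  expect_equal(ch$cab[ch$day == 200], 40, tolerance = 1)
  # chlorophyll down by at least half late in the year
  expect_lte(ch$cab[ch$day == 365], 0.5 * max(ch$cab))
  # brown pigment ramps monotonically through senescence
  expect_gt(ch$cbrown[ch$day == 365], ch$cbrown[ch$day == 200])
  expect_true(all(diff(ch$cbrown) >= 0))
})

test_that("observation calendars honour cadence, sun geometry and clouds", {
  cfg <- world_config()
  cal <- gen_calendar(cfg, "MSI", seed = 5)
  expect_equal(unique(diff(cal$day)), 5)
  expect_true(all(cal$theta_s >= 27.5 & cal$theta_s <= 80))
  # summer overpasses have the lowest sun zenith angles
  expect_lt(cal$theta_s[which.min(abs(cal$day - 172))],
            cal$theta_s[which.min(abs(cal$day - 355))])
  # all usable when the sky is always clear
  clear <- world_config(clear_sky = c("MSI" = 1, "ETM+" = 1, "OLI" = 1))
  expect_true(all(gen_calendar(clear, "MSI", seed = 5)$usable))
  # usable counts within binomial bounds of the clear-sky rates
  n_us <- purrr::map_int(1:20, function(s) {
    sum(gen_calendar(cfg, "MSI", seed = s)$usable)
  })
  p <- 0.33
  n <- nrow(cal)
  expect_gt(mean(n_us), n * p - 2 * sqrt(n * p * (1 - p)))
  expect_lt(mean(n_us), n * p + 2 * sqrt(n * p * (1 - p)))
  # Landsat: two 16-day tracks
  etm <- gen_calendar(cfg, "ETM+", seed = 1)
  expect_setequal(unique(diff(etm$day)), c(7, 9))
})

test_that("synthetic observations trace the truth reflectance", {
  # barren world: noiseless NIR equals the soil-derived band value
  bare <- world_config(plots = tibble::tibble(
    plot = "A", lai_max = 1e-9, crown_diameter = 7,
    n_scan_positions = 5, n_traps = 5
  ), clear_sky = c("MSI" = 1, "ETM+" = 1, "OLI" = 1))
  obs0 <- gen_observations(bare, "MSI", sigma_obs = 0, seed = 2)
  srfs <- build_srf(sensor_specs("MSI"))
  soil_b8a <- unname(convolve_to_bands(soil_spectrum(), srfs)["B8A"])
  # gaps fully sunlit at low sun angles only; at high SZA the shaded-soil
  # factor dims the scene, so compare at the summer minimum
  summer <- obs0[which.min(obs0$theta_s), ]
  expect_lt(abs(summer$B8A - soil_b8a) / soil_b8a, 0.05)
  # chlorophyll absorption: red band lower at peak season than in winter
  cfg <- world_config(clear_sky = c("MSI" = 1, "ETM+" = 1, "OLI" = 1))
  obs <- gen_observations(cfg, "MSI", sigma_obs = 0, seed = 2)
  for (p in cfg$plots$plot) {
    o <- obs[obs$plot == p, ]
    expect_lt(o$B4[which.min(abs(o$day - 200))],
              o$B4[which.min(o$day)])
  }
  # regeneration is identical under the same seed
  expect_identical(gen_observations(cfg, "MSI", seed = 9),
                   gen_observations(cfg, "MSI", seed = 9))
  cloudy <- world_config(clear_sky = c("MSI" = 0, "ETM+" = 0, "OLI" = 0))
  expect_error(gen_observations(cloudy, "MSI", seed = 1), "no usable")
})

test_that("TLS records invert to truth plant area", {
  cfg <- world_config(sigma_tls = 0)
  tls <- gen_tls(cfg, seed = 3)
  expect_equal(nrow(tls), 28 * 5)
  truth <- gen_phenology(cfg, days = sort(unique(tls$day)))
  j <- dplyr::inner_join(tls, truth, by = c("plot", "day"))
  expect_lt(max(abs(pai_from_gap(j$gap) - (j$lai + cfg$wai))), 1e-10)
  # gap fraction of a leaf-off stand carrying only wood area
  expect_equal(exp(-0.6 / 1.1), 0.5794, tolerance = 1e-3)
})

test_that("litter traps recover plot peak LAI and follow leaf fall", {
  cfg <- world_config(litter_cv = 0)
  lit <- gen_littertraps(cfg, seed = 6)
  expect_equal(dplyr::n_distinct(paste(lit$plot, lit$trap)), 25L)
  out <- littertrap_lai(lit)
  expect_equal(out$lai_lt,
               cfg$plots$lai_max[match(out$plot, cfg$plots$plot)],
               tolerance = 1e-9)
  # collections before leaf fall carry little mass
  early <- lit |> dplyr::group_by(plot) |>
    dplyr::summarise(frac = sum(mass[day < 281]) / sum(mass))
  expect_true(all(early$frac < 0.2))
})

test_that("the full world regenerates identically and closes end to end", {
  w1 <- build_world(seed = 5, sensors = "MSI")
  w2 <- build_world(seed = 5, sensors = "MSI")
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$tls, w2$tls)
  expect_identical(w1$litter, w2$litter)
  # noiseless closure through the reference pipeline, printed form:
  # residual only from the max-denominator and the wood-area offset
  cfg0 <- world_config(sigma_tls = 0, litter_cv = 0)
  w0 <- build_world(cfg0, seed = 5, sensors = "MSI", sigma_obs = 0)
  ref <- build_reference(w0)$series
  truth <- gen_phenology(cfg0, days = sort(unique(ref$date)))
  j <- dplyr::inner_join(ref, dplyr::rename(truth, date = day),
                         by = c("plot", "date"))
  err <- j |> dplyr::group_by(plot) |>
    dplyr::summarise(rmse = sqrt(mean((lai.x - lai.y)^2))) |>
    dplyr::left_join(cfg0$plots[c("plot", "lai_max")], by = "plot")
  expect_true(all(err$rmse <= 0.15 * err$lai_max))
  # with the range denominator and no wood area, recovery is exact up to
  # the phenology tails at the visit days
  cfge <- world_config(sigma_tls = 0, litter_cv = 0, wai = 0)
  we <- build_world(cfge, seed = 5, sensors = "MSI", sigma_obs = 0)
  refe <- build_reference(we, range_denominator = TRUE)$series
  truthe <- gen_phenology(cfge, days = sort(unique(refe$date)))
  je <- dplyr::inner_join(refe, dplyr::rename(truthe, date = day),
                          by = c("plot", "date"))
  expect_lt(max(abs(je$lai.x - je$lai.y)), 1e-5)
})
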