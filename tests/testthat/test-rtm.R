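test_that("absorption curves follow their closed forms", {
  k <- absorption_curves(c(670, 865, 1450))
  expect_equal(k$k_ab[1], 0.06, tolerance = 1e-6)
  # water absorption negligible in the NIR
  expect_lt(k$k_w[2], 0.01 * k$k_w[3])
  kk <- absorption_curves()
  expect_true(all(as.matrix(kk[-1]) >= 0))
})

test_that("leaf albedo and reflectance follow the two-stream closed forms", {
  # no absorbers: omega at the ceiling everywhere
  empty <- leaf_chem(n = 1, cab = 0, car = 0, cm = 0, cw = 0, cbrown = 0)
  expect_equal(unname(leaf_albedo(empty, c(500, 1500))), c(0.96, 0.96))
  # hand-evaluated chlorophyll case at 670 nm
  lf <- leaf_chem(n = 1.5, cab = 40, car = 0, cm = 0, cw = 0, cbrown = 0)
  expect_equal(unname(leaf_albedo(lf, 670)), 0.96 * exp(-1.6),
               tolerance = 1e-6)
  expect_equal(unname(leaf_reflectance(lf, 670)), 0.0538, tolerance = 1e-3)
  expect_equal(hylai:::two_stream_reflectance(0.96), 0.8 / 1.2,
               tolerance = 1e-12)
  expect_equal(hylai:::two_stream_reflectance(0), 0)
  # doubling n raises the albedo at every wavelength
  lf2 <- leaf_chem(n = 3, cab = 40, car = 0, cm = 0, cw = 0, cbrown = 0)
  expect_true(all(leaf_albedo(lf2) >= leaf_albedo(lf)))
  expect_error(leaf_chem(n = 0.5), ">= 1")
})

test_that("soil spectrum is the clipped brightness ramp", {
  expect_equal(soil_spectrum(400), 0.10)
  expect_equal(soil_spectrum(865), 0.1372)
  expect_true(all(soil_spectrum() <= 0.35))
  expect_error(soil_spectrum(500, brightness = 0), "> 0")
})

test_that("turbid surrogate matches hand-evaluated cases and bounds", {
  bare <- canopy_state(leaf_chem(), lai = 0)
  expect_equal(turbid_brf(bare), soil_spectrum(), tolerance = 1e-12)
  # NIR composition: omega = 0.96, soil 0.1372, theta 30, LAI 4
  st <- canopy_state(leaf_chem(n = 1, cab = 0, car = 0, cm = 0, cw = 0),
                     lai = 4, theta_s = 30)
  expect_equal(unname(turbid_brf(st, wavelength = 865)), 0.6596,
               tolerance = 1e-3)
  # extinction monotone: LAI 8 closer to the infinite-canopy limit
  st8 <- st
  st8$lai <- 8
  rho_inf <- 0.8 / 1.2
  expect_true(all(abs(turbid_brf(st8) - rho_inf) <
                    abs(turbid_brf(st) - rho_inf)))
  expect_error(canopy_state(lai = 9), "lai")
})

test_that("turbid NIR rises with LAI and red falls with chlorophyll", {
  lai_seq <- seq(0, 8, length.out = 50)
  st <- canopy_state(leaf_chem(), lai = lai_seq, theta_s = 35)
  nir <- turbid_brf(st, wavelength = 865)[, 1]
  expect_true(all(diff(nir) > 0))
  cab_seq <- seq(5, 80, length.out = 50)
  st2 <- canopy_state(leaf_chem(cab = cab_seq), lai = 3, theta_s = 35)
  red <- turbid_brf(st2, wavelength = 665)[, 1]
  expect_true(all(diff(red) < 0))
})

test_that("crown-explicit surrogate matches its composed closed form", {
  # crown cover for a 7 m crown at 0.05 trees/m2
  st <- canopy_state(leaf_chem(n = 1, cab = 0, car = 0, cm = 0, cw = 0),
                     lai = 4, theta_s = 45, crown_diameter = 7)
  a <- 3.5
  expect_equal(1 - exp(-0.05 * pi * a^2), 0.8540, tolerance = 1e-4)
  # sunlit gap fraction at 45 degrees
  a_sh <- pi * a * sqrt(a^2 + 3.5^2)
  g_sun <- exp(-0.05 * (a_sh - pi * a^2))
  expect_equal(g_sun, 0.4507, tolerance = 1e-3)
  expect_equal(unname(geom_brf(st, wavelength = 865)), 0.580,
               tolerance = 0.002)
})

test_that("crown model converges to the turbid model as cover closes", {
  st <- canopy_state(leaf_chem(), lai = 3, theta_s = 40, crown_diameter = 7)
  dense <- scene_geometry(tree_density = 1)
  g <- geom_brf(st, dense)
  t <- turbid_brf(st, dense)
  expect_true(all(abs(g - t) / pmax(t, 1e-6) < 0.01))
})

test_that("only the crown model responds to sun angle beyond extinction", {
  # at fixed high LAI the turbid NIR saturates towards rho_inf for any sun
  # angle, while crown gaps keep a shadow-driven sun-angle response
  lf <- leaf_chem()
  st_lo <- canopy_state(lf, lai = 2, theta_s = 27.5, crown_diameter = 7)
  st_hi <- canopy_state(lf, lai = 2, theta_s = 80, crown_diameter = 7)
  d_geom <- abs(geom_brf(st_lo, wavelength = 865) -
                  geom_brf(st_hi, wavelength = 865))
  expect_gt(d_geom, 0)
  expect_error(geom_brf(canopy_state(lf, crown_diameter = NA)), "crown")
})

test_that("all surrogate reflectances stay within [0, 1]", {
  rng <- param_ranges("free", "GEOM")
  params <- lhs_sample(60, rng, seed = 5)
  for (r in c("TURBID", "GEOM")) {
    b <- rtm_bands(params, rtm = r, sensor = "MSI")
    expect_true(all(as.matrix(b) >= 0 & as.matrix(b) <= 1))
  }
})
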