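#' Specific absorption curves of the surrogate leaf model
#'
#' Closed-form specific absorption spectra for the five leaf constituents
#' used by the surrogate leaf optical model: chlorophyll a+b (`k_ab`, cm2/ug),
#' carotenoids (`k_car`, cm2/ug), brown pigment (`k_brown`, per unit fraction),
#' water (`k_w`, 1/cm) and dry matter (`k_m`, cm2/g). Each curve is a sum of
#' Gaussian or exponential terms placed at the wavelengths where the
#' constituent absorbs in real leaves (chlorophyll red/blue peaks, carotenoid
#' blue shoulder, the 1200/1450/1650/1940 nm water features, the broad dry
#' matter SWIR feature).
#'
#' @param wavelength Wavelengths in nm (within 400-2400).
#' @return A tibble with columns `wavelength`, `k_ab`, `k_car`, `k_brown`,
#'   `k_w`, `k_m`; all curves non-negative.
#' @export
#' @examples
#' absorption_curves(c(490, 670, 865, 1450))
absorption_curves <- function(wavelength = hylai_grid()) {
  g <- function(l, c, w) exp(-((l - c)^2) / (2 * w^2))
  l <- wavelength
  tibble(
    wavelength = l,
    k_ab = 0.06 * g(l, 670, 45) + 0.04 * g(l, 450, 35),
    k_car = 0.05 * g(l, 490, 30),
    k_brown = 3.0 * exp(-(l - 400) / 250),
    k_w = 5 * g(l, 1200, 50) + 30 * g(l, 1450, 60) +
      12 * g(l, 1650, 120) + 45 * g(l, 1940, 80),
    k_m = 2 + 8 * g(l, 2100, 150)
  )
}

#' Leaf chemistry vector
#'
#' Constructor/validator for the leaf biochemical parameter set of the
#' surrogate leaf model: structure index `n` (dimensionless, >= 1),
#' chlorophyll `cab` (ug/cm2), carotenoids `car` (ug/cm2), dry matter `cm`
#' (g/cm2), water `cw` (cm) and brown pigment fraction `cbrown`.
#'
#' @param n,cab,car,cm,cw,cbrown Leaf parameters (scalars or equal-length
#'   vectors).
#' @return A tibble with one row per leaf.
#' @export
leaf_chem <- function(n = 1.5, cab = 40, car = 8.6, cm = 0.00263,
                      cw = 0.0053, cbrown = 0) {
  out <- tibble(n = n, cab = cab, car = car, cm = cm, cw = cw, cbrown = cbrown)
  if (any(out$n < 1)) abort("leaf structure index `n` must be >= 1")
  if (any(out$cab < 0 | out$car < 0 | out$cm < 0 | out$cw < 0 | out$cbrown < 0)) {
    abort("leaf constituent contents must be >= 0")
  }
  out
}

#' Single-scattering albedo of a leaf
#'
#' The surrogate leaf model attenuates a ceiling albedo `omega_max`
#' exponentially with the total specific absorption of the constituents,
#' divided by the structure index: `omega = omega_max * exp(-alpha)` with
#' `alpha = (k_ab*cab + k_car*car + k_brown*cbrown + k_w*cw + k_m*cm) / n`.
#'
#' @param leaf One-row tibble from [leaf_chem()] (or a multi-row tibble for a
#'   batch; the result is then a matrix, leaves in rows).
#' @param wavelength Wavelengths in nm.
#' @param omega_max Albedo ceiling in the absence of absorption.
#' @return Numeric vector (or matrix) of single-scattering albedos in
#'   `(0, omega_max]`.
#' @export
leaf_albedo <- function(leaf, wavelength = hylai_grid(), omega_max = 0.96) {
  if (any(leaf$n < 1)) abort("leaf structure index `n` must be >= 1")
  k <- absorption_curves(wavelength)
  K <- cbind(k$k_ab, k$k_car, k$k_brown, k$k_w, k$k_m)
  C <- cbind(leaf$cab, leaf$car, leaf$cbrown, leaf$cw, leaf$cm)
  alpha <- (C %*% t(K)) / leaf$n
  omega <- omega_max * exp(-alpha)
  if (nrow(leaf) == 1) drop(omega) else omega
}

# infinite-medium two-stream reflectance from single-scattering albedo
two_stream_reflectance <- function(omega) {
  s <- sqrt(pmax(1 - omega, 0))
  (1 - s) / (1 + s)
}

#' Leaf reflectance
#'
#' Reflectance of an optically thick leaf medium from its single-scattering
#' albedo via the two-stream closed form
#' `rho = (1 - sqrt(1 - omega)) / (1 + sqrt(1 - omega))`, strictly increasing
#' in `omega`.
#'
#' @inheritParams leaf_albedo
#' @return Numeric vector (or matrix) of leaf reflectances.
#' @export
#' @examples
#' leaf_reflectance(leaf_chem(n = 1.5, cab = 40, car = 0, cm = 0, cw = 0), 670)
leaf_reflectance <- function(leaf, wavelength = hylai_grid(), omega_max = 0.96) {
  two_stream_reflectance(leaf_albedo(leaf, wavelength, omega_max))
}

#' Soil background spectrum
#'
#' A brightness-scaled linear ramp standing in for the bare beech-forest soil
#' background estimated from barren winter scenes:
#' `rho_soil = brightness * (0.10 + 0.00008 * (wavelength - 400))`, clipped to
#' `[0, 0.35]`.
#'
#' @param wavelength Wavelengths in nm.
#' @param brightness Positive wet/dry brightness scalar.
#' @return Numeric vector of soil reflectances.
#' @export
soil_spectrum <- function(wavelength = hylai_grid(), brightness = 1) {
  if (brightness <= 0) abort("`brightness` must be > 0")
  pmin(pmax(brightness * (0.10 + 0.00008 * (wavelength - 400)), 0), 0.35)
}

#' Scene geometry constants for the canopy surrogates
#'
#' Fixed structural constants shared by the two canopy reflectance
#' surrogates: tree density of the crown-explicit scene (5 trees on a
#' 10 m x 10 m repetitive scene), the diffuse illumination factor of shaded
#' soil `beta`, the leaf projection coefficient `G` (0.5 approximates a
#' plagiophile leaf angle distribution at mid zenith angles), and the leaf
#' albedo ceiling `omega_max`.
#'
#' @param tree_density Trees per m2 (> 0).
#' @param beta Shaded-soil illumination factor in (0, 1].
#' @param G Leaf projection coefficient in (0, 1].
#' @param omega_max Leaf albedo ceiling in (0, 1).
#' @return A list of class `scene_geometry`.
#' @export
scene_geometry <- function(tree_density = 0.05, beta = 0.3, G = 0.5,
                           omega_max = 0.96) {
  stopifnot(tree_density > 0, beta > 0, beta <= 1, G > 0, G <= 1,
            omega_max > 0, omega_max < 1)
  structure(
    list(tree_density = tree_density, beta = beta, G = G,
         omega_max = omega_max),
    class = "scene_geometry"
  )
}

#' Canopy state vector
#'
#' One canopy condition for the reflectance surrogates: leaf chemistry plus
#' canopy structure and illumination. View zenith and relative azimuth are
#' fixed at 0 (near-nadir acquisitions); the hot-spot parameter and the soil
#' wet/dry factor are carried fixed at 0 and are inert in the surrogates.
#'
#' @param leaf Tibble from [leaf_chem()].
#' @param lai Leaf area index, m2/m2 in `[0, 8]`.
#' @param theta_s Sun zenith angle, degrees in `[27.5, 80]` for sampled
#'   states (values down to 0 are accepted for closed-form checks).
#' @param crown_diameter Crown diameter in m (5-9), used by the
#'   crown-explicit surrogate.
#' @param tree_height,crown_height Fixed structural sizes in m.
#' @return A one-row tibble combining all fields.
#' @export
canopy_state <- function(leaf = leaf_chem(), lai = 4, theta_s = 30,
                         crown_diameter = 7, tree_height = 20,
                         crown_height = 7) {
  if (any(lai < 0 | lai > 8)) abort("`lai` must lie in [0, 8]")
  if (any(theta_s < 0 | theta_s >= 90)) abort("`theta_s` must lie in [0, 90)")
  tibble(
    n = leaf$n, cab = leaf$cab, car = leaf$car, cm = leaf$cm, cw = leaf$cw,
    cbrown = leaf$cbrown,
    lai = lai, theta_s = theta_s, theta_o = 0, phi = 0, lad = "plagiophile",
    alpha_soil = 0, hspot = 0,
    tree_height = tree_height, crown_diameter = crown_diameter,
    crown_height = crown_height
  )
}

#' Turbid-medium canopy reflectance surrogate
#'
#' Homogeneous-canopy bidirectional reflectance: the canopy reflectance
#' relaxes from the soil background to the infinite-canopy leaf reflectance
#' with Beer-Lambert extinction along the combined sun and nadir-view paths,
#' `BRF = rho_inf + (rho_soil - rho_inf) * exp(-(G/cos(theta_s) + G) * LAI)`.
#'
#' @param state Tibble of canopy states ([canopy_state()] fields; one row per
#'   state).
#' @param geom [scene_geometry()] constants.
#' @param wavelength Wavelengths in nm.
#' @return Matrix of BRFs (states in rows, wavelengths in columns); a plain
#'   vector for a single state.
#' @export
#' @examples
#' st <- canopy_state(lai = 0)
#' all.equal(turbid_brf(st, wavelength = 865), soil_spectrum(865))
turbid_brf <- function(state, geom = scene_geometry(),
                       wavelength = hylai_grid()) {
  if (any(state$theta_s >= 90)) abort("`theta_s` must be < 90 degrees")
  leaf <- state[c("n", "cab", "car", "cm", "cw", "cbrown")]
  omega <- leaf_albedo(leaf, wavelength, geom$omega_max)
  if (is.null(dim(omega))) omega <- matrix(omega, nrow = 1)
  rho_inf <- two_stream_reflectance(omega)
  rho_soil <- soil_spectrum(wavelength)
  kext <- (geom$G / cos(state$theta_s * pi / 180) + geom$G) * state$lai
  ext <- exp(-kext)
  soil_m <- matrix(rho_soil, nrow = nrow(rho_inf), ncol = length(wavelength),
                   byrow = TRUE)
  brf <- rho_inf + (soil_m - rho_inf) * ext
  if (nrow(brf) == 1) drop(brf) else brf
}

#' Crown-explicit canopy reflectance surrogate
#'
#' Geometric-optical surrogate resolving crowns and sun-angle shadowing.
#' Crown cover follows a Poisson overlap model,
#' `C = 1 - exp(-density * pi * a^2)` with `a` the crown radius; the canopy
#' LAI is concentrated inside crowns (`LAI_c = LAI / C`); the per-tree ground
#' shadow of an ellipsoidal crown grows with the sun zenith angle,
#' `A_sh = pi * a * sqrt(a^2 + b^2 * tan(theta_s)^2)`, and the sunlit fraction
#' of the between-crown gaps is `g_sun = exp(-density * max(0, A_sh - pi a^2))`.
#' The scene BRF mixes the turbid within-crown signal with sunlit and shaded
#' soil:
#' `BRF = C * turbid(LAI/C) + (1 - C) * rho_soil * (g_sun + (1 - g_sun) * beta)`.
#' Unlike the turbid surrogate, the output depends on the sun angle even at
#' fixed LAI, through gap shadowing.
#'
#' @inheritParams turbid_brf
#' @return Matrix of BRFs (states in rows); a vector for a single state.
#' @export
geom_brf <- function(state, geom = scene_geometry(),
                     wavelength = hylai_grid()) {
  if (any(is.na(state$crown_diameter))) {
    abort("`crown_diameter` must be set for the crown-explicit surrogate")
  }
  a <- state$crown_diameter / 2
  b <- state$crown_height / 2
  cover <- 1 - exp(-geom$tree_density * pi * a^2)
  if (any(cover <= 0)) abort("crown cover is zero; check the scene geometry")
  inner <- state
  inner$lai <- state$lai / cover
  # within-crown LAI can exceed the [0, 8] canopy range by construction
  turbid <- turbid_brf(inner, geom, wavelength)
  if (is.null(dim(turbid))) turbid <- matrix(turbid, nrow = 1)
  tan_ts <- tan(state$theta_s * pi / 180)
  a_sh <- pi * a * sqrt(a^2 + b^2 * tan_ts^2)
  g_sun <- exp(-geom$tree_density * pmax(0, a_sh - pi * a^2))
  rho_soil <- soil_spectrum(wavelength)
  soil_m <- matrix(rho_soil, nrow = nrow(turbid), ncol = length(wavelength),
                   byrow = TRUE)
  brf <- cover * turbid +
    (1 - cover) * soil_m * (g_sun + (1 - g_sun) * geom$beta)
  if (nrow(brf) == 1) drop(brf) else brf
}

#' Evaluate a canopy surrogate for a parameter table and convolve to bands
#'
#' Batch driver used by the training-database and synthetic-world modules:
#' evaluates the chosen canopy reflectance surrogate on the 1-nm grid for
#' every parameter row and convolves the result to the bands of one sensor.
#'
#' @param params Tibble of canopy-state rows (columns `n`, `cab`, `car`,
#'   `cm`, `cw`, `cbrown`, `lai`, `theta_s` and, for `rtm = "GEOM"`,
#'   `crown_diameter`; `crown_height` defaults to 7 m when absent).
#' @param rtm `"TURBID"` (homogeneous) or `"GEOM"` (crown-explicit).
#' @param sensor Sensor name understood by [sensor_specs()].
#' @param geom [scene_geometry()] constants.
#' @return Tibble of band reflectances, one row per parameter row, columns
#'   named after the sensor's bands.
#' @export
rtm_bands <- function(params, rtm = c("TURBID", "GEOM"), sensor = "MSI",
                      geom = scene_geometry()) {
  rtm <- match.arg(rtm)
  srfs <- build_srf(sensor_specs(sensor))
  state <- as_tibble(params)
  if (!"crown_diameter" %in% names(state)) state$crown_diameter <- 7
  if (!"crown_height" %in% names(state)) state$crown_height <- 7
  wl <- hylai_grid()
  fun <- if (rtm == "TURBID") turbid_brf else geom_brf
  # evaluate in blocks to bound the n x 2001 intermediate
  n <- nrow(state)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 2000))
  bands <- map(blocks, function(idx) {
    spec <- fun(state[idx, , drop = FALSE], geom, wl)
    if (is.null(dim(spec))) spec <- matrix(spec, nrow = 1)
    convolve_to_bands(spec, srfs, wl)
  })
  out <- do.call(rbind, bands)
  as_tibble(as.data.frame(out))
}
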