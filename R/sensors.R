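#' Sensor band definitions
#'
#' Band sets for the three multispectral sensors handled by the package:
#' Sentinel-2A MSI (10 bands at 10/20 m; the 60 m atmospheric bands B01, B09
#' and B10 are excluded), Landsat 7 ETM+ (6 bands) and Landsat 8 OLI
#' (6 bands). Band centres and widths (in nm) are read from the JSON resource
#' shipped with the package.
#'
#' @param sensor Sensor name: `"MSI"`, `"ETM+"` or `"OLI"`. `NULL` returns all
#'   three.
#' @return A tibble with columns `sensor`, `band`, `domain` (VIS/NIR/SWIR),
#'   `center` and `width` (nm), bands ordered by wavelength.
#' @export
#' @examples
#' sensor_specs("MSI")
sensor_specs <- function(sensor = NULL) {
  path <- system.file("extdata", "sensor_bands.json", package = "hylai")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- imap(raw, function(x, nm) {
    as_tibble(x$bands) |> mutate(sensor = nm, .before = 1)
  }) |>
    list_rbind()
  if (!is.null(sensor)) {
    sensor <- match.arg(sensor, c("MSI", "ETM+", "OLI"))
    specs <- filter(specs, .data$sensor == !!sensor)
    if (nrow(specs) == 0) abort(paste0("unknown sensor: ", sensor))
  }
  specs
}

#' Build Gaussian spectral response functions for a band set
#'
#' Each band's spectral response is modelled as a Gaussian centred on the
#' band centre with a full width at half maximum equal to the published band
#' width, discretised on the common 1-nm grid ([hylai_grid()]), truncated at
#' +/- 4 standard deviations and renormalised to sum to 1.
#'
#' @param spec A band-specification tibble as returned by [sensor_specs()]
#'   (columns `band`, `center`, `width`; a `sensor` column is carried through).
#' @param grid Wavelength grid in nm; defaults to [hylai_grid()].
#' @return A tibble with one row per band: `band`, `center`, `fwhm`, `sigma`
#'   and list-columns `wavelength`/`weight` holding the truncated support and
#'   the normalised response weights.
#' @export
#' @examples
#' srfs <- build_srf(sensor_specs("MSI"))
#' vapply(srfs$weight, sum, numeric(1))  # all 1
build_srf <- function(spec, grid = hylai_grid()) {
  stopifnot(all(c("band", "center", "width") %in% names(spec)))
  if (any(spec$width <= 0)) abort("band widths must be > 0")
  outside <- spec$center < min(grid) | spec$center > max(grid)
  if (any(outside)) {
    abort(paste0(
      "band centre outside the wavelength grid: ",
      paste(spec$band[outside], collapse = ", ")
    ))
  }
  fwhm_to_sigma <- 2 * sqrt(2 * log(2))
  out <- spec |>
    mutate(
      fwhm = .data$width,
      sigma = .data$width / fwhm_to_sigma
    ) |>
    select(any_of("sensor"), "band", "center", "fwhm", "sigma")
  supports <- pmap(list(out$center, out$sigma), function(ctr, sg) {
    wl <- grid[abs(grid - ctr) <= 4 * sg]
    w <- exp(-((wl - ctr)^2) / (2 * sg^2))
    list(wavelength = wl, weight = w / sum(w))
  })
  out$wavelength <- map(supports, "wavelength")
  out$weight <- map(supports, "weight")
  out
}

#' Convolve a hyperspectral spectrum to sensor bands
#'
#' Band reflectance is the SRF-weighted mean of the spectrum, i.e. the
#' discrete quadrature of the spectrum under each band's normalised Gaussian
#' response.
#'
#' @param spectrum Numeric vector of reflectance on `grid`, or a matrix with
#'   one spectrum per row (columns = wavelengths).
#' @param srfs SRF tibble from [build_srf()].
#' @param grid Wavelength grid the spectrum is defined on; must equal the grid
#'   the SRFs were built for.
#' @return A named numeric vector of band reflectances (one per SRF row), or a
#'   matrix with one row per input spectrum.
#' @export
#' @examples
#' srfs <- build_srf(sensor_specs("MSI"))
#' convolve_to_bands(rep(0.3, 2001), srfs)
convolve_to_bands <- function(spectrum, srfs, grid = hylai_grid()) {
  single <- is.null(dim(spectrum))
  mat <- if (single) matrix(spectrum, nrow = 1) else as.matrix(spectrum)
  if (ncol(mat) != length(grid)) {
    abort("spectrum length does not match the wavelength grid")
  }
  # sparse-by-band weight matrix on the full grid
  W <- matrix(0, nrow = length(grid), ncol = nrow(srfs),
              dimnames = list(NULL, srfs$band))
  for (j in seq_len(nrow(srfs))) {
    idx <- match(srfs$wavelength[[j]], grid)
    if (anyNA(idx)) abort("SRF support does not match the wavelength grid")
    W[idx, j] <- srfs$weight[[j]]
  }
  bands <- mat %*% W
  if (single) bands[1, ] else bands
}

#' Plot-level reflectance from overlapping pixels
#'
#' Satellite pixels rarely coincide with field-plot polygons; the plot
#' reflectance is estimated as the mean of the overlapping pixels weighted by
#' their fractional overlap area with the plot polygon.
#'
#' @param pixels Matrix or data frame of per-pixel band reflectances (rows =
#'   pixels, columns = bands), or a numeric vector for a single band.
#' @param weights Non-negative overlap areas (any positive scale); at least
#'   one must be positive.
#' @return Named numeric vector of plot-level band reflectances.
#' @export
#' @examples
#' weighted_plot_brf(rbind(c(B4 = 0.2), c(B4 = 0.4)), c(1, 3))
weighted_plot_brf <- function(pixels, weights) {
  mat <- if (is.null(dim(pixels))) matrix(pixels, ncol = 1) else as.matrix(pixels)
  if (length(weights) != nrow(mat)) {
    abort("one weight per pixel row is required")
  }
  if (any(weights < 0)) abort("overlap weights must be >= 0")
  if (sum(weights) <= 0) abort("at least one overlap weight must be positive")
  w <- weights / sum(weights)
  drop(crossprod(mat, w))
}
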