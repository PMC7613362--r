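#' Plant area index from hinge-angle gap fraction
#'
#' Converts a terrestrial-laser-scanning gap fraction measured in the hinge
#' angle region (zenith ~57.5 deg, where the conversion is nearly independent
#' of the leaf angle distribution) to plant area index:
#' `PAI = -1.1 * log(P_gap)`.
#'
#' @param gap Gap fraction(s) in `(0, 1]`.
#' @return PAI in m2/m2 (>= 0), strictly decreasing in `gap`.
#' @export
#' @examples
#' pai_from_gap(0.5)  # 1.1 * log(2)
pai_from_gap <- function(gap) {
  if (any(!is.finite(gap)) || any(gap <= 0) || any(gap > 1)) {
    abort("gap fractions must lie in (0, 1]")
  }
  -1.1 * log(gap)
}

#' Specific leaf area from a leaf subsample
#'
#' Specific leaf area (leaf area per unit dry mass) of a subsample of leaves,
#' computed as total area over total mass.
#'
#' @param areas Leaf areas, cm2.
#' @param masses Leaf dry masses, g.
#' @return SLA in cm2/g.
#' @export
sla_from_subsample <- function(areas, masses) {
  if (length(areas) != length(masses)) {
    abort("areas and masses must have equal length")
  }
  if (any(masses < 0) || sum(masses) <= 0) {
    abort("total leaf mass must be positive")
  }
  sum(areas) / sum(masses)
}

#' Seasonal LAI from litter-trap collections
#'
#' Total seasonal LAI per litter trap is the total collected dry leaf mass
#' converted to one-sided leaf area with the specific leaf area and divided
#' by the trap surface area:
#' `LAI_trap = mass [g] * SLA [cm2/g] * 1e-4 [m2/cm2] / area [m2]`.
#' Plot LAI is the mean over the plot's traps, with the standard error of the
#' mean quantifying trap-to-trap variability.
#'
#' @param records Tibble of per-trap records with columns `plot`, `trap`,
#'   `mass` (total seasonal dry mass, g; pre-sum multiple collections per
#'   trap), `sla` (cm2/g) and `area` (m2, default trap ring of 0.79 m2 is
#'   used if the column is absent).
#' @return Tibble per plot: `plot`, `lai_lt`, `sem`, `n_traps`.
#' @export
#' @examples
#' littertrap_lai(tibble::tibble(plot = "A", trap = 1, mass = 197.5,
#'                               sla = 200, area = 0.79))
littertrap_lai <- function(records) {
  stopifnot(all(c("plot", "trap", "mass", "sla") %in% names(records)))
  if (nrow(records) == 0) abort("at least one litter trap is required")
  if (!"area" %in% names(records)) records$area <- 0.79
  if (any(records$mass < 0)) abort("trap masses must be >= 0")
  if (any(records$sla <= 0) || any(records$area <= 0)) {
    abort("SLA and trap area must be > 0")
  }
  records |>
    group_by(.data$plot, .data$trap) |>
    summarise(
      lai_trap = sum(.data$mass) * .data$sla[1] * 1e-4 / .data$area[1],
      .groups = "drop"
    ) |>
    group_by(.data$plot) |>
    summarise(
      lai_lt = mean(.data$lai_trap),
      sem = if (dplyr::n() > 1) sd(.data$lai_trap) / sqrt(dplyr::n()) else 0,
      n_traps = dplyr::n(),
      .groups = "drop"
    )
}

#' Calibrate a TLS PAI time series with litter-trap LAI
#'
#' Scales each plot's TLS-derived PAI series to an LAI series anchored on the
#' litter-trap seasonal total:
#' `LAI_i = (PAI_i - min(PAI)) / max(PAI) * LAI_LT`.
#' Subtracting the series minimum removes the (wood-dominated) leaf-off
#' baseline, so the calibrated series touches zero by construction. Note the
#' denominator is the series *maximum*, as printed in the source protocol —
#' when the series minimum is positive the calibrated peak therefore falls
#' short of `LAI_LT`; `range_denominator = TRUE` switches to the
#' `max(PAI) - min(PAI)` denominator, which makes the peak hit `LAI_LT`
#' exactly.
#'
#' @param pai Tibble with columns `plot`, `date` (numeric day or `Date`) and
#'   `pai`.
#' @param lai_lt Tibble with columns `plot` and `lai_lt` (e.g. from
#'   [littertrap_lai()]).
#' @param range_denominator Use `max - min` instead of `max` as denominator.
#' @return Tibble of class `reference_series`: `plot`, `date`, `lai`.
#' @export
calibrate_tls <- function(pai, lai_lt, range_denominator = FALSE) {
  stopifnot(all(c("plot", "date", "pai") %in% names(pai)),
            all(c("plot", "lai_lt") %in% names(lai_lt)))
  out <- pai |>
    inner_join(lai_lt[c("plot", "lai_lt")], by = "plot") |>
    group_by(.data$plot) |>
    group_modify(function(g, key) {
      if (nrow(g) < 2 || max(g$pai) <= min(g$pai)) {
        abort("each plot needs >= 2 PAI values with max > min")
      }
      if (max(g$pai) <= 0) abort("max(PAI) must be positive")
      denom <- if (range_denominator) max(g$pai) - min(g$pai) else max(g$pai)
      tibble(date = g$date,
             lai = (g$pai - min(g$pai)) / denom * g$lai_lt[1])
    }) |>
    ungroup()
  class(out) <- c("reference_series", class(out))
  out
}

#' Interpolate a reference series to arbitrary dates
#'
#' Piecewise-linear interpolation of a per-plot LAI series; exact at the
#' observation dates. Queries outside the observed date range are rejected
#' rather than extrapolated.
#'
#' @param series Tibble with columns `plot`, `date`, `lai`.
#' @param dates Numeric dates to interpolate to (recycled per plot).
#' @return Tibble `plot`, `date`, `lai` at the query dates.
#' @export
interp_series <- function(series, dates) {
  stopifnot(all(c("plot", "date", "lai") %in% names(series)))
  series |>
    group_by(.data$plot) |>
    group_modify(function(g, key) {
      if (any(dates < min(g$date)) || any(dates > max(g$date))) {
        abort("query dates outside the observed range; refusing to extrapolate")
      }
      tibble(date = dates,
             lai = approx(g$date, g$lai, xout = dates, ties = mean)$y)
    }) |>
    ungroup()
}

#' Score a predicted LAI series against a reference series
#'
#' Computes the three evaluation metrics used throughout the package:
#' `RMSE = sqrt(sum((pred_i - ref_i)^2) / t)`, the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`, and the mean bias
#' `mean(pred - ref)`. When the reference has zero variance the R-squared is
#' undefined and reported as `NA`; the RMSE is still returned.
#'
#' @param predicted,reference Aligned numeric LAI vectors (same dates).
#' @return One-row tibble: `rmse`, `r2`, `bias`, `n`.
#' @export
#' @examples
#' score_series(c(0, 0), c(3, 4))  # RMSE sqrt(12.5)
score_series <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    abort("predicted and reference series are not aligned")
  }
  if (length(predicted) < 2) abort("at least two dates are required")
  ss_res <- sum((predicted - reference)^2)
  ss_tot <- sum((reference - mean(reference))^2)
  tibble(
    rmse = sqrt(ss_res / length(predicted)),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    bias = mean(predicted - reference),
    n = length(predicted)
  )
}

#' Horizontal footprint radius of an inclined TLS ray
#'
#' The horizontal distance at which a scanner ray inclined at
#' `angle_above_horizon` degrees reaches `height` metres — the buffer radius
#' used to turn scan positions into plot polygons.
#'
#' @param height Canopy height, m.
#' @param angle_above_horizon Ray elevation above the horizon, degrees.
#' @return Radius in m.
#' @export
#' @examples
#' tls_buffer_radius(25, 60)  # ~14.4 m
tls_buffer_radius <- function(height = 25, angle_above_horizon = 60) {
  height / tan(angle_above_horizon * pi / 180)
}
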