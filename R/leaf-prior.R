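#' Free parameter ranges of the leaf model
#'
#' Literature box constraints used both for leaf-spectrum inversion and for
#' `free`-mode training databases.
#'
#' @return Tibble with columns `param`, `lower`, `upper`.
#' @export
leaf_free_bounds <- function() {
  tribble(
    ~param,   ~lower, ~upper,
    "n",       1,      2.5,
    "cab",     0,      80,
    "car",     0,      20,
    "cm",      0.001,  0.025,
    "cw",      0.002,  0.025,
    "cbrown",  0,      1
  )
}

#' Field best estimates of the stable leaf constituents
#'
#' Central values of the seasonally stable constituents obtained by inverting
#' field-sampled leaf spectra; used to constrain `prior`-mode training
#' databases.
#'
#' @return Named numeric vector (`n`, `car`, `cw`, `cm`).
#' @export
leaf_best_estimates <- function() {
  c(n = 1.27, car = 8.60, cw = 0.0053, cm = 0.00263)
}

#' Invert a leaf reflectance spectrum for its chemistry
#'
#' Box-constrained quasi-Newton (L-BFGS-B) least squares between a measured
#' leaf reflectance spectrum and the surrogate leaf model over the full 1-nm
#' grid, with 5 Latin-hypercube multi-starts over the box (the surrogate cost
#' surface may be multimodal). The best residual wins; residual ties are
#' broken towards the lowest chlorophyll estimate.
#'
#' The surrogate leaf model determines the constituents only up to a common
#' scaling with the structure index `n` (`alpha = sum(k_i c_i) / n`), so after
#' optimisation the estimate is canonicalised along this scaling ridge to the
#' point with `n` nearest `n_ref` (default 1.27, the broadleaf field
#' estimate), as far as the box allows, whenever the move does not worsen the
#' residual. See the methods vignette for the identifiability discussion.
#'
#' @param spectrum Numeric reflectance vector on `grid`, values in `[0, 1]`.
#' @param bounds Box constraints as a tibble (`param`, `lower`, `upper`);
#'   defaults to [leaf_free_bounds()].
#' @param grid Wavelength grid; defaults to [hylai_grid()].
#' @param n_starts Number of Latin-hypercube starts.
#' @param n_ref Canonical structure-index value used to resolve the scaling
#'   ridge.
#' @param seed Integer seed making the multi-start deterministic.
#' @return One-row tibble: the six estimates, `residual` (root-SSE over the
#'   grid), and `converged`.
#' @export
invert_leaf_spectrum <- function(spectrum, bounds = leaf_free_bounds(),
                                 grid = hylai_grid(), n_starts = 5,
                                 n_ref = 1.27, seed = 1) {
  check_finite(spectrum, "spectrum")
  if (length(spectrum) != length(grid)) {
    abort("spectrum length does not match the wavelength grid")
  }
  if (any(bounds$lower > bounds$upper)) abort("invalid bounds: lower > upper")
  par_names <- c("n", "cab", "car", "cm", "cw", "cbrown")
  bounds <- bounds[match(par_names, bounds$param), ]
  lo <- bounds$lower
  up <- bounds$upper
  K <- absorption_curves(grid)
  Kmat <- cbind(K$k_ab, K$k_car, K$k_brown, K$k_w, K$k_m)

  sse <- function(p) {
    alpha <- drop(Kmat %*% c(p[2], p[3], p[6], p[5], p[4])) / p[1]
    rho <- two_stream_reflectance(0.96 * exp(-alpha))
    sum((rho - spectrum)^2)
  }

  starts <- with_seed(seed, lhs::randomLHS(n_starts, length(par_names)))
  starts <- sweep(sweep(starts, 2, up - lo, `*`), 2, lo, `+`)

  fits <- map(seq_len(n_starts), function(i) {
    optim(starts[i, ], sse, method = "L-BFGS-B", lower = lo, upper = up,
          control = list(maxit = 1000, factr = 1e7, parscale = up - lo))
  })
  vals <- map_dbl(fits, "value")
  best_val <- min(vals)
  tied <- which(vals <= best_val + 1e-12)
  # ties -> lowest chlorophyll
  best <- fits[[tied[which.min(map_dbl(fits[tied], ~ .x$par[2]))]]]
  est <- setNames(best$par, par_names)

  # canonicalise along the n-scaling ridge towards n_ref
  t_lo <- max(lo / pmax(est, .Machine$double.eps))
  t_hi <- min(up / pmax(est, .Machine$double.eps))
  if (t_lo <= t_hi) {
    t_star <- min(max(n_ref / est[["n"]], t_lo), t_hi)
    cand <- est * t_star
    if (sse(cand) <= best$value + 1e-10) est <- cand
  }

  tibble(
    !!!as.list(est),
    residual = sqrt(sse(est)),
    converged = best$convergence == 0
  )
}

#' Invert a table of leaf spectra
#'
#' Batch wrapper around [invert_leaf_spectrum()] for the wide CSV layout used
#' for field spectroscopy exports: one `wavelength` column plus one column per
#' sample.
#'
#' @param spectra Data frame with a `wavelength` column and one reflectance
#'   column per sample.
#' @param dates Optional acquisition dates, one per sample column.
#' @inheritParams invert_leaf_spectrum
#' @return Tibble with one row per sample (`sample`, optional `date`, the
#'   estimates, `residual`, `converged`).
#' @export
invert_leaf_spectra <- function(spectra, dates = NULL,
                                bounds = leaf_free_bounds(), n_starts = 5,
                                n_ref = 1.27, seed = 1) {
  stopifnot("wavelength" %in% names(spectra))
  grid <- spectra$wavelength
  samples <- setdiff(names(spectra), "wavelength")
  out <- imap(samples, function(s, i) {
    invert_leaf_spectrum(spectra[[s]], bounds = bounds, grid = grid,
                         n_starts = n_starts, n_ref = n_ref,
                         seed = derive_seed(seed, s)) |>
      mutate(sample = s, .before = 1)
  }) |>
    list_rbind()
  if (!is.null(dates)) out <- mutate(out, date = dates, .after = "sample")
  out
}

#' Summarise seasonal stability of leaf constituents
#'
#' Decides which leaf constituents can be held fixed in a `prior`-mode
#' training database. A constituent is *fixed* when the coefficient of
#' variation of its per-date means across the season is at most
#' `cv_threshold`; its prior value is then the grand mean of the date means.
#' Constituents above the threshold (typically chlorophyll and brown pigment,
#' which senesce) are reported as varying.
#'
#' @param estimates Tibble of per-sample leaf estimates with a `date` column
#'   (e.g. from [invert_leaf_spectra()]).
#' @param cv_threshold Coefficient-of-variation cut-off, default 0.25.
#' @return Tibble of class `prior_summary`: `param`, `mean`, `cv`, `fixed`,
#'   `value` (grand mean where fixed, `NA` otherwise), with the per-date means
#'   nested in `date_means`.
#' @export
summarize_season_prior <- function(estimates, cv_threshold = 0.25) {
  stopifnot("date" %in% names(estimates))
  if (dplyr::n_distinct(estimates$date) < 2) {
    abort("at least two sampling dates are required to judge stability")
  }
  pars <- c("n", "cab", "car", "cm", "cw", "cbrown")
  by_date <- estimates |>
    group_by(.data$date) |>
    summarise(across(all_of(pars), mean), .groups = "drop")
  out <- by_date |>
    pivot_longer(all_of(pars), names_to = "param", values_to = "mean") |>
    group_by(.data$param) |>
    summarise(
      date_means = {
        d <- .data$date
        m <- .data$mean
        list(tibble(date = d, mean = m))
      },
      grand_mean = mean(.data$mean),
      cv = if (abs(mean(.data$mean)) < .Machine$double.eps) {
        ifelse(sd(.data$mean) == 0, 0, Inf)
      } else {
        sd(.data$mean) / abs(mean(.data$mean))
      },
      .groups = "drop"
    ) |>
    mutate(
      fixed = .data$cv <= cv_threshold,
      value = ifelse(.data$fixed, .data$grand_mean, NA_real_)
    ) |>
    arrange(match(.data$param, pars))
  class(out) <- c("prior_summary", class(out))
  out
}
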