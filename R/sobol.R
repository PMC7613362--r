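#' Saltelli evaluation design for total-effect Sobol indices
#'
#' Builds the radial Saltelli scheme: two independent uniform base matrices
#' `A` and `B` of `n_base` rows over the varying parameter ranges, plus the
#' `d` hybrid matrices `A_B^(i)` in which column `i` of `A` is replaced by
#' column `i` of `B` — `n_base * (d + 2)` model evaluations in total.
#'
#' @param ranges Tibble with columns `param`, `lower`, `upper` (rows with a
#'   non-`NA` `fixed` column are held constant and excluded from `d`).
#' @param n_base Base sample size (powers of two recommended).
#' @param seed Integer seed.
#' @return Object of class `saltelli_design`: the evaluation tibble
#'   (`design`), parameter names, `n_base` and the block structure.
#' @export
#' @examples
#' d <- saltelli_design(tibble::tibble(param = c("x1", "x2", "x3"),
#'                                     lower = 0, upper = 1), n_base = 8)
#' nrow(d$design)  # 8 * (3 + 2)
saltelli_design <- function(ranges, n_base, seed = 1) {
  if (nrow(ranges) == 0) abort("empty parameter ranges")
  if (!"fixed" %in% names(ranges)) ranges$fixed <- NA_real_
  varying <- ranges[is.na(ranges$fixed), ]
  d <- nrow(varying)
  if (d == 0) abort("no varying parameters")
  U <- with_seed(seed, matrix(runif(2 * n_base * d), ncol = 2 * d))
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  blocks <- c(list(A = A, B = B),
              setNames(map(seq_len(d), function(i) {
                M <- A
                M[, i] <- B[, i]
                M
              }), paste0("AB_", varying$param)))
  unit <- do.call(rbind, blocks)
  scaled <- sweep(sweep(unit, 2, varying$upper - varying$lower, `*`),
                  2, varying$lower, `+`)
  colnames(scaled) <- varying$param
  design <- as_tibble(as.data.frame(scaled))
  # re-attach fixed parameters as constant columns
  for (i in which(!is.na(ranges$fixed))) {
    design[[ranges$param[i]]] <- ranges$fixed[i]
  }
  design <- design[, ranges$param]
  structure(
    list(design = design, params = varying$param, n_base = n_base,
         d = d, seed = seed),
    class = "saltelli_design"
  )
}

#' Total-effect Sobol indices from model evaluations
#'
#' Jansen's estimator of the total-effect index of each parameter:
#' `S_Ti = (1/(2 n) * sum((f(A) - f(A_B^(i)))^2)) / Var(f)`, with the output
#' variance estimated over the `A` and `B` blocks. Small negative
#' Monte-Carlo estimates are floored at zero.
#'
#' @param outputs Numeric vector of model outputs aligned with
#'   `design$design` rows.
#' @param design A `saltelli_design`.
#' @return Named numeric vector of total-effect indices (one per varying
#'   parameter).
#' @export
total_effect <- function(outputs, design) {
  stopifnot(inherits(design, "saltelli_design"))
  n <- design$n_base
  d <- design$d
  if (length(outputs) != n * (d + 2)) {
    abort("outputs are not aligned with the Saltelli design")
  }
  fA <- outputs[seq_len(n)]
  fB <- outputs[n + seq_len(n)]
  v <- var(c(fA, fB))
  if (v <= 0) abort("zero output variance; total effects are undefined")
  st <- map_dbl(seq_len(d), function(i) {
    fABi <- outputs[(i + 1) * n + seq_len(n)]
    mean((fA - fABi)^2) / (2 * v)
  })
  pmax(setNames(st, design$params), 0)
}

#' Normalise sensitivity indices per band
#'
#' The sum of total-effect indices differs between spectral bands (it exceeds
#' one in the presence of interactions), so for comparison across bands each
#' band column is rescaled to sum to 1.
#'
#' @param raw Matrix or tibble of raw indices, parameters in rows, bands in
#'   columns.
#' @return The column-normalised matrix (columns sum to 1).
#' @export
normalise_per_band <- function(raw) {
  M <- as.matrix(raw)
  sums <- colSums(M)
  bad <- sums <= 0
  if (any(bad)) {
    abort(paste0("all-zero sensitivity column for band(s): ",
                 paste(colnames(M)[bad], collapse = ", ")))
  }
  sweep(M, 2, sums, `/`)
}

#' Sobol sensitivity analysis of a canopy reflectance surrogate
#'
#' Saltelli-samples the varying parameters of the chosen surrogate over their
#' free ranges, evaluates every MSI band for each design row, and returns raw
#' and normalised total-effect indices per band. Only the MSI band set is
#' analysed; it covers the same spectral domains as the other two sensors.
#'
#' @param rtm `"TURBID"` or `"GEOM"` (the crown-explicit surrogate adds the
#'   crown diameter to the varying set).
#' @param n_base Saltelli base sample size.
#' @param sensor Sensor band set to evaluate.
#' @param geom Scene geometry constants.
#' @param seed Integer seed.
#' @return Tibble of class `lai_sensitivity`: columns `rtm`, `parameter`,
#'   `band`, `st_raw`, `st_norm`.
#' @export
sobol_rtm <- function(rtm = c("TURBID", "GEOM"), n_base = 1024,
                      sensor = "MSI", geom = scene_geometry(), seed = 1) {
  rtm <- match.arg(rtm)
  ranges <- param_ranges("free", rtm)
  design <- saltelli_design(ranges, n_base, seed = seed)
  bands <- rtm_bands(design$design, rtm = rtm, sensor = sensor, geom = geom)
  raw <- vapply(bands, total_effect, numeric(design$d), design = design)
  norm <- normalise_per_band(raw)
  out <- as_tibble(as.data.frame(raw), rownames = "parameter") |>
    pivot_longer(-"parameter", names_to = "band", values_to = "st_raw") |>
    left_join(
      as_tibble(as.data.frame(norm), rownames = "parameter") |>
        pivot_longer(-"parameter", names_to = "band",
                     values_to = "st_norm"),
      by = c("parameter", "band")
    ) |>
    mutate(rtm = rtm, n_base = n_base, .before = 1)
  class(out) <- c("lai_sensitivity", class(out))
  out
}
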