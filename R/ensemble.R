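#' Workflow feature domains
#'
#' The five workflow features varied in the full factorial assessment and
#' their default levels: leaf-chemistry prior (free/prior), canopy surrogate
#' (TURBID/GEOM), additive noise level (4 levels), multiplicative noise level
#' (5 levels), sun-zenith-angle feature (without/with) and regression
#' algorithm (6 levels) — a 2 x 2 x 4 x 5 x 2 x 6 = 960-cell grid.
#'
#' @param prior,rtm,sigma_ai,sigma_mi,sza,mlra Level vectors; override to
#'   build reduced grids.
#' @return Named list of level vectors.
#' @export
feature_domains <- function(prior = c("free", "prior"),
                            rtm = c("TURBID", "GEOM"),
                            sigma_ai = c(0, 0.05, 0.10, 0.20),
                            sigma_mi = c(0, 0.05, 0.10, 0.20, 0.30),
                            sza = c(FALSE, TRUE),
                            mlra = mlra_algorithms()) {
  list(prior = prior, rtm = rtm, sigma_ai = sigma_ai, sigma_mi = sigma_mi,
       sza = sza, mlra = mlra)
}

#' Build the factorial realisation grid
#'
#' Cartesian product of the feature domains in a fixed documented order
#' (prior slowest, MLRA fastest), with deterministic realisation ids.
#'
#' @param domains Level list from [feature_domains()].
#' @return Tibble with one row per realisation: `id` plus one column per
#'   feature.
#' @export
#' @examples
#' nrow(build_grid())  # 960
build_grid <- function(domains = feature_domains()) {
  if (any(lengths(domains) == 0)) abort("empty feature domain")
  grid <- expand_grid(
    prior = domains$prior, rtm = domains$rtm, sigma_ai = domains$sigma_ai,
    sigma_mi = domains$sigma_mi, sza = domains$sza, mlra = domains$mlra
  )
  grid |>
    mutate(id = sprintf("r%04d", dplyr::row_number()), .before = 1)
}

#' Configuration of a grid run
#'
#' @param n_train,n_test Training-database split sizes per realisation.
#' @param seed Master seed; each realisation derives its own seed from it
#'   and its feature tuple, so individual cells can be re-run in isolation.
#' @param geom Scene geometry constants shared by all realisations.
#' @return List of class `grid_config`.
#' @export
grid_config <- function(n_train = 2500, n_test = 500, seed = 1,
                        geom = scene_geometry()) {
  structure(list(n_train = n_train, n_test = n_test, seed = seed,
                 geom = geom),
            class = "grid_config")
}

realisation_seed <- function(config, spec) {
  derive_seed(config$seed, paste(spec$prior, spec$rtm, spec$sigma_ai,
                                 spec$sigma_mi, spec$sza, spec$mlra,
                                 sep = "|"))
}

#' Run one realisation of the retrieval workflow
#'
#' Executes the complete hybrid workflow for one cell of the feature grid:
#' builds the training database prescribed by the cell (prior ranges, canopy
#' surrogate, noise levels), trains one inverter per sensor with the cell's
#' algorithm, predicts LAI for every usable synthetic observation, averages
#' the predictions over plots per date, merges the sensors into one dated
#' series and scores it against the interpolated plot-mean reference.
#' Deterministic under the cell's derived seed.
#'
#' Observation dates outside the reference series' date span cannot be
#' validated and are dropped (their count is reported as `n_dropped`).
#'
#' @param spec One-row tibble from [build_grid()].
#' @param world A `synth_world` from [build_world()].
#' @param reference Reference series tibble (`plot`, `date`, `lai`), e.g.
#'   `build_reference(world)$series`.
#' @param config A [grid_config()].
#' @return One-row tibble: the feature tuple, mean per-sensor `test_rmse`,
#'   validation `val_rmse`, `val_r2`, `val_bias`, `n_dates`, `n_negative`,
#'   `n_dropped`, `seed`, and a `series` list-column holding the dated
#'   predicted vs reference values.
#' @export
run_realisation <- function(spec, world, reference, config = grid_config()) {
  stopifnot(inherits(world, "synth_world"))
  sensors <- names(world$observations)
  if (length(sensors) == 0) abort("world holds no observations")
  seed <- realisation_seed(config, spec)

  db <- build_training_db(
    n_train = config$n_train, n_test = config$n_test,
    prior = spec$prior, rtm = spec$rtm,
    sigma_mi = spec$sigma_mi, sigma_ai = spec$sigma_ai,
    sensors = sensors, geom = config$geom, seed = seed
  )

  span <- range(reference$date)
  preds <- map(sensors, function(s) {
    tr <- assemble_features(db, s, use_sza = spec$sza, split = "train")
    te <- assemble_features(db, s, use_sza = spec$sza, split = "test")
    model <- fit_inverter(tr$features, tr$target, spec$mlra,
                          seed = derive_seed(seed, s),
                          test_features = te$features,
                          test_targets = te$target)
    obs <- world$observations[[s]]
    feats <- obs[, model$feature_names[model$feature_names != "sza"]]
    if (spec$sza) feats$sza <- obs$theta_s
    p <- predict_lai(model, feats)
    tibble(sensor = s, plot = obs$plot, date = obs$day,
           pred = as.numeric(p),
           test_rmse = model$test_rmse,
           n_negative = attr(p, "n_negative"))
  }) |>
    list_rbind()

  n_dropped <- sum(preds$date < span[1] | preds$date > span[2])
  preds_in <- filter(preds, .data$date >= span[1], .data$date <= span[2])
  if (nrow(preds_in) == 0) abort("no observation dates inside the reference span")

  # one combined time series: plot-average per sensor-date, sensors merged
  series <- preds_in |>
    group_by(.data$sensor, .data$date) |>
    summarise(pred = mean(.data$pred), .groups = "drop") |>
    arrange(.data$date, .data$sensor)
  ref_mean <- interp_series(reference, sort(unique(series$date))) |>
    group_by(.data$date) |>
    summarise(ref = mean(.data$lai), .groups = "drop")
  series <- left_join(series, ref_mean, by = "date")
  scores <- score_series(series$pred, series$ref)

  # per-plot mean bias over the leaf-on window (reference above half of the
  # plot's seasonal maximum)
  plot_bias <- preds_in |>
    group_by(.data$plot) |>
    group_modify(function(g, key) {
      ref_p <- interp_series(reference[reference$plot == key$plot, ],
                             sort(unique(g$date)))
      g <- left_join(g, ref_p[c("date", "lai")], by = "date")
      leaf_on <- g$lai > 0.5 * max(ref_p$lai)
      tibble(bias = if (any(leaf_on)) {
        mean(g$pred[leaf_on] - g$lai[leaf_on])
      } else NA_real_)
    }) |>
    ungroup()

  tibble(
    id = if ("id" %in% names(spec)) spec$id else NA_character_,
    prior = spec$prior, rtm = spec$rtm, sigma_ai = spec$sigma_ai,
    sigma_mi = spec$sigma_mi, sza = spec$sza, mlra = spec$mlra,
    test_rmse = mean(distinct(preds, .data$sensor,
                              .keep_all = TRUE)$test_rmse),
    val_rmse = scores$rmse, val_r2 = scores$r2, val_bias = scores$bias,
    n_dates = scores$n,
    n_negative = sum(preds$n_negative),
    n_dropped = n_dropped,
    seed = seed,
    series = list(series),
    plot_bias = list(plot_bias)
  )
}

#' Run a grid of realisations
#'
#' Maps [run_realisation()] over every row of a realisation grid.
#'
#' @param grid Tibble from [build_grid()].
#' @param world,reference,config As in [run_realisation()].
#' @param progress Print one line per completed realisation.
#' @return Tibble of class `grid_results` with one row per grid cell.
#' @export
run_grid <- function(grid, world, reference, config = grid_config(),
                     progress = FALSE) {
  out <- map(seq_len(nrow(grid)), function(i) {
    res <- run_realisation(grid[i, ], world, reference, config)
    if (progress) {
      cat(sprintf("[%d/%d] %s %s ai=%.2f mi=%.2f sza=%s %s: RMSE %.3f\n",
                  i, nrow(grid), grid$prior[i], grid$rtm[i],
                  grid$sigma_ai[i], grid$sigma_mi[i], grid$sza[i],
                  grid$mlra[i], res$val_rmse))
    }
    res
  }) |>
    list_rbind()
  class(out) <- c("grid_results", class(out))
  out
}

feature_names <- function() {
  c("prior", "rtm", "sigma_ai", "sigma_mi", "sza", "mlra")
}

#' Ensemble statistics per feature level
#'
#' For one workflow feature, summarises the validation RMSE of all
#' realisations implementing each level: the ensemble median, the 25-75%
#' interquartile range, and the difference of each level's median to the
#' best (lowest) level median.
#'
#' @param results `grid_results` tibble.
#' @param feature Feature column name (one of `prior`, `rtm`, `sigma_ai`,
#'   `sigma_mi`, `sza`, `mlra`).
#' @param metric Result column to summarise (default `val_rmse`).
#' @return Tibble: `feature`, `level`, `n`, `median_rmse`, `iqr`,
#'   `delta_rmse`.
#' @export
feature_ensemble_stats <- function(results, feature, metric = "val_rmse") {
  if (!feature %in% feature_names()) {
    abort(paste0("unknown feature: ", feature))
  }
  out <- results |>
    group_by(level = as.character(.data[[feature]])) |>
    summarise(
      n = dplyr::n(),
      median_rmse = median(.data[[metric]]),
      iqr = unname(diff(quantile(.data[[metric]], c(0.25, 0.75)))),
      .groups = "drop"
    ) |>
    mutate(
      feature = feature,
      delta_rmse = .data$median_rmse - min(.data$median_rmse),
      .before = 1
    )
  out
}

#' Paired significance test for a binary feature
#'
#' Wilcoxon signed-rank test on the paired validation RMSE differences of a
#' two-level feature, pairing realisations that agree on every other
#' feature. Zero-difference pairs are dropped; the reported statistic is the
#' smaller of the two signed-rank sums; the p-value is two-sided.
#'
#' @param results `grid_results` tibble.
#' @param feature Binary feature column name.
#' @return One-row tibble: `feature`, `n_pairs`, `n_nonzero`, `statistic`,
#'   `p_value`, `median_diff` (second level minus first).
#' @export
paired_feature_test <- function(results, feature) {
  levels <- sort(unique(as.character(results[[feature]])))
  if (feature == "sza") levels <- c("FALSE", "TRUE")
  if (length(levels) != 2) {
    abort("the paired test requires a feature with exactly two levels")
  }
  others <- setdiff(feature_names(), feature)
  wide <- results |>
    mutate(.level = as.character(.data[[feature]])) |>
    select(all_of(others), ".level", "val_rmse") |>
    pivot_wider(names_from = ".level", values_from = "val_rmse")
  if (!all(levels %in% names(wide)) || anyNA(wide[levels])) {
    abort("results are not pairable: incomplete grid")
  }
  d <- wide[[levels[2]]] - wide[[levels[1]]]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble(feature = feature, n_pairs = length(d), n_nonzero = 0L,
                  statistic = NA_real_, p_value = NA_real_,
                  median_diff = 0))
  }
  wt <- suppressWarnings(wilcox.test(nz, alternative = "two.sided"))
  v <- unname(wt$statistic)
  n <- length(nz)
  tibble(
    feature = feature,
    n_pairs = length(d),
    n_nonzero = n,
    statistic = min(v, n * (n + 1) / 2 - v),
    p_value = wt$p.value,
    median_diff = median(d)
  )
}

#' Scan first-order interactions of a feature
#'
#' For a feature A, measures how strongly each other feature B modulates
#' performance across the A x B cells: the interaction score of B is the
#' spread (max minus min) of the median validation RMSE over all A-level x
#' B-level cells. Features are ranked by score; ties keep the fixed feature
#' order.
#'
#' @param results `grid_results` tibble.
#' @param feature Feature A column name.
#' @return Tibble ranked by descending score: `feature`, `with`, `score`.
#' @export
interaction_scan <- function(results, feature) {
  others <- setdiff(feature_names(), feature)
  scores <- map_dbl(setNames(others, others), function(b) {
    cells <- results |>
      group_by(a = as.character(.data[[feature]]),
               b = as.character(.data[[b]])) |>
      summarise(m = median(.data$val_rmse), .groups = "drop")
    max(cells$m) - min(cells$m)
  })
  tibble(feature = feature, with = others, score = unname(scores)) |>
    arrange(dplyr::desc(.data$score), match(.data$with, feature_names()))
}

#' Report the best-performing realisation
#'
#' Returns the grid cell with the lowest validation RMSE (ties resolved by
#' grid order), with its full score set and per-plot leaf-on biases.
#'
#' @param results `grid_results` tibble.
#' @return List with `best` (one-row tibble), `series` (dated predicted vs
#'   reference values) and `plot_bias`.
#' @export
best_report <- function(results) {
  best <- results |>
    arrange(.data$val_rmse, match(.data$id, results$id)) |>
    dplyr::slice(1)
  list(
    best = select(best, -"series", -"plot_bias"),
    series = best$series[[1]],
    plot_bias = best$plot_bias[[1]]
  )
}

#' Table-style summary of all features
#'
#' Convenience wrapper applying [feature_ensemble_stats()] to every workflow
#' feature, in the layout of the feature-assessment summary table (median
#' RMSE, delta to the best level, IQR).
#'
#' @param results `grid_results` tibble.
#' @return Tibble with one row per feature level.
#' @export
summarize_grid <- function(results) {
  map(feature_names(), ~ feature_ensemble_stats(results, .x)) |>
    list_rbind()
}
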