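#' Persist a training database as CSV tables plus a JSON manifest
#'
#' Writes `params.csv`, per-sensor `clean_<sensor>.csv` and
#' `noisy_<sensor>.csv`, and `manifest.json` (ranges, seeds, noise spec,
#' column order) into a directory.
#'
#' @param db A `training_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_training_db <- function(db, dir) {
  stopifnot(inherits(db, "training_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(db$params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  safe <- function(s) gsub("[^A-Za-z0-9]", "", s)
  for (s in names(db$clean)) {
    utils::write.csv(db$clean[[s]],
                     file.path(dir, paste0("clean_", safe(s), ".csv")),
                     row.names = FALSE)
    utils::write.csv(db$noisy[[s]],
                     file.path(dir, paste0("noisy_", safe(s), ".csv")),
                     row.names = FALSE)
  }
  manifest <- db$manifest
  manifest$ranges <- as.data.frame(manifest$ranges)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Persist grid results as CSV
#'
#' Flat per-realisation scores go to `results.csv`; the per-feature summary
#' table to `summary.csv`.
#'
#' @param results `grid_results` tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_grid_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- results[, setdiff(names(results), c("series", "plot_bias"))]
  utils::write.csv(flat, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(summarize_grid(results), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read/write a reference series
#'
#' @param series Reference series tibble (`plot`, `date`, `lai`).
#' @param path CSV path.
#' @return The series (invisibly for the writer).
#' @export
write_reference_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(series)
}

#' @rdname write_reference_series
#' @export
read_reference_series <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  class(out) <- c("reference_series", class(out))
  out
}

#' Persist or load a seasonal prior summary
#'
#' The prior summary travels between the leaf-inversion stage and
#' training-database construction as JSON.
#'
#' @param prior A `prior_summary` from [summarize_season_prior()].
#' @param path JSON path.
#' @return The summary (invisibly for the writer).
#' @export
write_prior_summary <- function(prior, path) {
  flat <- prior[c("param", "grand_mean", "cv", "fixed", "value")]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(prior)
}

#' @rdname write_prior_summary
#' @export
read_prior_summary <- function(path) {
  out <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  out$value <- as.numeric(out$value)
  class(out) <- c("prior_summary", class(out))
  out
}
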