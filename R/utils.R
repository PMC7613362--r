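#' The common hyperspectral wavelength grid
#'
#' All leaf and canopy reflectance surrogates in this package are evaluated on
#' a fixed 1-nm grid from 400 to 2400 nm, the conventional range of field
#' spectroscopy, before being convolved to sensor bands. The 1-nm step keeps
#' the quadrature error of the Gaussian band convolution negligible.
#'
#' @return Integer vector of wavelengths in nm (length 2001).
#' @export
#' @examples
#' range(hylai_grid())
hylai_grid <- function() {
  400:2400
}

# Deterministic small-integer seed derived from a master seed and a string tag.
# Keeps every stochastic component independently re-runnable while staying
# below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# shared input checks ---------------------------------------------------------

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(paste0("`", what, "` contains non-finite values"))
  }
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))
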