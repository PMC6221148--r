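#' Wavelength grid
#'
#' A regular, inclusive wavelength grid in nanometres. All spectra in the
#' package live on such grids; the package default (300--700 nm at 1 nm)
#' covers both the ultraviolet (320--380 nm) and human-visible (400--680 nm)
#' camera passbands with margin.
#'
#' @param start_nm first wavelength (nm).
#' @param stop_nm last wavelength (nm), included.
#' @param step_nm grid spacing (nm); must divide `stop_nm - start_nm`.
#' @return numeric vector of wavelengths with class `"wl_grid"`.
#' @examples
#' g <- wl_grid()
#' range(g)
#' @export
wl_grid <- function(start_nm = 300, stop_nm = 700, step_nm = 1) {
  if (!is.finite(start_nm) || !is.finite(stop_nm) || !is.finite(step_nm))
    stop("grid endpoints and step must be finite")
  if (start_nm >= stop_nm) stop("start_nm must be < stop_nm")
  if (step_nm <= 0) stop("step_nm must be positive")
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-9)
    stop("step_nm must divide (stop_nm - start_nm)")
  structure(seq(start_nm, stop_nm, by = step_nm), class = "wl_grid")
}

#' Spectrum on a wavelength grid
#'
#' @param wl wavelength grid (numeric, regular spacing assumed for
#'   integration).
#' @param values nonnegative values, one per wavelength.
#' @param kind one of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#' @return object of class `"spectrum"`: list with `wl`, `values`, `kind`.
#' @export
spectrum <- function(wl, values, kind = c("reflectance", "illuminant", "sensitivity")) {
  kind <- match.arg(kind)
  wl <- as.numeric(wl)
  values <- as.numeric(values)
  if (length(wl) != length(values))
    stop("wl and values must have equal length")
  if (any(!is.finite(values)) || any(!is.finite(wl)))
    stop("spectrum contains non-finite values")
  if (any(values < 0)) stop("spectrum values must be nonnegative")
  if (kind == "reflectance" && any(values > 1.5))
    warning("reflectance values exceed 1.5; check units")
  structure(list(wl = wl, values = values, kind = kind), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm, max %.4g>\n",
              x$kind, length(x$wl), min(x$wl), max(x$wl), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto the target grid. Wavelengths outside the
#' source support are an error unless an extrapolation policy is given.
#'
#' @param s a [spectrum()].
#' @param g target wavelength grid.
#' @param extrapolate `"error"` (default), `"zero"` (zero-fill outside the
#'   support), or `"hold"` (extend the terminal values).
#' @return resampled [spectrum()] of the same kind; values clipped at 0.
#' @export
resample_spectrum <- function(s, g, extrapolate = c("error", "zero", "hold")) {
  extrapolate <- match.arg(extrapolate)
  stopifnot(is_spectrum(s))
  g <- as.numeric(g)
  outside <- g < min(s$wl) | g > max(s$wl)
  if (any(outside) && extrapolate == "error")
    stop(sprintf("requested range [%g, %g] outside spectrum support [%g, %g]; set an extrapolation policy",
                 min(g), max(g), min(s$wl), max(s$wl)))
  rule <- if (extrapolate == "hold") 2 else 1
  v <- stats::approx(s$wl, s$values, xout = g, rule = rule)$y
  if (extrapolate == "zero") v[outside] <- 0
  v[is.na(v)] <- 0
  spectrum(g, pmax(v, 0), kind = s$kind)
}

# Govardovskii-type A1 alpha+beta band constants; alpha-band position
# parameter `a` depends on lambda_max and is computed at evaluation time.
govardovskii_a1_params <- function(lambda_max) {
  list(
    lambda_max = lambda_max,
    A = 69.7, B = 28, C = -14.9, D = 0.674,
    b = 0.922, c = 1.104,
    beta_amp = 0.26,
    beta_peak_intercept = 189, beta_peak_slope = 0.315,
    beta_width_intercept = -40.5, beta_width_slope = 0.195
  )
}

#' Visual-pigment absorbance template
#'
#' Builds a receptor spectral sensitivity from a peak wavelength using the
#' standard A1 visual-pigment nomogram (alpha band plus beta band),
#' peak-normalized to 1. Only the peak wavelength is needed; the template
#' constants are injectable for alternative nomograms.
#'
#' @param lambda_max peak wavelength (nm); must lie inside the grid.
#' @param g wavelength grid (default 300--700 nm at 1 nm).
#' @param params template constants, as from `govardovskii_a1_params()`.
#' @return a [spectrum()] of kind `"sensitivity"` with maximum 1; the
#'   argmax lies within one grid step of `lambda_max`.
#' @examples
#' s <- pigment_template(555)
#' s$wl[which.max(s$values)]
#' @export
pigment_template <- function(lambda_max, g = wl_grid(),
                             params = govardovskii_a1_params(lambda_max)) {
  g <- as.numeric(g)
  if (lambda_max < min(g) || lambda_max > max(g))
    stop(sprintf("lambda_max %g nm outside grid range [%g, %g]",
                 lambda_max, min(g), max(g)))
  x <- lambda_max / g
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(params$A * (a - x)) + exp(params$B * (params$b - x)) +
                  exp(params$C * (params$c - x)) + params$D)
  beta_peak <- params$beta_peak_intercept + params$beta_peak_slope * lambda_max
  beta_width <- params$beta_width_intercept + params$beta_width_slope * lambda_max
  beta <- params$beta_amp * exp(-((g - beta_peak) / beta_width)^2)
  v <- alpha + beta
  spectrum(g, v / max(v), kind = "sensitivity")
}

#' Standard illuminants
#'
#' `"D65"` returns the CIE D65 relative spectral power distribution
#' (bundled 5 nm tabulation, normalized to 100 at 560 nm) resampled onto
#' the grid; `"flat"` returns an equal-energy illuminant of 1 everywhere.
#'
#' @param name `"D65"` or `"flat"`.
#' @param g wavelength grid.
#' @return a [spectrum()] of kind `"illuminant"`.
#' @export
standard_illuminant <- function(name = c("D65", "flat"), g = wl_grid()) {
  if (!is.character(name) || !(name[1] %in% c("D65", "flat")))
    stop("unknown illuminant '", name[1], "'; valid names: D65, flat")
  name <- match.arg(name)
  g <- as.numeric(g)
  if (name == "flat") return(spectrum(g, rep(1, length(g)), kind = "illuminant"))
  path <- system.file("extdata", "cie_d65_300_700.csv", package = "mimicolor")
  tab <- utils::read.csv(path, comment.char = "#")
  s <- spectrum(tab$wavelength_nm, tab$relative_power, kind = "illuminant")
  resample_spectrum(s, g)
}

#' Trapezoidal integral of a spectral product
#'
#' @param wl wavelength grid (uniform spacing).
#' @param y integrand values on `wl`.
#' @return the trapezoid-rule integral.
#' @keywords internal
trapz <- function(wl, y) {
  n <- length(wl)
  sum((y[-1] + y[-n]) / 2 * diff(wl))
}
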