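#' Default UV-capable camera channel set
#'
#' Four synthetic sensor channels for a UV-photography setup: a UV channel
#' (Gaussian centered at 350 nm, truncated to the 320--380 nm pass filter)
#' and visible blue/green/red channels (Gaussians at 460/540/600 nm,
#' truncated to the 400--680 nm UV/IR-cut passband). Real sensor curves
#' can be substituted: any list of peak-normalized sensitivity spectra
#' that are zero outside their passband works.
#'
#' @param g wavelength grid.
#' @return named list of `"camera_channel"` objects (`name`,
#'   `sensitivity`, `passband`).
#' @export
default_camera <- function(g = wl_grid()) {
  g <- as.numeric(g)
  make <- function(name, center, sigma, lo, hi) {
    v <- exp(-((g - center) / sigma)^2 / 2)
    v[g < lo | g > hi] <- 0
    structure(list(name = name,
                   sensitivity = spectrum(g, v / max(v), kind = "sensitivity"),
                   passband = c(lo, hi)),
              class = "camera_channel")
  }
  list(uv   = make("uv", 350, 20, 320, 380),
       visB = make("visB", 460, 40, 400, 680),
       visG = make("visG", 540, 45, 400, 680),
       visR = make("visR", 600, 45, 400, 680))
}

#' Synthetic training library for the cone-catch mapping
#'
#' Generates smooth wing-patch-like reflectances spanning the four color
#' classes with broadened parameter variation (amplitude CV 0.1,
#' inflection jitter 10 nm), the population a calibration library should
#' cover.
#'
#' @param n number of spectra.
#' @param g wavelength grid.
#' @param seed RNG seed offset.
#' @return list of reflectance [spectrum()]s.
#' @export
generate_training_library <- function(n = 200, g = wl_grid(), seed = 0) {
  classes <- c("yellow", "white", "red", "orange")
  lapply(seq_len(n), function(k) {
    m <- patch_spectrum_model(classes[(k %% 4) + 1], individual_cv = 0.1,
                              inflection_sd_nm = 10)
    spectrum(as.numeric(g), generate_patch_spectrum(m, 1, g, seed = seed + k)[, 1])
  })
}

#' Simulate raw camera responses for a patch
#'
#' Forward model for synthetic photography: each channel's linear response
#' is the catch of the patch relative to the catch of the gray standard,
#' scaled to the gray reflectance; the sensor then applies a gamma
#' (response exponent) and optional additive Gaussian read noise.
#'
#' @param r patch reflectance [spectrum()].
#' @param i illuminant [spectrum()].
#' @param cams list of camera channels, as from [default_camera()].
#' @param gamma sensor response exponent (> 0); raw = linear^(1/gamma).
#' @param noise_sd additive noise standard deviation on the raw scale.
#' @param gray_reflectance gray-standard reflectance (default 0.40).
#' @param seed RNG seed for the read noise; the response is a pure
#'   function of the seed.
#' @return object of class `"patch_response"`: `raw`, `gray_raw`, `gamma`,
#'   `normalized` (NULL until [linearize_normalize()]).
#' @export
simulate_camera_response <- function(r, i, cams = default_camera(),
                                     gamma = 1, noise_sd = 0,
                                     gray_reflectance = 0.40, seed = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  gray <- spectrum(r$wl, rep(gray_reflectance, length(r$wl)),
                   kind = "reflectance")
  lin <- vapply(cams, function(cam) {
    qg <- trapz(r$wl, gray$values * i$values * cam$sensitivity$values)
    qp <- trapz(r$wl, r$values * i$values * cam$sensitivity$values)
    if (qg == 0) {
      warning("camera channel ", cam$name, " has no overlap with the scene")
      return(0)
    }
    qp / qg * gray_reflectance
  }, numeric(1))
  raw <- lin^(1 / gamma)
  gray_raw <- rep(gray_reflectance^(1 / gamma), length(raw))
  names(gray_raw) <- names(raw)
  if (noise_sd > 0) {
    with_seed(seed, {
      raw <- pmax(raw + stats::rnorm(length(raw), 0, noise_sd), 0)
      gray_raw <- pmax(gray_raw + stats::rnorm(length(gray_raw), 0, noise_sd), 0)
    })
  }
  structure(list(raw = raw, gray_raw = gray_raw, gamma = gamma,
                 normalized = NULL),
            class = "patch_response")
}

#' Linearize and gray-normalize a patch response
#'
#' Undoes the sensor gamma and anchors the response to the gray standard,
#' so that the gray patch itself reads exactly its reflectance in every
#' channel: `normalized = (raw^gamma / gray_raw^gamma) * gray_reflectance`.
#'
#' @param p a `"patch_response"`.
#' @param gray_reflectance reflectance of the gray standard (default 0.40).
#' @return the response with `normalized` filled in.
#' @export
linearize_normalize <- function(p, gray_reflectance = 0.40) {
  stopifnot(inherits(p, "patch_response"))
  if (any(p$gray_raw <= 0)) stop("zero gray-standard reading; cannot calibrate")
  p$normalized <- (p$raw^p$gamma / p$gray_raw^p$gamma) * gray_reflectance
  p
}

#' Fit the camera-to-cone-catch mapping
#'
#' Least-squares regression from linearized, gray-normalized camera
#' responses to gray-normalized quantum catches of a target visual
#' system, over a training library of reflectance spectra. This is the
#' calibration step that lets calibrated photographs stand in for
#' spectrometry.
#'
#' @param library list of reflectance [spectrum()]s (training set).
#' @param i illuminant [spectrum()].
#' @param cams camera channels, as from [default_camera()].
#' @param sys target [visual_system()].
#' @param model_order `"linear"` (camera responses + intercept) or
#'   `"linear+products"` (adds pairwise products of camera responses).
#' @param gray_reflectance gray-standard reflectance.
#' @return object of class `"cone_mapping"`: `coefficients` (one row per
#'   receptor), `training_rms` per receptor, `model_order`, `channels`.
#' @export
fit_cone_mapping <- function(library, i, cams = default_camera(), sys,
                             model_order = c("linear", "linear+products"),
                             gray_reflectance = 0.40) {
  model_order <- match.arg(model_order)
  X <- t(vapply(library, function(r) {
    p <- simulate_camera_response(r, i, cams, gamma = 1,
                                  gray_reflectance = gray_reflectance)
    linearize_normalize(p, gray_reflectance)$normalized
  }, numeric(length(cams))))
  colnames(X) <- names(cams)
  design <- build_mapping_design(X, model_order)
  n_terms <- ncol(design)
  if (nrow(design) < 3 * n_terms)
    stop(sprintf("library of %d spectra is insufficient for %d predictor terms (need >= %d)",
                 nrow(design), n_terms, 3 * n_terms))
  qrd <- qr(design)
  if (qrd$rank < n_terms) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):n_terms]]
    stop("rank-deficient camera design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(vapply(library, function(r) {
    catch_vector(r, i, sys)$q
  }, numeric(length(sys$channels))))
  colnames(Y) <- channel_names(sys)
  coef <- qr.coef(qrd, Y)
  resid <- Y - design %*% coef
  rms <- sqrt(colMeans(resid^2))
  structure(list(coefficients = t(coef), training_rms = rms,
                 model_order = model_order, channels = names(cams),
                 terms = colnames(design)),
            class = "cone_mapping")
}

build_mapping_design <- function(X, model_order) {
  design <- cbind(intercept = 1, X)
  if (model_order == "linear+products") {
    cn <- colnames(X)
    for (a in seq_len(ncol(X) - 1)) for (b in (a + 1):ncol(X)) {
      design <- cbind(design, X[, a] * X[, b])
      colnames(design)[ncol(design)] <- paste0(cn[a], ":", cn[b])
    }
  }
  design
}

#' Predict cone catches from a calibrated patch response
#'
#' @param m a `"cone_mapping"` from [fit_cone_mapping()].
#' @param p a linearized `"patch_response"` (or a named numeric vector of
#'   normalized camera responses).
#' @return list with predicted normalized catches `q` and log signals `f`;
#'   nonpositive predictions are clamped to a small epsilon with a warning
#'   because downstream discrimination takes logs.
#' @export
apply_mapping <- function(m, p) {
  x <- if (inherits(p, "patch_response")) {
    if (is.null(p$normalized)) stop("patch response not linearized; call linearize_normalize() first")
    p$normalized
  } else p
  if (length(x) != length(m$channels))
    stop("response channels do not match the mapping's training layout")
  X <- matrix(x, nrow = 1, dimnames = list(NULL, m$channels))
  design <- build_mapping_design(X, m$model_order)
  q <- as.numeric(m$coefficients %*% t(design))
  names(q) <- rownames(m$coefficients)
  if (any(q <= 0)) {
    warning("nonpositive predicted catch clamped to epsilon")
    q <- pmax(q, 1e-6)
  }
  list(q = q, f = log(q))
}
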