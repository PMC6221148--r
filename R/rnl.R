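#' Receptor noise from cone abundances
#'
#' Noise of channel i scales with the inverse square root of its relative
#' abundance: `e_i = omega * sqrt(eta_max / eta_i)`, so the most frequent
#' cone type carries exactly the Weber fraction `omega`.
#'
#' @param sys a [visual_system()].
#' @return numeric vector of per-channel noise values, named by channel.
#' @examples
#' channel_noise(build_preset("bluetit-uvs"))
#' @export
channel_noise <- function(sys) {
  eta <- channel_etas(sys)
  if (any(eta <= 0)) stop("all channel abundances must be > 0")
  e <- sys$weber * sqrt(max(eta) / eta)
  names(e) <- channel_names(sys)
  e
}

#' Chromatic discriminability (receptor-noise model)
#'
#' Distance between two stimuli in just-noticeable-difference (JND)
#' units under the receptor-noise-limited model, using log-transformed
#' (Weber-Fechner) receptor signals. The general n-receptor quadratic
#' form is used:
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \ne i,j} e_k)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i (\prod_{k \ne i} e_k)^2}}
#' which reduces to the familiar dichromat, trichromat and tetrachromat
#' closed forms.
#'
#' @param a,b [catch_vector()]s from the same visual system.
#' @param noise per-channel noise, as from [channel_noise()].
#' @return object of class `"contrast_result"`: list with `delta_f`
#'   (per-channel log-signal differences), `delta_S` (JND), `kind`.
#' @export
chromatic_jnd <- function(a, b, noise) {
  if (!identical(a$system, b$system))
    stop("catch vectors come from different visual systems")
  n <- length(noise)
  if (length(a$q) != n || length(b$q) != n)
    stop("noise vector does not match the number of channels")
  if (any(a$q <= 0) || any(b$q <= 0))
    stop("nonpositive normalized catch; log signal undefined")
  df <- a$f - b$f
  e2 <- noise^2
  prod_all <- prod(e2)
  num <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    num <- num + prod_all / (e2[i] * e2[j]) * (df[i] - df[j])^2
  den <- sum(prod_all / e2)
  structure(list(delta_f = df, delta_S = unname(sqrt(num / den)),
                 kind = "chromatic"),
            class = "contrast_result")
}

#' Achromatic (luminance) discriminability
#'
#' Double-cone contrast: `|ln q_D(a) - ln q_D(b)| / e_D`. Only defined
#' for systems that carry an achromatic channel (the avian presets);
#' butterfly presets are rejected.
#'
#' @param a,b reflectance [spectrum()]s or precomputed achromatic catches.
#' @param i illuminant [spectrum()] (when `a`, `b` are spectra).
#' @param sys a [visual_system()] with an achromatic channel.
#' @param gray reference gray reflectance [spectrum()]; default flat 0.40.
#' @return a `"contrast_result"` of kind `"achromatic"`.
#' @export
achromatic_jnd <- function(a, b, i, sys, gray = NULL) {
  if (is.null(sys$achromatic_channel))
    stop("visual system '", sys$name, "' has no achromatic (double-cone) channel")
  ch <- sys$achromatic_channel
  if (is.null(gray))
    gray <- spectrum(a$wl, rep(0.4, length(a$wl)), kind = "reflectance")
  qg <- quantum_catch(gray, i, ch)
  qa <- quantum_catch(a, i, ch) / qg
  qb <- quantum_catch(b, i, ch) / qg
  if (qa <= 0 || qb <= 0) stop("nonpositive achromatic catch")
  df <- log(qa) - log(qb)
  structure(list(delta_f = df, delta_S = abs(df) / sys$achromatic_weber,
                 kind = "achromatic"),
            class = "contrast_result")
}

# Vectorized chromatic ΔS for a matrix of per-channel log signals
# (rows = channels, columns = stimuli) and a pair index; used by the
# pairwise JND tables where thousands of comparisons share one system.
rnl_delta_S_pairs <- function(f, idx_a, idx_b, noise) {
  e2 <- noise^2
  n <- length(e2)
  prod_all <- prod(e2)
  df <- f[, idx_a, drop = FALSE] - f[, idx_b, drop = FALSE]
  num <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    num <- num + prod_all / (e2[i] * e2[j]) * (df[i, ] - df[j, ])^2
  unname(sqrt(num / sum(prod_all / e2)))
}

#' Discriminability call at a JND threshold
#'
#' Two colors are called discriminable when their distance strictly
#' exceeds the threshold; distances below about 3 JND are generally hard
#' to tell apart under natural light, so 3.00 is the default. The
#' boundary itself (exactly 3.00) is *not* discriminable.
#'
#' @param result a `"contrast_result"` (or a bare JND value).
#' @param threshold JND threshold, default 3.00.
#' @return logical.
#' @export
discriminable <- function(result, threshold = 3.00) {
  if (threshold < 0) stop("threshold must be nonnegative")
  ds <- if (inherits(result, "contrast_result")) result$delta_S else result
  ds > threshold
}
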