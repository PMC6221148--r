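#' Receptor channel
#'
#' @param name channel label (e.g. `"UV"`, `"LW"`).
#' @param sensitivity a [spectrum()] of kind `"sensitivity"`,
#'   peak-normalized.
#' @param eta relative abundance of the cone type (dimensionless, > 0).
#' @param lambda_max nominal peak wavelength (nm).
#' @return object of class `"receptor_channel"`.
#' @export
receptor_channel <- function(name, sensitivity, eta, lambda_max) {
  stopifnot(is_spectrum(sensitivity), sensitivity$kind == "sensitivity")
  if (!is.numeric(eta) || eta <= 0) stop("eta must be > 0")
  if (abs(max(sensitivity$values) - 1) > 1e-9)
    stop("sensitivity must be peak-normalized to 1")
  structure(list(name = name, sensitivity = sensitivity, eta = eta,
                 lambda_max = lambda_max),
            class = "receptor_channel")
}

#' Visual system
#'
#' An ordered set of receptor channels (short to long peak wavelength)
#' plus the Weber fraction of the most abundant channel, and optionally an
#' achromatic (double-cone) channel used for luminance contrast.
#'
#' @param name system label.
#' @param channels list of [receptor_channel()], ordered by `lambda_max`.
#' @param weber Weber fraction of the most abundant channel (default 0.05).
#' @param achromatic_channel optional [receptor_channel()] (double cone).
#' @param achromatic_weber Weber fraction of the achromatic channel.
#' @return object of class `"visual_system"`.
#' @export
visual_system <- function(name, channels, weber = 0.05,
                          achromatic_channel = NULL, achromatic_weber = 0.05) {
  if (length(channels) < 2) stop("a visual system needs at least 2 channels")
  nm <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nm)) stop("channel names must be unique")
  lmax <- vapply(channels, function(ch) ch$lambda_max, numeric(1))
  if (is.unsorted(lmax)) stop("channels must be ordered short to long lambda_max")
  if (weber <= 0 || weber >= 1) stop("weber must be in (0, 1)")
  structure(list(name = name, channels = channels, weber = weber,
                 achromatic_channel = achromatic_channel,
                 achromatic_weber = achromatic_weber),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system %s: %d channels%s, weber %.3g>\n", x$name,
              length(x$channels),
              if (is.null(x$achromatic_channel)) "" else " + achromatic",
              x$weber))
  for (ch in x$channels)
    cat(sprintf("  %-4s lambda_max %g nm, eta %g\n", ch$name, ch$lambda_max, ch$eta))
  invisible(x)
}

#' Channel names and abundances of a visual system
#'
#' @param sys a [visual_system()].
#' @return character vector of channel names / numeric vector of relative
#'   abundances, in channel order.
#' @export
channel_names <- function(sys) vapply(sys$channels, `[[`, character(1), "name")

#' @rdname channel_names
#' @export
channel_etas <- function(sys) vapply(sys$channels, `[[`, numeric(1), "eta")

#' Read the packaged preset table
#'
#' @param path CSV file with columns preset, channel, lambda_max, eta,
#'   weber, achromatic; defaults to the table shipped with the package.
#' @return data.frame of the preset table.
#' @export
read_preset_table <- function(path = system.file("extdata", "visual_presets.csv",
                                                 package = "mimicolor")) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Build a named visual-system preset
#'
#' Presets cover the four visual systems of the mimicry analysis: the
#' ultraviolet-sensitive blue tit and violet-sensitive peafowl (avian,
#' with a double-cone achromatic channel), and female/male
#' *Heliconius erato* with either the green (555 nm) or red-filtered
#' (600 nm) long-wavelength receptor. Channel sensitivities are built with
#' [pigment_template()] at the preset peak wavelengths; abundances follow
#' the published cone proportions.
#'
#' @param name one of `"bluetit-uvs"`, `"peafowl-vs"`,
#'   `"erato-female-green"`, `"erato-female-red"`, `"erato-male-green"`,
#'   `"erato-male-red"`.
#' @param g wavelength grid for the sensitivities.
#' @param table preset table, as from [read_preset_table()].
#' @return a [visual_system()].
#' @examples
#' sys <- build_preset("bluetit-uvs")
#' sapply(sys$channels, function(ch) ch$eta)
#' @export
build_preset <- function(name, g = wl_grid(), table = read_preset_table()) {
  rows <- table[table$preset == name, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(unique(table$preset), collapse = ", "))
  chrom <- rows[rows$achromatic == 0, , drop = FALSE]
  chrom <- chrom[order(chrom$lambda_max), , drop = FALSE]
  channels <- lapply(seq_len(nrow(chrom)), function(i)
    receptor_channel(chrom$channel[i], pigment_template(chrom$lambda_max[i], g),
                     chrom$eta[i], chrom$lambda_max[i]))
  ach <- rows[rows$achromatic == 1, , drop = FALSE]
  ach_ch <- if (nrow(ach) == 1)
    receptor_channel(ach$channel[1], pigment_template(ach$lambda_max[1], g),
                     ach$eta[1], ach$lambda_max[1])
  visual_system(name, channels, weber = chrom$weber[1],
                achromatic_channel = ach_ch, achromatic_weber = ach$weber[1] %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Quantum catch of one receptor
#'
#' The receptor's stimulus estimate: the trapezoid-rule integral of
#' reflectance x illuminant x sensitivity over the common grid.
#'
#' @param r reflectance [spectrum()].
#' @param i illuminant [spectrum()].
#' @param ch a [receptor_channel()].
#' @return the catch Q (positive for nondegenerate stimuli).
#' @export
quantum_catch <- function(r, i, ch) {
  s <- ch$sensitivity
  if (length(r$wl) != length(s$wl) || any(r$wl != s$wl) ||
      length(i$wl) != length(s$wl) || any(i$wl != s$wl))
    stop("spectra are on different grids; resample first")
  y <- r$values * i$values * s$values
  q <- trapz(r$wl, y)
  if (q == 0) warning("degenerate stimulus: zero overlap with channel ", ch$name)
  q
}

#' Gray-normalized catch vector
#'
#' Computes raw catches for every channel of a visual system and applies
#' von-Kries-style normalization to the catch of a reference gray standard
#' (default: flat 40% reflectance, the photographic calibration standard),
#' channel by channel. Log signals `f = ln q` are the inputs to the
#' receptor-noise model.
#'
#' @param r reflectance [spectrum()].
#' @param i illuminant [spectrum()].
#' @param sys a [visual_system()].
#' @param gray reference reflectance [spectrum()]; default flat 0.40.
#' @return object of class `"catch_vector"`: list with `system` (name),
#'   `channels`, `Q` (raw), `q` (normalized), `f` (= log q).
#' @export
catch_vector <- function(r, i, sys, gray = NULL) {
  if (is.null(gray))
    gray <- spectrum(r$wl, rep(0.4, length(r$wl)), kind = "reflectance")
  Q <- vapply(sys$channels, function(ch) quantum_catch(r, i, ch), numeric(1))
  Qg <- vapply(sys$channels, function(ch) quantum_catch(gray, i, ch), numeric(1))
  if (any(Qg == 0)) stop("gray-standard catch is zero; cannot normalize")
  q <- Q / Qg
  structure(list(system = sys$name, channels = channel_names(sys),
                 Q = Q, q = q, f = log(q)),
            class = "catch_vector")
}

# Vectorized catches for a matrix of reflectances (columns = samples) on a
# fixed grid/illuminant/system; returns the gray-normalized q matrix
# (rows = channels). Trapezoid weights fold into one matrix product.
catch_matrix <- function(refl, wl, i_values, sys, gray_reflectance = 0.4) {
  w <- rep(1, length(wl)); w[1] <- 0.5; w[length(wl)] <- 0.5
  w <- w * c(diff(wl)[1])
  S <- vapply(sys$channels, function(ch) ch$sensitivity$values,
              numeric(length(wl)))
  kernel <- S * i_values * w          # length(wl) x nchan
  Q <- t(kernel) %*% refl             # nchan x nsamples
  Qg <- as.numeric(t(kernel) %*% rep(gray_reflectance, length(wl)))
  sweep(Q, 1, Qg, "/")
}
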