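# Evaluate an expression under a temporary RNG state so generators are
# pure functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wing-patch reflectance model
#'
#' Parametric model of a smooth wing-patch reflectance: a sigmoid
#' long-pass base (pigment absorption edge) plus an optional ultraviolet
#' Gaussian lobe, with individual-level variation as a multiplicative
#' lognormal amplitude factor and a Gaussian jitter of the long-pass
#' inflection wavelength. Defaults per color class emulate the yellow
#' (UV-reflecting), white, red and orange patch types of mimetic
#' butterflies; red carries extra inflection jitter, mimicking the
#' age-related fading of red pigment.
#'
#' @param color_class `"yellow"`, `"white"`, `"red"`, or `"orange"`.
#' @param longpass_inflection long-pass edge position (nm).
#' @param longpass_slope edge steepness (1/nm).
#' @param plateau long-wavelength reflectance plateau (0, 1].
#' @param uv_lobe `c(center_nm, width_nm, amplitude)` or `NULL`.
#' @param individual_cv coefficient of variation of the amplitude factor.
#' @param inflection_sd_nm standard deviation of the inflection jitter.
#' @return object of class `"patch_model"`.
#' @export
patch_spectrum_model <- function(color_class = c("yellow", "white", "red", "orange"),
                                 longpass_inflection = NULL,
                                 longpass_slope = NULL, plateau = NULL,
                                 uv_lobe = NULL, individual_cv = 0.05,
                                 inflection_sd_nm = NULL) {
  color_class <- match.arg(color_class)
  defaults <- list(
    yellow = list(infl = 500, slope = 0.07, plateau = 0.65,
                  uv = c(350, 25, 0.25), infl_sd = 3),
    white  = list(infl = 420, slope = 0.05, plateau = 0.80,
                  uv = NULL, infl_sd = 3),
    red    = list(infl = 600, slope = 0.08, plateau = 0.60,
                  uv = NULL, infl_sd = 8),
    orange = list(infl = 580, slope = 0.07, plateau = 0.65,
                  uv = NULL, infl_sd = 4))[[color_class]]
  m <- list(color_class = color_class,
            longpass_inflection = longpass_inflection %||% defaults$infl,
            longpass_slope = longpass_slope %||% defaults$slope,
            plateau = plateau %||% defaults$plateau,
            uv_lobe = if (is.null(uv_lobe)) defaults$uv else
              if (identical(uv_lobe, FALSE)) NULL else uv_lobe,
            individual_cv = individual_cv,
            inflection_sd_nm = inflection_sd_nm %||% defaults$infl_sd)
  if (m$plateau <= 0 || m$plateau > 1) stop("plateau must be in (0, 1]")
  if (!is.null(m$uv_lobe) && m$uv_lobe[3] < 0) stop("uv lobe amplitude must be >= 0")
  if (m$individual_cv < 0) stop("individual_cv must be >= 0")
  structure(m, class = "patch_model")
}

#' Generate wing-patch reflectance spectra
#'
#' @param m a [patch_spectrum_model()].
#' @param n number of individuals.
#' @param g wavelength grid.
#' @param seed RNG seed; generation is a pure function of the seed.
#' @return matrix of reflectances (rows = wavelengths, columns =
#'   individuals), clipped to \[0, 1.5\] with a warning if exceeded.
#' @export
generate_patch_spectrum <- function(m, n = 1, g = wl_grid(), seed = 1) {
  stopifnot(inherits(m, "patch_model"))
  g <- as.numeric(g)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + m$individual_cv^2))
    amp <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    infl <- m$longpass_inflection + stats::rnorm(n, 0, m$inflection_sd_nm)
    out <- vapply(seq_len(n), function(k) {
      base <- m$plateau / (1 + exp(-m$longpass_slope * (g - infl[k])))
      if (!is.null(m$uv_lobe))
        base <- base + m$uv_lobe[3] *
          exp(-((g - m$uv_lobe[1]) / m$uv_lobe[2])^2 / 2)
      amp[k] * base
    }, numeric(length(g)))
  })
  if (any(out > 1.5)) {
    warning("reflectance above 1.5 clipped")
    out[out > 1.5] <- 1.5
  }
  out[out < 0] <- 0
  colnames(out) <- paste0("ind", seq_len(n))
  out
}

#' Comimic ring scenario
#'
#' Describes a two-species Muellerian mimicry ring for simulation: sample
#' sizes, the strata (patch colors x wing sides) shared by the pair, the
#' within-species individual variation, and the controllable between-
#' species divergence (a shift of the long-pass inflection and of the UV
#' lobe amplitude applied to species B).
#'
#' @param species_a,species_b species labels.
#' @param n_a,n_b individuals per species (>= 2).
#' @param colors patch colors (subset of yellow/white/red/orange).
#' @param sides wing sides (dorsal/ventral).
#' @param divergence_nm inflection shift applied to species B (nm).
#' @param uv_divergence UV-lobe amplitude shift applied to species B.
#' @param individual_cv amplitude coefficient of variation.
#' @param inflection_sd_nm within-species inflection jitter (nm).
#' @param seed RNG seed.
#' @return object of class `"ring_scenario"`.
#' @export
ring_scenario <- function(species_a = "erato_like", species_b = "melpomene_like",
                          n_a = 10, n_b = 10, colors = "yellow",
                          sides = "dorsal", divergence_nm = 0,
                          uv_divergence = 0, individual_cv = 0.05,
                          inflection_sd_nm = 2, seed = 1) {
  if (n_a < 2 || n_b < 2) stop("scenario error: need >= 2 individuals per species")
  if (divergence_nm < 0 || uv_divergence < 0) stop("divergence must be >= 0")
  if (length(colors) == 0 || length(sides) == 0) stop("scenario error: empty strata")
  structure(list(species_a = species_a, species_b = species_b,
                 n_a = n_a, n_b = n_b, colors = colors, sides = sides,
                 divergence_nm = divergence_nm, uv_divergence = uv_divergence,
                 individual_cv = individual_cv,
                 inflection_sd_nm = inflection_sd_nm, seed = seed),
            class = "ring_scenario")
}

#' Generate a comimic ring dataset
#'
#' Draws reflectance spectra for every individual and stratum of the
#' scenario, computes gray-normalized catches under the requested visual
#' system, and returns the measurement table the statistics pipeline
#' consumes, together with the generating ground truth.
#'
#' @param r a [ring_scenario()].
#' @param sys a [visual_system()] (or preset name).
#' @param illuminant illuminant [spectrum()]; default D65.
#' @param g wavelength grid.
#' @return list: `measurements` (data.frame with `individual_id`,
#'   `species`, `ring`, `patch_color`, `wing_side`, `q.<ch>` and `f.<ch>`
#'   columns), `spectra` (list of reflectance matrices by stratum),
#'   `truth` (the scenario).
#' @export
generate_ring <- function(r, sys, illuminant = NULL, g = wl_grid()) {
  stopifnot(inherits(r, "ring_scenario"))
  if (is.character(sys)) sys <- build_preset(sys, g)
  gv <- as.numeric(g)
  if (is.null(illuminant)) illuminant <- standard_illuminant("D65", g)
  rows <- list(); spectra <- list()
  stratum_seed <- r$seed
  for (col in r$colors) for (side in r$sides) {
    stratum_seed <- stratum_seed + 1
    ma <- patch_spectrum_model(col, individual_cv = r$individual_cv,
                               inflection_sd_nm = r$inflection_sd_nm)
    mb <- ma
    mb$longpass_inflection <- ma$longpass_inflection + r$divergence_nm
    if (!is.null(mb$uv_lobe))
      mb$uv_lobe[3] <- max(0, mb$uv_lobe[3] + r$uv_divergence)
    else if (r$uv_divergence > 0)
      mb$uv_lobe <- c(350, 25, r$uv_divergence)
    ra <- generate_patch_spectrum(ma, r$n_a, g, seed = stratum_seed)
    rb <- generate_patch_spectrum(mb, r$n_b, g, seed = stratum_seed + 10000)
    refl <- cbind(ra, rb)
    q <- catch_matrix(refl, gv, illuminant$values, sys)
    ids <- c(paste0(r$species_a, "_", seq_len(r$n_a)),
             paste0(r$species_b, "_", seq_len(r$n_b)))
    df <- data.frame(individual_id = ids,
                     species = rep(c(r$species_a, r$species_b), c(r$n_a, r$n_b)),
                     ring = paste(r$species_a, r$species_b, sep = "/"),
                     patch_color = col, wing_side = side,
                     stringsAsFactors = FALSE)
    for (i in seq_along(sys$channels)) {
      df[[paste0("q.", channel_names(sys)[i])]] <- q[i, ]
      df[[paste0("f.", channel_names(sys)[i])]] <- log(q[i, ])
    }
    rows[[paste(col, side)]] <- df
    spectra[[paste(col, side)]] <- refl
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(measurements = measurements, spectra = spectra, truth = r)
}

#' Calibrate ring divergence to target mean JNDs
#'
#' Bisection against the generative model itself: first the
#' within-species inflection jitter is tuned so the conspecific mean
#' chromatic JND hits its target, then the between-species inflection
#' shift is tuned for the comimic target, both under the given visual
#' system and averaged over Monte-Carlo replicates at a fixed internal
#' seed.
#'
#' @param target_comimic desired comimic mean JND.
#' @param target_conspecific desired conspecific mean JND.
#' @param sys visual system preset name.
#' @param base scenario template, as from [ring_scenario()].
#' @param n_rep Monte-Carlo replicates per bisection evaluation.
#' @param tol JND tolerance for the bisection.
#' @return calibrated `"ring_scenario"` with an attribute `achieved`
#'   giving the attained mean JNDs.
#' @export
calibrate_ring_scenario <- function(target_comimic = 6, target_conspecific = 1,
                                    sys = "bluetit-uvs",
                                    base = ring_scenario(), n_rep = 5,
                                    tol = 0.05) {
  system <- if (is.character(sys)) build_preset(sys) else sys
  illum <- standard_illuminant("D65")
  mean_jnds <- function(sc) {
    cm <- cs <- numeric(n_rep)
    for (k in seq_len(n_rep)) {
      sc$seed <- 777000 + k
      ring <- generate_ring(sc, system, illum)
      recs <- pairwise_jnd_table(ring$measurements, system)
      cm[k] <- mean(recs$jnd[recs$pair_type == "comimic"])
      cs[k] <- mean(recs$jnd[recs$pair_type == "conspecific"])
    }
    c(comimic = mean(cm), conspecific = mean(cs))
  }
  # conspecific JND is monotone in the inflection jitter
  lo <- 0.1; hi <- 30
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    sc <- base; sc$inflection_sd_nm <- mid; sc$divergence_nm <- 0
    v <- mean_jnds(sc)["conspecific"]
    if (abs(v - target_conspecific) < tol) break
    if (v < target_conspecific) lo <- mid else hi <- mid
  }
  infl_sd <- mid
  # comimic JND is monotone in the species divergence
  lo <- 0; hi <- 60
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    sc <- base; sc$inflection_sd_nm <- infl_sd; sc$divergence_nm <- mid
    v <- mean_jnds(sc)["comimic"]
    if (abs(v - target_comimic) < tol) break
    if (v < target_comimic) lo <- mid else hi <- mid
  }
  out <- base
  out$inflection_sd_nm <- infl_sd
  out$divergence_nm <- mid
  attr(out, "achieved") <- mean_jnds(out)
  out
}

#' Generate mate-choice trials
#'
#' Simulates per-male approach and courtship counts toward comimic vs
#' conspecific female models under the two UV treatments. Event totals
#' are Poisson per male and treatment; the direction of each event is
#' Bernoulli with the treatment-specific probability of choosing the
#' comimic. Defaults reproduce the scale of the original experiment:
#' 41 males, about 709 approaches and 62 courtships in total.
#'
#' @param n_males number of males.
#' @param approaches_per_male Poisson mean of approach events per male
#'   and treatment.
#' @param courtships_per_male Poisson mean of courtship events per male
#'   and treatment.
#' @param p_approach named probabilities of approaching the comimic,
#'   `c(UVplus = , UVminus = )`.
#' @param p_courtship same for courtship.
#' @param seed RNG seed.
#' @return list: `trials` (data.frame in the trial-record layout) and
#'   `truth` (the generating probabilities and their log odds).
#' @export
generate_mate_choice_trials <- function(n_males = 41,
                                        approaches_per_male = 709 / (41 * 2),
                                        courtships_per_male = 62 / (41 * 2),
                                        p_approach = c(UVplus = 0.5, UVminus = 0.65),
                                        p_courtship = c(UVplus = 0.5, UVminus = 0.55),
                                        seed = 1) {
  for (p in c(p_approach, p_courtship))
    if (p <= 0 || p >= 1) stop("choice probabilities must be in (0, 1)")
  rows <- list()
  with_seed(seed, {
    for (m in seq_len(n_males)) for (tr in c("UVplus", "UVminus")) {
      na <- stats::rpois(1, approaches_per_male)
      nc <- stats::rpois(1, courtships_per_male)
      sa <- stats::rbinom(1, na, p_approach[[tr]])
      sc <- stats::rbinom(1, nc, p_courtship[[tr]])
      rows[[length(rows) + 1]] <- data.frame(
        male_id = sprintf("male%02d", m), treatment = tr,
        target_species = c("comimic_model", "conspecific_model"),
        approaches = c(sa, na - sa), courtships = c(sc, nc - sc),
        trials_observed = 2L)
    }
  })
  trials <- do.call(rbind, rows)
  truth <- list(p_approach = p_approach, p_courtship = p_courtship,
                log_odds_approach = stats::qlogis(p_approach),
                log_odds_courtship = stats::qlogis(p_courtship))
  list(trials = trials, truth = truth)
}
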