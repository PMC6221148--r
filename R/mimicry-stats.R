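#' Pairwise JND table for a mimicry ring
#'
#' Builds every within-stratum pairwise chromatic comparison: cross-species
#' pairs are `comimic`, within-species pairs `conspecific`. Strata are
#' patch color x wing side; a stratum present in only one species is
#' skipped with a message. When a visual model exists for only one clade
#' (the butterfly presets), `conspecific_restriction` limits conspecific
#' pairs to the named species.
#'
#' @param measurements data.frame with columns `individual_id`, `species`,
#'   `ring`, `patch_color`, `wing_side` and per-channel log-signal columns
#'   `f.<channel>` matching `sys`.
#' @param sys the [visual_system()] the measurements were computed under.
#' @param conspecific_restriction optional character vector of species
#'   whose conspecific pairs are kept.
#' @return data.frame of pair records: `ring`, `patch_color`, `wing_side`,
#'   `system`, `individual_a`, `individual_b`, `pair_type`, `jnd`.
#' @export
pairwise_jnd_table <- function(measurements, sys, conspecific_restriction = NULL) {
  noise <- channel_noise(sys)
  fcols <- paste0("f.", channel_names(sys))
  if (!all(fcols %in% names(measurements)))
    stop("measurements lack log-signal columns for system ", sys$name)
  species <- unique(measurements$species)
  if (length(species) != 2) stop("expected exactly 2 species in the ring")
  out <- list()
  strata <- unique(measurements[, c("patch_color", "wing_side")])
  for (k in seq_len(nrow(strata))) {
    col <- strata$patch_color[k]; side <- strata$wing_side[k]
    m <- measurements[measurements$patch_color == col &
                        measurements$wing_side == side, , drop = FALSE]
    if (length(unique(m$species)) < 2) {
      message("stratum ", col, "/", side, " missing in one species; skipped")
      next
    }
    f <- t(as.matrix(m[, fcols]))
    ia <- which(m$species == species[1]); ib <- which(m$species == species[2])
    # comimic: full cross product
    g <- expand.grid(a = ia, b = ib)
    pairs <- data.frame(a = g$a, b = g$b, pair_type = "comimic")
    # conspecific: within-species unordered pairs
    for (sp in species) {
      if (!is.null(conspecific_restriction) && !(sp %in% conspecific_restriction))
        next
      ii <- which(m$species == sp)
      if (length(ii) >= 2) {
        cmb <- utils::combn(ii, 2)
        pairs <- rbind(pairs, data.frame(a = cmb[1, ], b = cmb[2, ],
                                         pair_type = "conspecific"))
      }
    }
    jnd <- rnl_delta_S_pairs(f, pairs$a, pairs$b, noise)
    out[[k]] <- data.frame(
      ring = m$ring[1], patch_color = col, wing_side = side,
      system = sys$name,
      individual_a = m$individual_id[pairs$a],
      individual_b = m$individual_id[pairs$b],
      pair_type = pairs$pair_type, jnd = jnd,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no stratum present in both species")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-individual mean JNDs
#'
#' Averages each individual's pairwise JNDs separately for comimic and
#' conspecific comparisons, within each stratum. Individuals lacking
#' conspecific pairs (e.g. under a clade restriction) get `NA` and are
#' excluded by the downstream ANOVA.
#'
#' @param records pair records from [pairwise_jnd_table()] (one visual
#'   system).
#' @return data.frame: `individual`, `stratum`, `mean_comimic`,
#'   `mean_conspecific`.
#' @export
individual_mean_jnd <- function(records) {
  if (length(unique(records$system)) > 1)
    stop("records mix visual systems; compute means per system")
  records$stratum <- paste(records$patch_color, records$wing_side, sep = "/")
  out <- list()
  for (st in unique(records$stratum)) {
    r <- records[records$stratum == st, ]
    inds <- unique(c(r$individual_a, r$individual_b))
    for (ind in inds) {
      sel <- r$individual_a == ind | r$individual_b == ind
      mc <- r$jnd[sel & r$pair_type == "comimic"]
      ms <- r$jnd[sel & r$pair_type == "conspecific"]
      out[[length(out) + 1]] <- data.frame(
        individual = ind, stratum = st,
        mean_comimic = if (length(mc)) mean(mc) else NA_real_,
        mean_conspecific = if (length(ms)) mean(ms) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Comimic-vs-conspecific repeated-measures ANOVA
#'
#' Tests whether comimic distances exceed conspecific distances, with
#' each individual contributing one mean of each type. Means are
#' square-root transformed (JND data are right-skewed), then the balanced
#' two-level within-individual ANOVA is fitted: individuals act as the
#' random factor, and
#' `F = MS(pair type) / MS(pair type x individual)` with degrees of
#' freedom (1, n-1). In this design F equals the squared paired t
#' statistic.
#'
#' @param means table from [individual_mean_jnd()] (one stratum); rows
#'   with a missing mean are dropped with a message.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return list with `F`, `df_num`, `df_den`, `p`, `n`, `transform`,
#'   `degenerate` flag.
#' @export
comimic_vs_conspecific_anova <- function(means, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  keep <- stats::complete.cases(means[, c("mean_comimic", "mean_conspecific")])
  if (any(!keep))
    message(sum(!keep), " individual(s) without both means excluded")
  means <- means[keep, ]
  n <- nrow(means)
  if (n < 3) stop("insufficient data: need >= 3 individuals with both means")
  y1 <- means$mean_comimic; y2 <- means$mean_conspecific
  if (transform == "sqrt") { y1 <- sqrt(y1); y2 <- sqrt(y2) }
  grand <- mean(c(y1, y2))
  ind_mean <- (y1 + y2) / 2
  ss_treat <- n * ((mean(y1) - grand)^2 + (mean(y2) - grand)^2)
  ss_inter <- sum((y1 - ind_mean - mean(y1) + grand)^2 +
                    (y2 - ind_mean - mean(y2) + grand)^2)
  ms_inter <- ss_inter / (n - 1)
  if (ss_treat == 0)
    return(list(F = 0, df_num = 1L, df_den = n - 1L, p = 1, n = n,
                transform = transform, degenerate = FALSE))
  if (ms_inter == 0) {
    warning("zero residual mean square; perfectly constant differences")
    return(list(F = Inf, df_num = 1L, df_den = n - 1L, p = NA_real_, n = n,
                transform = transform, degenerate = TRUE))
  }
  f_stat <- ss_treat / ms_inter
  list(F = f_stat, df_num = 1L, df_den = n - 1L,
       p = stats::pf(f_stat, 1, n - 1, lower.tail = FALSE), n = n,
       transform = transform, degenerate = FALSE)
}

#' Permutation alternative to the repeated-measures ANOVA
#'
#' Flips the comimic/conspecific labels independently within individuals
#' and recomputes the mean difference; robust companion to the F test.
#'
#' @param means table from [individual_mean_jnd()] (one stratum).
#' @param n_perm number of sign flips.
#' @param seed RNG seed.
#' @return list with `observed` mean difference (sqrt scale) and `p`.
#' @export
comimic_permutation_test <- function(means, n_perm = 2000, seed = 1) {
  keep <- stats::complete.cases(means[, c("mean_comimic", "mean_conspecific")])
  means <- means[keep, ]
  d <- sqrt(means$mean_comimic) - sqrt(means$mean_conspecific)
  obs <- mean(d)
  with_seed(seed, {
    perm <- replicate(n_perm, mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
  })
  list(observed = obs, p = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
}
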