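# Shared test utilities: hand-rolled oracles kept independent of the
# package's production code paths.

# Build a catch_vector directly from normalized catches.
make_cv <- function(q, system = "test") {
  structure(list(system = system, channels = paste0("ch", seq_along(q)),
                 q = q, f = log(q)),
            class = "catch_vector")
}

# Closed-form RNL distances for 2-4 receptors, written out term by term.
closed_form_jnd <- function(df, e) {
  n <- length(df)
  if (n == 2) {
    sqrt((df[1] - df[2])^2 / (e[1]^2 + e[2]^2))
  } else if (n == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
      e[3]^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    sqrt(num / den)
  } else if (n == 4) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
      (e[1] * e[3])^2 * (df[4] - df[2])^2 +
      (e[1] * e[4])^2 * (df[3] - df[2])^2 +
      (e[2] * e[3])^2 * (df[4] - df[1])^2 +
      (e[2] * e[4])^2 * (df[3] - df[1])^2 +
      (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
      (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    sqrt(num / den)
  } else stop("closed forms cover 2-4 receptors")
}

# Brute-force oracle: Mahalanobis distance of the log-signal difference
# under the diagonal noise covariance, projected orthogonally to the
# achromatic (all-ones) direction, with an explicit matrix inversion.
mahalanobis_jnd <- function(df, e) {
  Sigma <- diag(e^2, length(e))
  Si <- solve(Sigma)
  ones <- rep(1, length(e))
  sqrt(drop(t(df) %*% Si %*% df -
              (t(ones) %*% Si %*% df)^2 / (t(ones) %*% Si %*% ones)))
}

# Random per-individual mean-JND table for the ANOVA engine.
rand_means_table <- function(n, shift = 0) {
  data.frame(individual = seq_len(n), stratum = "s",
             mean_comimic = rnorm(n, 5 + shift, 1)^2,
             mean_conspecific = rnorm(n, 5, 1)^2)
}

# Measurement table with prescribed per-channel log signals.
make_measurements <- function(f_by_ind, species, channels = c("u", "l"),
                              color = "yellow", side = "dorsal") {
  df <- data.frame(individual_id = names(species), species = unname(species),
                   ring = "A/B", patch_color = color, wing_side = side,
                   stringsAsFactors = FALSE)
  for (i in seq_along(channels)) {
    df[[paste0("q.", channels[i])]] <- exp(f_by_ind[i, ])
    df[[paste0("f.", channels[i])]] <- f_by_ind[i, ]
  }
  df
}

# Minimal two-channel visual system with flat equal abundances.
toy_system <- function(eta = c(1, 1), weber = 0.05, name = "toy") {
  g <- wl_grid(400, 500, 10)
  chans <- lapply(seq_along(eta), function(i)
    receptor_channel(paste0("ch", i), pigment_template(420 + 20 * i, g),
                     eta[i], 420 + 20 * i))
  visual_system(name, chans, weber = weber)
}
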