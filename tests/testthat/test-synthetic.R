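test_that("patch spectra obey the sigmoid-plus-lobe construction", {
  g <- wl_grid()
  m <- patch_spectrum_model("white", longpass_inflection = 500, plateau = 0.8,
                            individual_cv = 0, inflection_sd_nm = 0)
  r <- generate_patch_spectrum(m, 1, g, seed = 1)[, 1]
  expect_equal(r[as.numeric(g) == 650], 0.8, tolerance = 1e-3)
  expect_lt(r[as.numeric(g) == 350], 1e-3)

  m_uv <- m
  m_uv$uv_lobe <- c(350, 25, 0.3)
  r_uv <- generate_patch_spectrum(m_uv, 1, g, seed = 1)[, 1]
  expect_equal(r_uv[as.numeric(g) == 350] - r[as.numeric(g) == 350], 0.3,
               tolerance = 1e-6)
})

test_that("generators are pure functions of their seed", {
  m <- patch_spectrum_model("yellow")
  a <- generate_patch_spectrum(m, 3, seed = 7)
  b <- generate_patch_spectrum(m, 3, seed = 7)
  c2 <- generate_patch_spectrum(m, 3, seed = 8)
  expect_identical(a, b)
  expect_false(all(a == c2))

  t1 <- generate_mate_choice_trials(seed = 5)
  t2 <- generate_mate_choice_trials(seed = 5)
  expect_identical(t1$trials, t2$trials)

  # the caller's RNG stream is untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_patch_spectrum(m, 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("ring scenarios validate sample sizes and strata", {
  expect_error(ring_scenario(n_a = 1), "2 individuals")
  expect_error(ring_scenario(colors = character(0)), "empty strata")
  expect_error(ring_scenario(divergence_nm = -5), ">= 0")
})

test_that("ring generation returns measurements plus ground truth", {
  sc <- ring_scenario(n_a = 3, n_b = 3, colors = c("yellow", "red"),
                      sides = c("dorsal", "ventral"), seed = 2)
  sys <- build_preset("erato-male-green")
  ring <- generate_ring(sc, sys)
  expect_equal(nrow(ring$measurements), 6 * 4)
  expect_true(all(paste0("f.", channel_names(sys)) %in% names(ring$measurements)))
  expect_identical(ring$truth, sc)
  expect_length(ring$spectra, 4)
  # deterministic rerun
  ring2 <- generate_ring(sc, sys)
  expect_identical(ring$measurements, ring2$measurements)
})

test_that("zero divergence makes comimic and conspecific JNDs exchangeable", {
  sc <- ring_scenario(n_a = 12, n_b = 12, divergence_nm = 0, seed = 10)
  sys <- build_preset("bluetit-uvs")
  cm <- cs <- numeric(8)
  for (k in 1:8) {
    sc$seed <- 100 + k
    recs <- pairwise_jnd_table(generate_ring(sc, sys)$measurements, sys)
    cm[k] <- mean(recs$jnd[recs$pair_type == "comimic"])
    cs[k] <- mean(recs$jnd[recs$pair_type == "conspecific"])
  }
  # > 500 pairs pooled; means agree within Monte-Carlo error
  expect_lt(abs(mean(cm) - mean(cs)) / mean(cs), 0.1)
})

test_that("divergence increases comimic but not conspecific distances", {
  sys <- build_preset("bluetit-uvs")
  res <- sapply(c(0, 10, 20), function(d) {
    sc <- ring_scenario(divergence_nm = d, seed = 42)
    recs <- pairwise_jnd_table(generate_ring(sc, sys)$measurements, sys)
    c(mean(recs$jnd[recs$pair_type == "comimic"]),
      mean(recs$jnd[recs$pair_type == "conspecific"]))
  })
  expect_true(all(diff(res[1, ]) > 0))
  expect_lt(diff(range(res[2, ])), 1)
})

test_that("mate-choice generation recovers its own ground truth", {
  # null preference: fitted treatment effect near zero at 40 x 100 events
  big <- generate_mate_choice_trials(n_males = 40, approaches_per_male = 100,
                                     p_approach = c(UVplus = 0.5, UVminus = 0.5),
                                     seed = 3)
  f <- fit_weighted_binomial(build_choice_table(big$trials, "approach"),
                             "treatment")
  expect_lt(abs(unname(f$coefficients[2])), 0.1)

  # a true UV-removal effect is recovered within its confidence interval
  eff <- generate_mate_choice_trials(n_males = 60, approaches_per_male = 40,
                                     p_approach = c(UVplus = 0.5, UVminus = 0.65),
                                     seed = 4)
  f2 <- fit_weighted_binomial(build_choice_table(eff$trials, "approach"),
                              "treatment")
  truth <- log(0.65 / 0.35) - 0
  est <- unname(f2$coefficients[2]); se <- unname(f2$standard_errors[2])
  expect_lt(abs(est - truth), 1.96 * se)
  expect_equal(unname(eff$truth$log_odds_approach["UVminus"]), qlogis(0.65))

  expect_error(generate_mate_choice_trials(p_approach = c(UVplus = 0, UVminus = 0.5)),
               "probabilities")
})

test_that("the default trial scenario matches the experiment's scale", {
  sim <- generate_mate_choice_trials(seed = 6)
  expect_equal(length(unique(sim$trials$male_id)), 41)
  total_app <- sum(sim$trials$approaches)
  total_court <- sum(sim$trials$courtships)
  expect_gt(total_app, 550); expect_lt(total_app, 880)
  expect_gt(total_court, 35); expect_lt(total_court, 95)
})

test_that("scenario calibration hits its JND targets", {
  sc <- calibrate_ring_scenario(target_comimic = 6, target_conspecific = 1,
                                n_rep = 3)
  ach <- attr(sc, "achieved")
  expect_lt(abs(ach["comimic"] - 6), 0.5)
  expect_lt(abs(ach["conspecific"] - 1), 0.25)
  expect_gt(sc$divergence_nm, 0)
})
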