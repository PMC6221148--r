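trial_row <- function(male, tr, app_com, app_con, court_com = 0, court_con = 0) {
  data.frame(male_id = male, treatment = tr,
             target_species = c("comimic_model", "conspecific_model"),
             approaches = c(app_com, app_con),
             courtships = c(court_com, court_con), trials_observed = 2L)
}

test_that("choice tables count successes toward the comimic", {
  trials <- rbind(trial_row("m1", "UVplus", 6, 4), trial_row("m1", "UVminus", 2, 8))
  tab <- build_choice_table(trials, "approach")
  r <- tab[tab$treatment == "UVplus", ]
  expect_equal(r$successes, 6); expect_equal(r$failures, 4); expect_equal(r$weight, 10)
  expect_equal(tab$weight[tab$treatment == "UVminus"], 10)

  # all events to the conspecific: proportion 0
  trials0 <- rbind(trial_row("m2", "UVplus", 0, 5), trial_row("m2", "UVminus", 0, 3))
  tab0 <- build_choice_table(trials0, "approach")
  expect_true(all(tab0$successes == 0))

  # no events at all: weight-0 row retained
  trialsz <- rbind(trial_row("m3", "UVplus", 0, 0), trial_row("m3", "UVminus", 1, 1))
  tabz <- build_choice_table(trialsz, "approach")
  expect_equal(tabz$weight[tabz$treatment == "UVplus"], 0)

  # male missing one treatment is excluded
  expect_message(tab1 <- build_choice_table(trial_row("m4", "UVplus", 3, 3)),
                 "missing a treatment")
  expect_null(tab1)
})

test_that("IRLS reproduces closed-form logits and log odds ratios", {
  tab <- data.frame(male_id = "m1", treatment = "UVplus",
                    successes = 30, failures = 20, weight = 50)
  f <- fit_weighted_binomial(tab, "intercept_only")
  expect_equal(unname(f$coefficients), log(30 / 20), tolerance = 1e-6)
  expect_true(f$converged)

  tab2 <- data.frame(male_id = c("a", "b"), treatment = c("UVplus", "UVminus"),
                     successes = c(30, 20), failures = c(20, 30),
                     weight = c(50, 50))
  f2 <- fit_weighted_binomial(tab2, "treatment")
  expect_equal(unname(f2$coefficients[2]), log((20 / 30) / (30 / 20)),
               tolerance = 1e-6)
  expect_equal(abs(unname(f2$coefficients[2])), 0.810930, tolerance = 1e-6)
})

test_that("IRLS matches the reference GLM implementation in z to 1e-6", {
  set.seed(5)
  worst <- 0
  for (k in 1:50) {
    n <- 20
    tab <- data.frame(male_id = paste0("m", 1:n),
                      treatment = sample(c("UVplus", "UVminus"), n, TRUE),
                      weight = rpois(n, 10) + 1)
    tab$successes <- rbinom(n, tab$weight, 0.55)
    tab$failures <- tab$weight - tab$successes
    if (length(unique(tab$treatment)) < 2 || any(tapply(tab$successes, tab$treatment, sum) == 0))
      next
    f <- fit_weighted_binomial(tab, "treatment")
    ref <- glm(cbind(successes, failures) ~
                 factor(treatment, c("UVplus", "UVminus")),
               binomial, tab, control = glm.control(epsilon = 1e-12))
    worst <- max(worst, max(abs(f$z - coef(summary(ref))[, "z value"])))
  }
  expect_lt(worst, 1e-6)
})

test_that("aggregated and per-event tables give identical coefficients", {
  tab <- data.frame(male_id = rep(c("a", "b"), each = 2),
                    treatment = rep(c("UVplus", "UVminus"), 2),
                    successes = c(5, 2, 4, 7), failures = c(3, 6, 2, 1))
  tab$weight <- tab$successes + tab$failures
  f_agg <- fit_weighted_binomial(tab, "treatment")
  # disaggregate to Bernoulli rows
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    data.frame(male_id = tab$male_id[i], treatment = tab$treatment[i],
               successes = rep(c(1, 0), c(tab$successes[i], tab$failures[i])))))
  rows$failures <- 1 - rows$successes
  rows$weight <- 1
  f_bern <- fit_weighted_binomial(rows, "treatment")
  expect_equal(f_agg$coefficients, f_bern$coefficients, tolerance = 1e-10)
})

test_that("estimates are antisymmetric under swapping success and failure", {
  tab <- data.frame(male_id = letters[1:4],
                    treatment = rep(c("UVplus", "UVminus"), 2),
                    successes = c(8, 3, 6, 2), failures = c(2, 7, 4, 9))
  tab$weight <- tab$successes + tab$failures
  f1 <- fit_weighted_binomial(tab, "treatment")
  swapped <- tab
  swapped$successes <- tab$failures; swapped$failures <- tab$successes
  f2 <- fit_weighted_binomial(swapped, "treatment")
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-8)
})

test_that("the treatment-by-behavior design fits the stacked table", {
  trials <- rbind(trial_row("m1", "UVplus", 6, 4, 2, 1),
                  trial_row("m1", "UVminus", 3, 7, 1, 2),
                  trial_row("m2", "UVplus", 5, 5, 1, 1),
                  trial_row("m2", "UVminus", 2, 8, 0, 3))
  tab <- build_choice_table(trials, "both")
  expect_true("behavior" %in% names(tab))
  f <- fit_weighted_binomial(tab, "treatment_x_behavior")
  expect_length(f$coefficients, 4)
  expect_true(f$converged)
  expect_error(fit_weighted_binomial(build_choice_table(trials, "approach"),
                                     "treatment_x_behavior"), "behavior")
})

test_that("Wald tests read the named term", {
  fit <- structure(list(coefficients = c(intercept = 0, treatmentUVminus = 1.96),
                        standard_errors = c(1, 1),
                        z = c(intercept = 0, treatmentUVminus = 1.96),
                        p = c(intercept = 1,
                              treatmentUVminus = 2 * pnorm(-1.96))),
                   class = "glm_fit")
  expect_equal(wald_test(fit, "intercept")$z, 0)
  expect_equal(wald_test(fit, "intercept")$p, 1)
  expect_equal(wald_test(fit, "treatmentUVminus")$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fit, "nope"), "unknown term")
})

test_that("separation is flagged rather than silently reported", {
  tab <- data.frame(male_id = c("a", "b"), treatment = c("UVplus", "UVminus"),
                    successes = c(10, 0), failures = c(0, 10),
                    weight = c(10, 10))
  expect_warning(f <- fit_weighted_binomial(tab, "treatment"), "separation")
  expect_false(f$converged && max(abs(f$coefficients)) < 30)
})
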