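test_that("pair counts follow n_a*n_b and C(n,2) exactly", {
  sys <- toy_system()
  species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  f <- matrix(rnorm(8, 0, 0.1), nrow = 2)
  m <- make_measurements(f, species, channels = channel_names(sys))
  recs <- pairwise_jnd_table(m, sys)
  expect_equal(sum(recs$pair_type == "comimic"), 4)
  expect_equal(sum(recs$pair_type == "conspecific"), 2)

  # 5 + 3 individuals
  species2 <- setNames(rep(c("A", "B"), c(5, 3)), paste0("i", 1:8))
  f2 <- matrix(rnorm(16, 0, 0.1), nrow = 2)
  m2 <- make_measurements(f2, species2, channels = channel_names(sys))
  recs2 <- pairwise_jnd_table(m2, sys)
  expect_equal(sum(recs2$pair_type == "comimic"), 15)
  expect_equal(sum(recs2$pair_type == "conspecific"), choose(5, 2) + choose(3, 2))
})

test_that("the conspecific restriction drops the other clade's pairs", {
  sys <- toy_system()
  species <- setNames(rep(c("erato", "melpomene"), each = 3), paste0("i", 1:6))
  f <- matrix(rnorm(12, 0, 0.1), nrow = 2)
  m <- make_measurements(f, species, channels = channel_names(sys))
  recs <- pairwise_jnd_table(m, sys, conspecific_restriction = "erato")
  consp <- recs[recs$pair_type == "conspecific", ]
  all_erato <- grepl("^i[1-3]$", consp$individual_a) &
    grepl("^i[1-3]$", consp$individual_b)
  expect_true(all(all_erato))
  expect_equal(nrow(consp), choose(3, 2))
})

test_that("identical stimuli give zero JND everywhere and zero means", {
  sys <- toy_system()
  species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  f <- matrix(0.3, nrow = 2, ncol = 4)
  m <- make_measurements(f, species, channels = channel_names(sys))
  recs <- pairwise_jnd_table(m, sys)
  expect_true(all(recs$jnd == 0))
  means <- individual_mean_jnd(recs)
  expect_true(all(means$mean_comimic == 0))
  expect_true(all(means$mean_conspecific == 0))
})

test_that("per-individual means average that individual's pairs by type", {
  recs <- data.frame(ring = "A/B", patch_color = "yellow", wing_side = "dorsal",
                     system = "toy",
                     individual_a = c("x", "x", "x", "y"),
                     individual_b = c("p", "q", "y", "z"),
                     pair_type = c("comimic", "comimic", "conspecific", "conspecific"),
                     jnd = c(2, 4, 1.5, 2.5))
  means <- individual_mean_jnd(recs)
  x <- means[means$individual == "x", ]
  expect_equal(x$mean_comimic, 3)
  expect_equal(x$mean_conspecific, 1.5)
  # uniform conspecific JNDs give that constant for every individual
  species <- setNames(rep("A", 4), paste0("i", 1:4))
  recsu <- do.call(rbind, lapply(combn(4, 2, simplify = FALSE), function(pr)
    data.frame(ring = "A/B", patch_color = "y", wing_side = "d", system = "toy",
               individual_a = paste0("i", pr[1]), individual_b = paste0("i", pr[2]),
               pair_type = "conspecific", jnd = 0.7)))
  mu <- individual_mean_jnd(recsu)
  expect_true(all(mu$mean_conspecific == 0.7))
})

test_that("the repeated-measures F equals the squared paired t statistic", {
  set.seed(31)
  for (k in 1:100) {
    n <- sample(4:20, 1)
    tab <- rand_means_table(n, shift = runif(1, 0, 1))
    a <- comimic_vs_conspecific_anova(tab)
    tt <- t.test(sqrt(tab$mean_comimic), sqrt(tab$mean_conspecific), paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
    expect_equal(a$df_den, n - 1)
  }
})

test_that("the F test agrees with a random-intercept aov decomposition", {
  set.seed(13)
  tab <- rand_means_table(12, shift = 0.4)
  a <- comimic_vs_conspecific_anova(tab)
  long <- data.frame(y = sqrt(c(tab$mean_comimic, tab$mean_conspecific)),
                     type = rep(c("comimic", "conspecific"), each = 12),
                     ind = factor(rep(tab$individual, 2)))
  fit <- summary(aov(y ~ type + Error(ind/type), data = long))
  f_aov <- fit[["Error: ind:type"]][[1]]["type", "F value"]
  expect_equal(a$F, f_aov, tolerance = 1e-8)
})

test_that("degenerate and undersized mean tables are handled explicitly", {
  tab <- data.frame(individual = 1:5, stratum = "s",
                    mean_comimic = c(1, 2, 3, 4, 5),
                    mean_conspecific = c(1, 2, 3, 4, 5))
  a <- comimic_vs_conspecific_anova(tab)
  expect_equal(a$F, 0); expect_equal(a$p, 1)

  tab2 <- data.frame(individual = 1:5, stratum = "s",
                     mean_comimic = c(4, 9, 16, 25, 36),
                     mean_conspecific = c(1, 4, 9, 16, 25))
  expect_warning(a2 <- comimic_vs_conspecific_anova(tab2), "constant")
  expect_true(a2$degenerate)
  expect_true(is.na(a2$p))

  expect_error(comimic_vs_conspecific_anova(rand_means_table(2)), "insufficient")
  tab3 <- rand_means_table(5)
  tab3$mean_conspecific[1] <- NA
  expect_message(a3 <- comimic_vs_conspecific_anova(tab3), "excluded")
  expect_equal(a3$n, 4)
})

test_that("square-root transform is applied after averaging", {
  # means chosen so transform order matters: sqrt of the mean, not mean of sqrt
  tab <- data.frame(individual = 1:4, stratum = "s",
                    mean_comimic = c(4, 9, 16, 25),
                    mean_conspecific = c(1, 1, 1, 1))
  a <- comimic_vs_conspecific_anova(tab)
  d <- sqrt(tab$mean_comimic) - 1
  expect_equal(a$F, (mean(d) / (sd(d) / 2))^2, tolerance = 1e-10)
})

test_that("the permutation companion agrees with the F test direction", {
  set.seed(99)
  tab <- rand_means_table(10, shift = 1.5)
  p_perm <- comimic_permutation_test(tab, n_perm = 500, seed = 5)
  expect_lt(p_perm$p, 0.05)
  expect_gt(p_perm$observed, 0)
})

test_that("strata absent from one species are skipped with a message", {
  sys <- toy_system()
  species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  f <- matrix(rnorm(8, 0, 0.1), nrow = 2)
  m1 <- make_measurements(f, species, channels = channel_names(sys))
  m2 <- make_measurements(f[, 1:2, drop = FALSE], species[1:2],
                          channels = channel_names(sys), color = "red")
  m <- rbind(m1, m2)
  expect_message(recs <- pairwise_jnd_table(m, sys), "skipped")
  expect_true(all(recs$patch_color == "yellow"))
})
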