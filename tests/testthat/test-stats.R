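test_that("zero random variance reduces estimates to group means", {
  obs <- simulate_nested_trial(sd_site = 0, sd_plot = 0, sd_resid = 0.05,
                               n_trees = 30, seed = 2)
  fit <- suppressWarnings(fit_treatment_model(obs))
  gm <- tapply(obs$y, obs$treatment, mean)
  est <- fit$fixed$estimate[match(names(gm), fit$fixed$term)]
  expect_equal(unname(est), as.vector(gm), tolerance = 1e-6)
  expect_true(all(fit$varcomp$variance >= 0))
})

test_that("parameter recovery across replicates is unbiased", {
  truth <- c(none = 1.4, moderate = 1.5, intensive = 1.6)
  ests <- sapply(1:40, function(s) {
    fit <- suppressWarnings(
      fit_treatment_model(simulate_nested_trial(seed = 400 + s)))
    fit$fixed$estimate[match(names(truth), fit$fixed$term)]
  })
  expect_lt(max(abs(rowMeans(ests) - truth)), 0.015)
})

test_that("the treatment ANOVA detects the separation and respects nulls", {
  # the separation check is on the typical (median) p over replicates,
  # since any single draw can land a weak plot configuration
  ps <- sapply(1:11, function(s) {
    suppressWarnings(
      treatment_anova(fit_treatment_model(simulate_nested_trial(seed = s)))$p)
  })
  expect_lt(median(ps), 0.01)
  an <- treatment_anova(suppressWarnings(
    fit_treatment_model(simulate_nested_trial(seed = 1))))
  expect_equal(an$df1, 2)
  one <- simulate_nested_trial(means = c(none = 1.4), seed = 1)
  expect_error(treatment_anova(suppressWarnings(fit_treatment_model(one))),
               "single-treatment")
})

test_that("null p-values are roughly uniform", {
  ps <- sapply(1:60, function(s) {
    obs <- simulate_nested_trial(means = c(none = 1.5, moderate = 1.5,
                                           intensive = 1.5), seed = 700 + s)
    suppressWarnings(treatment_anova(fit_treatment_model(obs))$p)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Tukey contrasts separate only the distinct groups", {
  obs <- simulate_nested_trial(means = c(none = 1.40, moderate = 1.55,
                                         intensive = 1.55), seed = 31)
  fit <- suppressWarnings(fit_treatment_model(obs))
  tk <- tukey_contrasts(fit)
  expect_equal(nrow(tk), 3L)
  inv_mod <- tk$p_adj[tk$contrast == "intensive - moderate"]
  vs_none <- tk$p_adj[grepl("none", tk$contrast)]
  expect_gt(inv_mod, 0.05)
  expect_true(all(vs_none < 0.05))
})

test_that("with two levels the Tukey p equals the unadjusted pairwise p", {
  obs <- simulate_nested_trial(means = c(none = 1.4, moderate = 1.5),
                               seed = 5)
  fit <- suppressWarnings(fit_treatment_model(obs))
  tk <- tukey_contrasts(fit)
  emm <- emmeans::emmeans(fit$model, "treatment", lmer.df = fit$ddf)
  un <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
  expect_equal(tk$p_adj, un$p.value, tolerance = 1e-10)
})

test_that("attribute models recover a covariate slope within 2 SE", {
  set.seed(77)
  obs <- simulate_nested_trial(seed = 77)
  names(obs)[names(obs) == "y"] <- "box_dimension"
  b <- 12
  obs$crown_volume_m3 <- 5 + b * obs$box_dimension + rnorm(nrow(obs), 0, 2)
  fit <- suppressWarnings(attribute_model(obs, "crown_volume_m3"))
  row <- fit$fixed[fit$fixed$term == "box_dimension", ]
  expect_lt(abs(row$estimate - b), 2 * row$se)
  expect_equal(nrow(fit$fixed), 4L)       # 3 cell means + 1 covariate
  obs$flat <- 1
  expect_error(suppressWarnings(
    fit_treatment_model(obs, response = "crown_volume_m3",
                        covariate = "flat")), "constant")
})

test_that("REML components are shift invariant, fixed effects shift", {
  obs <- simulate_nested_trial(seed = 13)
  f1 <- suppressWarnings(fit_treatment_model(obs))
  obs$y <- obs$y + 10
  f2 <- suppressWarnings(fit_treatment_model(obs))
  expect_equal(f2$varcomp$variance, f1$varcomp$variance, tolerance = 1e-6)
  expect_equal(f2$fixed$estimate, f1$fixed$estimate + 10, tolerance = 1e-6)
})

test_that("per-treatment correlations behave at the extremes", {
  set.seed(19)
  n <- 250
  trees <- data.frame(
    treatment = rep(c("moderate", "none"), each = n),
    box_dimension = rnorm(2 * n, 1.5, 0.1))
  trees$linear <- 2 * trees$box_dimension          # exact linear
  z <- rnorm(2 * n)
  trees$correlated <- 0.6 * scale(trees$box_dimension)[, 1] +
    sqrt(1 - 0.36) * z
  trees$independent <- rnorm(2 * n)
  ct <- correlations_by_treatment(
    trees, c("linear", "correlated", "independent"))
  expect_equal(ct$r[ct$attribute == "linear"], c(1, 1), tolerance = 1e-9)
  expect_true(all(abs(ct$r[ct$attribute == "correlated"] - 0.6) < 0.1))
  expect_true(all(abs(ct$r[ct$attribute == "independent"]) < 0.15))
  expect_true(all(ct$sig[ct$attribute == "linear"]))
  expect_true(all(ct$strong[ct$attribute == "linear"]))
})

test_that("zero-variance attributes give missing correlation cells", {
  trees <- data.frame(treatment = rep("none", 10),
                      box_dimension = rnorm(10), flat = 1)
  ct <- correlations_by_treatment(trees, "flat")
  expect_true(is.na(ct$r))
})

test_that("Naslund height imputation is exact on noise-free data", {
  set.seed(4)
  d <- runif(20, 8, 32)
  a <- 1.4; b <- 0.17
  s <- data.frame(plot = "P1", dbh_cm = d, height_m = 1.3 + d^2 / (a + b * d)^2)
  tally <- data.frame(plot = "P1", dbh_cm = c(10, 18, 30))
  out <- estimate_tally_heights(s, tally)
  expect_equal(out$height_m, 1.3 + tally$dbh_cm^2 /
                 (a + b * tally$dbh_cm)^2, tolerance = 1e-6)
  # predictions are monotone in DBH
  grid <- estimate_tally_heights(s, data.frame(plot = "P1",
                                               dbh_cm = seq(5, 40, 1)))
  expect_true(all(diff(grid$height_m) > 0))
})

test_that("noisy Naslund fits keep prediction RMSE below 0.6 m", {
  rmse <- sapply(1:10, function(s) {
    set.seed(900 + s)
    d <- runif(20, 8, 32)
    h_true <- 1.3 + d^2 / (1.4 + 0.17 * d)^2
    smp <- data.frame(plot = "P1", dbh_cm = d,
                      height_m = pmax(h_true + rnorm(20, 0, 0.5), 2))
    dt <- runif(30, 8, 32)
    pred <- estimate_tally_heights(smp, data.frame(plot = "P1",
                                                   dbh_cm = dt))$height_m
    sqrt(mean((pred - (1.3 + dt^2 / (1.4 + 0.17 * dt)^2))^2))
  })
  expect_lt(mean(rmse), 0.6)
})

test_that("plots with too few sample trees fall back to the pooled fit", {
  s <- data.frame(plot = rep(c("P1", "P2"), c(10, 2)),
                  dbh_cm = runif(12, 10, 30))
  s$height_m <- 1.3 + s$dbh_cm^2 / (1.4 + 0.17 * s$dbh_cm)^2
  tally <- data.frame(plot = "P2", dbh_cm = 20)
  expect_warning(out <- estimate_tally_heights(s, tally), "pooled")
  expect_gt(out$height_m, 1.3)
})
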