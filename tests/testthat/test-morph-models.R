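# helper: recruit table at a chosen generating interaction, via the simulator
sim_recruit_table <- function(seed, ...) {
  b <- simulate_population(small_params(seed = seed, ...))
  ingest_bundle(b$registry, b$recruits, b$winters, b$prey)$recruits
}

test_that("identical yearly proportions give a near-zero GLM slope", {
  yearly <- tibble::tibble(n_brown = rep(3, 10), n_total = rep(10, 10),
                           anomaly_c = seq(-3, 3, length.out = 10))
  fit <- fit_brown_proportion_glm(yearly)
  expect_equal(fit$slope_estimate, 0, tolerance = 1e-8)
  expect_equal(fit$n_years, 10)
})

test_that("the GLM recovers a known logit slope within 2 SE and rejects degenerate data", {
  true_slope <- 0.6
  withr::with_seed(10, {
    anomaly <- rnorm(35, 0, 2)
    n_tot <- rpois(35, 6) + 1
    p <- plogis(-0.8 + true_slope * anomaly)
    yearly <- tibble::tibble(n_brown = rbinom(35, n_tot, p),
                             n_total = n_tot, anomaly_c = anomaly)
  })
  fit <- fit_brown_proportion_glm(yearly)
  expect_lt(abs(fit$slope_estimate - true_slope), 2 * fit$slope_se)
  expect_error(
    fit_brown_proportion_glm(
      tibble::tibble(n_brown = c(0, 0), n_total = c(4, 5), anomaly_c = c(-1, 1))),
    "one morph")
  expect_error(
    fit_brown_proportion_glm(
      tibble::tibble(n_brown = 1, n_total = 2, anomaly_c = 0)),
    "at least 2 years")
})

test_that("GLM type-I error is near nominal under a zero slope", {
  n_rep <- 200
  rejections <- withr::with_seed(77, {
    vapply(seq_len(n_rep), function(i) {
      anomaly <- rnorm(35, 0, 2)
      n_tot <- rpois(35, 6) + 1
      yearly <- tibble::tibble(n_brown = rbinom(35, n_tot, 0.3),
                               n_total = n_tot, anomaly_c = anomaly)
      fit <- suppressWarnings(fit_brown_proportion_glm(yearly))
      fit$p_value < 0.05
    }, logical(1))
  })
  # binomial 3 sigma around 5% at 200 replicates
  expect_lt(abs(mean(rejections) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("LMM coefficients equal OLS when random-effect variances collapse to zero", {
  # a replicate whose REML fit lands on the zero boundary for all three factors
  rec <- sim_recruit_table(seed = 36, sigma_box = 2.5)
  fit <- fit_dispersal_lmm(rec, set = "one_year_olds")
  expect_true(all(fit$varcomp$variance[fit$varcomp$group != "Residual"] < 1e-8))
  d <- fit$fit@frame
  ols <- lm(dispersal_km ~ morph * anomaly_c + prey_index + sex + mass_z, data = d)
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("the LMM reports crossed variance components and analysis-set bookkeeping", {
  rec <- sim_recruit_table(seed = 32, sigma_box = 3)
  fit_all <- fit_dispersal_lmm(rec, set = "all_ages")
  fit_yr1 <- fit_dispersal_lmm(rec, set = "one_year_olds")
  expect_setequal(fit_all$varcomp$group,
                  c("hatch_year", "brood_id", "natal_box_id", "Residual"))
  expect_true(all(fit_all$varcomp$variance >= 0))
  expect_lt(fit_yr1$n_used, fit_all$n_used)
  expect_equal(fit_yr1$n_used, sum(rec$age_at_recruitment == "1" & rec$complete))
  # age is tested as one 2-df term in the all-ages model and absent otherwise
  age_row <- dplyr::filter(fit_all$anova, .data$term == "age_at_recruitment")
  expect_equal(age_row$num_df, 2)
  expect_false("age_at_recruitment" %in% fit_yr1$anova$term)
  # listwise deletion is reported
  rec2 <- rec
  rec2$body_mass_g[1:4] <- NA
  fit2 <- fit_dispersal_lmm(rec2, set = "all_ages")
  expect_equal(fit2$n_used, fit_all$n_used - 4)
})

test_that("flipping the morph reference flips the interaction sign exactly", {
  rec <- sim_recruit_table(seed = 33)
  fit <- fit_dispersal_lmm(rec, set = "all_ages")
  rec_flip <- rec
  rec_flip$morph <- ifelse(rec_flip$morph == "gray", "brown", "gray")
  fit_flip <- fit_dispersal_lmm(rec_flip, set = "all_ages")
  ia <- function(f) f$coefficients$estimate[grepl(":", f$coefficients$term)]
  expect_equal(ia(fit), -ia(fit_flip), tolerance = 1e-6)
})

test_that("fixed effects are invariant to the labeling order of random factors", {
  rec <- sim_recruit_table(seed = 34, sigma_box = 2, sigma_year = 1)
  fit1 <- fit_dispersal_lmm(rec, set = "all_ages")
  rec_shuffled <- withr::with_seed(1, rec[sample(nrow(rec)), ])
  rec_shuffled$brood_id <- paste0("zz_", rec_shuffled$brood_id)
  fit2 <- fit_dispersal_lmm(rec_shuffled, set = "all_ages")
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("Satterthwaite df collapses to n - p when random variances are zero", {
  withr::with_seed(3, {
    n <- 40
    d <- data.frame(x = rnorm(n), g = factor(rep(1:8, each = 5)))
    d$y <- 1 + 2 * d$x + rnorm(n)
  })
  fit <- suppressMessages(lmerTest::lmer(y ~ x + (1 | g), data = d))
  # evaluated at a zero group variance the model is OLS: df = n - p exactly
  s2 <- sigma(fit)^2
  expect_equal(contrast_df(fit, c(0, 1), varcomp = c(0, s2)), n - 2)
  expect_equal(contrast_df(fit, c(1, 0), varcomp = c(0, s2)), n - 2)
})

test_that("the variance-component df matches the Welch-Satterthwaite closed form", {
  withr::with_seed(14, {
    n1 <- 30; n2 <- 25
    y1 <- rnorm(n1, 0, 1); y2 <- rnorm(n2, 1, 3)
  })
  s1 <- var(y1); s2 <- var(y2)
  # mean-difference variance as a function of the two group variances
  var_value <- s1 / n1 + s2 / n2
  grad <- c(1 / n1, 1 / n2)
  vcov_vc <- diag(c(2 * s1^2 / (n1 - 1), 2 * s2^2 / (n2 - 1)))
  df <- satterthwaite_df(var_value, grad, vcov_vc)
  welch <- unname(t.test(y2, y1)$parameter)  # independent closed-form oracle
  expect_equal(df, welch, tolerance = 1e-8)
})

test_that("df moves from (groups - 1) toward n - p as the true variance shrinks", {
  # balanced one-way: interior fits give the between-group df for the
  # intercept; as the generating variance shrinks, REML increasingly lands on
  # the zero boundary, where the df collapses to the residual n - p
  withr::with_seed(15, {
    d <- data.frame(g = factor(rep(1:10, each = 4)))
    d$y <- rnorm(40) + rep(rnorm(10, 0, 2), each = 4)
  })
  fit <- suppressMessages(lmerTest::lmer(y ~ 1 + (1 | g), data = d))
  # large between-group variance pins the intercept df at (groups - 1)
  expect_equal(contrast_df(fit, 1, varcomp = c(100, 1)), 9, tolerance = 0.2)
  expect_equal(contrast_df(fit, 1, varcomp = c(4, 1)), 9, tolerance = 0.2)
  # zero variance gives the residual df
  expect_equal(contrast_df(fit, 1, varcomp = c(0, 1)), 39)

  mean_df_at <- function(tau, seeds) {
    mean(vapply(seeds, function(s) {
      withr::with_seed(s, {
        dd <- data.frame(g = factor(rep(1:10, each = 4)))
        dd$y <- rnorm(40) + rep(rnorm(10, 0, tau), each = 4)
      })
      f <- suppressMessages(lmerTest::lmer(y ~ 1 + (1 | g), data = dd))
      suppressWarnings(contrast_df(f, 1))
    }, numeric(1)))
  }
  seeds <- 1:25
  dfs <- vapply(c(2, 0.3, 0), mean_df_at, numeric(1), seeds = seeds)
  expect_true(all(diff(dfs) > 0))
  expect_lt(dfs[1], 12)
  expect_gt(dfs[3], 20)
})

test_that("in-package Satterthwaite df agrees with lmerTest on a crossed fit", {
  withr::with_seed(20, {
    n <- 240
    d <- data.frame(f1 = factor(sample(1:12, n, TRUE)),
                    f2 = factor(sample(1:20, n, TRUE)),
                    x = rnorm(n))
    d$y <- 2 + 0.5 * d$x + rnorm(12, 0, 1.5)[d$f1] + rnorm(20, 0, 1)[d$f2] + rnorm(n)
  })
  fit <- lmerTest::lmer(y ~ x + (1 | f1) + (1 | f2), data = d)
  cf <- coef(summary(fit))
  # expected-information route vs lmerTest's observed-Hessian route
  expect_equal(contrast_df(fit, c(1, 0)), unname(cf["(Intercept)", "df"]),
               tolerance = 0.02)
  expect_equal(contrast_df(fit, c(0, 1)), unname(cf["x", "df"]),
               tolerance = 0.02)
})

test_that("marginal effects reflect the fitted interaction geometry", {
  rec <- sim_recruit_table(seed = 37)
  fit <- fit_dispersal_lmm(rec, set = "all_ages")
  grid <- seq(-2, 2, length.out = 9)
  me <- marginal_effects(fit, anomaly_grid = grid)
  slopes <- me |>
    dplyr::group_by(.data$morph) |>
    dplyr::summarise(slope = coef(lm(estimate ~ anomaly_c))[2], .groups = "drop")
  ia <- fit$coefficients$estimate[grepl(":", fit$coefficients$term)]
  got <- slopes$slope[slopes$morph == "brown"] - slopes$slope[slopes$morph == "gray"]
  expect_equal(unname(got), unname(ia), tolerance = 1e-6)
  # CI is narrowest near the anomaly mean, wider at the extremes
  gray <- dplyr::filter(me, .data$morph == "gray")
  width <- gray$conf.high - gray$conf.low
  center <- which.min(abs(gray$anomaly_c - mean(fit$fit@frame$anomaly_c)))
  expect_lt(width[center], width[1])
  expect_lt(width[center], width[length(width)])
  expect_s3_class(autoplot(me), "ggplot")
})

test_that("a zero generating interaction yields parallel marginal-effect lines", {
  rec <- sim_recruit_table(seed = 38, beta_interaction_km_per_c = 0,
                           beta_morph_km = 0)
  fit <- fit_dispersal_lmm(rec, set = "all_ages")
  ia <- fit$coefficients
  ia_row <- ia[grepl(":", ia$term), ]
  # estimated interaction is statistically indistinguishable from zero
  expect_lt(abs(ia_row$estimate) / ia_row$std.error, 3)
})
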