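sim_long <- function(n_pat, effect_wd = 0, effect_day = 0, sd_int = 1,
                     sd_noise = 0.5, sd_slope = 0, n_weeks = 5, seed = 1) {
  set.seed(seed)
  p0 <- sim_patient("template")
  sched <- simulate_week_cycle(p0, n_weeks)
  do.call(rbind, lapply(seq_len(n_pat), function(i) {
    b0 <- rnorm(1, 10, sd_int)
    b1 <- effect_day + if (sd_slope > 0) rnorm(1, 0, sd_slope) else 0
    data.frame(patient_id = sprintf("P%02d", i),
               study_day = sched$study_day,
               weekday_treatment = sched$weekday_treatment,
               variable = "dv",
               value = b0 + b1 * sched$study_day +
                 effect_wd * sched$weekday_treatment +
                 rnorm(nrow(sched), 0, sd_noise))
  }))
}

test_that("the mixed model recovers a noise-free weekday effect exactly", {
  tab <- sim_long(10, effect_wd = -0.38, sd_noise = 0)
  fit <- fit_lmm_aic(tab, "dv")
  expect_equal(unname(fit$beta_weekday["est"]), -0.38, tolerance = 1e-6)
  expect_lt(fit$p_weekday, 1e-10)
  expect_true(fit$beta_weekday["lo"] <= fit$beta_weekday["est"] &&
                fit$beta_weekday["est"] <= fit$beta_weekday["hi"])
})

test_that("AIC selects random slopes when patients have heterogeneous trends", {
  tab <- sim_long(20, sd_slope = 0.3, sd_noise = 0.5, seed = 5)
  fit <- fit_lmm_aic(tab, "dv")
  expect_equal(fit$chosen, "random_slopes")
  expect_gt(fit$sd_slope, 0.1)
  # homogeneous cohort: intercept-only wins
  tab0 <- sim_long(20, sd_slope = 0, sd_noise = 0.5, seed = 6)
  fit0 <- fit_lmm_aic(tab0, "dv")
  expect_equal(fit0$chosen, "intercept_only")
  expect_true(is.na(fit0$sd_slope))
})

test_that("confounders enter the fixed-effects structure", {
  tab <- sim_long(12, effect_wd = -0.3, sd_noise = 0.3, seed = 7)
  cov <- data.frame(patient_id = sprintf("P%02d", 1:12),
                    age = round(runif(12, 30, 85)), sex = rbinom(12, 1, 0.5))
  fit <- fit_lmm_aic(tab, "dv", covariates = cov)
  expect_equal(unname(fit$beta_weekday["est"]), -0.3, tolerance = 0.2)
})

test_that("rmcorr equals the centered-Pearson oracle and handles toy cases", {
  # two subjects, y = x + offset: perfect common slope
  sub <- rep(1:2, each = 4)
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  y <- x + rep(c(0, -10), each = 4)
  r <- rmcorr_pairs(sub, x, y)
  expect_equal(r$rho_rm, 1.0, tolerance = 1e-12)
  expect_equal(r$error_df, 8 - 2 - 1)
  # 3-subject toy data: match brute force to 1e-12
  sub3 <- rep(1:3, each = 5)
  set.seed(13)
  x3 <- rnorm(15); y3 <- 0.5 * x3 + rnorm(15, 0, 0.7) + rep(c(0, 3, -2), each = 5)
  r3 <- rmcorr_pairs(sub3, x3, y3)
  expect_equal(r3$rho_rm, brute_rmcorr(sub3, x3, y3), tolerance = 1e-12)
  expect_equal(r3$n_pairs, 15)
  # all-constant x: no within-subject information
  expect_error(rmcorr_pairs(sub, rep(c(1, 2), each = 4), y), "variance")
})

test_that("rmcorr extracts variable pairs from the long table", {
  tab <- rbind(
    data.frame(patient_id = rep(c("A", "B"), each = 3),
               study_day = rep(1:3, 2), weekday_treatment = 1,
               variable = "x", value = c(1, 2, 3, 2, 3, 4)),
    data.frame(patient_id = rep(c("A", "B"), each = 3),
               study_day = rep(1:3, 2), weekday_treatment = 1,
               variable = "y", value = c(2, 4, 6, -1, 1, 3)))
  expect_equal(rmcorr(tab, "x", "y")$rho_rm, 1.0, tolerance = 1e-12)
})

test_that("per-patient CVs match hand arithmetic", {
  tab <- data.frame(patient_id = c(rep("A", 3), rep("B", 2), "C"),
                    study_day = c(1:3, 1:2, 1), weekday_treatment = 1,
                    variable = "v", value = c(4, 5, 6, 7, 7, 9))
  cv <- per_patient_cv(tab, "v")
  expect_equal(unname(cv$cv["A"]), 20.0)  # sd 1, mean 5
  expect_equal(unname(cv$cv["B"]), 0.0)
  expect_false("C" %in% names(cv$cv))     # single observation dropped
  # zero-mean patients are excluded with a flag
  tab0 <- data.frame(patient_id = rep("Z", 2), study_day = 1:2,
                     weekday_treatment = 1, variable = "v", value = c(-1, 1))
  expect_equal(per_patient_cv(tab0, "v")$excluded, "Z")
})

test_that("euvolemic-mass CV stays below 1% at realistic noise", {
  set.seed(17)
  tab <- do.call(rbind, lapply(1:25, function(i) {
    data.frame(patient_id = sprintf("P%02d", i), study_day = 1:14,
               weekday_treatment = 1, variable = "M_eu",
               value = rnorm(14, 78, 0.5))
  }))
  expect_lt(per_patient_cv(tab, "M_eu")$mean_cv, 1.0)
})

test_that("bootstrap CI of the mean is calibrated and degenerate-safe", {
  expect_equal(unname(bootstrap_ci_mean(rep(3.2, 10), seed = 1)),
               c(3.2, 3.2, 3.2))
  expect_warning(one <- bootstrap_ci_mean(5, seed = 1), "single")
  expect_equal(unname(one), c(5, 5, 5))
  set.seed(2); x <- rnorm(100)
  ci <- bootstrap_ci_mean(x, n_boot = 2000, seed = 3)
  width <- ci[["hi"]] - ci[["lo"]]
  expect_lt(abs(width - 2 * 1.96 / sqrt(100)) / (2 * 1.96 / sqrt(100)), 0.2)
  # deterministic under a fixed seed
  expect_identical(bootstrap_ci_mean(x, seed = 9), bootstrap_ci_mean(x, seed = 9))
})

test_that("BH adjustment matches the longhand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("fluid-overload stratification applies the closed lower tie rule", {
  tab <- data.frame(patient_id = rep(c("A", "B", "C"), each = 2),
                    study_day = rep(1:2, 3), weekday_treatment = 1,
                    variable = "F_fo_ecf",
                    value = c(11, 13, 17, 19, 15, 15))
  s <- stratify_by_mean_relative_fo(tab, 15)
  expect_equal(as.character(s$group), c("<=15%", ">15%", "<=15%"))
  # default synthetic cohort populates both strata
  sim <- generate_cohort(dv_config(cohort = list(n_patients = 10, n_weeks = 2)),
                         seed = 3)
  tab2 <- build_cohort_table(sim$records)
  s2 <- stratify_by_mean_relative_fo(tab2, 15)
  expect_equal(nlevels(s2$group), 2)
  expect_true(all(table(s2$group) > 0))
})

test_that("simulated power is near the level under the null and 1 for large effects", {
  de <- list(n_patients = 10, n_weeks = 2, sd_intercept = 1, sd_noise = 0.6)
  p0 <- power_by_simulation(0, design = de, n_sims = 120, seed = 2)
  expect_lt(p0$power, 0.13)
  p1 <- power_by_simulation(-2, design = de, n_sims = 100, seed = 3)
  expect_gt(p1$power, 0.95)
})
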