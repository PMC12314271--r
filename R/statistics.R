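#' Linear mixed model with AIC-selected random slopes
#'
#' Fits one dependent variable from the long cohort table against study day
#' and treatment within the week (both fixed effects in the same model, the
#' weekday index coded numerically 1-3 so that a single slope captures the
#' within-week trend), with optional age/sex confounders, and patient random
#' intercepts. Two random structures are fitted by maximum likelihood — with
#' and without random study-day slopes — and the one with the lower AIC is
#' selected and refitted by REML for reporting. Missing rows are dropped
#' listwise. Wald 95% confidence intervals and p-values for the fixed effects
#' use a t reference distribution with `n_patients - 1` degrees of freedom —
#' the conservative cluster-count rule, which in simulation keeps the
#' interval coverage at its nominal level where the plain normal
#' approximation slightly undercovers at cohort sizes around 25.
#'
#' @param table long cohort table ([build_cohort_table()]).
#' @param dv dependent-variable name (a level of `table$variable`).
#' @param covariates optional data frame `patient_id`, `age`, `sex`
#'   (sex coded 0/1) used as confounders.
#' @return list of class `lmm_result`: `dv`, `beta_day`, `beta_weekday`
#'   (each `c(est, lo, hi)`), `p_day`, `p_weekday`, `sd_slope` (SD of random
#'   study-day slopes, `NA` when the intercept-only model was chosen),
#'   `aic_with_slopes`, `aic_without`, `chosen`, `converged`, `n_obs`,
#'   `n_patients`.
#' @export
fit_lmm_aic <- function(table, dv, covariates = NULL) {
  d <- table[table$variable == dv, c("patient_id", "study_day",
                                     "weekday_treatment", "value")]
  if (!is.null(covariates)) {
    d <- merge(d, covariates, by = "patient_id")
  }
  d <- d[complete.cases(d), ]
  n_per <- table(d$patient_id)
  if (sum(n_per >= 2) < 2) {
    stop("need at least 2 patients with 2+ observations for dv ", dv)
  }
  covs <- if (!is.null(covariates)) " + age + sex" else ""
  f_with <- as.formula(paste0(
    "value ~ study_day + weekday_treatment", covs,
    " + (1 + study_day | patient_id)"))
  f_without <- as.formula(paste0(
    "value ~ study_day + weekday_treatment", covs, " + (1 | patient_id)"))
  quiet_fit <- function(f, reml) {
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = d, REML = reml,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      )),
      error = function(e) NULL)
  }
  m_with <- quiet_fit(f_with, FALSE)
  m_without <- quiet_fit(f_without, FALSE)
  converged <- !is.null(m_with) && !is.null(m_without)
  aic_with <- if (!is.null(m_with)) AIC(m_with) else NA_real_
  aic_without <- if (!is.null(m_without)) AIC(m_without) else NA_real_
  chosen <- if (is.na(aic_with) ||
                (!is.na(aic_without) && aic_without <= aic_with)) {
    "intercept_only"
  } else {
    "random_slopes"
  }
  f_final <- if (chosen == "random_slopes") f_with else f_without
  m <- quiet_fit(f_final, TRUE)
  if (is.null(m)) {
    # last resort: intercept-only by REML
    chosen <- "intercept_only"; converged <- FALSE
    m <- quiet_fit(f_without, TRUE)
    if (is.null(m)) stop("mixed model failed to fit for dv ", dv)
  }
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  df_t <- length(unique(d$patient_id)) - 1
  ci <- function(term) {
    est <- fe[[term]]; s <- se[[term]]
    q <- stats::qt(0.975, df_t)
    c(est = est, lo = est - q * s, hi = est + q * s)
  }
  pval <- function(term) {
    tt <- fe[[term]] / se[[term]]
    2 * stats::pt(-abs(tt), df_t)
  }
  sd_slope <- NA_real_
  if (chosen == "random_slopes") {
    vc <- lme4::VarCorr(m)$patient_id
    sd_slope <- unname(attr(vc, "stddev")["study_day"])
  }
  structure(list(dv = dv, beta_day = ci("study_day"),
                 beta_weekday = ci("weekday_treatment"),
                 p_day = pval("study_day"),
                 p_weekday = pval("weekday_treatment"),
                 sd_slope = sd_slope,
                 aic_with_slopes = aic_with, aic_without = aic_without,
                 chosen = chosen, converged = converged,
                 n_obs = nrow(d), n_patients = length(unique(d$patient_id))),
            class = "lmm_result")
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation between two variables observed
#' repeatedly in the same subjects, via the analysis-of-covariance
#' decomposition: a linear model of `y` on the subject factor plus `x` yields
#' the measure and error sums of squares, and
#' `rho_rm = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))` with
#' `error_df = n_pairs - n_subjects - 1`. The p-value comes from the
#' corresponding F statistic and the confidence interval from the Fisher
#' z-transform with that error df.
#'
#' `rmcorr_pairs()` is the vector interface; `rmcorr()` extracts a variable
#' pair from the long cohort table (complete pairs only).
#'
#' @param subject subject identifiers.
#' @param x,y paired observations (`rmcorr_pairs`) or variable names
#'   (`rmcorr`).
#' @param conf confidence level.
#' @return list of class `rmcorr_result`: `rho_rm`, `ci`, `p`, `error_df`,
#'   `n_pairs`, `n_subjects`.
#' @export
rmcorr_pairs <- function(subject, x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y) & !is.na(subject)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  tab <- table(subject)
  keep <- subject %in% names(tab)[tab >= 2]
  subject <- droplevels(subject[keep]); x <- x[keep]; y <- y[keep]
  if (nlevels(subject) < 2) stop("need >= 2 subjects with >= 2 complete pairs")
  varx <- tapply(x, subject, function(v) var(v))
  if (all(varx == 0 | is.na(varx))) {
    stop("no within-subject variance in x for any subject")
  }
  m <- lm(y ~ subject + x)
  # anova.lm warns on numerically perfect fits; those are legitimate here
  a <- suppressWarnings(anova(m))
  ss_measure <- a["x", "Sum Sq"]
  ss_error <- a["Residuals", "Sum Sq"]
  slope <- coef(m)[["x"]]
  rho <- sign(slope) * sqrt(ss_measure / (ss_measure + ss_error))
  df_err <- length(x) - nlevels(subject) - 1
  Fstat <- (ss_measure / 1) / (ss_error / df_err)
  p <- pf(Fstat, 1, df_err, lower.tail = FALSE)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  zse <- 1 / sqrt(df_err - 1)
  q <- qnorm(1 - (1 - conf) / 2)
  structure(list(rho_rm = rho, ci = c(lo = tanh(z - q * zse),
                                      hi = tanh(z + q * zse)),
                 p = p, error_df = df_err, n_pairs = length(x),
                 n_subjects = nlevels(subject)),
            class = "rmcorr_result")
}

#' @rdname rmcorr_pairs
#' @param table long cohort table.
#' @export
rmcorr <- function(table, x, y, conf = 0.95) {
  dx <- table[table$variable == x, c("patient_id", "study_day", "value")]
  dy <- table[table$variable == y, c("patient_id", "study_day", "value")]
  names(dx)[3] <- "x"; names(dy)[3] <- "y"
  d <- merge(dx, dy, by = c("patient_id", "study_day"))
  rmcorr_pairs(d$patient_id, d$x, d$y, conf = conf)
}

#' Per-patient coefficients of variation
#'
#' Computes `CV_i = 100 * SD_i / |mean_i|` (sample SD) of one variable per
#' patient over the whole study and averages the CVs across the cohort.
#' Patients with fewer than two observations are dropped; patients with zero
#' mean are excluded with a flag.
#'
#' @param table long cohort table.
#' @param variable variable name.
#' @return list of class `cv_summary`: `variable`, `cv` (named per-patient
#'   CVs in %), `mean_cv`, `sd_cv`, `excluded` (patient ids with zero mean).
#' @export
per_patient_cv <- function(table, variable) {
  d <- table[table$variable == variable & !is.na(table$value), ]
  groups <- split(d$value, d$patient_id)
  groups <- groups[vapply(groups, length, 0L) >= 2]
  excluded <- names(groups)[vapply(groups, mean, 0) == 0]
  groups <- groups[!names(groups) %in% excluded]
  cv <- vapply(groups, function(v) 100 * sd(v) / abs(mean(v)), 0)
  structure(list(variable = variable, cv = cv,
                 mean_cv = if (length(cv)) mean(cv) else NA_real_,
                 sd_cv = if (length(cv) > 1) sd(cv) else NA_real_,
                 excluded = excluded),
            class = "cv_summary")
}

#' Bootstrap percentile confidence interval of the mean
#'
#' @param values numeric vector (NAs dropped).
#' @param n_boot number of resamples.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param conf confidence level.
#' @return `c(mean, lo, hi)`.
#' @export
bootstrap_ci_mean <- function(values, n_boot = 1000, seed = 1, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
  if (length(values) == 1) {
    warning("bootstrap CI of a single observation is degenerate")
    return(c(mean = values, lo = values, hi = values))
  }
  set.seed(seed)
  means <- vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(length(values), replace = TRUE)]), 0)
  qs <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(mean = mean(values), lo = qs[1], hi = qs[2])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' The family is all p-values emitted in one pipeline run (mixed-model fixed
#' effects plus the correlation matrix).
#'
#' @param p p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Stratify patients by mean relative fluid overload
#'
#' Labels each patient by whether their study-average pre-dialysis fluid
#' overload relative to extracellular fluid exceeds the threshold; a mean of
#' exactly the threshold falls in the lower group.
#'
#' @param table long cohort table containing variable `"F_fo_ecf"`.
#' @param threshold percent of extracellular fluid (default 15).
#' @return data frame `patient_id`, `mean_F_fo_ecf`, `group` (factor with
#'   levels `"<=15%"`, `">15%"` for the default threshold).
#' @export
stratify_by_mean_relative_fo <- function(table, threshold = 15) {
  d <- table[table$variable == "F_fo_ecf" & !is.na(table$value), ]
  if (nrow(d) == 0) stop("no F_fo_ecf observations in table")
  m <- tapply(d$value, d$patient_id, mean)
  labs <- c(paste0("<=", threshold, "%"), paste0(">", threshold, "%"))
  data.frame(patient_id = names(m), mean_F_fo_ecf = as.numeric(m),
             group = factor(ifelse(m > threshold, labs[2], labs[1]),
                            levels = labs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulation-based power for the within-week trend
#'
#' Estimates the power to detect a linear per-treatment within-week change of
#' `effect` in a cohort of the given shape: each simulation draws patient
#' intercepts and residual noise on the thrice-weekly schedule, fits the
#' mixed model and tests the weekday slope at `alpha` (single-test,
#' unadjusted).
#'
#' @param effect change per within-week treatment step (units of the dv).
#' @param design list: `n_patients`, `n_weeks`, `sd_intercept`, `sd_noise`,
#'   optional `sd_slope_day` (random study-day slope SD, default 0).
#' @param n_sims number of simulations (>= 100 recommended; fewer warns).
#' @param seed RNG seed.
#' @param alpha test level.
#' @return list: `power`, `n_sims`, `rejections`.
#' @export
power_by_simulation <- function(effect, design = list(), n_sims = 200,
                                seed = 1, alpha = 0.05) {
  if (n_sims < 100) warning("n_sims below 100 gives a noisy power estimate")
  de <- merge_cfg(list(n_patients = 25, n_weeks = 5, sd_intercept = 1.0,
                       sd_noise = 0.7, sd_slope_day = 0), design)
  p0 <- sim_patient("template")
  sched <- simulate_week_cycle(p0, de$n_weeks)[, c("study_day",
                                                   "weekday_treatment")]
  rej <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(derive_seed(seed, s))
    rows <- do.call(rbind, lapply(seq_len(de$n_patients), function(i) {
      b0 <- rnorm(1, 0, de$sd_intercept)
      b1 <- if (de$sd_slope_day > 0) rnorm(1, 0, de$sd_slope_day) else 0
      data.frame(patient_id = sprintf("P%02d", i),
                 study_day = sched$study_day,
                 weekday_treatment = sched$weekday_treatment,
                 variable = "dv",
                 value = b0 + b1 * sched$study_day +
                   effect * sched$weekday_treatment +
                   rnorm(nrow(sched), 0, de$sd_noise))
    }))
    fit <- fit_lmm_aic(rows, "dv")
    rej[s] <- is.finite(fit$p_weekday) && fit$p_weekday < alpha
  }
  list(power = mean(rej), n_sims = n_sims, rejections = sum(rej))
}
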