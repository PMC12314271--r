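#' Simulate a cohort bundle to disk
#'
#' Orchestration wrapper around [generate_cohort()]: writes the CSV bundle
#' and a run manifest (config snapshot, seed, per-stage counts, package
#' version). Reruns with the same config and seed produce identical trees.
#'
#' @param config a [dv_config()].
#' @param out_dir output directory.
#' @param seed master seed.
#' @return (invisibly) the [generate_cohort()] result.
#' @export
cohort_simulate <- function(config = dv_config(), out_dir, seed = 1) {
  sim <- generate_cohort(config, seed = seed, out_dir = out_dir)
  manifest <- list(
    stage = "simulate", seed = seed,
    config = unclass(config),
    n_patients = length(sim$patients),
    n_treatments = length(sim$records$treatments),
    package_version = as.character(utils::packageVersion("dialvol"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

q13 <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, 0))
  c(median(x), quantile(x, 0.25, names = FALSE),
    quantile(x, 0.75, names = FALSE), length(x))
}

#' Analyze a treatment bundle
#'
#' Full pipeline on a bundle directory: validate and load, preprocess every
#' treatment, estimate blood volume from the bolus, build and clean the
#' volume series, summarize per treatment, assemble the long cohort table and
#' fit the longitudinal statistics (mixed models per variable,
#' repeated-measures correlation matrix, per-patient CVs, stratification by
#' mean relative fluid overload). Benjamini-Hochberg adjustment is applied
#' across all p-values of the run (mixed-model fixed effects plus the
#' correlation matrix).
#'
#' Writes to `out_dir`: `summary_table.csv` (median and quartiles per
#' variable, overall and by treatment within the week), `lmm_table.csv`,
#' `rmcorr_matrix.csv`, `cv_table.csv`, `strata.csv`, `exclusions.csv`,
#' `cohort_summaries.csv` (one row per treatment) and `manifest.json`.
#'
#' @param bundle_dir bundle directory ([read_treatment_bundle()] dialect).
#' @param config a [dv_config()].
#' @param out_dir report directory (created if needed); `NULL` to skip
#'   writing.
#' @param lmm_covariates optional `patient_id`/`age`/`sex` data frame; when
#'   the bundle was produced by [cohort_simulate()] these are not on disk and
#'   the models are fitted without confounders.
#' @param rmcorr_vars variables for the correlation matrix (default: the
#'   fluid-status and blood-volume variables).
#' @return (invisibly) list with `table` (long cohort table), `summaries`,
#'   `estimates`, `lmm`, `rmcorr`, `cv`, `strata`, `exclusions`.
#' @export
cohort_analyze <- function(bundle_dir, config = dv_config(), out_dir = NULL,
                           lmm_covariates = NULL,
                           rmcorr_vars = c("V_fo", "F_fo_ecf", "V_ecf",
                                           "V_icf", "V_b_start", "V_b_end",
                                           "V_b_bm_start", "V_r_total",
                                           "V_u_total")) {
  records <- read_treatment_bundle(bundle_dir)
  if (length(records$treatments) == 0) stop("empty bundle: ", bundle_dir)
  res <- lapply(seq_along(records$treatments), function(i) {
    tx <- records$treatments[[i]]
    bio <- NULL
    for (b in records$bioimpedance) {
      if (b$patient_id == tx$patient_id && b$study_day == tx$study_day) bio <- b
    }
    analyze_treatment(tx, bio, config)
  })
  summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
  estimates <- lapply(res, `[[`, "estimate")
  exclusions <- data.frame(
    treatment_id = vapply(estimates, `[[`, "", "treatment_id"),
    quality = vapply(estimates, `[[`, "", "quality"),
    reason = vapply(estimates, function(e)
      if (is.na(e$exclusion_reason)) "" else e$exclusion_reason, ""),
    stringsAsFactors = FALSE)
  summaries$idh <- as.numeric(summaries$idh)
  tab <- build_cohort_table(records, summaries = summaries)

  dvs <- intersect(unique(tab$variable),
                   c("M_pre", "M_eu", "V_fo", "F_fo_ecf", "V_tbf", "V_ecf",
                     "V_icf", "V_isf", "F_b_end", "V_b_start", "V_b_end",
                     "V_b_bm_start", "V_b_bm_end", "V_b_lt_start",
                     "V_b_lt_end", "F_b_ecf", "V_u_total", "V_r_total",
                     "Q_u_start", "Q_u_end", "Q_r_start", "Q_r_end",
                     "F_ruq_start", "F_ruq_end", "F_ruv_start", "F_ruv_end"))
  lmm <- list()
  for (dv in dvs) {
    fit <- tryCatch(fit_lmm_aic(tab, dv, covariates = lmm_covariates),
                    error = function(e) NULL)
    if (!is.null(fit)) lmm[[dv]] <- fit
  }
  rmc <- list()
  pairs <- if (length(rmcorr_vars) >= 2) combn(
    intersect(rmcorr_vars, unique(tab$variable)), 2, simplify = FALSE)
  else list()
  for (pr in pairs) {
    r <- tryCatch(rmcorr(tab, pr[1], pr[2]), error = function(e) NULL)
    if (!is.null(r)) rmc[[paste(pr, collapse = "~")]] <- r
  }
  # one BH family per run: every p emitted by models and correlations
  fam <- c(vapply(lmm, `[[`, 0, "p_day"), vapply(lmm, `[[`, 0, "p_weekday"),
           vapply(rmc, `[[`, 0, "p"))
  fam_adj <- bh_adjust(fam)
  nl <- length(lmm)
  lmm_tab <- data.frame(
    dv = names(lmm),
    beta_day = vapply(lmm, function(f) f$beta_day[["est"]], 0),
    day_lo = vapply(lmm, function(f) f$beta_day[["lo"]], 0),
    day_hi = vapply(lmm, function(f) f$beta_day[["hi"]], 0),
    p_day = vapply(lmm, `[[`, 0, "p_day"),
    p_day_adj = fam_adj[seq_len(nl)],
    beta_weekday = vapply(lmm, function(f) f$beta_weekday[["est"]], 0),
    weekday_lo = vapply(lmm, function(f) f$beta_weekday[["lo"]], 0),
    weekday_hi = vapply(lmm, function(f) f$beta_weekday[["hi"]], 0),
    p_weekday = vapply(lmm, `[[`, 0, "p_weekday"),
    p_weekday_adj = fam_adj[nl + seq_len(nl)],
    sd_slope = vapply(lmm, `[[`, 0, "sd_slope"),
    chosen = vapply(lmm, `[[`, "", "chosen"),
    row.names = NULL, stringsAsFactors = FALSE)
  rmc_tab <- data.frame(
    pair = names(rmc),
    rho_rm = vapply(rmc, `[[`, 0, "rho_rm"),
    lo = vapply(rmc, function(r) r$ci[["lo"]], 0),
    hi = vapply(rmc, function(r) r$ci[["hi"]], 0),
    p = vapply(rmc, `[[`, 0, "p"),
    p_adj = if (length(rmc)) fam_adj[2 * nl + seq_along(rmc)] else numeric(0),
    error_df = vapply(rmc, `[[`, 0, "error_df"),
    row.names = NULL, stringsAsFactors = FALSE)
  cvs <- lapply(dvs, function(v) per_patient_cv(tab, v))
  cv_tab <- data.frame(
    variable = dvs,
    mean_cv_pct = vapply(cvs, `[[`, 0, "mean_cv"),
    sd_cv_pct = vapply(cvs, function(x)
      if (is.na(x$sd_cv)) NA_real_ else x$sd_cv, 0),
    n_patients = vapply(cvs, function(x) length(x$cv), 0L),
    stringsAsFactors = FALSE)
  strata <- tryCatch(
    stratify_by_mean_relative_fo(tab, config$stats$fo_threshold_pct),
    error = function(e) NULL)

  sum_rows <- do.call(rbind, lapply(unique(tab$variable), function(v) {
    sub <- tab[tab$variable == v, ]
    overall <- q13(sub$value)
    per_wd <- lapply(1:3, function(w) q13(sub$value[sub$weekday_treatment == w]))
    data.frame(variable = v, n = overall[4], median = overall[1],
               q1 = overall[2], q3 = overall[3],
               median_wd1 = per_wd[[1]][1], median_wd2 = per_wd[[2]][1],
               median_wd3 = per_wd[[3]][1], stringsAsFactors = FALSE)
  }))

  out <- list(table = tab, summaries = summaries, estimates = estimates,
              lmm = lmm, lmm_table = lmm_tab, rmcorr = rmc,
              rmcorr_table = rmc_tab, cv = cvs, cv_table = cv_tab,
              strata = strata, exclusions = exclusions,
              summary_table = sum_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sum_rows, file.path(out_dir, "summary_table.csv"),
              row.names = FALSE)
    write.csv(lmm_tab, file.path(out_dir, "lmm_table.csv"), row.names = FALSE)
    write.csv(rmc_tab, file.path(out_dir, "rmcorr_matrix.csv"),
              row.names = FALSE)
    write.csv(cv_tab, file.path(out_dir, "cv_table.csv"), row.names = FALSE)
    if (!is.null(strata)) {
      write.csv(strata, file.path(out_dir, "strata.csv"), row.names = FALSE)
    }
    write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    write.csv(summaries, file.path(out_dir, "cohort_summaries.csv"),
              row.names = FALSE)
    manifest <- list(
      stage = "analyze", bundle = bundle_dir, config = unclass(config),
      n_treatments = length(records$treatments),
      n_estimates_ok = sum(exclusions$quality == "ok"),
      n_estimates_excluded = sum(!exclusions$quality %in% c("ok", "no_bolus")),
      exclusion_reasons = as.list(table(exclusions$quality)),
      package_version = as.character(utils::packageVersion("dialvol")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
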