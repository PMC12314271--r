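#' Default run configuration
#'
#' Returns the full configuration list driving every pipeline stage. Each
#' protocol constant is a named key so that a single config file reproduces a
#' run. Values can be overridden via `...` (top-level keys) or by passing a
#' nested list, e.g. `dv_config(cohort = list(n_patients = 2))` merges into the
#' defaults.
#'
#' Key groups:
#' \describe{
#'   \item{bolus}{Dialysate bolus protocol: infusion start `t_inf_s` (s),
#'     volume `V_inf_l` (l), rate `Q_inf_ml_min` (ml/min), and
#'     `first_treatment` — the first treatment index with a bolus (the
#'     estimation protocol starts at the third session).}
#'   \item{clean}{Signal cleaning: median-filter window `window_s` (s), early
#'     exclusion `early_min` (min), peri-bolus exclusion `peri_pre_min` /
#'     `peri_post_min` (min before infusion start / after infusion end),
#'     despiking threshold `z_thresh` (multiples of local MAD), MAD floor
#'     `mad_floor` (percentage points), despiking cap `max_frac`.}
#'   \item{estimate}{Bolus-step quantification: baseline windows (min relative
#'     to infusion start), plausibility range for blood volume (l),
#'     signal-to-noise multiple `snr_mult`, residual-SD ceiling
#'     `resid_sd_max_pp`.}
#'   \item{hemo}{Refilling computation: derivative regression window
#'     `deriv_window_s`, start/end averaging window `avg_window_min`, range
#'     filters for refilling fractions (`frac_lo_pct`, `frac_hi_pct`) and
#'     rates (`qr_min_ml_min`), denominator guards, Nadir90/100 thresholds.}
#'   \item{stats}{Bootstrap resamples, fluid-overload stratification threshold
#'     (% of extracellular fluid).}
#'   \item{cohort}{Synthetic-cohort shape and physiology parameters (see
#'     [generate_cohort()]).}
#' }
#'
#' @param ... top-level overrides; nested lists are merged key-wise.
#' @return a named list of class `dv_config`.
#' @export
dv_config <- function(...) {
  cfg <- list(
    bolus = list(
      t_inf_s = 3600,
      V_inf_l = 0.240,
      Q_inf_ml_min = 200,
      first_treatment = 3
    ),
    clean = list(
      window_s = 313,
      early_min = 5,
      peri_pre_min = 1,
      peri_post_min = 5,
      z_thresh = 5,
      mad_floor = 0.05,
      max_frac = 0.10
    ),
    estimate = list(
      # post window after the peri-bolus exclusion; pre window roughly
      # mirrored about the infusion midpoint so trend-curvature bias cancels
      # (lengths set empirically: see the methods vignette)
      pre_window_min = c(-36, -4),
      post_window_min = c(5, 37),
      vb_range_l = c(2, 12),
      snr_mult = 3,
      resid_sd_max_pp = 1.0,
      overshoot_slope_pp_min = 0.1,
      overshoot_sd_ratio = 3
    ),
    hemo = list(
      deriv_window_s = 300,
      avg_window_min = 30,
      frac_lo_pct = -100,
      frac_hi_pct = 200,
      qr_min_ml_min = -50,
      qu_eps_ml_min = 1,
      vu_eps_l = 0.05,
      idh_nadir_low = 90,
      idh_nadir_high = 100,
      idh_pre_cutoff = 160
    ),
    stats = list(
      n_boot = 1000,
      fo_threshold_pct = 15
    ),
    cohort = list(
      n_patients = 25,
      n_weeks = 5,
      # interdialytic gaps (days) preceding within-week treatments 1, 2, 3
      gap_days = c(3, 2, 2),
      duration_min_mean = 239, duration_min_sd = 10,
      M_eu_mean_kg = 80, M_eu_sd_kg = 12,
      height_mean_m = 1.75, height_sd_m = 0.07,
      age_mean = 63, age_sd = 13,
      p_male = 0.88,
      V_b_eu_mean_l = 4.7, V_b_eu_sd_l = 0.7,
      V_ecf_eu_frac = 0.21,       # of euvolemic mass
      V_icf_frac = 0.235,         # of euvolemic mass
      isf_frac_of_ecf = 0.74,
      lti_mean = 12, lti_sd = 2.4,
      fti_mean = 13.5, fti_sd = 4.5,
      accumulation_mean_l_day = 0.95, accumulation_sd = 0.20,
      fo_residual_mean_l = 0.8, fo_residual_sd = 0.30,
      fo_blood_fraction = 0.10,
      K_r_mean = 4.8, K_r_sd = 1.0,  # ml/min per l interstitial excess
      sigma_rbv_pp = 0.3,
      sigma_uf_l = 0.005,
      sigma_mass_kg = 0.4,
      sigma_bio_l = 0.30,
      spike_rate_per_hour = 1.5,   # 3/min machines only
      spike_amp_pp = c(2, 8),
      overshoot_prob = 0.3,
      overshoot_amp_pp = c(1, 3),
      overshoot_tau_s = 90,
      sbp_pre_mean = 142, sbp_pre_sd = 15,
      idh_prob = 0.09,
      dt_int_s = 1
    ),
    seed = 1
  )
  dots <- list(...)
  merge_cfg(cfg, dots)
}

merge_lists <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_lists(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

merge_cfg <- function(base, over) {
  out <- merge_lists(unclass(base), over)
  class(out) <- "dv_config"
  out
}

#' Read / write a run configuration as JSON
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path JSON file path.
#' @return [read_config()]: a `dv_config`; [write_config()]: `path`, invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- dv_config()
  check_keys <- function(over, base, prefix = "") {
    for (k in names(over)) {
      if (!k %in% names(base)) {
        stop("unknown config key: ", prefix, k, call. = FALSE)
      }
      if (is.list(over[[k]]) && is.list(base[[k]])) {
        check_keys(over[[k]], base[[k]], paste0(prefix, k, "$"))
      }
    }
  }
  check_keys(raw, defaults)
  merge_cfg(defaults, raw)
}

#' @rdname read_config
#' @param cfg a `dv_config` list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
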