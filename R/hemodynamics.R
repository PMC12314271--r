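#' Absolute blood volume series
#'
#' Scales the start-normalized RBV trace by the estimated blood volume at
#' treatment start: `V_b(t) = V_b_start * F_b(t) / 100` on the retained grid.
#'
#' @param trace a [clean_trace()] of start-normalized RBV (%).
#' @param V_b_start blood volume at treatment start (l).
#' @return `clean_trace` of absolute blood volume (l).
#' @export
blood_volume_series <- function(trace, V_b_start) {
  stopifnot(V_b_start > 0)
  out <- trace
  out$value <- V_b_start * trace$value / 100
  out
}

#' Specific blood volume
#'
#' Normalizes blood volume to post-dialysis body mass and, when available, to
#' lean tissue mass (`LTM = LTI * height^2`).
#'
#' @param V_b blood volume (l), scalar or vector.
#' @param M_post post-dialysis body mass (kg).
#' @param LTM lean tissue mass (kg) or `NULL`.
#' @return list with `V_b_bm` (ml/kg) and `V_b_lt` (ml/kg or `NA`).
#' @export
specific_blood_volume <- function(V_b, M_post, LTM = NULL) {
  if (is.na(M_post) || M_post <= 0) stop("M_post must be positive")
  list(V_b_bm = 1000 * V_b / M_post,
       V_b_lt = if (!is.null(LTM) && !is.na(LTM) && LTM > 0)
         1000 * V_b / LTM else NA_real_)
}

cum_infusion <- function(t, infusion) {
  if (is.null(infusion)) return(rep(0, length(t)))
  pmin(pmax(t - infusion$t_inf, 0) / infusion$duration_s, 1) * infusion$V_inf
}

#' Vascular refilling volume series
#'
#' Mass-balance decomposition of the intradialytic volume changes: the
#' cumulative refilling volume is what entered the vascular space beyond what
#' the machine accounts for,
#' `V_r(t) = V_b(t) - V_b(0) + V_u(t) - V_inf_cum(t)`,
#' where `V_u` is the machine-reported cumulative ultrafiltration (which
#' includes the extra ultrafiltration compensating the bolus) and
#' `V_inf_cum` ramps linearly from 0 to the bolus volume over the infusion
#' interval.
#'
#' @param vb a [clean_trace()] of absolute blood volume (l).
#' @param uf a [clean_trace()] of cumulative ultrafiltration (l); interpolated
#'   onto the blood-volume grid.
#' @param infusion an [infusion_event()] or `NULL`.
#' @param V_b_start reference volume `V_b(0)`; defaults to the first retained
#'   blood-volume sample.
#' @return `clean_trace` of cumulative refilling volume (l).
#' @export
refilling_volume_series <- function(vb, uf, infusion = NULL,
                                    V_b_start = NULL) {
  keep <- which(vb$retained)
  if (length(keep) == 0) stop("no retained blood-volume samples")
  if (is.null(V_b_start)) V_b_start <- vb$value[keep[1]]
  ukeep <- uf$retained
  if (sum(ukeep) < 2) stop("cumulative-UF grid not alignable (fewer than 2 samples)")
  vu <- approx(uf$t[ukeep], uf$value[ukeep], xout = vb$t, rule = 2)$y
  out <- vb
  out$value <- vb$value - V_b_start + vu - cum_infusion(vb$t, infusion)
  out
}

window_slope <- function(t, v, half_s) {
  n <- length(t)
  slope <- rep(NA_real_, n)
  lo <- 1L; hi <- 0L
  for (i in seq_len(n)) {
    while (lo <= n && t[lo] < t[i] - half_s) lo <- lo + 1L
    while (hi < n && t[hi + 1L] <= t[i] + half_s) hi <- hi + 1L
    if (hi - lo + 1L >= 2L) {
      tt <- t[lo:hi]; vv <- v[lo:hi]
      tc <- tt - mean(tt)
      slope[i] <- sum(tc * (vv - mean(vv))) / sum(tc^2)
    }
  }
  slope
}

#' Vascular refilling rate series
#'
#' Instantaneous mass balance on the vascular compartment:
#' `Q_r(t) = dV_b/dt + Q_u(t) - Q_inf(t)` (ml/min). The derivative of blood
#' volume and the ultrafiltration rate are both estimated as slopes of
#' centered regression windows (default 5 min) over retained samples; plain
#' two-point differences are too noisy at 1/min sampling.
#'
#' @param vb [clean_trace()] of absolute blood volume (l).
#' @param uf [clean_trace()] of filtered cumulative ultrafiltration (l).
#' @param infusion an [infusion_event()] or `NULL`.
#' @param deriv_window_s regression window (s).
#' @return list of clean traces on the blood-volume grid: `Q_r`, `Q_u`
#'   (ml/min); samples whose window holds fewer than two points are masked
#'   (reason `"rate_range"`).
#' @export
refilling_rate_series <- function(vb, uf, infusion = NULL,
                                  deriv_window_s = 300) {
  half <- deriv_window_s / 2
  keep <- which(vb$retained)
  dvb <- rep(NA_real_, nrow(vb))
  dvb[keep] <- window_slope(vb$t[keep], vb$value[keep], half) * 60000  # ml/min
  ukeep <- which(uf$retained)
  qu_u <- window_slope(uf$t[ukeep], uf$value[ukeep], half) * 60000
  ok <- !is.na(qu_u)
  qu <- approx(uf$t[ukeep][ok], qu_u[ok], xout = vb$t, rule = 2)$y
  qinf <- if (is.null(infusion)) rep(0, nrow(vb)) else
    ifelse(vb$t >= infusion$t_inf &
             vb$t < infusion$t_inf + infusion$duration_s,
           infusion$Q_inf, 0)
  qr_val <- dvb + qu - qinf
  qr <- vb
  qr$value <- qr_val
  bad <- vb$retained & is.na(qr_val)
  qr <- mask_samples(qr, bad, "rate_range")
  qu_ct <- vb
  qu_ct$value <- qu
  list(Q_r = qr, Q_u = qu_ct)
}

#' Refilling fractions
#'
#' Fraction of ultrafiltration compensated by vascular refilling, from rates
#' (`F_ruq = 100 * Q_r / Q_u`) and from cumulative volumes
#' (`F_ruv = 100 * V_r / V_u`). Denominators below the guards are masked
#' rather than divided.
#'
#' @param Q_r,Q_u rates (ml/min), numeric vectors.
#' @param V_r,V_u cumulative volumes (l), numeric vectors.
#' @param qu_eps,vu_eps denominator guards (ml/min, l).
#' @return list of numeric vectors `F_ruq`, `F_ruv` (%, `NA` where masked)
#'   and logical vectors `masked_q`, `masked_v`.
#' @export
refilling_fractions <- function(Q_r, Q_u, V_r, V_u, qu_eps = 1,
                                vu_eps = 0.05) {
  masked_q <- is.na(Q_u) | Q_u <= qu_eps
  masked_v <- is.na(V_u) | V_u <= vu_eps
  F_ruq <- ifelse(masked_q, NA_real_, 100 * Q_r / Q_u)
  F_ruv <- ifelse(masked_v, NA_real_, 100 * V_r / V_u)
  list(F_ruq = F_ruq, F_ruv = F_ruv, masked_q = masked_q, masked_v = masked_v)
}

#' Build the time-resolved volume series for one treatment
#'
#' Runs the full per-treatment chain after preprocessing: blood-volume
#' scaling, refilling volume/rate, ultrafiltration rate and refilling
#' fractions, assembled on the retained RBV grid, followed by the range
#' cleaning of [clean_series()].
#'
#' @param pre output of [preprocess_treatment()].
#' @param record the [treatment_record()].
#' @param V_b_start estimated blood volume at treatment start (l).
#' @param config a [dv_config()].
#' @return a `volume_series` data frame with columns `t`, `F_b`, `V_b`,
#'   `V_r`, `Q_r`, `Q_u`, `F_ruq`, `F_ruv`, `retained`, `reason`.
#' @export
volume_series <- function(pre, record, V_b_start, config = dv_config()) {
  h <- config$hemo
  vb <- blood_volume_series(pre$rbv, V_b_start)
  vr <- refilling_volume_series(vb, pre$uf, record$infusion,
                                V_b_start = V_b_start)
  rates <- refilling_rate_series(vb, pre$uf, record$infusion,
                                 deriv_window_s = h$deriv_window_s)
  ukeep <- pre$uf$retained
  vu <- approx(pre$uf$t[ukeep], pre$uf$value[ukeep], xout = vb$t, rule = 2)$y
  fr <- refilling_fractions(rates$Q_r$value, rates$Q_u$value, vr$value, vu,
                            qu_eps = h$qu_eps_ml_min, vu_eps = h$vu_eps_l)
  vs <- data.frame(t = vb$t, F_b = pre$rbv$value, V_b = vb$value,
                   V_r = vr$value, V_u = vu,
                   Q_r = rates$Q_r$value, Q_u = rates$Q_u$value,
                   F_ruq = fr$F_ruq, F_ruv = fr$F_ruv,
                   retained = vb$retained, reason = vb$reason,
                   stringsAsFactors = FALSE)
  vs$Q_r[!rates$Q_r$retained] <- NA_real_
  class(vs) <- c("volume_series", "data.frame")
  clean_series(vs, config)
}

#' Range cleaning of a volume series
#'
#' Applies the analysis range filters: refilling fractions outside
#' `(frac_lo_pct, frac_hi_pct)` (default −100% to 200%) are set to `NA`
#' (reason `"fraction_range"`), refilling rates below `qr_min_ml_min`
#' (default −50 ml/min) are set to `NA` along with the fractions computed
#' from them (reason `"rate_range"`). Early-treatment and peri-bolus samples
#' are already masked upstream.
#'
#' @param vs a `volume_series`.
#' @param config a [dv_config()].
#' @return cleaned `volume_series`; per-cell exclusions are appended to the
#'   `reason` column.
#' @export
clean_series <- function(vs, config = dv_config()) {
  h <- config$hemo
  add_reason <- function(idx, code) {
    idx <- which(idx)
    vs$reason[idx] <<- ifelse(is.na(vs$reason[idx]), code,
                              paste(vs$reason[idx], code, sep = ";"))
  }
  bad_qr <- !is.na(vs$Q_r) & vs$Q_r < h$qr_min_ml_min
  if (any(bad_qr)) {
    add_reason(bad_qr, "rate_range")
    vs$F_ruq[bad_qr] <- NA_real_
    vs$Q_r[bad_qr] <- NA_real_
  }
  for (col in c("F_ruq", "F_ruv")) {
    bad <- !is.na(vs[[col]]) &
      (vs[[col]] <= h$frac_lo_pct | vs[[col]] >= h$frac_hi_pct)
    if (any(bad)) {
      add_reason(bad, "fraction_range")
      vs[[col]][bad] <- NA_real_
    }
  }
  vs
}

#' Intradialytic hypotension classification (Nadir90/100)
#'
#' A treatment is complicated by intradialytic hypotension when any
#' intradialytic systolic reading falls below 90 mmHg if the pre-dialysis
#' systolic pressure was below 160 mmHg, or below 100 mmHg if it was 160 mmHg
#' or higher.
#'
#' @param bp data frame with columns `phase` (`"pre"`/`"intra"`/`"post"`) and
#'   `SBP` (mmHg).
#' @param pre_cutoff,nadir_low,nadir_high criterion thresholds (mmHg).
#' @return `TRUE`/`FALSE`, or `NA` when the pre-dialysis or all intradialytic
#'   readings are missing.
#' @export
classify_idh <- function(bp, pre_cutoff = 160, nadir_low = 90,
                         nadir_high = 100) {
  if (is.null(bp) || nrow(bp) == 0) return(NA)
  pre <- bp$SBP[bp$phase == "pre"]
  intra <- bp$SBP[bp$phase == "intra"]
  pre <- pre[!is.na(pre)]; intra <- intra[!is.na(intra)]
  if (length(pre) == 0 || length(intra) == 0) return(NA)
  cutoff <- if (pre[1] < pre_cutoff) nadir_low else nadir_high
  any(intra < cutoff)
}

win_mean <- function(x, t, lo, hi) {
  v <- x[!is.na(x) & t >= lo & t <= hi]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Per-treatment summary
#'
#' Reduces a volume series to the per-treatment variables of the cohort
#' table: start/end blood volumes (absolute, per post-dialysis body mass, per
#' lean tissue mass), final relative blood volume, cumulative ultrafiltration
#' and refilling volumes, ultrafiltration/refilling rates and refilling
#' fractions averaged over the first and last `avg_window_min` minutes
#' (retained samples only), the blood-volume-to-extracellular-fluid ratio and
#' the intradialytic-hypotension flag. Empty windows yield `NA` (with a
#' warning) rather than an error.
#'
#' @param vs a `volume_series`.
#' @param record the [treatment_record()].
#' @param bio matching [bioimpedance_record()] or `NULL`.
#' @param V_b_start estimated start blood volume (l).
#' @param config a [dv_config()].
#' @return one-row data frame of summary variables.
#' @export
summarize_treatment <- function(vs, record, bio = NULL, V_b_start,
                                config = dv_config()) {
  h <- config$hemo
  dur_s <- record$duration_min * 60
  w <- h$avg_window_min * 60
  keep <- vs$retained
  t_k <- vs$t[keep]
  last <- function(x) {
    v <- x[keep]; v <- v[!is.na(v)]
    if (length(v)) v[length(v)] else NA_real_
  }
  # LTM = LTI * height^2; height recovered from BMI = M_pre / height^2
  ltm <- if (!is.null(bio) && !is.na(bio$LTI) && !is.na(bio$BMI) &&
             bio$BMI > 0 && !is.na(record$M_pre))
    bio$LTI * record$M_pre / bio$BMI else NULL
  sv_start <- specific_blood_volume(V_b_start, record$M_post, ltm)
  V_b_end <- last(vs$V_b)
  sv_end <- specific_blood_volume(V_b_end, record$M_post, ltm)
  start_stats <- lapply(c(Q_u = "Q_u", Q_r = "Q_r", F_ruq = "F_ruq",
                          F_ruv = "F_ruv"), function(col)
    win_mean(vs[[col]][keep], t_k, 0, w))
  end_stats <- lapply(c(Q_u = "Q_u", Q_r = "Q_r", F_ruq = "F_ruq",
                        F_ruv = "F_ruv"), function(col)
    win_mean(vs[[col]][keep], t_k, dur_s - w, dur_s))
  if (all(is.na(unlist(end_stats)))) {
    warning("last-", h$avg_window_min, "-min window fully masked for ",
            record$treatment_id)
  }
  data.frame(
    patient_id = record$patient_id, study_day = record$study_day,
    weekday_treatment = record$weekday_treatment,
    V_b_start = V_b_start, V_b_end = V_b_end,
    V_b_bm_start = sv_start$V_b_bm, V_b_bm_end = sv_end$V_b_bm,
    V_b_lt_start = sv_start$V_b_lt, V_b_lt_end = sv_end$V_b_lt,
    F_b_end = last(vs$F_b),
    V_u_total = last(vs$V_u), V_r_total = last(vs$V_r),
    Q_u_start = start_stats$Q_u, Q_u_end = end_stats$Q_u,
    Q_r_start = start_stats$Q_r, Q_r_end = end_stats$Q_r,
    F_ruq_start = start_stats$F_ruq, F_ruq_end = end_stats$F_ruq,
    F_ruv_start = start_stats$F_ruv, F_ruv_end = end_stats$F_ruv,
    F_b_ecf = if (!is.null(bio) && !is.na(bio$V_ecf) && bio$V_ecf > 0)
      100 * V_b_start / bio$V_ecf else NA_real_,
    idh = classify_idh(record$bp, pre_cutoff = h$idh_pre_cutoff,
                       nadir_low = h$idh_nadir_low,
                       nadir_high = h$idh_nadir_high),
    stringsAsFactors = FALSE
  )
}

#' Analyze a single treatment end to end
#'
#' Preprocess, estimate blood volume from the bolus, build and clean the
#' volume series and summarize. When the bolus estimate is excluded (or no
#' bolus was given) the blood-volume-derived outputs are `NA` but
#' ultrafiltration and blood-pressure summaries are still produced.
#'
#' @param record a [treatment_record()].
#' @param bio matching [bioimpedance_record()] or `NULL`.
#' @param config a [dv_config()].
#' @return list with `estimate` (a `bolus_estimate`), `series` (a
#'   `volume_series` or `NULL`) and `summary` (one-row data frame).
#' @export
analyze_treatment <- function(record, bio = NULL, config = dv_config()) {
  pre <- preprocess_treatment(record, config)
  est <- estimate_bolus(record, config, trace = pre$rbv_raw)
  h <- config$hemo
  if (identical(est$quality, "ok")) {
    vs <- volume_series(pre, record, est$V_b_start, config)
    summary <- summarize_treatment(vs, record, bio, est$V_b_start, config)
  } else {
    vs <- NULL
    keep <- pre$uf$retained
    dur_s <- record$duration_min * 60
    w <- h$avg_window_min * 60
    qu <- window_slope(pre$uf$t[keep], pre$uf$value[keep],
                       h$deriv_window_s / 2) * 60000
    t_k <- pre$uf$t[keep]
    fb_keep <- pre$rbv$retained
    fb <- pre$rbv$value[fb_keep]
    summary <- data.frame(
      patient_id = record$patient_id, study_day = record$study_day,
      weekday_treatment = record$weekday_treatment,
      V_b_start = NA_real_, V_b_end = NA_real_,
      V_b_bm_start = NA_real_, V_b_bm_end = NA_real_,
      V_b_lt_start = NA_real_, V_b_lt_end = NA_real_,
      F_b_end = if (length(fb)) fb[length(fb)] else NA_real_,
      V_u_total = {
        vu <- pre$uf$value[keep]
        if (length(vu)) vu[length(vu)] else NA_real_
      },
      V_r_total = NA_real_,
      Q_u_start = win_mean(qu, t_k, 0, w),
      Q_u_end = win_mean(qu, t_k, dur_s - w, dur_s),
      Q_r_start = NA_real_, Q_r_end = NA_real_,
      F_ruq_start = NA_real_, F_ruq_end = NA_real_,
      F_ruv_start = NA_real_, F_ruv_end = NA_real_,
      F_b_ecf = NA_real_,
      idh = classify_idh(record$bp, pre_cutoff = h$idh_pre_cutoff,
                         nadir_low = h$idh_nadir_low,
                         nadir_high = h$idh_nadir_high),
      stringsAsFactors = FALSE)
  }
  list(estimate = est, series = vs, summary = summary)
}
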