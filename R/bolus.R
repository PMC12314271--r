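#' Baseline fits around the bolus
#'
#' Fits least-squares lines separately to the retained, cleaned RBV samples
#' in a pre-bolus and a post-bolus window. The post window starts beyond the
#' peri-bolus exclusion; the default pre window is the mirror image of the
#' post window about the infusion midpoint, which cancels the leading-order
#' bias from any smooth curvature of the underlying trend (vascular refilling
#' decays slowly, so the limbs are gently curved rather than straight). The
#' fits are made on the unfiltered despiked trace: the least-squares line
#' already averages noise, whereas median filtering next to the masked
#' peri-bolus gap biases the edge samples.
#'
#' @param trace a [clean_trace()] of start-normalized RBV (%) with exclusion
#'   windows applied (not median-filtered).
#' @param infusion an [infusion_event()].
#' @param pre_window_min,post_window_min windows in minutes relative to
#'   infusion start, `c(from, to)`.
#' @param min_n minimum retained samples per window (default 4).
#' @return list with `pre` and `post` fits — each `list(intercept, slope_pp_s,
#'   slope_pp_min, resid_sd, n)` — or `NULL` with attribute `"reason"` set to
#'   `"excluded_unstable"` when a window has too few samples.
#' @export
fit_baselines <- function(trace, infusion, pre_window_min = c(-36, -4),
                          post_window_min = c(5, 37), min_n = 4) {
  fit_one <- function(win) {
    sel <- trace$retained & trace$t >= infusion$t_inf + win[1] * 60 &
      trace$t <= infusion$t_inf + win[2] * 60
    if (sum(sel) < min_n) return(NULL)
    tt <- trace$t[sel]; vv <- trace$value[sel]
    m <- lm(vv ~ tt)
    r <- m$residuals
    list(intercept = unname(coef(m)[1]), slope_pp_s = unname(coef(m)[2]),
         slope_pp_min = unname(coef(m)[2]) * 60,
         resid_sd = if (length(r) > 2) sqrt(sum(r^2) / (length(r) - 2)) else 0,
         n = sum(sel))
  }
  pre <- fit_one(pre_window_min)
  post <- fit_one(post_window_min)
  if (is.null(pre) || is.null(post)) {
    return(structure(list(failed = TRUE), reason = "excluded_unstable"))
  }
  list(pre = pre, post = post)
}

line_at <- function(fit, t) fit$intercept + fit$slope_pp_s * t

#' Infusion-induced RBV step
#'
#' Extrapolates the pre- and post-bolus baseline lines to the infusion
#' midpoint and takes their difference: with locally linear limbs this is an
#' unbiased estimate of the start-normalized step (percentage points) caused
#' by diluting the blood with the known bolus volume.
#'
#' @param fits output of [fit_baselines()].
#' @param infusion an [infusion_event()].
#' @param overshoot_slope_pp_min,overshoot_sd_ratio shape guard: a strongly
#'   positive post slope combined with a post residual SD exceeding this
#'   multiple of the pre residual SD marks an unresolved overshoot.
#' @return `delta` in percentage points with attribute `"reason"` `NA`; on a
#'   non-positive step or an overshoot-shaped post window the attribute is
#'   `"excluded_shape"`.
#' @export
delta_rbv <- function(fits, infusion, overshoot_slope_pp_min = 0.1,
                      overshoot_sd_ratio = 3) {
  t_mid <- infusion$t_inf + infusion$duration_s / 2
  delta <- line_at(fits$post, t_mid) - line_at(fits$pre, t_mid)
  reason <- NA_character_
  if (delta <= 1e-9) {  # tolerance so an exactly-zero step is not saved by rounding
    reason <- "excluded_shape"
  } else if (fits$post$slope_pp_min > overshoot_slope_pp_min &&
             fits$post$resid_sd > overshoot_sd_ratio * max(fits$pre$resid_sd,
                                                           1e-12)) {
    reason <- "excluded_shape"
  }
  attr(delta, "reason") <- reason
  delta
}

#' Absolute blood volume from the dilution step
#'
#' Indicator-dilution relation on the start-normalized RBV scale: a bolus of
#' `V_inf` litres raising RBV by `delta_F_b` percentage points implies
#' `V_b_start = 100 * V_inf / delta_F_b` litres at treatment start.
#'
#' @param delta_F_b step in percentage points (> 0).
#' @param V_inf bolus volume (l).
#' @return blood volume at treatment start (l).
#' @export
estimate_vb_start <- function(delta_F_b, V_inf) {
  if (is.na(delta_F_b) || delta_F_b <= 0) {
    stop("delta_F_b must be positive")
  }
  100 * V_inf / delta_F_b
}

#' Plausibility screening of a bolus estimate
#'
#' Codified replacement for manual screening: an estimate is excluded when
#' the blood volume falls outside the physiological range, when the step is
#' smaller than `snr_mult` times the pre-baseline residual SD
#' (signal-to-noise rule), or when the pre-baseline residual SD itself
#' exceeds `resid_sd_max_pp` (unstable trace). Screening only annotates,
#' never raises.
#'
#' @param e a `bolus_estimate`.
#' @param vb_range_l plausible blood-volume range (l).
#' @param snr_mult signal-to-noise multiple.
#' @param resid_sd_max_pp ceiling on the pre-fit residual SD (pp).
#' @return the estimate with `quality` and `exclusion_reason` updated.
#' @export
plausibility_screen <- function(e, vb_range_l = c(2, 12), snr_mult = 3,
                                resid_sd_max_pp = 1.0) {
  if (e$quality != "ok") return(e)
  if (is.na(e$V_b_start) || e$V_b_start < vb_range_l[1] ||
      e$V_b_start > vb_range_l[2]) {
    e$quality <- "excluded_range"
    e$exclusion_reason <- sprintf("V_b_start %.2f l outside [%g, %g] l",
                                  e$V_b_start, vb_range_l[1], vb_range_l[2])
  } else if (e$delta_F_b < snr_mult * e$pre_fit$resid_sd) {
    e$quality <- "excluded_unstable"
    e$exclusion_reason <- sprintf(
      "step %.2f pp below %g x pre residual SD (%.2f pp)",
      e$delta_F_b, snr_mult, e$pre_fit$resid_sd)
  } else if (e$pre_fit$resid_sd > resid_sd_max_pp) {
    e$quality <- "excluded_unstable"
    e$exclusion_reason <- sprintf("pre residual SD %.2f pp above %g pp",
                                  e$pre_fit$resid_sd, resid_sd_max_pp)
  }
  e
}

new_bolus_estimate <- function(treatment_id, delta = NA_real_,
                               V_b_start = NA_real_, pre_fit = NULL,
                               post_fit = NULL, quality = "ok",
                               reason = NA_character_) {
  structure(list(treatment_id = treatment_id, delta_F_b = delta,
                 V_b_start = V_b_start, pre_fit = pre_fit,
                 post_fit = post_fit, quality = quality,
                 exclusion_reason = reason),
            class = "bolus_estimate")
}

#' Estimate absolute blood volume for one treatment
#'
#' Full bolus-dilution chain for a treatment: preprocess the RBV stream
#' (despike on high-rate machines, renormalize, exclusion windows, median
#' filter), fit the pre/post baselines, quantify the step at the infusion
#' midpoint, convert to blood volume and screen for plausibility.
#'
#' @param record a [treatment_record()] (must carry an infusion), or a
#'   preprocessed [clean_trace()] via `trace =`.
#' @param config a [dv_config()].
#' @param trace optional preprocessed, unfiltered RBV `clean_trace`
#'   (the `rbv_raw` element of [preprocess_treatment()]) to use instead of
#'   preprocessing `record$rbv`.
#' @return a `bolus_estimate`: `delta_F_b` (pp), `V_b_start` (l), baseline
#'   fits, `quality` in `{"ok", "excluded_unstable", "excluded_shape",
#'   "excluded_range", "no_bolus"}` and `exclusion_reason`.
#' @export
estimate_bolus <- function(record, config = dv_config(), trace = NULL) {
  id <- if (inherits(record, "treatment_record")) record$treatment_id else "trace"
  infusion <- if (inherits(record, "treatment_record")) record$infusion else
    attr(trace, "infusion")
  if (is.null(infusion)) {
    return(new_bolus_estimate(id, quality = "no_bolus",
                              reason = "no infusion event recorded"))
  }
  if (is.null(trace)) {
    trace <- preprocess_treatment(record, config)$rbv_raw
  }
  est <- config$estimate
  fits <- fit_baselines(trace, infusion,
                        pre_window_min = est$pre_window_min,
                        post_window_min = est$post_window_min)
  if (isTRUE(fits$failed)) {
    return(new_bolus_estimate(id, quality = "excluded_unstable",
                              reason = "insufficient retained samples in baseline window"))
  }
  delta <- delta_rbv(fits, infusion,
                     overshoot_slope_pp_min = est$overshoot_slope_pp_min,
                     overshoot_sd_ratio = est$overshoot_sd_ratio)
  if (!is.na(attr(delta, "reason"))) {
    return(new_bolus_estimate(id, delta = as.numeric(delta),
                              pre_fit = fits$pre, post_fit = fits$post,
                              quality = attr(delta, "reason"),
                              reason = "non-positive or overshoot-shaped step"))
  }
  vb <- estimate_vb_start(as.numeric(delta), infusion$V_inf)
  e <- new_bolus_estimate(id, delta = as.numeric(delta), V_b_start = vb,
                          pre_fit = fits$pre, post_fit = fits$post)
  plausibility_screen(e, vb_range_l = est$vb_range_l,
                      snr_mult = est$snr_mult,
                      resid_sd_max_pp = est$resid_sd_max_pp)
}
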