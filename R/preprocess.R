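#' Clean-trace container
#'
#' A cleaned signal: time (s), value, a per-sample retention mask and a reason
#' code for each excluded sample (`"spike"`, `"early"`, `"peri_bolus"`,
#' `"manual"`, or downstream range codes). Excluded samples never enter later
#' statistics; no interpolation is performed across them — downstream
#' operations consume the irregular retained grid.
#'
#' @param t sample times (s), strictly increasing.
#' @param value signal values.
#' @param retained logical mask (default all retained).
#' @param reason character reason codes, `NA` where retained.
#' @return a data frame of class `clean_trace`.
#' @export
clean_trace <- function(t, value, retained = rep(TRUE, length(t)),
                        reason = rep(NA_character_, length(t))) {
  stopifnot(length(t) == length(value), length(retained) == length(t),
            length(reason) == length(t))
  if (length(t) > 1 && any(diff(t) <= 0)) stop("time not strictly increasing")
  structure(data.frame(t = as.numeric(t), value = as.numeric(value),
                       retained = retained, reason = reason,
                       stringsAsFactors = FALSE),
            class = c("clean_trace", "data.frame"))
}

#' @rdname clean_trace
#' @param x an [rbv_trace()] or [uf_trace()].
#' @export
as_clean_trace <- function(x) {
  if (inherits(x, "rbv_trace")) return(clean_trace(x$t, x$F_b))
  if (inherits(x, "uf_trace")) return(clean_trace(x$t, x$V_u))
  if (inherits(x, "clean_trace")) return(x)
  stop("cannot convert to clean_trace")
}

mask_samples <- function(ct, idx, reason) {
  hit <- idx & ct$retained
  ct$retained[hit] <- FALSE
  ct$reason[hit] <- reason
  ct
}

#' Sliding median filter over a time window
#'
#' Replaces each retained sample by the median of the retained samples within
#' a centered time window of `window_s` seconds (samples within
#' `window_s / 2` of the target time). The window shrinks at the trace
#' boundaries; excluded samples neither contribute nor are changed. The
#' default 313-s window spans about 5 samples on 1/min machines and about 15
#' on 3/min machines.
#'
#' @param trace a [clean_trace()] (or raw trace, converted).
#' @param window_s window length in seconds.
#' @return filtered `clean_trace`.
#' @export
median_filter <- function(trace, window_s = 313) {
  stopifnot(window_s > 0)
  ct <- as_clean_trace(trace)
  keep <- which(ct$retained)
  if (length(keep) == 0) stop("all samples excluded; nothing to filter")
  t_r <- ct$t[keep]; v_r <- ct$value[keep]
  half <- window_s / 2
  out <- v_r
  lo <- 1L; hi <- 0L; n <- length(t_r)
  for (i in seq_len(n)) {
    while (lo <= n && t_r[lo] < t_r[i] - half) lo <- lo + 1L
    while (hi < n && t_r[hi + 1L] <= t_r[i] + half) hi <- hi + 1L
    out[i] <- median(v_r[lo:hi])
  }
  ct$value[keep] <- out
  ct
}

#' Despike a high-rate RBV trace
#'
#' Masks samples whose deviation from the local (leave-one-out) running
#' median exceeds `z_thresh` times a robust scale. The scale is the local
#' MAD floored by the trace-wide MAD of the running-median residuals and by
#' an absolute epsilon: the global floor protects against chance collapse of
#' a short-window MAD (which would flag ordinary noise), the epsilon floor
#' catches isolated spikes on flat segments where every MAD is zero. At most
#' a fraction `max_frac` of samples is masked; if more would qualify, the
#' worst offenders are masked, a warning is emitted and the
#' `"despike_capped"` attribute is set.
#'
#' @param trace a trace or [clean_trace()].
#' @param z_thresh threshold in multiples of the local MAD.
#' @param window_s local window (s) for the running median/MAD.
#' @param mad_floor minimum MAD (same units as the signal).
#' @param max_frac cap on the masked fraction.
#' @return `clean_trace` with spikes masked (reason `"spike"`).
#' @export
despike <- function(trace, z_thresh = 5, window_s = 313, mad_floor = 0.05,
                    max_frac = 0.10) {
  ct <- as_clean_trace(trace)
  keep <- which(ct$retained)
  if (length(keep) < 3) return(ct)
  t_r <- ct$t[keep]; v_r <- ct$value[keep]
  half <- window_s / 2
  n <- length(t_r)
  dev <- numeric(n); scale <- numeric(n)
  lo <- 1L; hi <- 0L
  for (i in seq_len(n)) {
    while (lo <= n && t_r[lo] < t_r[i] - half) lo <- lo + 1L
    while (hi < n && t_r[hi + 1L] <= t_r[i] + half) hi <- hi + 1L
    win <- v_r[lo:hi]
    if (length(win) > 2) win <- win[-(i - lo + 1L)]  # leave-one-out
    m <- median(win)
    dev[i] <- abs(v_r[i] - m)
    scale[i] <- mad(win, center = m, constant = 1.4826)
  }
  global_scale <- 1.4826 * median(dev)
  scale <- pmax(scale, global_scale, mad_floor)
  bad <- which(dev > z_thresh * scale)
  cap <- floor(max_frac * n)
  capped <- FALSE
  if (length(bad) > cap) {
    warning("despike: ", length(bad), " candidates exceed the ", max_frac,
            " cap; masking only the ", cap, " largest deviations")
    bad <- bad[order(dev[bad], decreasing = TRUE)][seq_len(cap)]
    capped <- TRUE
  }
  idx <- rep(FALSE, nrow(ct)); idx[keep[bad]] <- TRUE
  ct <- mask_samples(ct, idx, "spike")
  attr(ct, "despike_capped") <- capped
  ct
}

#' Exclude early-treatment and peri-bolus windows
#'
#' Masks samples from the first `early_min` minutes of treatment (reason
#' `"early"`) and, when an infusion event is given, from `peri_pre_min`
#' minutes before infusion start to `peri_post_min` minutes after infusion
#' end (reason `"peri_bolus"`). The infusion end is `t_inf + V_inf / Q_inf`.
#'
#' @param trace a trace or [clean_trace()].
#' @param infusion an [infusion_event()] or `NULL`.
#' @param early_min early-exclusion window (min).
#' @param peri_pre_min,peri_post_min peri-bolus margins (min).
#' @return masked `clean_trace`.
#' @export
apply_exclusion_windows <- function(trace, infusion = NULL, early_min = 5,
                                    peri_pre_min = 1, peri_post_min = 5) {
  ct <- as_clean_trace(trace)
  ct <- mask_samples(ct, ct$t < early_min * 60, "early")
  if (!is.null(infusion)) {
    t0 <- infusion$t_inf - peri_pre_min * 60
    t1 <- infusion$t_inf + infusion$duration_s + peri_post_min * 60
    ct <- mask_samples(ct, ct$t >= t0 & ct$t <= t1, "peri_bolus")
  }
  ct
}

#' Renormalize an RBV clean-trace to its first retained sample
#'
#' Machine RBV streams are normalized internally; to make dialects uniform the
#' trace is rescaled so that the first retained sample reads exactly 100%.
#'
#' @param ct a `clean_trace` of RBV values (%).
#' @return rescaled `clean_trace`.
#' @export
renormalize_rbv <- function(ct) {
  keep <- which(ct$retained)
  if (length(keep) == 0) stop("all samples excluded; cannot renormalize")
  ref <- ct$value[keep[1]]
  if (!is.finite(ref) || ref <= 0) stop("non-positive reference RBV sample")
  ct$value <- 100 * ct$value / ref
  ct
}

#' Standard preprocessing for one treatment's signals
#'
#' Applies the cleaning chain in the documented order: despiking (high-rate
#' machines by default), renormalization to the first retained sample, early
#' and peri-bolus exclusion, then median filtering; the cumulative-UF stream
#' is median-filtered on its own grid. The unfiltered (but despiked, masked
#' and renormalized) RBV trace is returned alongside for the bolus-step
#' quantification, which fits baselines and must not see the filter's edge
#' bias next to the masked peri-bolus gap.
#'
#' @param record a [treatment_record()].
#' @param config a [dv_config()].
#' @return list with clean traces `rbv` (median-filtered), `rbv_raw`
#'   (unfiltered) and `uf` (median-filtered cumulative UF).
#' @export
preprocess_treatment <- function(record, config = dv_config()) {
  cl <- config$clean
  rbv <- as_clean_trace(record$rbv)
  if (identical(record$machine, "M_3perMin")) {
    rbv <- despike(rbv, z_thresh = cl$z_thresh, window_s = cl$window_s,
                   mad_floor = cl$mad_floor, max_frac = cl$max_frac)
  }
  rbv <- renormalize_rbv(rbv)
  rbv <- apply_exclusion_windows(rbv, record$infusion,
                                 early_min = cl$early_min,
                                 peri_pre_min = cl$peri_pre_min,
                                 peri_post_min = cl$peri_post_min)
  uf <- median_filter(as_clean_trace(record$uf), cl$window_s)
  list(rbv = median_filter(rbv, cl$window_s), rbv_raw = rbv, uf = uf)
}
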