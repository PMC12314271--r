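# Independent brute-force oracles kept deliberately naive: each recomputes
# its quantity from first principles, without reusing package internals.

# sliding time-window median with boundary shrink, O(n^2)
brute_median_filter <- function(t, v, window_s) {
  vapply(seq_along(t), function(i) {
    median(v[abs(t - t[i]) <= window_s / 2])
  }, 0)
}

# Benjamini-Hochberg step-up, written out longhand
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  if (n > 1) {
    for (i in (n - 1):1) ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(ranked, 1)
  out
}

# repeated-measures correlation as the Pearson correlation of
# within-subject-centered values
brute_rmcorr <- function(subject, x, y) {
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# piecewise-linear RBV trace with a clean bolus step (1/min by default)
make_step_trace <- function(step_pp = 4.8, slope_pp_min = -0.02,
                            t_step_s = 3600, dur_min = 240, dt_s = 60,
                            noise_sd = 0, seed = NULL) {
  t <- seq(0, dur_min * 60, by = dt_s)
  Fb <- 100 + slope_pp_min * t / 60 + ifelse(t >= t_step_s, step_pp, 0)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) Fb <- Fb + rnorm(length(t), 0, noise_sd)
  rbv_trace("step", t, Fb, machine = if (dt_s == 60) "M_1perMin" else "M_3perMin")
}

# minimal treatment record around a trace (linear cumulative UF)
make_record <- function(rbv, uf_total_l = 2.74, duration_min = 240,
                        infusion = infusion_event(3600), patient_id = "P01",
                        study_day = 1, weekday_treatment = 1, M_pre = 82,
                        M_post = 79.3, bp = NULL) {
  uf <- uf_trace(rbv$treatment_id, rbv$t, uf_total_l * rbv$t / max(rbv$t))
  treatment_record(patient_id, study_day, 1, weekday_treatment, duration_min,
                   rbv$machine, M_pre, M_post, M_post, rbv, uf, infusion, bp)
}

# stub records for table-shape tests: 3-sample traces, no infusion
make_stub_records <- function(n_patients, n_days, with_bio = TRUE) {
  txs <- list(); bios <- list()
  for (i in seq_len(n_patients)) {
    for (d in seq_len(n_days)) {
      pid <- sprintf("P%02d", i)
      id <- paste0(pid, "_d", sprintf("%02d", d))
      txs[[length(txs) + 1]] <- treatment_record(
        pid, d, 1L + (d - 1L) %/% 3L, 1L + (d - 1L) %% 3L, 240, "M_1perMin",
        82, 79.5, 79.5,
        rbv_trace(id, c(0, 60, 120), c(100, 99.9, 99.8)),
        uf_trace(id, c(0, 60, 120), c(0, 0.01, 0.02)))
      if (with_bio) {
        bios[[length(bios) + 1]] <- bioimpedance_record(
          pid, d, 20, 18.5, 38.5, 14.8, 3, 15, 79, 12, 13.8, 26.7)
      }
    }
  }
  list(treatments = txs, bioimpedance = bios)
}

noise_free <- list(sigma_rbv_pp = 0, sigma_uf_l = 0, sigma_mass_kg = 0,
                   sigma_bio_l = 0)
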