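#' Synthetic patient for the fluid-kinetics simulator
#'
#' Parameterises one simulated patient of the two-compartment
#' (intravascular/interstitial) intradialytic model with sawtooth
#' interdialytic fluid-overload accumulation.
#'
#' @param patient_id identifier.
#' @param M_eu_true euvolemic body mass (kg), constant over the study.
#' @param V_b_eu euvolemic blood volume (l).
#' @param V_ecf_eu,V_icf_eu euvolemic extracellular / intracellular fluid (l).
#' @param accumulation_rate interdialytic fluid accumulation (l/day).
#' @param fo_residual fluid overload left in place by ultrafiltration (l); the
#'   prescribed target mass is the euvolemic mass plus this residual.
#' @param fo_blood_fraction share of excess fluid allocated to the
#'   intravascular space (0..1). 0 reproduces purely interstitial
#'   accumulation (blood volume independent of fluid overload), 1 purely
#'   intravascular accumulation.
#' @param K_r refilling conductance, ml/min per litre of interstitial excess.
#' @param duration_min usual treatment duration (min).
#' @param height_m,age,sex anthropometry (sex coded 0 = female, 1 = male).
#' @param LTI,FTI lean / fat tissue mass indices (kg/m2).
#' @param machine_initial machine for weeks 1-3 (`"M_1perMin"`/`"M_3perMin"`);
#'   the cohort protocol switches to the alternative model afterwards.
#' @param noise list of measurement noise SDs: `sigma_rbv_pp` (percentage
#'   points), `sigma_uf_l` (l), `sigma_mass_kg` (kg), `sigma_bio_l` (l).
#' @return object of class `sim_patient`.
#' @export
sim_patient <- function(patient_id, M_eu_true = 80, V_b_eu = 4.7,
                        V_ecf_eu = 16.8, V_icf_eu = 18.8,
                        accumulation_rate = 0.75, fo_residual = 1.2,
                        fo_blood_fraction = 0.10, K_r = 3.5,
                        duration_min = 239, height_m = 1.75, age = 63,
                        sex = 1, LTI = 12, FTI = 13.5,
                        machine_initial = "M_1perMin",
                        noise = list(sigma_rbv_pp = 0.3, sigma_uf_l = 0.005,
                                     sigma_mass_kg = 0.4, sigma_bio_l = 0.3)) {
  stopifnot(M_eu_true > 0, V_b_eu > 0, V_ecf_eu > 0, V_icf_eu > 0,
            K_r >= 0, accumulation_rate >= 0)
  if (fo_blood_fraction < 0 || fo_blood_fraction > 1) {
    stop("fo_blood_fraction must lie in [0, 1]")
  }
  structure(list(patient_id = patient_id, M_eu_true = M_eu_true,
                 V_b_eu = V_b_eu, V_ecf_eu = V_ecf_eu, V_icf_eu = V_icf_eu,
                 accumulation_rate = accumulation_rate,
                 fo_residual = fo_residual,
                 fo_blood_fraction = fo_blood_fraction, K_r = K_r,
                 duration_min = duration_min, height_m = height_m, age = age,
                 sex = sex, LTI = LTI, FTI = FTI,
                 machine_initial = machine_initial, noise = noise),
            class = "sim_patient")
}

derive_seed <- function(seed, i, j = 0) {
  # per-patient / per-treatment streams by fixed offsets; stays below 2^31
  as.integer((as.numeric(seed) * 10007 + i * 131071 + j * 257) %% 2147483562) + 1L
}

#' Interdialytic week-cycle simulation
#'
#' Propagates the pre-dialysis state of one patient over a thrice-weekly
#' schedule. Fluid overload accumulates linearly over each interdialytic gap
#' and is removed by ultrafiltration down to the patient's residual, producing
#' the sawtooth pattern: highest overload after the long gap (first treatment
#' of the week), lower at the second and third. The study starts at the
#' week's second treatment and ends with the third treatment of the last
#' week, i.e. `3 * n_weeks - 1` treatments (14 over 31 days for the default
#' five weeks).
#'
#' Excess fluid is split between compartments by `fo_blood_fraction`:
#' pre-dialysis blood volume is `V_b_eu + f * V_fo_pre` and the interstitial
#' excess is `(1 - f) * V_fo_pre`. Euvolemic mass and intracellular volume are
#' constant up to measurement noise.
#'
#' @param p a [sim_patient()].
#' @param n_weeks number of study weeks (>= 1).
#' @param gap_days interdialytic gaps (days) preceding within-week treatments
#'   1, 2, 3; default `c(3, 2, 2)` (long gap before the week's first session).
#' @param seed integer seed for the measurement-noise stream, or `NULL` for
#'   noise-free output (observed columns equal the true ones).
#' @return data frame with one row per treatment: schedule columns
#'   (`tx_index`, `week_index`, `weekday_treatment`, `study_day`, `gap_days`),
#'   ground-truth columns (`V_fo_pre_true`, `uf_net_l`, `V_b_start_true`,
#'   `V_is_excess_true`, `M_pre_true`) and observed pre-dialysis
#'   bioimpedance/mass columns (suffix `_obs`).
#' @export
simulate_week_cycle <- function(p, n_weeks, gap_days = c(3, 2, 2),
                                seed = NULL) {
  stopifnot(n_weeks >= 1)
  n_tx <- max(2L, 3L * as.integer(n_weeks) - 1L)
  weekday <- integer(n_tx); week <- integer(n_tx); day <- integer(n_tx)
  gap <- numeric(n_tx)
  weekday[1] <- 2L; week[1] <- 1L; day[1] <- 1L; gap[1] <- gap_days[2]
  for (k in seq_len(n_tx - 1L) + 1L) {
    weekday[k] <- if (weekday[k - 1L] == 3L) 1L else weekday[k - 1L] + 1L
    week[k] <- week[k - 1L] + (weekday[k] == 1L)
    gap[k] <- gap_days[weekday[k]]
    day[k] <- day[k - 1L] + gap[k]
  }
  f <- p$fo_blood_fraction
  V_fo_pre <- numeric(n_tx); uf_net <- numeric(n_tx)
  fo_post_prev <- p$fo_residual   # steady-state entry into the study
  for (k in seq_len(n_tx)) {
    V_fo_pre[k] <- fo_post_prev + p$accumulation_rate * gap[k]
    uf_net[k] <- max(V_fo_pre[k] - p$fo_residual, 0)
    fo_post_prev <- V_fo_pre[k] - uf_net[k]
  }
  V_b_start <- p$V_b_eu + f * V_fo_pre
  V_is_excess <- (1 - f) * V_fo_pre
  if (any(V_b_start <= 0)) stop("non-positive blood volume from parameters")
  M_pre_true <- p$M_eu_true + V_fo_pre
  n <- p$noise
  rn <- function(sd) {
    if (is.null(seed) || sd <= 0) rep(0, n_tx) else rnorm(n_tx, 0, sd)
  }
  if (!is.null(seed)) set.seed(seed)
  M_pre_obs <- M_pre_true + rn(n$sigma_mass_kg)
  V_fo_obs <- V_fo_pre + rn(n$sigma_bio_l)
  V_ecf_obs <- p$V_ecf_eu + V_fo_pre + rn(n$sigma_bio_l)
  V_icf_obs <- p$V_icf_eu + rn(n$sigma_bio_l)
  if (any(V_ecf_obs <= 0) || any(V_icf_obs <= 0)) {
    stop("non-positive fluid volume from parameters")
  }
  data.frame(
    tx_index = seq_len(n_tx), week_index = week, weekday_treatment = weekday,
    study_day = day, gap_days = gap,
    V_fo_pre_true = V_fo_pre, uf_net_l = uf_net,
    V_b_start_true = V_b_start, V_is_excess_true = V_is_excess,
    M_pre_true = M_pre_true,
    M_pre_obs = M_pre_obs,
    M_eu_obs = M_pre_obs - V_fo_obs,   # consistent by construction
    V_fo_obs = V_fo_obs,
    V_ecf_obs = V_ecf_obs,
    V_icf_obs = V_icf_obs,
    V_tbf_obs = V_ecf_obs + V_icf_obs,
    V_isf_obs = 0.74 * V_ecf_obs,
    F_fo_ecf_obs = 100 * V_fo_obs / V_ecf_obs
  )
}

#' Intradialytic two-compartment treatment simulation
#'
#' Integrates the intradialytic fluid kinetics with explicit Euler at a 1-s
#' internal step: `dV_b/dt = Q_r - Q_u + Q_inf`, `dV_is/dt = -Q_r`, with the
#' refilling rate linear in the interstitial excess volume,
#' `Q_r = K_r * max(V_is - V_is_eq, 0)` (a lumped Starling surrogate). The
#' machine-reported cumulative ultrafiltration runs at a constant rate
#' removing the net target plus the bolus compensation over the treatment.
#' Emits the machine-sampled RBV trace (`F_b(t) = 100 * V_b(t) / V_b(0)` plus
#' Gaussian noise), the cumulative-UF trace, and the pre-noise ground truth.
#'
#' @param state one row of [simulate_week_cycle()] output (or a list with
#'   `V_b_start_true`, `V_is_excess_true`, `uf_net_l`).
#' @param p a [sim_patient()].
#' @param protocol an [infusion_event()] or `NULL` for no bolus.
#' @param dt machine sampling interval (s): 60 (1/min) or 20 (3/min).
#' @param seed integer for the noise stream, `NULL` for noise-free traces.
#' @param duration_min treatment duration; defaults to the patient's usual.
#' @param treatment_id identifier attached to the traces.
#' @param dt_int internal Euler step (s).
#' @return list with elements `rbv` ([rbv_trace()]), `uf` ([uf_trace()]) and
#'   `truth` — a data frame of pre-noise `t`, `V_b`, `V_is_excess`, `V_u`,
#'   `V_inf_cum`, `Q_r_ml_min`, `V_r` at the machine samples.
#' @export
simulate_treatment_trace <- function(state, p, protocol = NULL, dt = 60,
                                     seed = NULL,
                                     duration_min = p$duration_min,
                                     treatment_id = "sim", dt_int = 1) {
  if (!dt %in% c(20, 60)) stop("dt must be 20 or 60 s")
  dur_s <- round(duration_min * 60)
  V_inf <- if (is.null(protocol)) 0 else protocol$V_inf
  uf_total <- state$uf_net_l + V_inf   # machine compensates the bolus
  if (uf_total < 0) stop("negative ultrafiltration plan")
  Qu <- uf_total / dur_s                         # l/s, constant
  Qinf_rate <- if (is.null(protocol)) 0 else protocol$Q_inf / 60000  # l/s
  t_inf0 <- if (is.null(protocol)) Inf else protocol$t_inf
  t_inf1 <- if (is.null(protocol)) Inf else protocol$t_inf + protocol$duration_s
  kr_ls <- p$K_r / 60000                         # (l/s) per l excess

  n_steps <- ceiling(dur_s / dt_int)
  t_grid <- seq(0, dur_s, by = dt)
  n_out <- length(t_grid)
  Vb <- state$V_b_start_true
  Vis_ex <- state$V_is_excess_true
  Vu <- 0; Vinf_cum <- 0
  out <- matrix(NA_real_, n_out, 6)
  rec <- function(i, tt) {
    qr <- kr_ls * max(Vis_ex, 0) * 60000
    out[i, ] <<- c(tt, Vb, Vis_ex, Vu, Vinf_cum, qr)
  }
  rec(1L, 0)
  nxt <- 2L
  tt <- 0
  for (s in seq_len(n_steps)) {
    h <- min(dt_int, dur_s - tt)
    qr <- kr_ls * max(Vis_ex, 0)
    qinf <- if (tt >= t_inf0 && tt < t_inf1) Qinf_rate else 0
    Vb <- Vb + (qr - Qu + qinf) * h
    Vis_ex <- Vis_ex - qr * h
    Vu <- Vu + Qu * h
    Vinf_cum <- Vinf_cum + qinf * h
    tt <- tt + h
    if (Vb <= 0) {
      stop("blood volume depleted during simulation (over-aggressive UF)")
    }
    while (nxt <= n_out && t_grid[nxt] <= tt + 1e-9) {
      rec(nxt, t_grid[nxt]); nxt <- nxt + 1L
    }
  }
  truth <- data.frame(t = out[, 1], V_b = out[, 2], V_is_excess = out[, 3],
                      V_u = out[, 4], V_inf_cum = out[, 5],
                      Q_r_ml_min = out[, 6])
  truth$V_r <- truth$V_b - truth$V_b[1] + truth$V_u - truth$V_inf_cum
  F_b <- 100 * truth$V_b / truth$V_b[1]
  V_u_obs <- truth$V_u
  if (!is.null(seed)) {
    set.seed(seed)
    if (p$noise$sigma_rbv_pp > 0) {
      F_b <- F_b + rnorm(n_out, 0, p$noise$sigma_rbv_pp)
    }
    if (p$noise$sigma_uf_l > 0) {
      V_u_obs <- V_u_obs + rnorm(n_out, 0, p$noise$sigma_uf_l)
    }
  }
  list(rbv = rbv_trace(treatment_id, truth$t, F_b,
                       machine = if (dt == 60) "M_1perMin" else "M_3perMin"),
       uf = uf_trace(treatment_id, truth$t, V_u_obs),
       truth = truth)
}

#' Inject measurement artifacts into an RBV trace
#'
#' Adds the artifact classes seen in machine RBV streams: isolated spikes
#' (high-rate optical monitors), a post-bolus overshoot decaying
#' exponentially, or plain Gaussian noise. Artifact positions are recorded in
#' the `"artifact_idx"` attribute for test assertions.
#'
#' @param trace an [rbv_trace()].
#' @param kind `"spikes"`, `"overshoot"` or `"gaussian"`.
#' @param params list; for spikes: `n` (count) or `idx` (explicit indices),
#'   `amp_pp` (range, percentage points); for overshoot: `t0` (start, s),
#'   `amp_pp`, `tau_s` (decay constant); for gaussian: `sigma_pp`.
#' @param seed RNG seed (positions/amplitudes); unused when fully specified.
#' @return corrupted copy of `trace` with attribute `"artifact_idx"`.
#' @export
add_artifacts <- function(trace, kind = c("spikes", "overshoot", "gaussian"),
                          params = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  F_b <- trace$F_b
  idx <- integer(0)
  if (kind == "gaussian") {
    sigma <- params$sigma_pp %||% 0.3
    if (sigma > 0) {
      F_b <- F_b + rnorm(length(F_b), 0, sigma)
      idx <- seq_along(F_b)
    }
  } else if (kind == "spikes") {
    idx <- params$idx
    if (is.null(idx)) {
      n <- params$n %||% 3
      if (n > 0) idx <- sort(sample(seq_along(F_b), min(n, length(F_b))))
    }
    amp <- params$amp_pp %||% c(2, 8)
    if (length(idx)) {
      a <- runif(length(idx), amp[1], amp[length(amp)]) *
        sample(c(-1, 1), length(idx), replace = TRUE)
      F_b[idx] <- F_b[idx] + a
    }
  } else { # overshoot
    t0 <- params$t0
    if (is.null(t0)) stop("overshoot requires params$t0 (infusion end, s)")
    amp <- params$amp_pp %||% 2
    tau <- params$tau_s %||% 90
    sel <- trace$t >= t0
    F_b[sel] <- F_b[sel] + amp * exp(-(trace$t[sel] - t0) / tau)
    idx <- which(sel)
  }
  out <- trace
  out$F_b <- F_b
  attr(out, "artifact_idx") <- idx
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort bundle
#'
#' Draws a cohort of [sim_patient()]s from the configured parameter
#' distributions, simulates the interdialytic week cycles and every
#' intradialytic treatment (with bolus infusions from the configured treatment
#' index onwards, machine dialects with the mid-study model switch, spikes and
#' post-bolus overshoot on high-rate machines), and assembles validated
#' records. Deterministic given `seed`; writing the same cohort twice yields
#' byte-identical bundles.
#'
#' @param config a [dv_config()].
#' @param seed master integer seed; per-patient and per-treatment streams are
#'   derived by fixed offsets.
#' @param out_dir if non-`NULL`, the bundle is written there via
#'   [write_treatment_bundle()].
#' @return (invisibly) list with `records` (as [read_treatment_bundle()]),
#'   `truth` (per-treatment ground-truth list, names = treatment ids),
#'   `states` (per-patient week-cycle data frames) and `patients`.
#' @export
generate_cohort <- function(config = dv_config(), seed = 1, out_dir = NULL) {
  cc <- config$cohort
  n_pat <- cc$n_patients
  patients <- vector("list", n_pat)
  txs <- list(); bios <- list(); truth <- list(); states <- list()
  for (i in seq_len(n_pat)) {
    set.seed(derive_seed(seed, i, 0))
    M_eu <- max(45, rnorm(1, cc$M_eu_mean_kg, cc$M_eu_sd_kg))
    height <- rnorm(1, cc$height_mean_m, cc$height_sd_m)
    p <- sim_patient(
      patient_id = sprintf("P%02d", i),
      M_eu_true = M_eu,
      V_b_eu = max(2.5, rnorm(1, cc$V_b_eu_mean_l, cc$V_b_eu_sd_l)),
      V_ecf_eu = cc$V_ecf_eu_frac * M_eu,
      V_icf_eu = cc$V_icf_frac * M_eu,
      accumulation_rate = max(0.1, rnorm(1, cc$accumulation_mean_l_day,
                                         cc$accumulation_sd)),
      fo_residual = max(0, rnorm(1, cc$fo_residual_mean_l, cc$fo_residual_sd)),
      fo_blood_fraction = cc$fo_blood_fraction,
      K_r = max(0.5, rnorm(1, cc$K_r_mean, cc$K_r_sd)),
      duration_min = max(150, rnorm(1, cc$duration_min_mean, cc$duration_min_sd)),
      height_m = height,
      age = round(max(20, min(90, rnorm(1, cc$age_mean, cc$age_sd)))),
      sex = rbinom(1, 1, cc$p_male),
      LTI = max(6, rnorm(1, cc$lti_mean, cc$lti_sd)),
      FTI = max(3, rnorm(1, cc$fti_mean, cc$fti_sd)),
      machine_initial = if (i %% 2 == 1) "M_1perMin" else "M_3perMin",
      noise = list(sigma_rbv_pp = cc$sigma_rbv_pp, sigma_uf_l = cc$sigma_uf_l,
                   sigma_mass_kg = cc$sigma_mass_kg, sigma_bio_l = cc$sigma_bio_l)
    )
    patients[[i]] <- p
    st <- simulate_week_cycle(p, cc$n_weeks, cc$gap_days,
                              seed = derive_seed(seed, i, 1))
    states[[p$patient_id]] <- st
    for (k in seq_len(nrow(st))) {
      row <- st[k, ]
      machine <- if (row$week_index <= 3) p$machine_initial else
        setdiff(c("M_1perMin", "M_3perMin"), p$machine_initial)
      dt <- if (machine == "M_1perMin") 60 else 20
      inf <- if (row$tx_index >= config$bolus$first_treatment) {
        infusion_event(config$bolus$t_inf_s, config$bolus$V_inf_l,
                       config$bolus$Q_inf_ml_min)
      } else NULL
      sim <- simulate_treatment_trace(row, p, inf, dt = dt,
                                      seed = derive_seed(seed, i, 10 + k),
                                      treatment_id = "tmp")
      rbv <- sim$rbv
      set.seed(derive_seed(seed, i, 200 + k))
      if (machine == "M_3perMin") {
        n_spk <- rpois(1, cc$spike_rate_per_hour * p$duration_min / 60)
        if (n_spk > 0) {
          rbv <- add_artifacts(rbv, "spikes",
                               list(n = n_spk, amp_pp = cc$spike_amp_pp))
        }
        if (!is.null(inf) && runif(1) < cc$overshoot_prob) {
          rbv <- add_artifacts(rbv, "overshoot",
                               list(t0 = inf$t_inf + inf$duration_s,
                                    amp_pp = runif(1, cc$overshoot_amp_pp[1],
                                                   cc$overshoot_amp_pp[2]),
                                    tau_s = cc$overshoot_tau_s))
        }
      }
      bp <- simulate_bp(p, row, cc, seed = derive_seed(seed, i, 300 + k))
      set.seed(derive_seed(seed, i, 400 + k))
      M_post <- row$M_pre_obs - row$uf_net_l + rnorm(1, 0, 0.05)
      M_target <- round((p$M_eu_true + p$fo_residual) * 2) / 2
      tx <- treatment_record(
        p$patient_id, row$study_day, row$week_index, row$weekday_treatment,
        p$duration_min, machine,
        M_pre = row$M_pre_obs, M_post = M_post, M_target = M_target,
        rbv = rbv_trace(paste0(p$patient_id, "_d",
                               sprintf("%02d", row$study_day)),
                        rbv$t, rbv$F_b, machine),
        uf = uf_trace(paste0(p$patient_id, "_d",
                             sprintf("%02d", row$study_day)),
                      sim$uf$t, sim$uf$V_u),
        infusion = inf, bp = bp)
      txs[[length(txs) + 1L]] <- tx
      truth[[tx$treatment_id]] <- c(
        list(V_b_start_true = row$V_b_start_true,
             V_fo_pre_true = row$V_fo_pre_true,
             V_is_excess_true = row$V_is_excess_true),
        list(series = sim$truth))
      bios[[length(bios) + 1L]] <- bioimpedance_record(
        p$patient_id, row$study_day,
        V_ecf = row$V_ecf_obs, V_icf = row$V_icf_obs, V_tbf = row$V_tbf_obs,
        V_isf = row$V_isf_obs, V_fo = row$V_fo_obs,
        F_fo_ecf = row$F_fo_ecf_obs, M_eu = row$M_eu_obs,
        LTI = p$LTI, FTI = p$FTI, BMI = row$M_pre_obs / p$height_m^2)
    }
  }
  records <- list(treatments = txs, bioimpedance = bios)
  if (!is.null(out_dir)) write_treatment_bundle(records, out_dir)
  invisible(list(records = records, truth = truth, states = states,
                 patients = patients))
}

simulate_bp <- function(p, row, cc, seed) {
  set.seed(seed)
  pre_sbp <- round(rnorm(1, cc$sbp_pre_mean, cc$sbp_pre_sd))
  n_intra <- max(2, floor(p$duration_min / 40))
  t_intra <- round(seq(30, p$duration_min - 10, length.out = n_intra))
  drop <- seq(0, rnorm(1, 8, 4), length.out = n_intra)
  intra_sbp <- round(pre_sbp - drop + rnorm(n_intra, 0, 7))
  if (runif(1) < cc$idh_prob) {
    nadir_cut <- if (pre_sbp < 160) 90 else 100
    intra_sbp[sample(n_intra, 1)] <- nadir_cut - sample(3:12, 1)
  }
  post_sbp <- round(pre_sbp - rnorm(1, 4, 8))
  sbp <- c(pre_sbp, intra_sbp, post_sbp)
  sbp <- pmax(sbp, 65)
  dbp <- pmin(round(0.55 * sbp + rnorm(length(sbp), 0, 4)), sbp - 15)
  dbp <- pmax(dbp, 35)
  data.frame(phase = c("pre", rep("intra", n_intra), "post"),
             t_min = c(0, t_intra, p$duration_min),
             SBP = sbp, DBP = dbp, stringsAsFactors = FALSE)
}
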