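test_that("week cycle reproduces the sawtooth closed form", {
  # complete removal each treatment: overload equals rate x preceding gap
  p <- sim_patient("P1", accumulation_rate = 1.0, fo_residual = 0,
                   noise = noise_free)
  st <- simulate_week_cycle(p, 5)
  expect_equal(nrow(st), 14)
  expect_equal(max(st$study_day), 31)
  expect_equal(as.numeric(tapply(st$V_fo_pre_true, st$weekday_treatment,
                                 unique)),
               c(3.0, 2.0, 2.0))
  # first treatment of the week carries the highest overload
  for (w in 2:5) {
    wk <- st[st$week_index == w, ]
    expect_equal(which.max(wk$V_fo_pre_true), 1L)
  }
})

test_that("degenerate accumulation and allocation behave as constructed", {
  p0 <- sim_patient("P1", accumulation_rate = 0, fo_residual = 0,
                    noise = noise_free)
  st0 <- simulate_week_cycle(p0, 2)
  expect_true(all(st0$V_fo_pre_true == 0))
  expect_equal(st0$M_pre_obs, rep(p0$M_eu_true, nrow(st0)))

  pb <- sim_patient("P1", fo_blood_fraction = 0, noise = noise_free)
  stb <- simulate_week_cycle(pb, 3)
  expect_equal(length(unique(stb$V_b_start_true)), 1L)
  expect_equal(unique(stb$V_b_start_true), pb$V_b_eu)
})

test_that("constant-UF no-refilling treatment matches the closed form", {
  p <- sim_patient("P1", K_r = 0, noise = noise_free)
  state <- list(V_b_start_true = 5.0, V_is_excess_true = 2.0, uf_net_l = 2.4)
  tr <- simulate_treatment_trace(state, p, protocol = NULL, dt = 60,
                                 duration_min = 240)
  # Q_u = 2.4 l / 240 min = 10 ml/min; V_b(240 min) = 5.0 - 2.4 = 2.6 l
  end <- nrow(tr$truth)
  expect_equal(tr$truth$V_b[end], 2.6, tolerance = 1e-9)
  expect_equal(tr$rbv$F_b[end], 52, tolerance = 1e-7)
})

test_that("mass is conserved at machine precision and integration is converged", {
  p <- sim_patient("P1", noise = noise_free)
  st <- simulate_week_cycle(p, 2)[3, ]
  inf <- infusion_event(3600, 0.24, 200)
  tr <- simulate_treatment_trace(st, p, inf, dt = 60)
  total <- tr$truth$V_b + tr$truth$V_is_excess + tr$truth$V_u -
    tr$truth$V_inf_cum
  expect_lt(max(abs(total - total[1])), 1e-10)
  # halving the internal step barely moves the endpoint (integration order)
  tr2 <- simulate_treatment_trace(st, p, inf, dt = 60, dt_int = 0.5)
  expect_lt(abs(tr2$truth$V_b[nrow(tr2$truth)] -
                  tr$truth$V_b[nrow(tr$truth)]), 1e-4)  # < 0.1 ml
})

test_that("over-aggressive ultrafiltration raises a simulation error", {
  p <- sim_patient("P1", K_r = 0, noise = noise_free)
  state <- list(V_b_start_true = 3.0, V_is_excess_true = 0, uf_net_l = 3.5)
  expect_error(simulate_treatment_trace(state, p, duration_min = 240),
               "depleted")
})

test_that("artifact injection is exact and logged", {
  tr <- make_step_trace()
  # identity when nothing is injected
  same <- add_artifacts(tr, "gaussian", list(sigma_pp = 0))
  expect_identical(same$F_b, tr$F_b)
  # exactly 3 samples differ for 3 injected spikes
  spk <- add_artifacts(tr, "spikes", list(idx = c(10, 50, 120)), seed = 1)
  expect_equal(which(spk$F_b != tr$F_b), c(10, 50, 120))
  expect_equal(attr(spk, "artifact_idx"), c(10, 50, 120))
  # overshoot decays below 0.1 pp within 3 decay constants x ln(20)
  ov <- add_artifacts(tr, "overshoot", list(t0 = 3672, amp_pp = 2, tau_s = 90))
  excess <- ov$F_b - tr$F_b
  expect_true(all(excess[tr$t >= 3672 + 90 * log(2 / 0.1)] < 0.1))
  # first sample on the 60-s grid after t0 = 3672 sits at 3720
  expect_equal(max(excess), 2 * exp(-(3720 - 3672) / 90), tolerance = 1e-9)
})

test_that("generated cohorts are deterministic and pass validation", {
  cfg <- dv_config(cohort = list(n_patients = 2, n_weeks = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- generate_cohort(cfg, seed = 7, out_dir = d1)
  generate_cohort(cfg, seed = 7, out_dir = d2)
  expect_equal(length(sim$records$treatments), 2 * 5)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  back <- read_treatment_bundle(d1)
  expect_length(back$treatments, 10)
  # schedule gaps preserved: study days follow the (2,2,3) gap pattern
  days <- sort(unique(vapply(back$treatments, `[[`, 0L, "study_day")))
  expect_equal(days, c(1, 3, 6, 8, 10))
})

test_that("the generator spans the fluid-allocation hypothesis contrast", {
  # a small measurement jitter stands in for estimation noise so the
  # correlation is well defined when blood volume carries no overload signal
  mk <- function(f) {
    states <- lapply(1:8, function(i) {
      p <- sim_patient(sprintf("P%d", i), V_b_eu = 4 + 0.2 * i,
                       accumulation_rate = 0.5 + 0.05 * i,
                       fo_blood_fraction = f, noise = noise_free)
      simulate_week_cycle(p, 3)
    })
    sub <- do.call(rbind, Map(cbind, pid = seq_along(states), states))
    set.seed(77)
    y <- sub$V_b_start_true + rnorm(nrow(sub), 0, 0.02)
    rmcorr_pairs(sub$pid, sub$V_fo_pre_true, y)$rho_rm
  }
  expect_lt(abs(mk(0)), 0.2)
  expect_gt(mk(1), 0.99)
})
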