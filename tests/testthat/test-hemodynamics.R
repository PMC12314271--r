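test_that("volume scaling and specific volumes follow the worked arithmetic", {
  ct <- clean_trace(c(0, 60), c(100, 92.9))
  vb <- blood_volume_series(ct, 5.0)
  expect_equal(vb$value, c(5.0, 4.645))
  expect_equal(specific_blood_volume(5.0, 80.65)$V_b_bm, 62.0,
               tolerance = 1e-4)
  sv <- specific_blood_volume(5.0, 80.65, LTM = 36.98)
  expect_equal(sv$V_b_lt, 135.2, tolerance = 1e-3)
  expect_equal(specific_blood_volume(0, 80)$V_b_bm, 0)
  expect_error(specific_blood_volume(5, 0), "positive")
})

test_that("refilling volume closes the mass balance", {
  inf <- infusion_event(3600, 0.24, 200)
  vb <- clean_trace(c(0, 7200, 14340), c(5.0, 4.8, 4.645))
  uf <- clean_trace(c(0, 7200, 14340), c(0, 1.25, 2.5))
  vr <- refilling_volume_series(vb, uf, inf)
  expect_equal(vr$value[3], 4.645 - 5.0 + 2.5 - 0.24)  # 1.905 l
  # no UF, no bolus, flat RBV: zero refilling throughout
  vb0 <- clean_trace(seq(0, 600, 60), rep(5, 11))
  uf0 <- clean_trace(seq(0, 600, 60), rep(0, 11))
  expect_equal(refilling_volume_series(vb0, uf0, NULL)$value, rep(0, 11))
})

test_that("computed series equal simulator truth pre-noise", {
  p <- sim_patient("P1", noise = noise_free)
  st <- simulate_week_cycle(p, 2)[4, ]
  tr <- simulate_treatment_trace(st, p, protocol = NULL, dt = 60)
  vb <- blood_volume_series(clean_trace(tr$rbv$t, tr$rbv$F_b),
                            st$V_b_start_true)
  uf <- clean_trace(tr$uf$t, tr$uf$V_u)
  vr <- refilling_volume_series(vb, uf, NULL)
  expect_equal(vr$value, tr$truth$V_r, tolerance = 1e-9)
  # integrated refilling rate closes against the cumulative volume (< 1%)
  qr <- refilling_rate_series(vb, uf, NULL)$Q_r
  ok <- !is.na(qr$value)
  v_int <- sum((qr$value[ok][-1] + qr$value[ok][-sum(ok)]) / 2 *
                 diff(qr$t[ok]) / 60) / 1000  # ml/min over s -> l
  expect_lt(abs(v_int - vr$value[length(vr$value)]) /
              vr$value[length(vr$value)], 0.01)
})

test_that("refilling rates follow the pointwise mass balance", {
  t <- seq(0, 7200, 60)
  uf <- clean_trace(t, 0.010 * t / 60)          # Q_u = 10 ml/min
  flat <- clean_trace(t, rep(5, length(t)))
  qr <- refilling_rate_series(flat, uf, NULL)$Q_r
  expect_equal(qr$value[qr$retained], rep(10, sum(qr$retained)),
               tolerance = 1e-9)
  # declining blood volume at 5 ml/min: Q_r = -5 + 10 = 5
  dec <- clean_trace(t, 5 - 0.005 * t / 60)
  qr2 <- refilling_rate_series(dec, uf, NULL)$Q_r
  expect_equal(qr2$value[qr2$retained], rep(5, sum(qr2$retained)),
               tolerance = 1e-9)
  # during a bolus-compensating infusion with flat RBV and Q_u = 210
  inf <- infusion_event(3600, 0.24, 200)
  uf210 <- clean_trace(t, 0.210 * t / 60)
  qr3 <- refilling_rate_series(flat, uf210, inf)$Q_r
  during <- qr3$t >= 3600 & qr3$t < 3672
  expect_equal(qr3$value[during], rep(10, sum(during)), tolerance = 1e-9)
})

test_that("refilling fractions guard their denominators", {
  fr <- refilling_fractions(7.3, 10, 1.9, 2.5)
  expect_equal(fr$F_ruq, 73.0)
  expect_equal(fr$F_ruv, 76.0)
  fr0 <- refilling_fractions(5, 0, 1, 2.5)
  expect_true(is.na(fr0$F_ruq))
  expect_true(fr0$masked_q)
  frv <- refilling_fractions(5, 10, 2.5, 2.5)
  expect_equal(frv$F_ruv, 100)
})

test_that("range cleaning masks fractions and rates per the analysis rules", {
  cfg <- dv_config()
  vs <- data.frame(t = c(0, 60, 120), F_b = 100, V_b = 5, V_r = 1, V_u = 1,
                   Q_r = c(5, -60, 5), Q_u = 10,
                   F_ruq = c(250, 50, 50), F_ruv = c(50, 50, -150),
                   retained = TRUE, reason = NA_character_)
  class(vs) <- c("volume_series", "data.frame")
  out <- clean_series(vs, cfg)
  expect_true(is.na(out$F_ruq[1]))
  expect_match(out$reason[1], "fraction_range")
  expect_true(is.na(out$Q_r[2]) && is.na(out$F_ruq[2]))
  expect_match(out$reason[2], "rate_range")
  expect_true(is.na(out$F_ruv[3]))
  # fully clean series gains no masks
  vs$Q_r <- 5; vs$F_ruq <- 50; vs$F_ruv <- 50
  expect_true(all(is.na(clean_series(vs, cfg)$reason)))
})

test_that("flat RBV under active UF forces a 100% rate fraction", {
  set.seed(21)
  for (i in 1:20) {
    qu <- runif(1, 2, 20)           # ml/min
    dur <- sample(120:280, 1) * 60
    t <- seq(0, dur, 60)
    flat <- clean_trace(t, rep(runif(1, 3, 7), length(t)))
    uf <- clean_trace(t, qu / 60000 * t)
    rates <- refilling_rate_series(flat, uf, NULL)
    fr <- refilling_fractions(rates$Q_r$value, rates$Q_u$value, 1, 1)
    expect_equal(fr$F_ruq[!is.na(fr$F_ruq)],
                 rep(100, sum(!is.na(fr$F_ruq))), tolerance = 1e-6)
  }
})

test_that("treatment summaries average the start and end windows", {
  p <- sim_patient("P1", noise = noise_free)
  st <- simulate_week_cycle(p, 2)[4, ]
  inf <- infusion_event(3600, 0.24, 200)
  tr <- simulate_treatment_trace(st, p, inf, dt = 60)
  rec <- make_record(tr$rbv, uf_total_l = st$uf_net_l + 0.24,
                     duration_min = p$duration_min)
  bio <- bioimpedance_record("P01", 1, 20.0, 18.5, 38.5, 14.8, 3, 15, 79,
                             12, 13.8, 26.7)
  res <- analyze_treatment(rec, bio, dv_config())
  expect_equal(res$estimate$quality, "ok")
  s <- res$summary
  expect_equal(s$F_b_ecf, 100 * res$estimate$V_b_start / 20.0)
  # noise-free: summary refilling rates close to simulator truth windows
  tru <- tr$truth
  q_start <- mean(tru$Q_r_ml_min[tru$t <= 1800 & tru$t >= 300])
  expect_equal(s$Q_r_start, q_start, tolerance = 0.15)
  # filtered cumulative UF ends on a shrunken median window: ~1 sample bias
  expect_equal(s$V_u_total, st$uf_net_l + 0.24, tolerance = 0.02)
  expect_equal(s$V_r_total, tru$V_r[nrow(tru)], tolerance = 0.05)
})

test_that("summary handles a fully masked end window with NA and warning", {
  tr <- make_step_trace()
  rec <- make_record(tr)
  pre <- preprocess_treatment(rec, dv_config())
  vs <- volume_series(pre, rec, 5.0, dv_config())
  cut <- (240 - 31) * 60
  vs$Q_r[vs$t >= cut] <- NA
  vs$Q_u[vs$t >= cut] <- NA
  vs$F_ruq[vs$t >= cut] <- NA
  vs$F_ruv[vs$t >= cut] <- NA
  vs$retained[vs$t >= cut] <- FALSE
  expect_warning(s <- summarize_treatment(vs, rec, NULL, 5.0, dv_config()),
                 "masked")
  expect_true(is.na(s$Q_r_end))
})

test_that("Nadir90/100 classification follows both branches", {
  mk <- function(pre, nadir) data.frame(
    phase = c("pre", "intra", "intra", "post"), t_min = c(0, 60, 120, 240),
    SBP = c(pre, nadir + 5, nadir, pre - 5), DBP = c(70, 65, 60, 68))
  expect_true(classify_idh(mk(150, 89)))
  expect_true(classify_idh(mk(165, 95)))
  expect_false(classify_idh(mk(150, 95)))
  expect_false(classify_idh(mk(165, 101)))
  no_pre <- data.frame(phase = "intra", t_min = 60, SBP = 80, DBP = 50)
  expect_true(is.na(classify_idh(no_pre)))
})
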