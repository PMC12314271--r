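test_that("median filter matches the worked example and degenerate cases", {
  ct <- clean_trace(c(0, 60, 120, 180, 240), c(100, 99, 120, 98, 97))
  out <- median_filter(ct, window_s = 180)
  expect_equal(out$value, c(99.5, 100, 99, 98, 97.5))
  # constants unchanged
  cc <- clean_trace(seq(0, 600, 60), rep(5, 11))
  expect_equal(median_filter(cc, 313)$value, rep(5, 11))
  # window shorter than one sampling interval: identity
  noisy <- clean_trace(seq(0, 600, 60), rnorm(11))
  expect_equal(median_filter(noisy, 30)$value, noisy$value)
  # all-excluded input errors
  dead <- clean_trace(c(0, 60), c(1, 2), retained = c(FALSE, FALSE),
                      reason = c("manual", "manual"))
  expect_error(median_filter(dead), "excluded")
})

test_that("median filter equals the brute-force sliding median on random traces", {
  set.seed(11)
  for (case in 1:200) {
    n <- sample(3:60, 1)
    dt <- sample(c(20, 60), 1)
    t <- seq(0, by = dt, length.out = n)
    v <- rnorm(n, 100, 3)
    w <- runif(1, 10, 600)
    expect_equal(median_filter(clean_trace(t, v), w)$value,
                 brute_median_filter(t, v, w), tolerance = 1e-12)
  }
})

test_that("despiking flags injected spikes and only those", {
  tr <- make_step_trace(dt_s = 20, noise_sd = 0.2, seed = 3)
  idx <- c(40, 200, 500)
  spiked <- add_artifacts(tr, "spikes", list(idx = idx, amp_pp = c(5, 5)),
                          seed = 4)
  out <- despike(spiked)
  expect_equal(which(!out$retained), idx)
  expect_equal(unique(out$reason[!out$retained]), "spike")
  # spike-free trace: nothing masked
  clean <- despike(tr)
  expect_equal(sum(!clean$retained), 0)
  # flat trace with one spike: caught despite MAD = 0 (epsilon floor)
  flat <- clean_trace(seq(0, 1200, 20), rep(100, 61))
  flat$value[30] <- 103
  expect_equal(which(!despike(flat)$retained), 30L)
})

test_that("despiking caps the masked fraction and warns", {
  set.seed(5)
  t <- seq(0, 2400, 20)
  v <- rep(100, length(t))
  bad <- sample(length(t), 30)  # 25% corrupted
  v[bad] <- 100 + runif(30, 4, 9)
  expect_warning(out <- despike(clean_trace(t, v)), "cap")
  expect_lte(sum(!out$retained), floor(0.1 * length(t)))
  expect_true(attr(out, "despike_capped"))
})

test_that("exclusion windows follow the early and peri-bolus rules", {
  tr <- make_step_trace()  # 1/min grid
  inf <- infusion_event(3600, 0.24, 200)
  expect_equal(inf$duration_s, 72)
  out <- apply_exclusion_windows(as_clean_trace(tr), inf)
  # early: t < 300 s
  expect_equal(out$reason[out$t < 300], rep("early", 5))
  # peri-bolus: [t_inf - 60, t_inf + 72 + 300]
  peri <- out$t >= 3540 & out$t <= 3972
  expect_true(all(!out$retained[peri]))
  expect_equal(unique(out$reason[peri]), "peri_bolus")
  expect_true(all(out$retained[out$t >= 300 & out$t < 3540]))
  expect_true(all(out$retained[out$t > 3972]))
  # no infusion: only the early window is masked
  out2 <- apply_exclusion_windows(as_clean_trace(tr), NULL)
  expect_equal(sum(!out2$retained), 5)
  # infusion at trace end: truncated window, no error
  out3 <- apply_exclusion_windows(as_clean_trace(tr),
                                  infusion_event(240 * 60 - 30))
  expect_true(all(!out3$retained[out3$t >= 240 * 60 - 90]))
})

test_that("filtering a masked trace equals filtering the retained subset", {
  # order contract: excluded samples are invisible to the filter, so
  # mask-then-filter must agree with filtering the restriction
  tr <- make_step_trace(noise_sd = 0.3, seed = 8)
  inf <- infusion_event(3600)
  masked <- apply_exclusion_windows(as_clean_trace(tr), inf)
  a <- median_filter(masked, 313)
  keep <- masked$retained
  b <- median_filter(clean_trace(masked$t[keep], masked$value[keep]), 313)
  expect_equal(a$value[keep], b$value, tolerance = 1e-12)
})

test_that("filtered cumulative UF is non-decreasing at moderate noise", {
  set.seed(9)
  t <- seq(0, 14340, 60)
  vu <- 2.5 * t / max(t) + rnorm(length(t), 0, 0.003)
  out <- median_filter(clean_trace(t, vu), 313)
  expect_true(all(diff(out$value) >= -1e-12))
})
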