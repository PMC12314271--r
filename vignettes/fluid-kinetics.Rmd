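---
title: "Fluid-volume kinetics in hemodialysis: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluid-volume kinetics in hemodialysis: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialvol)
```

## The problem

Dialysis machines monitor blood volume only *relatively*: the RBV signal
`F_b(t)` expresses intravascular volume as a percentage of its value at
treatment start. Absolute volumes matter clinically — the same 10% drop
means something different in a 4-l and a 7-l circulation — and they are the
key to quantifying vascular refilling, the flux of interstitial fluid into
the vasculature that partially offsets ultrafiltration. `dialvol`
implements the dialysate-bolus route to absolute blood volume and the
mass-balance decomposition of refilling, embedded in the longitudinal
statistics needed for cohorts on a thrice-weekly schedule.

## Measurement model and assumptions

A bolus of ultra-pure dialysate of known volume $V_\mathrm{inf}$ is infused
in pre-dilution mode at a known rate. On the start-normalized RBV scale, an
instantaneous well-mixed dilution by $V_\mathrm{inf}$ raises the signal by

$$\Delta F_b = 100 \cdot \frac{V_\mathrm{inf}}{V_{b,\mathrm{start}}}
\quad\Longleftrightarrow\quad
V_{b,\mathrm{start}} = \frac{100 \cdot V_\mathrm{inf}}{\Delta F_b}.$$

Assumptions: (i) the RBV sensor tracks hemoconcentration linearly over the
step; (ii) mixing is fast relative to the baseline windows; (iii) the
machine adds the infusion volume to the ultrafiltration target, so the
bolus does not change the net fluid balance (the cumulative-UF convention
throughout the package: `V_u` *includes* the bolus compensation); (iv)
start-normalization makes the step scale directly to treatment-start
volume, so no back-correction from infusion time to start is applied.

Given $V_{b,\mathrm{start}}$, absolute volume is
$V_b(t) = V_{b,\mathrm{start}} F_b(t)/100$, specific volumes divide by
post-dialysis body mass or lean tissue mass, and the refilling measures
follow from mass balance on the vascular compartment:

$$V_r(t) = V_b(t) - V_b(0) + V_u(t) - V_{\mathrm{inf,cum}}(t), \qquad
Q_r(t) = \frac{dV_b}{dt} + Q_u(t) - Q_\mathrm{inf}(t),$$

with refilling fractions $F_{r/u,q} = 100\,Q_r/Q_u$ and
$F_{r/u,v} = 100\,V_r/V_u$. These identities hold *by construction* on the
cleaned series; the tests verify them against the simulator's ground truth
and against the time-integral of $Q_r$.

## Signal cleaning

* **Renormalization.** Machines normalize internally, but dialects differ;
  every trace is rescaled so its first retained sample reads exactly 100%.
  Whether machines anchor at treatment start or at the first post-priming
  sample is not observable from the exported stream; renormalization makes
  synthetic and real dialects uniform and is our declared convention.
* **Despiking** (high-rate 3/min machines). A sample is a spike when its
  deviation from the local leave-one-out running median exceeds
  `z_thresh = 5` times a robust scale. The scale is the local MAD *floored
  by* the trace-wide MAD of running-median residuals and by an absolute
  0.05-pp epsilon. The global floor matters: a 313-s window holds only
  ~15 samples at 3/min, and the sample MAD of 15 Gaussian draws
  occasionally collapses far below the true noise scale, which would flag
  ordinary noise. The epsilon floor catches isolated spikes on flat
  segments where every MAD is zero. At most 10% of samples may be masked;
  beyond that the worst offenders are masked, a warning is raised and the
  trace is flagged.
* **Exclusion windows.** The first 5 min of treatment and the interval from
  1 min before infusion start to 5 min after infusion *end*
  (end = start + $V_\mathrm{inf}/Q_\mathrm{inf}$, 72 s at the defaults) are
  masked. Masked samples are invisible to every downstream computation; no
  interpolation is performed across them.
* **Median filter.** A centered *time* window of 313 s (~5 samples at
  1/min, ~15 at 3/min) over retained samples, shrinking at the trace
  boundaries; the median of an even-sized window is the mean of the two
  central values. Applied to RBV (for the volume series) and cumulative UF.

## Step quantification: design of the baseline fits

The bolus step is measured as the difference of two least-squares lines —
one fitted to a pre-bolus window, one to a post-bolus window — extrapolated
to the infusion midpoint. Three numerical choices deserve justification:

1. **Fits run on the unfiltered (despiked, masked) trace.** A least-squares
   line already averages noise; median filtering adds nothing to precision
   but biases the samples adjacent to the peri-bolus mask, where the filter
   window shrinks asymmetrically on a sloped signal. On a noise-free
   piecewise-linear trace that edge bias alone shifts the recovered volume
   by about half a percent.
2. **Windows are long and roughly mirrored about the infusion midpoint**
   (pre $[-36, -4]$ min, post $[+5, +37]$ min relative to infusion start;
   the post window effectively begins after the peri-bolus exclusion).
   Mirroring cancels the leading-order extrapolation bias caused by the
   slow curvature of the RBV trend (refilling decays over hours, so the
   limbs are gently curved, not straight); length controls the
   extrapolation variance, which is dominated by the slope error times the
   window-center-to-midpoint distance. Window lengths were chosen on an
   independent simulation stream and validated on fresh streams and both
   machine dialects; the test suite verifies noise-free recovery to better
   than 0.1% and a median relative error below 5% at 0.5-pp Gaussian noise
   and 1/min sampling.
3. **Screening is codified, not manual**: estimates are excluded when the
   volume leaves [2, 12] l, the step is below 3 pre-window residual SDs, or
   the pre-window residual SD exceeds 1 pp; a strongly rising post window
   (slope > 0.1 pp/min) with a post residual SD more than 3 times the pre
   SD is rejected as an unresolved overshoot. Every exclusion carries a
   machine-readable reason, and the per-run exclusion rate is reported.

All windows and thresholds are config keys (`dv_config()$estimate`,
`$clean`) with the defaults above.

## Tunable constants

| Key | Default | Units | Meaning |
|---|---|---|---|
| `bolus$t_inf_s` | 3600 | s | infusion start (~60 min into treatment) |
| `bolus$V_inf_l` | 0.240 | l | bolus volume |
| `bolus$Q_inf_ml_min` | 200 | ml/min | infusion rate (72-s bolus) |
| `bolus$first_treatment` | 3 | – | first session with a bolus |
| `clean$window_s` | 313 | s | median-filter window |
| `clean$early_min` | 5 | min | early exclusion |
| `clean$peri_pre_min`, `peri_post_min` | 1, 5 | min | peri-bolus margins |
| `clean$z_thresh`, `mad_floor`, `max_frac` | 5, 0.05 pp, 0.10 | – | despiking |
| `estimate$pre_window_min`, `post_window_min` | (−36, −4), (5, 37) | min | baseline windows |
| `estimate$vb_range_l` | (2, 12) | l | plausibility range |
| `estimate$snr_mult`, `resid_sd_max_pp` | 3, 1.0 pp | – | screening |
| `hemo$deriv_window_s` | 300 | s | derivative regression window |
| `hemo$avg_window_min` | 30 | min | start/end averaging |
| `hemo$frac_lo_pct`, `frac_hi_pct`, `qr_min_ml_min` | −100, 200, −50 | %, ml/min | range filters |
| `hemo$qu_eps_ml_min`, `vu_eps_l` | 1, 0.05 | ml/min, l | denominator guards |
| `stats$n_boot` | 1000 | – | bootstrap resamples |
| `stats$fo_threshold_pct` | 15 | % | overload stratification |

The range filters and the 313-s/30-min/5-min/−1+5-min windows follow the
published analysis conventions for this data type; the denominator guards,
despiking constants and baseline windows are this package's own, exposed in
config.

## Statistics layer

* **Mixed models.** `value ~ study_day + weekday_treatment (+ age + sex)`
  with patient random intercepts; the weekday index is numeric 1–3, so a
  single slope captures the within-week trend (the convention under which a
  single coefficient per variable is reportable). Random study-day slopes
  are included if they lower the ML AIC; the chosen structure is refitted
  by REML. Fixed-effect CIs and p-values use a t reference with
  `n_patients − 1` degrees of freedom: a coverage simulation at this
  cohort's size (25 patients × 14 occasions) showed the plain Wald-normal
  interval slightly undercovering (~93%), while the cluster-count t keeps
  coverage at its nominal level (the suite checks 93–97% over 400
  simulations). Satterthwaite/Kenward–Roger machinery is intentionally not
  a dependency. Singular or failed random-slope fits fall back to the
  intercept-only structure with a convergence flag.
* **Repeated-measures correlation.** The ANCOVA formulation: regress `y` on
  the subject factor plus `x`; the common within-subject correlation is the
  signed square root of `SS_x / (SS_x + SS_error)` with
  `error_df = n_pairs − n_subjects − 1`; p from the F statistic, CI by
  Fisher z with that df. This equals the Pearson correlation of
  within-subject-centered values, which is the independent oracle used in
  the tests.
* **Multiplicity.** Benjamini–Hochberg across *all* p-values emitted in one
  pipeline run (both fixed effects of every mixed model plus the whole
  correlation matrix) — the widest defensible reading of "across all
  analyses"; the family membership is visible in the report tables.
* **Bootstrap CIs** of the mean are percentile-based with 1000 resamples
  (count and method are conventions, neither is critical at these sample
  sizes); single observations return a degenerate interval with a warning.
* **Coefficients of variation** are `100·SD/|mean|` per patient (≥2
  observations), then averaged over the cohort.

## The synthetic cohort: what it does and does not emulate

The generator's world is fixed, not fitted: 25 patients, 5 weeks, 14
treatments on a (2,2,3)-day schedule starting at the week's second session
(study days 1–31); interdialytic fluid accumulation ~0.95 l/day toward a
pre-dialysis overload of ~3 l, removed each session down to a ~0.8-l
residual (sawtooth); euvolemic mass and intracellular volume constant up to
noise; a 240-ml bolus from the third session onward; half the cohort on
1/min machines and half on 3/min, switching models after week 3; Gaussian
measurement noise (0.3 pp RBV, 5 ml UF, 0.4 kg mass, 0.3 l bioimpedance),
Poisson spikes and occasional post-bolus overshoot on high-rate machines.
Intradialytic kinetics follow two compartments with explicit-Euler
integration at 1 s:

$$\frac{dV_b}{dt} = Q_r - Q_u + Q_\mathrm{inf}, \qquad
\frac{dV_{is}}{dt} = -Q_r, \qquad
Q_r = K_r \cdot \max(V_{is} - V_{is,\mathrm{eq}}, 0),$$

with $K_r = 4.8$ ml/min per litre of interstitial excess, chosen together
with the accumulation parameters so that the simulated cohort reproduces
the canonical magnitudes of this population (start blood volume ~5 l, UF
total ~2.2–2.5 l over ~239 min, end RBV ~93%). The share of excess fluid
allocated to blood (`fo_blood_fraction`, default 0.1) spans the competing
hypotheses: 0 makes blood volume independent of overload, 1 makes them
proportional.

Known departures from real data, hence what a green test does *not*
establish:

* The linear interstitial-excess refilling law yields a refilling rate that
  *declines* monotonically within a treatment. Real cohorts show rates
  rising toward treatment end (blood-side Starling forces dominate late);
  the simulator therefore overstates early refilling and understates late
  refilling, and tests validate computation, not late-treatment physiology.
* Osmotic red-cell water shifts on optical monitors, bioimpedance model
  error, pre-dialysis tissue-sodium effects and non-random missingness are
  not modeled; the default world has complete data.
* Blood-pressure series are stylized (a drift plus noise with a forced
  nadir in ~9% of treatments) — sufficient for classifying, not for
  hemodynamic modeling.
* The default artifact levels leave essentially all bolus estimates
  passing the screen; real data lose of the order of a third of estimates.
  Screening behaviour under heavy artifacts is exercised by dedicated
  tests, not by the default cohort.

## Numerical choices and degenerate inputs

* Explicit Euler with a 1-s internal step: the kinetics are smooth and
  nearly linear at that scale; halving the step moves the endpoint by less
  than 0.1 ml (tested), and mass
  $V_b + V_{is} + V_u - V_{\mathrm{inf,cum}}$ is conserved to machine
  precision at every step.
* Derivatives ($dV_b/dt$, $Q_u$) are slopes of centered 5-min regression
  windows over retained samples; two-point differences are unusably noisy
  at 1/min. Windows with fewer than two samples mask the sample.
* A step of exactly zero is rejected with an explicit epsilon (1e-9 pp) so
  floating-point rounding cannot rescue it; screening would otherwise catch
  the absurd volume anyway.
* Refilling fractions guard their denominators (`Q_u` ≤ 1 ml/min,
  `V_u` ≤ 0.05 l are masked rather than divided); the published range
  filters (fractions outside (−100%, 200%), rates below −50 ml/min) are
  applied verbatim on top.
* Ties and edges: even-window medians average the central pair; filter and
  derivative windows shrink at boundaries; the cumulative-UF total read
  from the filtered trace carries a ≲1-sample boundary bias (~0.01 l),
  accepted and documented in the tests.
* Bundles are written with fixed 6-decimal formatting, making
  write–read–write cycles byte-identical (tested), and all randomness
  derives from one master seed via fixed offsets, so any single treatment
  is reproducible in isolation.

## Open design points resolved here

* **Schedule length.** "n weeks" means: start at the week's second session,
  end at week n's third — `3n − 1` sessions per patient (14 for the
  reference five-week study; a floor of two sessions applies to n = 1).
* **Renormalization** to the first retained sample (above).
* **UF convention.** `V_u` includes the bolus compensation; this is the
  only convention under which the mass-balance decomposition reproduces the
  canonical refilling volume from the canonical start volume, end RBV and
  UF total (5.0, 92.9%, 2.5 l → 1.9 l).
* **Weekday coding** is numeric (1–3), making the within-week trend a
  single slope; treating it as categorical is a trivial user-side change.

## Limitations

Beyond the generator's physiological simplifications above: the
bolus-dilution method presumes a stable baseline around the infusion —
treatments with erratic RBV around minute 60 are excluded rather than
rescued; mixed-model inference uses a conservative df approximation rather
than Satterthwaite; and the package deliberately does not model
plasma-vs-whole-blood distinctions, red-cell volume, or anthropometric
blood-volume equations (the last would presuppose the mass–volume coupling
these analyses are designed to test).
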