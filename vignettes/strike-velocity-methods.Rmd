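---
title: "Measuring strike velocity from a wrist- or shin-mounted smartphone accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring strike velocity from a wrist- or shin-mounted smartphone accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikevel)
```

## The measurement model

A smartphone strapped to the distal wrist (punches) or distal calf (kicks)
records triaxial acceleration while an athlete delivers maximal strikes at
a heavy bag. Because the sensor's orientation relative to the limb and the
world changes throughout a strike, `strikevel` works exclusively on the
acceleration norm

$$A(t) = \sqrt{A_x(t)^2 + A_y(t)^2 + A_z(t)^2},$$

an orientation-free scalar. This sidesteps sensor fusion at a known cost:
the integrated velocity is a speed along the (curved) sensor path in the
local frame, not a displacement rate in a global frame. For near-linear
ballistic strikes the two are close; for strongly curved movements the norm
integral overestimates the straight-line velocity. Within one protocol the
measure is used *relatively* — for tracking change and quantifying
repeatability — which is exactly what the reliability battery assesses.

The test protocol assumed by the defaults: the athlete holds a stationary
guard for 5 s (a pure noise window used to characterize the noise floor),
then delivers 5 maximal strikes with at least 10 s rest between them.

## Segmentation

1. **Threshold.** Fixed mode uses 2 m/s², the noise ceiling established by
   inspection of guard-position recordings for this protocol; it
   presupposes gravity-free ("linear acceleration") sensor output, which is
   why `analyze_session()` warns prominently when the median baseline norm
   lies in [8.5, 11] m/s² — the signature of a gravity-contaminated trace —
   and subtracts the median baseline norm only when the user explicitly
   opts in (`subtract_gravity = TRUE`); data are never silently altered.
   Adaptive mode (mean + k·SD of the baseline norm, k = 3 by default)
   re-estimates the floor per recording, useful across heterogeneous
   phones.
2. **Impact detection.** The instant of bag contact is the maximum of
   A(t). With five strikes per file, detection is iterative max-and-mask:
   take the global maximum of the unmasked region after the baseline, mask
   ±1 s around it (conservative, given ≥ 10 s rest), repeat up to
   `n_strikes` times or until nothing exceeds the threshold. A shortfall
   is a warning plus a shorter result, never an error: partial data is
   still data.
3. **Onset.** From each peak the series is traversed backwards to the
   first sample *strictly* below the threshold (a sample exactly at the
   threshold does not stop the scan). The backward scan is bounded at
   0.6 s, matching the display window within which real strikes were
   observed to complete; if no crossing exists in that window the segment
   is flagged `"no onset crossing"` rather than silently extended.
4. **Validity screen.** Real protocols discard repetitions with execution
   abnormalities or sensor read errors. Those judgements are
   operationalized here as: at least 3 samples, duration within
   [0.04, 0.6] s, all samples finite. All bounds are config keys
   (`strike_config()`); duration comparisons carry a 1e-9 s tolerance so a
   segment of exactly the minimum duration on an accumulated float grid is
   not rejected by rounding.

Indices are 1-based and segments inclusive of both endpoints, following R
convention.

## Velocity integration

Over the segment the norm is integrated with the trapezoidal rule using
actual per-interval time steps (no resampling),

$$v_j = \sum_{k=1}^{j} \frac{A(t_{k-1}) + A(t_k)}{2}\,\Delta t_k,
\qquad v_0 = 0,$$

with the initial velocity zero because the guard position is stationary.
Integration stops at the peak — nothing after impact contributes. Because
the integrand is a non-negative norm, the profile is monotone and the
velocity *at* impact is also the maximum velocity of the segment; this
differs from component-wise integration and is documented deliberately.
The session average is the mean and the session peak the maximum of the
valid strikes' impact velocities; aggregation happens at full precision,
with rounding to 2 decimals only in printed/written output.

## Reliability battery

Given an $n \times k$ subjects × sessions table (complete cases only,
$n \ge 3$, $k = 2$ in the standard design):

* **CV%** $= 100\,SD/M$ with the sample SD ($n-1$ denominator; the
  classical formula leaves the denominator open and the sample SD is the
  standard choice for small samples). Within-day CVs use the valid strikes
  of one session; between-day CVs use each subject's two session values.
* **ICC(3,1)**, the two-way mixed, single-measure, *consistency*
  intraclass correlation (Shrout–Fleiss Case 3):
  $\mathrm{ICC} = (MS_B - MS_E)/(MS_B + (k-1)MS_E)$ from the two-way
  decomposition with subjects and sessions as factors. Session effects are
  fixed, so a constant between-day offset does not lower the coefficient.
  The 95% CI is the Shrout–Fleiss F-based interval with
  $F = MS_B/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of freedom.
* **SEM** $= \sqrt{MS_E}$ from the *same* decomposition — chosen over the
  one-way variant for consistency with ICC(3,1) — and SEM% relative to the
  grand mean.
* **Bland–Altman** 95% limits of agreement $MD \pm 1.96\,SD(d)$ on the
  session 2 − session 1 differences. The direction is a convention; it
  affects only signs of MD and *t*, never magnitudes or the LOA width.
  The identity $LOA_{up} + LOA_{low} = 2\,MD$ holds by construction and is
  used as an internal-consistency check on published tables.
* **Paired t-test** (two-sided, df $= n-1$) for systematic bias, with the
  zero-SD degenerate case handled explicitly ($t=0, p=1$ for zero mean
  difference; $\pm\infty, p=0$ otherwise).

Reported precision mirrors common practice: ICC and SEM to 3 decimals,
CV to 2.

## The synthetic generator

`simulate_trace()` emulates the protocol with a half-sine pulse model:
each strike contributes $a(t) = A\sin(\pi(t-t_0)/T)$ on $[t_0, t_0+T]$,
projected on a per-strike unit direction, plus i.i.d. Gaussian noise per
axis. The half-sine was chosen for its closed-form integrals, not for
biomechanical fidelity — real strike profiles are asymmetric (longer
acceleration build-up, very sharp impact deceleration) and superimpose
limb-rotation components. Defaults are A = 80 m/s², T = 0.1 s, 50 Hz
sampling, 5 strikes, 5 s baseline, 10 s spacing, noise SD 0.3 m/s² per
axis (a realistic guard-position noise floor, comfortably below the
2 m/s² threshold).

**Ground truth.** The pipeline integrates onset → peak, and the norm peak
of a half-sine sits mid-pulse, so the matching analytic truth is
$\int_{t_0}^{t_p} a\,dt = \frac{AT}{\pi}\bigl(1 - \cos(\pi(t_p-t_0)/T)\bigr)$
evaluated at the *sampled* norm's peak time $t_p$ (equal to $AT/\pi$ when
a sample lands exactly mid-pulse). The full-pulse value $2AT/\pi$ is
reported alongside for sampling-rate studies. Defining truth at the peak
*sample* isolates the trapezoid's discretization error from the peak
localization granularity; both shrink as the rate grows. One discrete
artifact is worth knowing: when $f_s T$ is even, the two samples
flanking mid-pulse tie in exact arithmetic and the winner is decided by
floating-point rounding (or noise) — truth and pipeline resolve the tie
identically on noise-free input because they evaluate the same array.

`simulate_cohort()` generates session scores $x_{is} = \mu_i +
\delta_{is}$, $\mu_i \sim N(\mu_{pop}, \sigma_b)$, $\delta_{is} \sim
N(0, \sigma_w)$, with analytic $\mathrm{ICC} =
\sigma_b^2/(\sigma_b^2+\sigma_w^2)$. Defaults ($\mu_{pop} = 6.11$,
$\sigma_b = 1.06$, $\sigma_w = 0.488$ m/s) reproduce the jab-average
velocity distribution of a trained adult cohort, with the within-subject
SD set to the SEM scale observed for that metric. What the simulations do
**not** model: drift and bias instability (irrelevant over < 1 s
segments), sensor saturation and clipping, bag recoil, inter-strike
fatigue trends, non-Gaussian movement artifacts. Passing tests therefore
demonstrate algorithmic correctness under the stated signal model, not
field validity of the hardware.

## Sampling-rate considerations

An impact transient of width 15 ms — reported for experienced boxers'
straight punches — is guaranteed to contain a sample only if the sampling
interval is at most 15 ms, i.e. at `required_sampling_rate(0.015)` =
67 Hz; treating that as the signal bandwidth, Nyquist demands
`nyquist_rate(0.015)` = 134 Hz for full reconstruction. Phone sensors
commonly deliver 50 Hz, which is why `sampling_rate_study()` quantifies
what is lost: detection collapses once the pulse fits between samples,
and at full detection the trapezoid bias falls with rate (about 3.3% at
50 Hz versus 0.03% at 500 Hz for the default pulse, as the test suite and
acceptance script measure).

## Numerical and design choices

* Non-uniform timestamps are honoured exactly; nothing is resampled.
* Ties at the detection maximum resolve to the earliest sample.
* The gravity heuristic warns but never modifies data without
  `subtract_gravity = TRUE`.
* Degenerate inputs (all-noise traces, all-identical reliability
  matrices, 2-sample segments) produce flagged results or precise errors,
  never crashes; an all-identical matrix makes ICC mathematically
  undefined (zero denominator) and is reported as such.
* Problem sizes in the test and acceptance batteries — 200 random
  matrices for oracle equivalence, 500 replicate cohorts at n = 38 for
  parameter recovery, 5-pulse traces at 50–1000 Hz — were chosen to
  estimate each quantity to well inside its assertion tolerance.
* Stochastic functions take explicit seeds; every stochastic test states
  its seed.

## Known limitations

Velocities live in the local sensor frame; the norm integral conflates
translation with rotation of the limb; the half-sine is a stylized pulse;
the 2 m/s² default threshold is protocol-specific and should be
re-estimated (adaptive mode) when hardware or mounting changes; and
reliability statistics on $k = 2$ sessions estimate variance components
with wide uncertainty at small $n$ — the CI on ICC(3,1) makes that
explicit.
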