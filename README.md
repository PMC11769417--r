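# strikevel

Strike velocity measurement and test–retest reliability analysis for
smartphone-IMU recordings of punches and kicks.

## The problem

Striking velocity is a key performance indicator in boxing, kickboxing,
Karate and Taekwondo, but the gold-standard tools for measuring it
(marker-based motion capture) are expensive and immobile. A low-cost
alternative straps an ordinary smartphone to the athlete's wrist or shin and
records the built-in triaxial accelerometer (e.g. with the PhyPhox app)
while the athlete strikes a heavy bag. `strikevel` implements the complete
measurement chain for such recordings, for sport scientists and coaches who
want velocity numbers and, just as importantly, want to know how repeatable
those numbers are.

## The method

Everything operates on the orientation-free **acceleration norm**

    A(t) = sqrt(Ax(t)^2 + Ay(t)^2 + Az(t)^2)

so no gyroscope, magnetometer or pose estimation is needed.

1. **Segmentation.** A recording starts with ~5 s of stationary
   guard-position data, which characterizes the noise floor; the onset
   threshold is either the fixed 2 m/s² established for this protocol or
   re-estimated as mean + k·SD of the baseline norm. Impact instants are
   the maxima of A(t) (iterative max-and-mask for multi-strike files).
   From each peak `A_peak` the series is traversed backwards to the first
   sample strictly below the threshold, `A_initial`; the inclusive slice
   `[A_initial, A_peak]` is the strike.
2. **Integration.** The impact velocity is the trapezoidal-rule integral
   of A(t) over the segment,
   `v = Σ_k (A(t_{k-1}) + A(t_k))/2 · Δt_k`,
   using the actual per-interval time steps. Session metrics are the
   average and the peak of the valid strikes' impact velocities.
3. **Reliability battery** on subjects × sessions tables: within- and
   between-day CV% (`100·SD/mean`, sample SD), the two-way mixed
   single-measure consistency **ICC(3,1)** after Shrout & Fleiss,
   `(MS_B − MS_E)/(MS_B + (k−1)·MS_E)` with its F-based 95% CI, the
   **SEM** `sqrt(MS_E)` from the same ANOVA decomposition, **Bland–Altman**
   95% limits of agreement `MD ± 1.96·SD(d)`, and a paired *t*-test.
4. **Synthetic validation.** A signal generator produces traces of
   half-sine acceleration pulses `a(t) = A·sin(π(t−t0)/T)` with
   closed-form velocity integrals, plus cohorts with known
   between-/within-subject variance components (analytic
   ICC = σ_b²/(σ_b²+σ_w²)), so every stage is testable without recorded
   data. A sampling-rate study quantifies detection and integration bias;
   a 15 ms punch impact needs ≥ 67 Hz for guaranteed detection and 134 Hz
   by the Nyquist criterion.

## Worked example

```r
library(strikevel)

# a synthetic 5-strike session: half-sine pulses, A = 80 m/s^2, T = 0.1 s,
# 250 Hz, guard-position noise SD 0.3 m/s^2 per axis
sim <- simulate_trace(noise_sd = 0.3, sampling_rate = 250, seed = 42)
analyze_session(sim$trace)
#> <session_result> simulated
#>   threshold 2 m/s^2, 5 strike(s) detected, 5 valid
#>  strike onset_time peak_time duration_s n_samples impact_velocity valid
#>       1          6     6.048      0.048        13            2.39  TRUE
#>       2         16    16.048      0.048        13            2.38  TRUE
#>       3         26    26.052      0.052        14            2.70  TRUE
#>       4         36    36.052      0.052        14            2.70  TRUE
#>       5         46    46.052      0.052        14            2.71  TRUE
#>   session average 2.58 m/s, session peak 2.71 m/s
```

Each row is one detected strike: its onset (`A_initial`) and impact
(`A_peak`) times, segment duration and sample count, and the integrated
impact velocity in m/s (near the analytic onset-to-peak value
A·T/π ≈ 2.55 m/s for these pulses). The session average and peak are the
two metrics carried into reliability analysis.

```r
# a simulated 38-athlete two-session cohort at the package's reference
# condition (mean 6.11 m/s, sigma_between 1.06, sigma_within 0.488)
cohort <- simulate_cohort(n_subjects = 38, seed = 42)
reliability_report(cohort$table)
#> <reliability_report> 'simulated' (n = 38 subjects)
#>   between-day CV: min 0.39%, mean 5.45%, max 18.07%
#>   ICC(3,1) 0.913, 95% CI [0.839, 0.954]
#>   SEM 0.376 m/s (6.11% of mean)
#>   Bland-Altman MD 0.009 m/s, 95% LOA [-1.034, 1.052]
#>   paired t(37) = 0.104, p = 0.917, MD = 0.009 m/s
```

ICC(3,1) is relative test–retest reliability (1 = perfect consistency),
SEM the absolute measurement error in m/s, the limits of agreement the
range within which 95% of between-session differences fall, and the
non-significant paired *t* indicates no systematic bias between sessions.

## Command line

A thin shim over the same functions is installed at
`inst/cli/strikevel`:

```sh
strikevel analyze session.csv --out results.csv
strikevel reliability day1.csv day2.csv --out report.csv
strikevel simulate --seed 7 --out trace.csv --truth truth.csv
strikevel rate-study --rates 50,100,200,500 --durations 0.015,0.1
```

Input for `analyze` is a PhyPhox accelerometer CSV (header + time and
x/y/z acceleration columns; comma or semicolon delimited, "." or ","
decimals). `reliability` takes two session-level CSVs with columns
`subject_id,value`. Every `--out` run writes a provenance YAML (package
version, arguments, resolved configuration) next to its output.

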