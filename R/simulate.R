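# Synthetic accelerometer signals with analytic ground truth. Each strike is
# a half-sine acceleration pulse a(t) = A sin(pi (t - t0) / T) on
# [t0, t0 + T], projected on a unit direction vector, with i.i.d. Gaussian
# noise per axis. The half-sine admits closed-form velocity integrals:
# onset to the sampled norm's peak gives (A T / pi) (1 - cos(pi (tp - t0)/T))
# (equal to A T / pi when the peak sample sits exactly mid-pulse), and the
# full pulse gives 2 A T / pi.

#' Simulate a strike-test accelerometer trace with ground truth
#'
#' Emulates the field protocol: a noise-only guard-position baseline,
#' followed by `n_strikes` well-separated half-sine acceleration pulses of
#' amplitude `amplitude` and duration `pulse_duration`, each preceded by a
#' short lead-in after the (virtual) strike command. Per-axis white Gaussian
#' noise is added throughout. Deterministic for a given `seed`.
#'
#' Ground truth per strike: the onset time, the continuous pulse peak time
#' (`t0 + T/2`), the time of the noise-free sampled norm's maximum (which is
#' what the pipeline's peak detector sees at zero noise), the analytic
#' velocity integral from onset to that peak sample (`v_impact`, the
#' quantity the pipeline estimates), and the full-pulse integral
#' `v_full = 2 A T / pi`.
#'
#' @param n_strikes Number of strikes. Default 5.
#' @param amplitude Pulse amplitude A in m/s^2. Default 80.
#' @param pulse_duration Pulse duration T in s. Default 0.1.
#' @param inter_strike_interval Onset-to-onset spacing in s; must exceed
#'   2 * `pulse_duration`. Default 10 (the minimum rest between strikes).
#' @param baseline_seconds Leading noise-only window in s. Default 5.
#' @param noise_sd Per-axis noise SD in m/s^2. Default 0.3.
#' @param sampling_rate Sampling rate in Hz. Default 50.
#' @param directions Optional `n_strikes` x 3 matrix of strike directions
#'   (rows are normalized); random unit vectors when `NULL`.
#' @param seed Optional integer seed (sets the RNG via `set.seed()`).
#' @param lead_in Seconds between baseline end (or previous interval start)
#'   and pulse onset. Default 1.
#' @param tail Trailing seconds after the last pulse. Default 1.
#' @return An object of class `strike_sim`: list with `trace` (an
#'   [acceleration_trace()]), `truth` (data frame: `strike`, `onset_time`,
#'   `peak_time`, `peak_sample_time`, `v_impact`, `v_full`) and `params`.
#' @examples
#' sim <- simulate_trace(noise_sd = 0, sampling_rate = 500, seed = 1)
#' sim$truth$v_impact  # ~ A T / pi = 2.546 m/s each
#' @export
simulate_trace <- function(n_strikes = 5, amplitude = 80,
                           pulse_duration = 0.1,
                           inter_strike_interval = 10,
                           baseline_seconds = 5, noise_sd = 0.3,
                           sampling_rate = 50, directions = NULL,
                           seed = NULL, lead_in = 1, tail = 1) {
  if (n_strikes < 1) stop("n_strikes must be >= 1", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (pulse_duration <= 0) stop("pulse_duration must be > 0", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (inter_strike_interval <= 2 * pulse_duration) {
    stop("inter_strike_interval must exceed 2 * pulse_duration",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  total <- baseline_seconds + lead_in + (n_strikes - 1) * inter_strike_interval +
    pulse_duration + tail
  n_samp <- floor(total * sampling_rate) + 1L
  t <- (0:(n_samp - 1L)) / sampling_rate
  t0 <- baseline_seconds + lead_in + (0:(n_strikes - 1)) * inter_strike_interval

  if (is.null(directions)) {
    directions <- matrix(stats::rnorm(3 * n_strikes), ncol = 3L)
  } else {
    directions <- matrix(as.numeric(directions), ncol = 3L)
    stopifnot(nrow(directions) == n_strikes)
  }
  directions <- directions / sqrt(rowSums(directions^2))

  cx <- cy <- cz <- numeric(n_samp)
  truth <- vector("list", n_strikes)
  for (j in seq_len(n_strikes)) {
    idx <- which(t >= t0[j] & t <= t0[j] + pulse_duration)
    amp <- amplitude * sin(pi * (t[idx] - t0[j]) / pulse_duration)
    cx[idx] <- cx[idx] + amp * directions[j, 1L]
    cy[idx] <- cy[idx] + amp * directions[j, 2L]
    cz[idx] <- cz[idx] + amp * directions[j, 3L]
    # peak sample of the noise-free norm, i.e. what a zero-noise pipeline sees
    norm_clean <- sqrt((amp * directions[j, 1L])^2 +
                       (amp * directions[j, 2L])^2 +
                       (amp * directions[j, 3L])^2)
    tp <- t[idx][which.max(norm_clean)]
    truth[[j]] <- data.frame(
      strike = j,
      onset_time = t0[j],
      peak_time = t0[j] + pulse_duration / 2,
      peak_sample_time = tp,
      v_impact = amplitude * pulse_duration / pi *
        (1 - cos(pi * (tp - t0[j]) / pulse_duration)),
      v_full = 2 * amplitude * pulse_duration / pi
    )
  }
  if (noise_sd > 0) {
    cx <- cx + stats::rnorm(n_samp, 0, noise_sd)
    cy <- cy + stats::rnorm(n_samp, 0, noise_sd)
    cz <- cz + stats::rnorm(n_samp, 0, noise_sd)
  }
  structure(
    list(trace = acceleration_trace(t, cx, cy, cz,
                                    nominal_rate = sampling_rate,
                                    label = "simulated"),
         truth = do.call(rbind, truth),
         params = list(n_strikes = n_strikes, amplitude = amplitude,
                       pulse_duration = pulse_duration,
                       inter_strike_interval = inter_strike_interval,
                       baseline_seconds = baseline_seconds,
                       noise_sd = noise_sd, sampling_rate = sampling_rate,
                       seed = seed)),
    class = "strike_sim"
  )
}

#' @export
print.strike_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<strike_sim> %d strike(s), A = %g m/s^2, T = %g s, fs = %g Hz, noise SD %g\n",
    p$n_strikes, p$amplitude, p$pulse_duration, p$sampling_rate, p$noise_sd))
  invisible(x)
}

#' Simulate a test-retest cohort with known variance components
#'
#' Session scores follow x_is = mu_i + delta_is with subject means
#' mu_i ~ Normal(mu_pop, sigma_between) and within-subject session noise
#' delta_is ~ Normal(0, sigma_within). The analytic consistency ICC of this
#' model is sigma_between^2 / (sigma_between^2 + sigma_within^2).
#'
#' Defaults emulate the jab-average velocity distribution of a trained
#' adult cohort: population mean 6.11 m/s, between-subject SD 1.06 m/s,
#' within-subject SD 0.488 m/s (the SEM scale observed for that metric).
#'
#' @param n_subjects Number of subjects (>= 3). Default 38.
#' @param n_sessions Number of sessions k. Default 2.
#' @param mu_pop Population mean velocity in m/s. Default 6.11.
#' @param sigma_between Between-subject SD in m/s. Default 1.06.
#' @param sigma_within Within-subject (session) SD in m/s. Default 0.488.
#' @param seed Optional integer seed.
#' @param metric Metric label for the generated table.
#' @return List with `table` (a [reliability_table()]) and `icc_true`.
#' @examples
#' sim <- simulate_cohort(sigma_between = 1, sigma_within = 0.5, seed = 7)
#' sim$icc_true  # 0.8
#' @export
simulate_cohort <- function(n_subjects = 38, n_sessions = 2,
                            mu_pop = 6.11, sigma_between = 1.06,
                            sigma_within = 0.488, seed = NULL,
                            metric = "simulated") {
  if (n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  if (n_sessions < 2) stop("n_sessions must be >= 2", call. = FALSE)
  if (sigma_between < 0 || sigma_within < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mu_i <- stats::rnorm(n_subjects, mu_pop, sigma_between)
  delta <- matrix(stats::rnorm(n_subjects * n_sessions, 0, sigma_within),
                  nrow = n_subjects)
  values <- mu_i + delta
  list(table = reliability_table(values, metric = metric),
       icc_true = sigma_between^2 / (sigma_between^2 + sigma_within^2))
}

#' Minimum sampling rate to catch an impact of a given duration
#'
#' An impact transient of width `impact_duration` seconds is guaranteed to
#' contain at least one sample only if the sampling interval does not exceed
#' that width, i.e. at the smallest integer rate `ceiling(1 / duration)`.
#' For the 15 ms impacts reported for straight punches this gives 67 Hz.
#'
#' @param impact_duration Impact width in s.
#' @return Minimal integer sampling rate in Hz.
#' @export
required_sampling_rate <- function(impact_duration) {
  stopifnot(impact_duration > 0)
  ceiling(1 / impact_duration)
}

#' Nyquist rate for the bandwidth implied by an impact duration
#'
#' Treating the detection rate of [required_sampling_rate()] as the highest
#' frequency content B of the impact, full signal reconstruction needs
#' sampling at 2B (the Nyquist rate): 134 Hz for a 15 ms impact.
#'
#' @param impact_duration Impact width in s.
#' @return Nyquist rate in Hz.
#' @export
nyquist_rate <- function(impact_duration) {
  2 * required_sampling_rate(impact_duration)
}

#' Sampling-rate study: detection rate and velocity bias vs ground truth
#'
#' Runs the full pipeline on simulated traces over a grid of sampling rates
#' and pulse durations, reporting per cell the fraction of strikes detected,
#' the fraction valid, and the mean relative bias of the estimated impact
#' velocities against the analytic onset-to-peak-sample ground truth.
#' Deterministic given `seed`.
#'
#' @param rates Sampling rates in Hz.
#' @param pulse_durations Pulse durations in s.
#' @param reps Replicates per grid cell.
#' @param amplitude Pulse amplitude in m/s^2.
#' @param noise_sd Per-axis noise SD in m/s^2.
#' @param inter_strike_interval Onset spacing in s (kept small so high-rate
#'   traces stay short).
#' @param seed Optional integer seed.
#' @param config Pipeline [strike_config()].
#' @return Data frame with columns `pulse_duration`, `sampling_rate`, `rep`,
#'   `n_detected`, `n_valid`, `detection_rate`, `mean_rel_bias`.
#' @export
sampling_rate_study <- function(rates = c(50, 100, 200, 500, 1000),
                                pulse_durations = 0.1, reps = 1,
                                amplitude = 80, noise_sd = 0,
                                inter_strike_interval = 3,
                                seed = NULL,
                                config = strike_config()) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (dur in pulse_durations) {
    for (fs in rates) {
      for (r in seq_len(reps)) {
        sim <- simulate_trace(
          n_strikes = config$n_strikes, amplitude = amplitude,
          pulse_duration = dur,
          inter_strike_interval = inter_strike_interval,
          baseline_seconds = config$baseline_seconds,
          noise_sd = noise_sd, sampling_rate = fs
        )
        res <- suppressWarnings(analyze_session(sim$trace, config))
        st <- res$strikes
        # match each detected peak to the pulse whose window contains it
        bias <- NA_real_
        if (nrow(st)) {
          rel <- rep(NA_real_, nrow(st))
          for (i in seq_len(nrow(st))) {
            j <- which(sim$truth$onset_time <= st$peak_time[i] &
                       st$peak_time[i] <= sim$truth$onset_time + dur)
            if (length(j) == 1L && st$valid[i]) {
              rel[i] <- (st$impact_velocity[i] - sim$truth$v_impact[j]) /
                sim$truth$v_impact[j]
            }
          }
          if (any(is.finite(rel))) bias <- mean(rel[is.finite(rel)])
        }
        out[[length(out) + 1L]] <- data.frame(
          pulse_duration = dur, sampling_rate = fs, rep = r,
          n_detected = nrow(st), n_valid = sum(st$valid),
          detection_rate = nrow(st) / config$n_strikes,
          mean_rel_bias = bias
        )
      }
    }
  }
  do.call(rbind, out)
}
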