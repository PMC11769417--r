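# Acceleration-to-velocity integration. The acceleration norm over the
# onset..peak slice is integrated with the trapezoidal rule, using the actual
# per-interval time step. Because the integrand is a non-negative norm, the
# cumulative velocity is monotone and the impact velocity is its last value.

#' Integrate a strike segment to a velocity profile
#'
#' Cumulative trapezoidal integration of the acceleration norm over the
#' segment: v\[j\] = sum over k <= j of (a\[k-1\] + a\[k\]) / 2 * dt\[k\],
#' with v\[1\] = 0 (the guard position is stationary, so the velocity at
#' onset is zero). The impact velocity is the cumulative velocity at the
#' peak sample.
#'
#' @param segment A valid `strike_segment` with at least 2 samples.
#' @return An object of class `velocity_profile`: list with `time`, `v`
#'   (m/s, non-decreasing, `v[1] == 0`) and `impact_velocity` (m/s).
#' @examples
#' ns <- structure(list(time = c(0, 0.02, 0.04, 0.06, 0.08),
#'                      a_abs = c(0.5, 1, 4, 30, 80)), class = "norm_series")
#' seg <- segment_strike(ns, 5, threshold = 2)
#' integrate_velocity(seg)$impact_velocity  # 1.49
#' @export
integrate_velocity <- function(segment) {
  stopifnot(inherits(segment, "strike_segment"))
  if (!segment$valid) {
    stop("segment is invalid (", segment$invalid_reason,
         "); filter invalid strikes before integrating", call. = FALSE)
  }
  n <- length(segment$a_abs)
  if (n < 2L) {
    stop("need at least 2 samples to integrate, got ", n, call. = FALSE)
  }
  a <- segment$a_abs
  dt <- diff(segment$time)
  inc <- (a[-n] + a[-1L]) / 2 * dt
  v <- c(0, cumsum(inc))
  structure(
    list(time = segment$time, v = v, impact_velocity = v[n]),
    class = "velocity_profile"
  )
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %d samples, impact velocity %.2f m/s\n",
              length(x$v), x$impact_velocity))
  invisible(x)
}

#' Session-level velocity metrics
#'
#' Aggregates per-strike impact velocities into the two session metrics:
#' the session average (arithmetic mean over valid strikes) and the session
#' peak (highest impact velocity of a valid strike).
#'
#' @param velocities Numeric vector of per-strike impact velocities (m/s);
#'   invalid strikes may carry `NA`.
#' @param valid Logical vector marking valid strikes.
#' @return List with `session_average`, `session_peak`, `n_valid`. With no
#'   valid strike both metrics are `NA` and a warning is raised.
#' @examples
#' session_metrics(c(6, 6.5, 7, 5.5, 6))  # average 6.2, peak 7
#' @export
session_metrics <- function(velocities, valid = rep(TRUE, length(velocities))) {
  if (!length(velocities)) {
    stop("at least one strike must be supplied", call. = FALSE)
  }
  stopifnot(length(valid) == length(velocities))
  ok <- valid & is.finite(velocities)
  n_valid <- sum(ok)
  if (n_valid == 0L) {
    warning("no valid strikes in session; metrics undefined", call. = FALSE)
    return(list(session_average = NA_real_, session_peak = NA_real_,
                n_valid = 0L))
  }
  list(session_average = mean(velocities[ok]),
       session_peak = max(velocities[ok]),
       n_valid = n_valid)
}

#' Analyze one test session end to end
#'
#' Full pipeline on one recording: acceleration norm, threshold (fixed or
#' re-estimated from the baseline), impact peak detection, per-strike
#' backward segmentation, validity screening, trapezoidal integration, and
#' session aggregation. Deterministic for fixed input and configuration.
#'
#' If the median baseline norm sits near 1 g (8.5-11 m/s^2) the trace very
#' likely includes gravity; a prominent warning is raised and, only when
#' `subtract_gravity` is set in the config, the median baseline norm is
#' subtracted from the whole series (floored at 0).
#'
#' @param trace An [acceleration_trace()].
#' @param config A [strike_config()].
#' @return An object of class `session_result`: list with `strikes` (data
#'   frame: `strike`, `onset_time`, `peak_time`, `duration_s`, `n_samples`,
#'   `impact_velocity`, `valid`, `invalid_reason`), `threshold`,
#'   `session_average`, `session_peak`, `n_valid`, `label`.
#' @export
analyze_session <- function(trace, config = strike_config()) {
  stopifnot(inherits(trace, "acceleration_trace"))
  norm <- acceleration_norm(trace)

  base_idx <- norm$time < config$baseline_seconds
  if (any(base_idx)) {
    med_base <- stats::median(norm$a_abs[base_idx])
    if (med_base >= 8.5 && med_base <= 11) {
      warning("median baseline norm is ", round(med_base, 2),
              " m/s^2: trace appears to include gravity; record ",
              "gravity-free linear acceleration or set subtract_gravity",
              call. = FALSE)
      if (isTRUE(config$subtract_gravity)) {
        norm$a_abs <- pmax(norm$a_abs - med_base, 0)
      }
    }
  }

  thr <- estimate_threshold(norm, mode = config$threshold_mode,
                            fixed_value = config$threshold_value,
                            k = config$threshold_k,
                            baseline_seconds = config$baseline_seconds)
  peaks <- detect_impacts(norm, thr, n_expected = config$n_strikes,
                          min_separation = config$min_separation_s,
                          baseline_end = config$baseline_seconds)

  rows <- vector("list", length(peaks))
  vels <- numeric(length(peaks))
  val <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    seg <- segment_strike(norm, peaks[i], thr,
                          max_lookback = config$max_lookback_s)
    seg <- apply_validity_rules(seg, min_samples = config$min_samples,
                                min_duration = config$min_duration_s,
                                max_duration = config$max_duration_s)
    v <- if (seg$valid) integrate_velocity(seg)$impact_velocity else NA_real_
    ns <- length(seg$a_abs)
    rows[[i]] <- data.frame(
      strike = i,
      onset_time = seg$time[1L],
      peak_time = seg$time[ns],
      duration_s = seg$time[ns] - seg$time[1L],
      n_samples = ns,
      impact_velocity = v,
      valid = seg$valid,
      invalid_reason = seg$invalid_reason,
      stringsAsFactors = FALSE
    )
    vels[i] <- v
    val[i] <- seg$valid
  }
  strikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strike = integer(0), onset_time = numeric(0),
               peak_time = numeric(0), duration_s = numeric(0),
               n_samples = integer(0), impact_velocity = numeric(0),
               valid = logical(0), invalid_reason = character(0),
               stringsAsFactors = FALSE)

  if (length(peaks)) {
    m <- session_metrics(vels, val)
  } else {
    m <- list(session_average = NA_real_, session_peak = NA_real_,
              n_valid = 0L)
  }
  structure(
    list(strikes = strikes, threshold = thr,
         session_average = m$session_average,
         session_peak = m$session_peak,
         n_valid = m$n_valid, label = trace$label),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat(sprintf("  threshold %.3g m/s^2, %d strike(s) detected, %d valid\n",
              x$threshold, nrow(x$strikes), x$n_valid))
  if (nrow(x$strikes)) {
    df <- x$strikes
    df$impact_velocity <- round(df$impact_velocity, 2L)
    print(df, row.names = FALSE)
  }
  if (x$n_valid > 0L) {
    cat(sprintf("  session average %.2f m/s, session peak %.2f m/s\n",
                x$session_average, x$session_peak))
  } else {
    cat("  no valid strikes; session metrics undefined\n")
  }
  invisible(x)
}
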