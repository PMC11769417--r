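# Strike segmentation on the acceleration norm. The norm is orientation-free,
# so no pose estimation or sensor fusion is needed: the maximum of the norm
# marks bag contact, and scanning backwards from it to the first sub-threshold
# sample recovers the strike onset.

#' Acceleration norm of a triaxial trace
#'
#' The Euclidean magnitude sqrt(ax^2 + ay^2 + az^2) at each sample: an
#' orientation-free scalar, invariant under axis permutation and sign flips.
#'
#' @param trace An [acceleration_trace()].
#' @return An object of class `norm_series`: list with `time` (s) and
#'   `a_abs` (m/s^2, non-negative).
#' @examples
#' tr <- acceleration_trace(c(0, 0.02), c(3, 0), c(4, 0), c(0, 0))
#' acceleration_norm(tr)$a_abs  # 5, 0
#' @export
acceleration_norm <- function(trace) {
  stopifnot(inherits(trace, "acceleration_trace"))
  structure(
    list(time = trace$time,
         a_abs = sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)),
    class = "norm_series"
  )
}

#' @export
print.norm_series <- function(x, ...) {
  cat(sprintf("<norm_series> %d samples, max %.2f m/s^2\n",
              length(x$a_abs), max(x$a_abs)))
  invisible(x)
}

#' Onset threshold from the baseline noise window
#'
#' In `"fixed"` mode returns `fixed_value` (default 2 m/s^2, the noise
#' threshold established by visual inspection of guard-position recordings).
#' In `"adaptive"` mode returns mean + k * SD of the norm over the leading
#' baseline window, re-estimating the noise floor per recording.
#'
#' @param norm A `norm_series`.
#' @param mode `"fixed"` or `"adaptive"`.
#' @param fixed_value Threshold in m/s^2 for fixed mode.
#' @param k SD multiplier for adaptive mode.
#' @param baseline_seconds Length of the leading noise window in s.
#' @return Threshold in m/s^2.
#' @export
estimate_threshold <- function(norm, mode = c("fixed", "adaptive"),
                               fixed_value = 2, k = 3,
                               baseline_seconds = 5) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    return(fixed_value)
  }
  idx <- norm$time < baseline_seconds
  if (!any(idx)) {
    stop("empty baseline window: no samples before ", baseline_seconds,
         " s", call. = FALSE)
  }
  x <- norm$a_abs[idx]
  s <- stats::sd(x)
  if (is.na(s)) s <- 0  # single-sample window
  mean(x) + k * s
}

#' Locate impact peaks in a norm series
#'
#' Iterative max-and-mask: repeatedly take the global maximum of the
#' still-unmasked region after the baseline, mask `min_separation` seconds
#' on either side of it, and stop after `n_expected` peaks or when nothing
#' above `threshold` remains. Each peak sample is the instant of bag impact.
#'
#' @param norm A `norm_series`.
#' @param threshold Detection threshold in m/s^2; only samples strictly
#'   above it are peak candidates.
#' @param n_expected Number of strikes to look for.
#' @param min_separation Mask half-width in s.
#' @param baseline_end Peaks are searched only at `time >= baseline_end` (s).
#' @return Integer vector of peak indices, sorted by time. If fewer than
#'   `n_expected` are found a warning is raised and the shorter (possibly
#'   empty) vector returned.
#' @export
detect_impacts <- function(norm, threshold, n_expected = 5,
                           min_separation = 1, baseline_end = 5) {
  stopifnot(n_expected >= 1)
  masked <- norm$time < baseline_end
  peaks <- integer(0)
  for (i in seq_len(n_expected)) {
    cand <- which(!masked & norm$a_abs > threshold)
    if (!length(cand)) break
    p <- cand[which.max(norm$a_abs[cand])]
    peaks <- c(peaks, p)
    masked[abs(norm$time - norm$time[p]) <= min_separation] <- TRUE
  }
  if (length(peaks) < n_expected) {
    warning(sprintf("expected %d strike(s) above %.3g m/s^2, found %d",
                    n_expected, threshold, length(peaks)), call. = FALSE)
  }
  sort(peaks)
}

#' Segment one strike: backward scan from peak to onset
#'
#' Starting at the peak, the norm is traversed backwards (descending
#' timestamps) until the first sample strictly below `threshold`; that
#' sample is the strike onset and the inclusive slice onset..peak is the
#' strike. Samples exactly at the threshold do not terminate the scan. If no
#' sub-threshold sample exists within `max_lookback` seconds of the peak,
#' the segment is flagged invalid with reason `"no onset crossing"`.
#'
#' @param norm A `norm_series`.
#' @param peak_index Index of the impact peak (1-based).
#' @param threshold Onset threshold in m/s^2 (> 0).
#' @param max_lookback Backward scan bound in s.
#' @return An object of class `strike_segment`: list with `start_index`,
#'   `peak_index`, `time`, `a_abs` (the inclusive slice), `threshold`,
#'   `valid`, `invalid_reason`.
#' @export
segment_strike <- function(norm, peak_index, threshold, max_lookback = 0.6) {
  n <- length(norm$a_abs)
  peak_index <- as.integer(peak_index)
  if (is.na(peak_index) || peak_index < 1L || peak_index > n) {
    stop("peak_index out of range [1, ", n, "]", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  t_peak <- norm$time[peak_index]
  start <- NA_integer_
  i <- peak_index - 1L
  while (i >= 1L && t_peak - norm$time[i] <= max_lookback) {
    if (norm$a_abs[i] < threshold) {
      start <- i
      break
    }
    i <- i - 1L
  }
  valid <- !is.na(start)
  reason <- ""
  if (!valid) {
    reason <- "no onset crossing"
    # earliest index inside the lookback window, so the slice is inspectable
    start <- max(i + 1L, 1L)
  }
  structure(
    list(start_index = start, peak_index = peak_index,
         time = norm$time[start:peak_index],
         a_abs = norm$a_abs[start:peak_index],
         threshold = threshold, valid = valid, invalid_reason = reason),
    class = "strike_segment"
  )
}

#' Validity screen for a strike segment
#'
#' Operationalizes the exclusion of abnormal repetitions and sensor read
#' errors: a valid segment has at least `min_samples` samples, a duration
#' inside `[min_duration, max_duration]` seconds, and only finite values.
#' Segments already flagged invalid are passed through unchanged.
#'
#' @param segment A `strike_segment`.
#' @param min_samples Minimum sample count (default 3).
#' @param min_duration,max_duration Duration bounds in s (default 0.04, 0.6).
#' @return The segment, with `valid`/`invalid_reason` updated.
#' @export
apply_validity_rules <- function(segment, min_samples = 3,
                                 min_duration = 0.04, max_duration = 0.6) {
  stopifnot(inherits(segment, "strike_segment"))
  if (!segment$valid) return(segment)
  ns <- length(segment$a_abs)
  dur <- segment$time[ns] - segment$time[1L]
  tol <- 1e-9  # grid times are accumulated floats; 0.04 s can read as 0.04 - eps
  if (ns < min_samples) {
    segment$valid <- FALSE
    segment$invalid_reason <- "too few samples"
  } else if (dur < min_duration - tol || dur > max_duration + tol) {
    segment$valid <- FALSE
    segment$invalid_reason <- "duration out of range"
  } else if (!all(is.finite(segment$a_abs)) ||
             !all(is.finite(segment$time))) {
    segment$valid <- FALSE
    segment$invalid_reason <- "non-finite samples"
  }
  segment
}

#' @export
print.strike_segment <- function(x, ...) {
  ns <- length(x$a_abs)
  cat(sprintf(
    "<strike_segment> [%d..%d] %d samples, %.3f s, peak %.2f m/s^2, %s\n",
    x$start_index, x$peak_index, ns, x$time[ns] - x$time[1L],
    x$a_abs[ns], if (x$valid) "valid" else paste0("invalid (", x$invalid_reason, ")")))
  invisible(x)
}
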