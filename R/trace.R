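#' Triaxial accelerometer trace
#'
#' Container for a timestamped triaxial acceleration recording, typically a
#' smartphone accelerometer export. Timestamps are seconds from recording
#' start and need not be uniformly spaced (phone sensors rarely are);
#' accelerations are in m/s^2. All downstream computations use the actual
#' per-interval time step, so non-uniform sampling is honoured exactly.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing,
#'   length at least 2.
#' @param ax,ay,az Numeric vectors of per-axis acceleration in m/s^2, same
#'   length as `time`.
#' @param nominal_rate Optional nominal sampling rate in Hz (metadata only).
#' @param label Free-text source identifier, e.g. the file name.
#'
#' @return An object of class `acceleration_trace`: a list with elements
#'   `time`, `ax`, `ay`, `az`, `nominal_rate`, `label`.
#' @examples
#' tr <- acceleration_trace(c(0, 0.02, 0.04), c(1, 0, 0), c(2, 0, 0), c(2, 0, 0))
#' tr
#' @export
acceleration_trace <- function(time, ax, ay, az, nominal_rate = NULL,
                               label = "") {
  time <- as.numeric(time)
  ax <- as.numeric(ax)
  ay <- as.numeric(ay)
  az <- as.numeric(az)
  n <- length(time)
  if (n < 2L) {
    stop("an acceleration trace needs at least 2 samples, got ", n,
         call. = FALSE)
  }
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("time, ax, ay, az must have identical length (time has ", n, ")",
         call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(ax)) ||
      !all(is.finite(ay)) || !all(is.finite(az))) {
    stop("acceleration trace contains non-finite values", call. = FALSE)
  }
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop("timestamps not strictly increasing at row ", bad[1L] + 1L,
         call. = FALSE)
  }
  structure(
    list(time = time, ax = ax, ay = ay, az = az,
         nominal_rate = nominal_rate, label = as.character(label)[1L]),
    class = "acceleration_trace"
  )
}

#' @export
print.acceleration_trace <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1L]
  cat("<acceleration_trace>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat(sprintf("  %d samples over %.2f s (median rate %.1f Hz)\n",
              length(x$time), dur,
              1 / stats::median(diff(x$time))))
  if (!is.null(x$nominal_rate)) {
    cat(sprintf("  nominal rate: %g Hz\n", x$nominal_rate))
  }
  invisible(x)
}

#' @export
length.acceleration_trace <- function(x) length(x$time)

#' Convert an acceleration trace to a data frame
#'
#' @param x An `acceleration_trace`.
#' @param ... Unused.
#' @return A data frame with columns `time`, `ax`, `ay`, `az`.
#' @export
as.data.frame.acceleration_trace <- function(x, ...) {
  data.frame(time = x$time, ax = x$ax, ay = x$ay, az = x$az)
}
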