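# PhyPhox exports vary with the phone's locale: comma- or semicolon-delimited,
# "." or "," decimal mark, and header spellings like "Time (s)",
# "Acceleration x (m/s^2)" or "Linear Acceleration x (m/s^2)". The reader
# sniffs the dialect from the first two lines and matches columns by keyword,
# so column order never matters.

sniff_dialect <- function(path) {
  head2 <- readLines(path, n = 2L, warn = FALSE)
  if (length(head2) < 1L || !nzchar(head2[1L])) {
    stop("empty or header-less file: ", path, call. = FALSE)
  }
  n_semi <- nchar(gsub("[^;]", "", head2[1L]))
  n_comma <- nchar(gsub("[^,]", "", head2[1L]))
  sep <- if (n_semi >= max(1L, n_comma)) ";" else ","
  dec <- "."
  if (sep == ";" && length(head2) == 2L &&
      grepl("[0-9],[0-9]", head2[2L])) {
    dec <- ","
  }
  list(sep = sep, dec = dec)
}

match_axis_column <- function(nms, candidates, axis) {
  hit <- candidates[grepl(axis, nms[candidates], ignore.case = TRUE)]
  if (!length(hit)) {
    stop(sprintf(
      "no '%s' acceleration column found in header: %s",
      axis, paste(nms, collapse = ", ")), call. = FALSE)
  }
  hit[1L]
}

#' Read a PhyPhox accelerometer CSV export
#'
#' Reads a triaxial accelerometer recording in the PhyPhox export dialect:
#' a one-line header followed by four numeric columns (time plus x/y/z
#' acceleration). Both comma- and semicolon-delimited variants are accepted,
#' with "." or "," decimal marks (locale variants). The time column is
#' identified by the substring "Time" (case-insensitive), the axis columns
#' by "x"/"y"/"z"; column order is irrelevant. Units are taken as exported:
#' seconds and m/s^2.
#'
#' @param path Path to the CSV file.
#' @param label Source label stored on the trace; defaults to the file name.
#' @return An [acceleration_trace()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Time (s),Acceleration x (m/s^2),Acceleration y (m/s^2),Acceleration z (m/s^2)",
#'              "0.00,1.0,2.0,2.0", "0.02,0,0,0", "0.04,0,0,0"), f)
#' read_phyphox_csv(f)
#' @export
read_phyphox_csv <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- sniff_dialect(path)
  dat <- utils::read.table(path, header = TRUE, sep = d$sep, dec = d$dec,
                           check.names = FALSE, strip.white = TRUE,
                           comment.char = "")
  if (nrow(dat) < 2L) {
    stop("fewer than 2 data rows in ", path, call. = FALSE)
  }
  nms <- names(dat)
  tcol <- grep("time", nms, ignore.case = TRUE)
  if (!length(tcol)) {
    stop("no time column ('Time') found in header: ",
         paste(nms, collapse = ", "), call. = FALSE)
  }
  tcol <- tcol[1L]
  rest <- setdiff(seq_along(nms), tcol)
  xc <- match_axis_column(nms, rest, "x")
  yc <- match_axis_column(nms, rest, "y")
  zc <- match_axis_column(nms, rest, "z")
  cols <- c(tcol, xc, yc, zc)
  for (j in cols) {
    if (!is.numeric(dat[[j]])) {
      stop("column '", nms[j], "' is not numeric", call. = FALSE)
    }
  }
  acceleration_trace(dat[[tcol]], dat[[xc]], dat[[yc]], dat[[zc]],
                     label = label)
}

#' Write an acceleration trace as a PhyPhox-dialect CSV
#'
#' Writes the standard comma-delimited, "."-decimal variant; the result is
#' readable by [read_phyphox_csv()] and round-trips exactly for values with
#' up to 6 decimal digits.
#'
#' @param trace An [acceleration_trace()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phyphox_csv <- function(trace, path) {
  stopifnot(inherits(trace, "acceleration_trace"))
  df <- data.frame(
    "Time (s)" = format_num(trace$time),
    "Acceleration x (m/s^2)" = format_num(trace$ax),
    "Acceleration y (m/s^2)" = format_num(trace$ay),
    "Acceleration z (m/s^2)" = format_num(trace$az),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = ",", dec = ".", quote = TRUE,
                     row.names = FALSE)
  invisible(path)
}

# full-precision decimal formatting; output always uses "." as decimal mark
format_num <- function(x) {
  formatC(x, format = "g", digits = 15L)
}

#' Write per-strike session results as CSV
#'
#' One row per detected strike plus the strike table header. Velocities are
#' reported rounded to 2 decimals (full precision is kept internally and in
#' session aggregates).
#'
#' @param result A `session_result` from [analyze_session()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_session_csv <- function(result, path) {
  stopifnot(inherits(result, "session_result"))
  df <- result$strikes
  if (nrow(df) == 0L) {
    warning("session contains no detected strikes; writing header-only file",
            call. = FALSE)
  }
  df$impact_velocity <- round(df$impact_velocity, 2L)
  utils::write.table(df, path, sep = ",", dec = ".", quote = TRUE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a reliability report as a flat CSV
#'
#' One row per metric, columns `metric,value`. Together with
#' [read_report_csv()] this round-trips all values to within 1e-9.
#'
#' @param report A `reliability_report` from [reliability_report()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  flat <- flatten_report(report)
  df <- data.frame(metric = names(flat), value = format_num(unname(flat)))
  utils::write.table(df, path, sep = ",", dec = ".", quote = TRUE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat reliability report CSV
#'
#' @param path Path written by [write_report_csv()].
#' @return A named numeric vector of report metrics.
#' @export
read_report_csv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", dec = ".",
                          check.names = FALSE)
  stats::setNames(as.numeric(df$value), df$metric)
}

flatten_report <- function(report) {
  out <- c(
    n_subjects = report$n_subjects,
    cv_between_min = report$between_day_cv$min,
    cv_between_mean = report$between_day_cv$mean,
    cv_between_max = report$between_day_cv$max,
    icc = report$icc$icc,
    icc_ci_lower = report$icc$ci_lower,
    icc_ci_upper = report$icc$ci_upper,
    sem = report$sem$sem,
    sem_pct = report$sem$sem_pct,
    mean_difference = report$bland_altman$mean_difference,
    loa_upper = report$bland_altman$loa_upper,
    loa_lower = report$bland_altman$loa_lower,
    t = report$paired_t$t,
    df = report$paired_t$df,
    p = report$paired_t$p
  )
  if (!is.null(report$within_day_cv)) {
    for (s in names(report$within_day_cv)) {
      w <- report$within_day_cv[[s]]
      out[paste0("cv_within_", s, "_min")] <- w$min
      out[paste0("cv_within_", s, "_mean")] <- w$mean
      out[paste0("cv_within_", s, "_max")] <- w$max
    }
  }
  out
}
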