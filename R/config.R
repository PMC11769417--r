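#' Strike-analysis configuration
#'
#' Bundles every tunable of the segmentation/velocity pipeline with its
#' default. Defaults mirror the field-test protocol the pipeline was built
#' for: a 5 s stationary guard-position baseline, 5 maximal strikes with at
#' least 10 s rest, and a 2 m/s^2 noise threshold for gravity-free linear
#' acceleration.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{threshold_mode}{`"fixed"` or `"adaptive"`. Fixed uses
#'     `threshold_value`; adaptive estimates mean + `threshold_k` * SD of the
#'     baseline norm. Default `"fixed"`.}
#'   \item{threshold_value}{Fixed onset threshold in m/s^2. Default 2.}
#'   \item{threshold_k}{SD multiplier for adaptive mode. Default 3.}
#'   \item{baseline_seconds}{Leading noise-only window in s. Default 5.}
#'   \item{n_strikes}{Expected strikes per recording. Default 5.}
#'   \item{min_separation_s}{Mask half-width around each detected peak in s.
#'     Default 1 (conservative: rest between strikes is >= 10 s).}
#'   \item{max_lookback_s}{Bound on the backward onset scan in s. Default 0.6.}
#'   \item{min_samples}{Minimum samples for a valid strike segment. Default 3.}
#'   \item{min_duration_s, max_duration_s}{Valid segment duration range in s.
#'     Default \[0.04, 0.6\].}
#'   \item{subtract_gravity}{If `TRUE`, subtract the median baseline norm
#'     from the whole norm series (floored at 0) when the baseline sits near
#'     1 g. Off by default: data are never silently altered, only a warning
#'     is raised.}
#' }
#' @return A named list of class `strike_config`.
#' @examples
#' strike_config(threshold_mode = "adaptive", threshold_k = 4)
#' @export
strike_config <- function(...) {
  cfg <- list(
    threshold_mode = "fixed",
    threshold_value = 2,
    threshold_k = 3,
    baseline_seconds = 5,
    n_strikes = 5L,
    min_separation_s = 1,
    max_lookback_s = 0.6,
    min_samples = 3L,
    min_duration_s = 0.04,
    max_duration_s = 0.6,
    subtract_gravity = FALSE
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  if (!cfg$threshold_mode %in% c("fixed", "adaptive")) {
    stop("threshold_mode must be 'fixed' or 'adaptive'", call. = FALSE)
  }
  structure(cfg, class = c("strike_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Accepts either flat keys (as in [strike_config()]) or the nested groups
#' `threshold: {mode, value, k}` and
#' `validity: {min_samples, min_duration_s, max_duration_s}`.
#'
#' @param path Path to a YAML file.
#' @return A `strike_config` with the file's values merged over the defaults.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  flat <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    if (key == "threshold" && is.list(val)) {
      if (!is.null(val$mode)) flat$threshold_mode <- val$mode
      if (!is.null(val$value)) flat$threshold_value <- val$value
      if (!is.null(val$k)) flat$threshold_k <- val$k
    } else if (key == "validity" && is.list(val)) {
      for (vk in names(val)) flat[[vk]] <- val[[vk]]
    } else {
      flat[[key]] <- val
    }
  }
  do.call(strike_config, flat)
}
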