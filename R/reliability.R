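# Test-retest reliability battery on subjects x sessions velocity tables:
# coefficients of variation, the two-way mixed single-measure (consistency)
# intraclass correlation ICC(3,1) after Shrout & Fleiss, the standard error
# of measurement from the same two-way ANOVA decomposition, Bland-Altman 95%
# limits of agreement, and a paired t-test for systematic bias. Sample SD
# (n - 1 denominator) is used throughout.

#' Subjects x sessions reliability table
#'
#' Complete-case matrix of session-level velocities: one row per subject,
#' one column per session.
#'
#' @param values Numeric matrix (or object coercible to one), subjects in
#'   rows, sessions in columns. No missing cells; at least 3 subjects and
#'   2 sessions.
#' @param subject_ids Optional character vector of subject identifiers.
#' @param metric Name of the measured quantity, e.g. `"jab_avg"`.
#' @return An object of class `reliability_table`.
#' @export
reliability_table <- function(values, subject_ids = NULL,
                              metric = "velocity") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  k <- ncol(values)
  if (n < 3L) {
    stop("at least 3 complete subjects are required, got ", n, call. = FALSE)
  }
  if (k < 2L) stop("at least 2 sessions are required, got ", k, call. = FALSE)
  if (!all(is.finite(values))) {
    stop("reliability table must be complete (no missing/non-finite cells)",
         call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%02d", seq_len(n))
  }
  stopifnot(length(subject_ids) == n)
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 metric = metric),
            class = "reliability_table")
}

#' Build a reliability table from two per-session data frames
#'
#' Joins two session tables (columns `subject_id` and one value column) on
#' subject id; subjects missing either session are dropped (complete-case)
#' and the dropped count is reported via `message()`.
#'
#' @param session1,session2 Data frames with a `subject_id` column and the
#'   value column named by `metric` (or, if absent, their second column).
#' @param metric Value column name / metric label.
#' @return A [reliability_table()] with k = 2.
#' @export
reliability_table_from_sessions <- function(session1, session2,
                                            metric = "value") {
  pick <- function(df) {
    if (!("subject_id" %in% names(df))) {
      stop("session table needs a 'subject_id' column", call. = FALSE)
    }
    col <- if (metric %in% names(df)) metric else setdiff(names(df), "subject_id")[1L]
    data.frame(subject_id = as.character(df$subject_id),
               value = as.numeric(df[[col]]), stringsAsFactors = FALSE)
  }
  s1 <- pick(session1)
  s2 <- pick(session2)
  common <- intersect(s1$subject_id, s2$subject_id)
  dropped <- length(union(s1$subject_id, s2$subject_id)) - length(common)
  if (dropped > 0L) {
    message(dropped, " subject(s) without both sessions dropped (complete-case)")
  }
  v <- cbind(s1$value[match(common, s1$subject_id)],
             s2$value[match(common, s2$subject_id)])
  reliability_table(v, subject_ids = common, metric = metric)
}

#' @export
print.reliability_table <- function(x, ...) {
  cat(sprintf("<reliability_table> '%s': %d subjects x %d sessions\n",
              x$metric, nrow(x$values), ncol(x$values)))
  invisible(x)
}

table_values <- function(table) {
  if (inherits(table, "reliability_table")) table$values else {
    v <- as.matrix(table)
    storage.mode(v) <- "double"
    v
  }
}

#' Coefficient of variation in percent
#'
#' CV% = 100 * SD / M, with the sample SD (n - 1 denominator) over the
#' supplied values and M their mean. Scale-invariant: rescaling all values
#' by a positive constant leaves it unchanged.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(4, 6))  # 100 * sqrt(2) / 5 = 28.28
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) {
    stop("CV needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Between-day coefficient of variation
#'
#' Per subject, the CV% over that subject's session values (two values per
#' subject for the usual two-session design), summarized over subjects as
#' min / mean / max.
#'
#' @param table A [reliability_table()] or numeric matrix.
#' @return List with `per_subject` (named vector) and `min`, `mean`, `max`.
#' @export
between_day_cv <- function(table) {
  v <- table_values(table)
  per <- apply(v, 1L, cv_percent)
  if (inherits(table, "reliability_table")) names(per) <- table$subject_ids
  list(per_subject = per, min = min(per), mean = mean(per), max = max(per))
}

# two-way (subjects x sessions) mean-square decomposition shared by the
# ICC and the SEM
two_way_ms <- function(v) {
  n <- nrow(v)
  k <- ncol(v)
  grand <- mean(v)
  rm_ <- rowMeans(v)
  cm_ <- colMeans(v)
  ss_b <- k * sum((rm_ - grand)^2)
  ss_s <- n * sum((cm_ - grand)^2)
  resid <- v - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  ss_e <- sum(resid^2)
  list(n = n, k = k, grand_mean = grand,
       ms_between = ss_b / (n - 1),
       ms_sessions = ss_s / (k - 1),
       ms_error = ss_e / ((n - 1) * (k - 1)))
}

#' ICC(3,1): two-way mixed, single-measure, consistency ICC
#'
#' Shrout-Fleiss Case 3 single-measure intraclass correlation:
#' ICC = (MS_B - MS_E) / (MS_B + (k - 1) MS_E), where MS_B is the
#' between-subjects and MS_E the residual mean square of the two-way
#' subjects x sessions decomposition. Session (rater) effects are fixed, so
#' a constant session offset does not lower the coefficient. The confidence
#' interval is the Shrout-Fleiss F-based interval with
#' F = MS_B / MS_E on (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @param table A [reliability_table()] or numeric matrix.
#' @param alpha Significance level for the (1 - alpha) CI. Default 0.05.
#' @return List with `icc`, `ci_lower`, `ci_upper`, `f`, `df1`, `df2`,
#'   `ms_between`, `ms_error`, `alpha`.
#' @examples
#' m <- cbind(1:10, 1:10 + 0.5)
#' icc_3_1(m)$icc  # 1: a constant session offset is removed
#' @export
icc_3_1 <- function(table, alpha = 0.05) {
  v <- table_values(table)
  ms <- two_way_ms(v)
  k <- ms$k
  n <- ms$n
  den <- ms$ms_between + (k - 1) * ms$ms_error
  if (den <= 0) {
    stop("all cells identical; ICC undefined", call. = FALSE)
  }
  icc <- (ms$ms_between - ms$ms_error) / den
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (ms$ms_error == 0) {
    ci <- c(1, 1)  # limit of the F interval as F -> Inf
    f0 <- Inf
  } else {
    f0 <- ms$ms_between / ms$ms_error
    fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_lower = ci[1L], ci_upper = ci[2L],
       f = f0, df1 = df1, df2 = df2,
       ms_between = ms$ms_between, ms_error = ms$ms_error, alpha = alpha)
}

#' Standard error of measurement from the repeated-measures ANOVA
#'
#' SEM = sqrt(MS_E), the square root of the residual mean square of the
#' same two-way subjects x sessions decomposition that underlies ICC(3,1);
#' SEM% expresses it relative to the grand mean. Translation-invariant:
#' adding a constant to every cell changes SEM% but not SEM.
#'
#' @param table A [reliability_table()] or numeric matrix.
#' @return List with `sem` (m/s) and `sem_pct` (% of the grand mean).
#' @export
sem_from_anova <- function(table) {
  v <- table_values(table)
  ms <- two_way_ms(v)
  sem <- sqrt(ms$ms_error)
  list(sem = sem, sem_pct = 100 * sem / ms$grand_mean)
}

#' Bland-Altman 95% limits of agreement
#'
#' Differences are session 2 minus session 1. The limits of agreement are
#' the mean difference +/- 1.96 sample SD of the differences, so
#' `loa_upper + loa_lower == 2 * mean_difference` always.
#'
#' @param table A [reliability_table()] or numeric matrix with k = 2.
#' @return List with `mean_difference`, `loa_upper`, `loa_lower`,
#'   `sd_difference`.
#' @export
bland_altman <- function(table) {
  v <- table_values(table)
  if (ncol(v) != 2L) stop("Bland-Altman needs exactly 2 sessions", call. = FALSE)
  if (nrow(v) < 2L) stop("Bland-Altman needs at least 2 subjects", call. = FALSE)
  d <- v[, 2L] - v[, 1L]
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_difference = md, loa_upper = md + 1.96 * s,
       loa_lower = md - 1.96 * s, sd_difference = s)
}

#' Paired t-test between the two sessions
#'
#' Two-sided paired t-test on the session 2 minus session 1 differences
#' (df = n - 1), probing for a systematic bias between test days. When the
#' differences have zero SD the statistic is degenerate: t = 0, p = 1 for a
#' zero mean difference, otherwise t = +/-Inf, p = 0.
#'
#' @param table A [reliability_table()] or numeric matrix with k = 2.
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(table) {
  v <- table_values(table)
  if (ncol(v) != 2L) stop("paired t-test needs exactly 2 sessions", call. = FALSE)
  n <- nrow(v)
  if (n < 2L) stop("paired t-test needs at least 2 subjects", call. = FALSE)
  d <- v[, 2L] - v[, 1L]
  md <- mean(d)
  if (stats::sd(d) == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_difference = 0))
    }
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_difference = md))
  }
  tt <- stats::t.test(v[, 2L], v[, 1L], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Full test-retest reliability report
#'
#' Composes the whole battery on a subjects x sessions table: between-day
#' CVs, ICC(3,1) with CI, SEM and SEM%, Bland-Altman limits of agreement,
#' and the paired t-test. If per-strike velocities are supplied, within-day
#' CVs per session are summarized as well.
#'
#' @param table A [reliability_table()] with k = 2.
#' @param strikes Optional long data frame of per-strike velocities with
#'   columns `subject_id`, `session`, `velocity` (valid strikes only), used
#'   for the within-day CVs.
#' @param alpha Significance level for the ICC CI.
#' @return An object of class `reliability_report`.
#' @export
reliability_report <- function(table, strikes = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "reliability_table"))
  within <- NULL
  if (!is.null(strikes)) {
    stopifnot(all(c("subject_id", "session", "velocity") %in% names(strikes)))
    within <- list()
    for (s in sort(unique(strikes$session))) {
      sub <- strikes[strikes$session == s, ]
      per <- vapply(split(sub$velocity, sub$subject_id), cv_percent,
                    numeric(1))
      within[[paste0("session", s)]] <-
        list(per_subject = per, min = min(per), mean = mean(per),
             max = max(per))
    }
  }
  structure(
    list(metric = table$metric,
         n_subjects = nrow(table$values),
         within_day_cv = within,
         between_day_cv = between_day_cv(table),
         icc = icc_3_1(table, alpha = alpha),
         sem = sem_from_anova(table),
         bland_altman = bland_altman(table),
         paired_t = paired_t(table)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> '%s' (n = %d subjects)\n",
              x$metric, x$n_subjects))
  if (!is.null(x$within_day_cv)) {
    for (s in names(x$within_day_cv)) {
      w <- x$within_day_cv[[s]]
      cat(sprintf("  within-day CV %s: min %.2f%%, mean %.2f%%, max %.2f%%\n",
                  s, w$min, w$mean, w$max))
    }
  }
  b <- x$between_day_cv
  cat(sprintf("  between-day CV: min %.2f%%, mean %.2f%%, max %.2f%%\n",
              b$min, b$mean, b$max))
  cat(sprintf("  ICC(3,1) %.3f, 95%% CI [%.3f, %.3f]\n",
              x$icc$icc, x$icc$ci_lower, x$icc$ci_upper))
  cat(sprintf("  SEM %.3f m/s (%.2f%% of mean)\n",
              x$sem$sem, x$sem$sem_pct))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman MD %.3f m/s, 95%% LOA [%.3f, %.3f]\n",
              ba$mean_difference, ba$loa_lower, ba$loa_upper))
  pt <- x$paired_t
  cat(sprintf("  paired t(%d) = %.3f, p = %.3f, MD = %.3f m/s\n",
              pt$df, pt$t, pt$p, pt$mean_difference))
  invisible(x)
}
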