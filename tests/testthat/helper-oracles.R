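# Independent oracles: deliberately naive, loop-based computations kept
# separate from the package's closed-form implementations.

# brute-force two-way (subjects x sessions) ANOVA sums of squares
oracle_two_way <- function(v) {
  n <- nrow(v)
  k <- ncol(v)
  grand <- sum(v) / (n * k)
  ss_b <- 0
  for (i in seq_len(n)) {
    rm_ <- sum(v[i, ]) / k
    ss_b <- ss_b + k * (rm_ - grand)^2
  }
  ss_s <- 0
  for (j in seq_len(k)) {
    cm_ <- sum(v[, j]) / n
    ss_s <- ss_s + n * (cm_ - grand)^2
  }
  ss_t <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_t <- ss_t + (v[i, j] - grand)^2
    }
  }
  ss_e <- ss_t - ss_b - ss_s
  list(ms_b = ss_b / (n - 1), ms_s = ss_s / (k - 1),
       ms_e = ss_e / ((n - 1) * (k - 1)))
}

oracle_icc31 <- function(v) {
  ms <- oracle_two_way(v)
  (ms$ms_b - ms$ms_e) / (ms$ms_b + (ncol(v) - 1) * ms$ms_e)
}

# textbook paired t: t = mean(d) / (sd(d) / sqrt(n))
oracle_paired_t <- function(v) {
  d <- v[, 2] - v[, 1]
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  t <- md / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# naive two-pass mean/SD (for the adaptive threshold check)
oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- 0
  for (xi in x) s2 <- s2 + (xi - m)^2
  list(mean = m, sd = sqrt(s2 / (n - 1)))
}

# analytic velocity integral of the half-sine pulse a(t) = A sin(pi t / T)
# from 0 to tau (0 <= tau <= T)
halfsine_integral <- function(A, T_, tau) {
  A * T_ / pi * (1 - cos(pi * tau / T_))
}

# write an acceleration table as a PhyPhox-style CSV in a chosen dialect
write_dialect_csv <- function(df, path, sep = ",", dec = ".") {
  hdr <- c("Time (s)", "Acceleration x (m/s^2)",
           "Acceleration y (m/s^2)", "Acceleration z (m/s^2)")
  fmt <- function(x) {
    s <- formatC(x, format = "g", digits = 15)
    if (dec != ".") s <- gsub(".", dec, s, fixed = TRUE)
    s
  }
  lines <- c(paste(shQuote(hdr, type = "cmd"), collapse = sep),
             apply(df, 1, function(r) paste(vapply(r, fmt, ""), collapse = sep)))
  writeLines(lines, path)
  path
}

# simple norm series constructor for hand-built fixtures
norm_fixture <- function(time, a_abs) {
  structure(list(time = time, a_abs = a_abs), class = "norm_series")
}
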