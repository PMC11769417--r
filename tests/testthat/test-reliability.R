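test_that("CV% follows the sample-SD definition and is scale invariant", {
  expect_equal(cv_percent(c(6, 6, 6)), 0)
  expect_equal(cv_percent(c(4, 6)), 100 * sqrt(2) / 5)
  set.seed(41)
  x <- runif(8, 4, 12)
  expect_equal(cv_percent(3.7 * x), cv_percent(x))
  expect_error(cv_percent(5), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("between-day CV summarizes per-subject two-session CVs", {
  expect_equal(cv_percent(c(6, 6)), 0)
  expect_equal(cv_percent(c(5, 6)), 100 * sqrt(0.5) / 5.5)

  # three subjects engineered to CVs 0, 10, 20 %
  make_pair <- function(cv_target, m = 10) {
    d <- cv_target * m / 100 * sqrt(2) / 2
    c(m - d, m + d)
  }
  v <- rbind(make_pair(0), make_pair(10), make_pair(20))
  bd <- between_day_cv(reliability_table(v))
  expect_equal(unname(bd$per_subject), c(0, 10, 20), tolerance = 1e-12)
  expect_equal(bd$min, 0)
  expect_equal(bd$mean, 10)
  expect_equal(bd$max, 20)
})

test_that("ICC(3,1) is 1 for identical sessions and for constant offsets", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc_3_1(m)$icc, 1)
  m2 <- cbind(1:10, 1:10 + 0.5)  # consistency ICC removes session effects
  expect_equal(icc_3_1(m2)$icc, 1)
  expect_equal(icc_3_1(m2)$ci_lower, 1)
  expect_error(icc_3_1(matrix(5, 6, 2)), "identical")
})

test_that("closed-form ICC and SEM match the loop-based ANOVA oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    k <- sample(2:3, 1)
    v <- matrix(rnorm(n * k, 8, 2), nrow = n)
    expect_equal(icc_3_1(v)$icc, oracle_icc31(v), tolerance = 1e-10)
    expect_equal(sem_from_anova(v)$sem, sqrt(oracle_two_way(v)$ms_e),
                 tolerance = 1e-10)
  }
})

test_that("the mean squares agree with stats::aov on a fixed table", {
  set.seed(43)
  v <- matrix(rnorm(24, 7, 1.5), nrow = 12)
  long <- data.frame(y = as.vector(v),
                     subject = factor(rep(seq_len(12), 2)),
                     session = factor(rep(1:2, each = 12)))
  fit <- summary(stats::aov(y ~ subject + session, data = long))[[1]]
  ms_e <- fit["Residuals", "Mean Sq"]
  ms_b <- fit["subject", "Mean Sq"]
  res <- icc_3_1(v)
  expect_equal(res$ms_error, ms_e, tolerance = 1e-10)
  expect_equal(res$ms_between, ms_b, tolerance = 1e-10)
  expect_equal(sem_from_anova(v)$sem, sqrt(ms_e), tolerance = 1e-10)
})

test_that("ICC/SEM invariances: translation for both, scaling for ICC", {
  set.seed(44)
  v <- matrix(rnorm(20, 6, 1), nrow = 10)
  base_icc <- icc_3_1(v)$icc
  base_sem <- sem_from_anova(v)$sem
  expect_equal(icc_3_1(v + 3.2)$icc, base_icc, tolerance = 1e-12)
  expect_equal(sem_from_anova(v + 3.2)$sem, base_sem, tolerance = 1e-12)
  expect_equal(icc_3_1(2.5 * v)$icc, base_icc, tolerance = 1e-12)
  # SEM% changes under translation while SEM does not
  expect_false(isTRUE(all.equal(sem_from_anova(v + 3.2)$sem_pct,
                                sem_from_anova(v)$sem_pct)))
})

test_that("Bland-Altman limits behave and satisfy the 2*MD identity", {
  same <- cbind(c(5, 6, 7), c(5, 6, 7))
  ba0 <- bland_altman(same)
  expect_equal(unlist(ba0[1:3]), c(mean_difference = 0, loa_upper = 0,
                                   loa_lower = 0))
  shift <- cbind(c(5, 6, 7), c(6, 7, 8))
  bas <- bland_altman(shift)
  expect_equal(bas$mean_difference, 1)
  expect_equal(bas$loa_upper, 1)
  expect_equal(bas$loa_lower, 1)

  set.seed(45)
  for (rep in 1:20) {
    v <- matrix(rnorm(2 * sample(3:30, 1), 8, 2), ncol = 2)
    ba <- bland_altman(v)
    expect_equal(ba$loa_upper + ba$loa_lower, 2 * ba$mean_difference,
                 tolerance = 1e-12)
  }
})

test_that("paired t matches the textbook formula and df convention", {
  same <- cbind(c(5, 6, 7), c(5, 6, 7))
  pt0 <- paired_t(same)
  expect_equal(pt0$t, 0)
  expect_equal(pt0$p, 1)

  set.seed(46)
  v <- matrix(rnorm(76, 8, 1.5), ncol = 2)  # n = 38 as in a full cohort
  pt <- paired_t(v)
  o <- oracle_paired_t(v)
  expect_equal(pt$df, 37)
  expect_equal(pt$t, o$t, tolerance = 1e-10)
  expect_equal(pt$p, o$p, tolerance = 1e-10)

  degen <- cbind(c(5, 6, 7), c(6, 7, 8))
  ptd <- paired_t(degen)
  expect_true(is.infinite(ptd$t))
  expect_equal(ptd$p, 0)
})

test_that("a zero within-subject-noise cohort reports perfect reliability", {
  sim <- simulate_cohort(10, 2, 6, 1, 0, seed = 47)
  rep_ <- reliability_report(sim$table)
  expect_equal(rep_$icc$icc, 1)
  expect_equal(rep_$sem$sem, 0)
  expect_equal(rep_$between_day_cv$max, 0)
  expect_equal(rep_$bland_altman$loa_upper, 0)
  expect_equal(rep_$bland_altman$loa_lower, 0)
})

test_that("complete-case join keeps shared subjects and enforces n >= 3", {
  s1 <- data.frame(subject_id = c("a", "b", "c", "d"), value = c(5, 6, 7, 8))
  s2 <- data.frame(subject_id = c("b", "c", "d", "e"), value = c(6, 7, 8, 9))
  expect_message(tab <- reliability_table_from_sessions(s1, s2),
                 "2 subject\\(s\\)")
  expect_equal(tab$subject_ids, c("b", "c", "d"))
  expect_equal(unname(tab$values[, 1]), c(6, 7, 8))

  few1 <- data.frame(subject_id = c("a", "b"), value = c(5, 6))
  few2 <- data.frame(subject_id = c("a", "b"), value = c(5.5, 6.5))
  expect_error(reliability_table_from_sessions(few1, few2),
               "at least 3 complete subjects")
})

test_that("the report composes every battery member with matching values", {
  sim <- simulate_cohort(15, 2, 6, 1, 0.4, seed = 48)
  strikes <- do.call(rbind, lapply(seq_len(15), function(i) {
    do.call(rbind, lapply(1:2, function(s) {
      data.frame(subject_id = sprintf("S%02d", i), session = s,
                 velocity = sim$table$values[i, s] + rnorm(5, 0, 0.2))
    }))
  }))
  rep_ <- reliability_report(sim$table, strikes = strikes)
  expect_equal(rep_$icc$icc, icc_3_1(sim$table)$icc)
  expect_equal(rep_$sem$sem, sem_from_anova(sim$table)$sem)
  expect_equal(rep_$bland_altman, bland_altman(sim$table))
  expect_named(rep_$within_day_cv, c("session1", "session2"))
  expect_length(rep_$within_day_cv$session1$per_subject, 15L)
  expect_output(print(rep_), "ICC\\(3,1\\)")
})
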