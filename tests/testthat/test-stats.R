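test_that("two-sided t-tail probabilities match classical values", {
  expect_equal(student_t_two_sided_p(0, 9), 1)
  expect_equal(round(student_t_two_sided_p(0.96, 9), 3), 0.362)
  expect_equal(round(student_t_two_sided_p(12.706, 1), 3), 0.050)
  # strictly decreasing in |t|, symmetric in sign
  ts <- seq(0, 5, by = 0.25)
  expect_true(all(diff(student_t_two_sided_p(ts, 7)) < 0))
  expect_equal(student_t_two_sided_p(-2.3, 5), student_t_two_sided_p(2.3, 5))
  expect_error(student_t_two_sided_p(1, 0), "df")
})

test_that("paired t-test agrees with stats::t.test and handles degeneracy", {
  co <- make_paired_cohort(15, slope = 1, bias = 0.2, noise_sd = 0.3, seed = 2)
  got <- paired_ttest(co)
  ref <- stats::t.test(co$predicted, co$observed, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter))
  # identical pairs
  same <- paired_cohort(tibble::tibble(predicted = 1:5, observed = 1:5))
  expect_equal(paired_ttest(same)$t, 0)
  expect_equal(paired_ttest(same)$p_two_sided, 1)
  # constant nonzero difference: degenerate branch
  degen <- paired_cohort(tibble::tibble(predicted = c(1, 2, 3), observed = c(0, 1, 2)))
  dt <- paired_ttest(degen)
  expect_equal(dt$mean_diff, 1)
  expect_equal(dt$sd_diff, 0)
  expect_equal(dt$p_two_sided, 0)
  expect_true(dt$degenerate)
})

test_that("swapping predicted and observed negates t and keeps p", {
  co <- make_paired_cohort(12, slope = 1.1, noise_sd = 0.2, seed = 9)
  sw <- paired_cohort(tibble::tibble(predicted = co$observed,
                                     observed = co$predicted))
  a <- paired_ttest(co); b <- paired_ttest(sw)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("regression through origin: closed forms and lm cross-check", {
  exact <- paired_cohort(tibble::tibble(observed = c(1, 2, 4), predicted = c(2, 4, 8)))
  r <- regression_through_origin(exact)
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  hand <- paired_cohort(tibble::tibble(observed = c(1, 2, 3), predicted = c(2, 3, 5)))
  expect_equal(regression_through_origin(hand)$slope, 23 / 14)
  co <- make_paired_cohort(40, slope = 0.94, noise_sd = 0.1, seed = 3,
                           x_range = c(0.5, 1.5))
  got <- regression_through_origin(co)
  ref <- stats::lm(predicted ~ 0 + observed, data = co)
  expect_equal(got$slope, unname(coef(ref)), tolerance = 1e-12)
  zero <- paired_cohort(tibble::tibble(observed = c(0, 0), predicted = c(1, 2)))
  expect_error(regression_through_origin(zero), "zero")
})

test_that("mean slope recovery at the protocol's reported coefficients", {
  for (beta in c(0.94, 0.965, 1.05, 1.097)) {
    slopes <- vapply(1:200, function(s) {
      co <- make_paired_cohort(10, slope = beta, noise_sd = 0.05 * beta,
                               x_range = c(0.5, 1.5), seed = s)
      regression_through_origin(co)$slope
    }, numeric(1))
    expect_rel_error(mean(slopes), beta, 0.02)
  }
})

test_that("Bland-Altman bias and limits of agreement", {
  same <- paired_cohort(tibble::tibble(predicted = 1:5, observed = 1:5))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  shift <- paired_cohort(tibble::tibble(predicted = 1:4 + 0.3, observed = 1:4))
  bas <- bland_altman(shift)
  expect_equal(bas$bias, 0.3)
  expect_equal(bas$loa_low, bas$loa_high)
  # loa invariants and width under known noise
  co <- make_paired_cohort(500, slope = 1, bias = 0, noise_sd = 0.1,
                           x_range = c(0.5, 1.5), seed = 4)
  ba <- bland_altman(co)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  expect_rel_error(ba$loa_high - ba$loa_low, 2 * 1.96 * 0.1, 0.10)
})

test_that("Friedman grades: unanimity, tie handling, independent oracles", {
  same <- matrix(c(0, 1, 2, 0, 1, 2), 3, 2)
  fs <- friedman_grades(same)
  expect_equal(fs$statistic, 0)
  expect_equal(fs$p, 1)
  # method B always one grade higher, 4 subjects, k = 2 -> statistic 4
  up <- matrix(c(0, 1, 0, 1, 1, 2, 1, 2), 4, 2)
  expect_equal(friedman_grades(up)$statistic, 4)
  # untied cases agree with stats::friedman.test
  set.seed(10)
  for (rep in 1:5) {
    m <- t(replicate(6, sample(seq(0, 10) / 3, 3)))
    expect_equal(friedman_grades(m)$statistic,
                 unname(stats::friedman.test(m)$statistic), tolerance = 1e-12)
  }
  # tied cases agree with an independent midrank oracle
  oracle_stat <- function(gm) {
    n <- nrow(gm); k <- ncol(gm)
    r <- gm
    for (i in seq_len(n)) for (j in seq_len(k))
      r[i, j] <- sum(gm[i, ] < gm[i, j]) + (sum(gm[i, ] == gm[i, j]) + 1) / 2
    num <- (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (den <= 0) 0 else num / den
  }
  set.seed(11)
  for (rep in 1:20) {
    gm <- matrix(sample(0:2, 12, replace = TRUE), 4, 3)
    expect_equal(friedman_grades(gm)$statistic, oracle_stat(gm), tolerance = 1e-12)
  }
})

test_that("Friedman exact permutation reference behaves correctly", {
  up <- matrix(c(0, 1, 0, 1, 1, 2, 1, 2), 4, 2)
  ex <- friedman_exact_p(up)
  expect_equal(ex$statistic, 4)
  expect_equal(ex$p_exact, 2 / 16)   # the two unanimous orderings out of 2^4
  # ties everywhere but one subject: only that subject's ordering matters
  near_tied <- matrix(c(1, 1, 1, 0, 1, 1, 1, 1), 4, 2)
  ex2 <- friedman_exact_p(near_tied)
  expect_equal(ex2$p_exact, 1)   # k=2: permuting the one untied row gives the
                                 # same statistic either way
  # long-format input with a missing method drops the subject
  long <- tibble::tibble(subject = rep(1:3, each = 2),
                         method = rep(c("mri", "cfd"), 3),
                         grade = c("none", "mild", "mild", "marked", "none", NA))
  expect_message(fr <- friedman_grades(long), "dropping")
  expect_equal(fr$n_subjects, 2)
})

test_that("KS normality screen: null consistency, power, small-sample D", {
  set.seed(20)
  null_sample <- rnorm(10000)
  ks0 <- ks_normality(null_sample)
  expect_gt(ks0$p, 0.05)
  skew <- rexp(10000)
  ks1 <- ks_normality(skew)
  expect_lt(ks1$p, 0.001)
  # hand-computed D for the symmetric n = 3 sample (-1, 0, 1):
  # largest empirical-vs-fitted gap is 1/3 - pnorm(-1)
  expect_warning(ks3 <- ks_normality(c(-1, 0, 1)), "n >= 5")
  expect_equal(ks3$statistic, 1 / 3 - pnorm(-1), tolerance = 1e-12)
  # our D equals the nortest implementation's D
  x <- rnorm(50, 2, 3)
  expect_equal(ks_normality(x)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 10)), "zero")
  # plain-KS switch gives a (different) valid p
  expect_true(ks_normality(x, method = "ks")$p >= 0)
})

test_that("Bonferroni adjustment reproduces the six-endpoint threshold", {
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  b6 <- bonferroni_alpha(0.05, 6)
  expect_equal(attr(b6, "formatted"), 0.0083)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 5)), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("tidy and glance methods return one-row tibbles", {
  co <- make_paired_cohort(10, seed = 5, noise_sd = 0.1)
  for (obj in list(paired_ttest(co), regression_through_origin(co),
                   bland_altman(co), friedman_grades(matrix(c(0, 1, 1, 2), 2, 2)))) {
    td <- tidy(obj)
    expect_s3_class(td, "tbl_df")
    expect_equal(nrow(td), 1)
  }
})
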