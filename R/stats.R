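#' Paired predicted/observed cohort
#'
#' A per-subject table of one haemodynamic metric measured two ways
#' (model prediction vs post-operative observation). Pairs with a missing
#' side are dropped at construction with a message. All protocol statistics
#' use the difference direction `predicted - observed`.
#'
#' @param data Data frame with columns `predicted` and `observed` (and
#'   optionally `subject_id`).
#' @param metric_name,units Labels.
#' @return A `paired_cohort` tibble.
#' @export
paired_cohort <- function(data, metric_name = "metric", units = "") {
  data <- as_tibble(data)
  if (!all(c("predicted", "observed") %in% names(data)))
    stop_af("cohort needs `predicted` and `observed` columns")
  if (!"subject_id" %in% names(data))
    data$subject_id <- paste0("S", seq_len(nrow(data)))
  miss <- !stats::complete.cases(data[, c("predicted", "observed")])
  if (any(miss)) {
    message(sprintf("dropping %d pair(s) with a missing side", sum(miss)))
    data <- data[!miss, ]
  }
  if (nrow(data) < 2) stop_af("cohort needs >= 2 complete pairs")
  data <- data[, c("subject_id", "predicted", "observed")]
  class(data) <- c("paired_cohort", class(data))
  attr(data, "metric_name") <- metric_name
  attr(data, "units") <- units
  data
}

#' Two-sided Student-t p-value
#'
#' `2 * P(T_df > |t|)` — the tail probability behind every paired t-test in
#' the validation protocol.
#'
#' @param t Test statistic.
#' @param df Degrees of freedom (integer >= 1).
#' @export
student_t_two_sided_p <- function(t, df) {
  if (any(df < 1)) stop_af("`df` must be >= 1")
  2 * stats::pt(-abs(t), df)
}

#' Paired t-test on a predicted/observed cohort
#'
#' Differences `d = predicted - observed`; `t = mean(d) / (sd(d) / sqrt(n))`
#' with `n - 1` degrees of freedom. Degenerate cohorts are handled
#' explicitly: all-identical pairs give t = 0, p = 1; zero-variance
#' differences with nonzero mean give p = 0 with `degenerate = TRUE`.
#'
#' @param cohort A [paired_cohort()].
#' @return An object of class `paired_ttest`: `t`, `df`, `p_two_sided`,
#'   `mean_diff`, `sd_diff`, `n`, `degenerate`.
#' @export
paired_ttest <- function(cohort) {
  d <- cohort$predicted - cohort$observed
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  degenerate <- FALSE
  if (s == 0) {
    degenerate <- m != 0
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- student_t_two_sided_p(t, n - 1)
  }
  structure(list(t = t, df = n - 1L, p_two_sided = p,
                 mean_diff = m, sd_diff = s, n = n, degenerate = degenerate,
                 metric_name = attr(cohort, "metric_name")),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("paired t-test (%s): t = %.3g, d.f. = %d, p = %.3f%s\n",
              x$metric_name %||% "metric", x$t, x$df, x$p_two_sided,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble(metric = x$metric_name %||% NA_character_, t = x$t, df = x$df,
         p_two_sided = x$p_two_sided, mean_diff = x$mean_diff,
         sd_diff = x$sd_diff, n = x$n)
}

#' @export
glance.paired_ttest <- function(x, ...) tidy(x)

#' Linear regression through the origin
#'
#' No-intercept fit `predicted = slope * observed`:
#' `slope = sum(x y) / sum(x^2)`. The reported R-squared is
#' `1 - SS_res / SS_tot` with the total sum of squares about the *mean* of
#' the response — the convention of common statistics packages; no-intercept
#' R-squared conventions differ, so it can be negative for a poor fit.
#'
#' @param cohort A [paired_cohort()].
#' @return An object of class `origin_regression`: `slope`, `r_squared`, `n`.
#' @export
regression_through_origin <- function(cohort) {
  x <- cohort$observed; y <- cohort$predicted
  if (sum(x^2) == 0) stop_af("regression_through_origin: all observed values are zero")
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, r_squared = r2, n = length(x),
                 metric_name = attr(cohort, "metric_name"),
                 data = tibble(observed = x, predicted = y)),
            class = "origin_regression")
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("regression through origin (%s): predicted = %.4g x observed, R^2 = %.3f, n = %d\n",
              x$metric_name %||% "metric", x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.origin_regression <- function(x, ...) {
  tibble(metric = x$metric_name %||% NA_character_, slope = x$slope,
         r_squared = x$r_squared, n = x$n)
}

#' @export
glance.origin_regression <- function(x, ...) tidy(x)

#' Bland-Altman agreement analysis
#'
#' Bias = mean of `predicted - observed`; limits of agreement are
#' `bias +/- 1.96 * sd(differences)` (1.96 is a fixed constant, not a t
#' quantile). Per-subject (mean, difference) pairs are kept for plotting the
#' differences against the pair means.
#'
#' @param cohort A [paired_cohort()].
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `data` (tibble with `mean` and `difference`).
#' @export
bland_altman <- function(cohort) {
  d <- cohort$predicted - cohort$observed
  m <- (cohort$predicted + cohort$observed) / 2
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 metric_name = attr(cohort, "metric_name"),
                 units = attr(cohort, "units"),
                 data = tibble(subject_id = cohort$subject_id,
                               mean = m, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.3g, limits of agreement [%.3g, %.3g] (n = %d)\n",
              x$metric_name %||% "metric", x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(metric = x$metric_name %||% NA_character_, bias = x$bias,
         sd_diff = x$sd_diff, loa_low = x$loa_low, loa_high = x$loa_high,
         n = x$n)
}

# grade table -> n_subjects x n_methods numeric matrix (none=0, mild=1, marked=2)
grades_to_matrix_ <- function(grades) {
  if (is.matrix(grades)) {
    gm <- grades
  } else {
    grades <- as_tibble(grades)
    if (!all(c("subject", "method", "grade") %in% names(grades)))
      stop_af("grade table needs `subject`, `method`, `grade` columns")
    wide <- tidyr::pivot_wider(grades, id_cols = "subject",
                               names_from = "method", values_from = "grade")
    miss <- !stats::complete.cases(wide)
    if (any(miss)) {
      message(sprintf("dropping %d subject(s) with a missing method", sum(miss)))
      wide <- wide[!miss, ]
    }
    gm <- as.matrix(wide[, -1])
  }
  if (!is.numeric(gm)) {
    lv <- c("none", "mild", "marked")
    gm <- matrix(as.numeric(factor(gm, levels = lv)) - 1, nrow(gm), ncol(gm),
                 dimnames = dimnames(gm))
    if (any(is.na(gm))) stop_af("grades must be none/mild/marked or numeric")
  }
  if (nrow(gm) < 2 || ncol(gm) < 2)
    stop_af("Friedman test needs >= 2 subjects and >= 2 methods")
  gm
}

# tie-corrected Friedman chi-square from a subjects x methods matrix
friedman_statistic_ <- function(gm) {
  n <- nrow(gm); k <- ncol(gm)
  r <- t(apply(gm, 1, rank))    # midranks within each subject
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)       # every subject fully tied
  num / den
}

#' Friedman test on ordinal flow grades across methods
#'
#' Within-subject midranks of the grades (none = 0, mild = 1, marked = 2)
#' across methods; tie-corrected Friedman chi-square with `k - 1` degrees of
#' freedom. With two methods this reduces to a sign-test-like statistic,
#' which is retained because the protocol compares exactly two methods.
#'
#' @param grades Either a subjects x methods matrix (numeric or
#'   none/mild/marked), or a long data frame with columns `subject`,
#'   `method`, `grade`. Subjects missing a method are dropped with a
#'   message.
#' @return An object of class `friedman_grades`: `statistic`, `df`, `p`,
#'   `n_subjects`, `n_methods`.
#' @export
friedman_grades <- function(grades) {
  gm <- grades_to_matrix_(grades)
  stat <- friedman_statistic_(gm)
  df <- ncol(gm) - 1L
  p <- if (stat == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 n_subjects = nrow(gm), n_methods = ncol(gm)),
            class = "friedman_grades")
}

#' @export
print.friedman_grades <- function(x, ...) {
  cat(sprintf("Friedman test: chi^2 = %.4g, d.f. = %d, p = %.3f (%d subjects, %d methods)\n",
              x$statistic, x$df, x$p, x$n_subjects, x$n_methods))
  invisible(x)
}

#' @export
tidy.friedman_grades <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p = x$p,
         n_subjects = x$n_subjects, n_methods = x$n_methods)
}

#' Exact permutation p-value for the Friedman statistic
#'
#' Enumerates all within-subject orderings (`factorial(k)^n` of them) of the
#' observed values and returns the exact probability of a Friedman statistic
#' at least as large as the observed one. Feasible for small tables
#' (n <= 6, k <= 3); intended as an exact reference for the chi-square
#' approximation.
#'
#' @inheritParams friedman_grades
#' @return List with `statistic` (observed) and `p_exact`.
#' @export
friedman_exact_p <- function(grades) {
  gm <- grades_to_matrix_(grades)
  n <- nrow(gm); k <- ncol(gm)
  if (factorial(k)^n > 5e5) stop_af("exact enumeration infeasible for this size")
  perms <- permutations_(k)
  obs <- friedman_statistic_(gm)
  idx <- rep(1L, n)
  np <- nrow(perms)
  count <- 0L; total <- 0L
  repeat {
    g2 <- gm
    for (i in seq_len(n)) g2[i, ] <- gm[i, perms[idx[i], ]]
    if (friedman_statistic_(g2) >= obs - 1e-12) count <- count + 1L
    total <- total + 1L
    j <- 1L
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L; j <- j + 1L
      if (j > n) break
    }
    if (j > n) break
  }
  list(statistic = obs, p_exact = count / total)
}

permutations_ <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  matrix(as.integer(out), nrow(out), k)
}

#' Kolmogorov-Smirnov normality screen (Lilliefors-corrected)
#'
#' One-sample KS distance of the sample against a normal distribution with
#' the sample mean and SD. Because the parameters are estimated, the default
#' p-value uses the Lilliefors small-sample correction; `method = "ks"`
#' switches to the plain KS p-value (anti-conservative with estimated
#' parameters, provided for comparability with software that ignores the
#' correction).
#'
#' @param values Numeric sample, n >= 3, non-degenerate.
#' @param method "lilliefors" (default) or "ks".
#' @return List with `statistic` (D) and `p`. For `n < 5` the Lilliefors
#'   p-value is unavailable and returned as NA with a warning.
#' @export
ks_normality <- function(values, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop_af("ks_normality needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) stop_af("ks_normality: zero sample standard deviation")
  z <- sort((values - mean(values)) / s)
  cdf <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - cdf)
  d_minus <- max(cdf - (seq_len(n) - 1) / n)
  D <- max(d_plus, d_minus)
  p <- if (method == "lilliefors") {
    if (n >= 5) nortest::lillie.test(values)$p.value
    else { warn("Lilliefors p-value needs n >= 5; returning NA"); NA_real_ }
  } else {
    suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  }
  list(statistic = D, p = p)
}

#' Bonferroni-adjusted significance level
#'
#' `alpha / m` for `m` validation endpoints; with the protocol's six
#' endpoints and alpha = 0.05 this gives 0.0083 (4 d.p.).
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param m Number of endpoints (>= 1).
#' @param digits Rounding used by the formatted attribute (default 4).
#' @return The adjusted level, with a `formatted` attribute rounded for
#'   reporting.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1, digits = 4) {
  if (m < 1) stop_af("`m` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_af("`alpha` must be in (0, 1)")
  out <- alpha / m
  attr(out, "formatted") <- round(out, digits)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
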