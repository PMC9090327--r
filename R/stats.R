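#' One-sided (upper-tail) exact binomial test
#'
#' Exact tail probability `P(X >= K)` for `X ~ Binomial(N, p0)`, the test
#' used throughout the categorization experiments to compare observed correct
#' proportions against chance.
#'
#' @param K number of successes.
#' @param N number of trials.
#' @param p0 null proportion, strictly between 0 and 1.
#' @param alternative `"greater"` (default, upper tail) or `"less"`.
#' @return list with `K`, `N`, `p0`, `proportion` (= K/N), `p_value`,
#'   `alternative`; class `binomial_test_result`.
#' @export
binomial_test_one_sided <- function(K, N, p0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (N < 0 || K < 0 || K > N) stop("need 0 <= K <= N")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be strictly between 0 and 1")
  p <- if (alternative == "greater") {
    stats::pbinom(K - 1, N, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(K, N, p0)
  }
  structure(list(K = K, N = N, p0 = p0, proportion = K / N,
                 p_value = p, alternative = alternative),
            class = "binomial_test_result")
}

#' @export
print.binomial_test_result <- function(x, ...) {
  cat(sprintf("one-sided binomial test (%s): K = %d, N = %d, p0 = %g\n",
              x$alternative, x$K, x$N, x$p0))
  cat(sprintf("  observed proportion %.4f, p = %.4g\n", x$proportion, x$p_value))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#' @param family_alpha family-wise error rate.
#' @param m number of comparisons (>= 1).
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (m < 1) stop("m must be >= 1")
  family_alpha / m
}

#' Cohen's h effect size for two proportions
#'
#' `h = 2*asin(sqrt(p1)) - 2*asin(sqrt(p2))`; antisymmetric in its arguments
#' and bounded by pi in magnitude.
#' @param p1,p2 proportions in `[0, 1]`.
#' @return numeric effect size.
#' @export
cohens_h <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Confusion-matrix analysis with per-cell one-sided binomial tests
#'
#' Builds the true-category x response count matrix, row-normalized
#' proportions, and per-cell one-sided exact binomial tests against chance
#' (`1/n_categories`): upper tail where the observed proportion exceeds
#' chance, lower tail otherwise. Cells are flagged significant at the
#' supplied per-cell alpha (by default the family alpha Bonferroni-divided by
#' the number of possible outcomes per row).
#'
#' @param choices data frame with columns `true` and `response` (category
#'   ids, coerced to factors over `categories`).
#' @param categories vector of category levels; default `1:8`.
#' @param family_alpha family-wise alpha, default 0.05.
#' @param cell_alpha per-cell alpha; default `family_alpha / n_categories`.
#'   Set explicitly (e.g. 0.015) to reproduce differently adjusted analyses.
#' @return list with `counts`, `proportions`, `p_values`, `direction`
#'   (`"above"`/`"below"`), `significant`, `cell_alpha`, `accuracy`;
#'   class `confusion_analysis`.
#' @export
confusion_analysis <- function(choices, categories = 1:8,
                               family_alpha = 0.05, cell_alpha = NULL) {
  tr <- factor(choices$true, levels = categories)
  rs <- factor(choices$response, levels = categories)
  if (anyNA(tr) || anyNA(rs)) stop("choices outside the category set")
  counts <- table(true = tr, response = rs)
  m <- length(categories)
  if (is.null(cell_alpha)) cell_alpha <- bonferroni_alpha(family_alpha, m)
  rowN <- rowSums(counts)
  props <- sweep(unclass(counts), 1L, pmax(rowN, 1L), "/")
  p0 <- 1 / m
  pv <- dir <- matrix(NA_real_, m, m, dimnames = dimnames(counts))
  dir <- matrix(NA_character_, m, m, dimnames = dimnames(counts))
  for (a in seq_len(m)) {
    if (rowN[a] == 0) next
    for (b in seq_len(m)) {
      above <- props[a, b] > p0
      res <- binomial_test_one_sided(counts[a, b], rowN[a], p0,
                                     if (above) "greater" else "less")
      pv[a, b] <- res$p_value
      dir[a, b] <- if (above) "above" else "below"
    }
  }
  acc <- sum(diag(counts)) / max(sum(counts), 1L)
  structure(list(counts = unclass(counts), proportions = props,
                 p_values = pv, direction = dir,
                 significant = pv < cell_alpha, cell_alpha = cell_alpha,
                 accuracy = acc, empty_rows = names(rowN)[rowN == 0]),
            class = "confusion_analysis")
}

#' @export
print.confusion_analysis <- function(x, ...) {
  cat(sprintf("confusion analysis: %d categories, overall accuracy %.3f\n",
              nrow(x$counts), x$accuracy))
  cat(sprintf("  per-cell one-sided binomial tests at alpha = %g\n", x$cell_alpha))
  invisible(x)
}

#' Sample size for a one-sided one-sample binomial test
#'
#' Normal-approximation formula
#' `n = ceil(((z_{1-a} sqrt(p0 q0) + z_{1-b} sqrt(p1 q1)) / (p1 - p0))^2)`,
#' reported alongside an exact-binomial search (smallest `n` for which some
#' critical value keeps size <= alpha and power >= target).
#'
#' @param p0 null proportion; @param p1 alternative proportion (> p0).
#' @param alpha one-sided significance level. @param power target power.
#' @return list with `n` (normal approximation, the headline number),
#'   `n_exact`, and the input parameters; class `sample_size_result`.
#' @export
binomial_sample_size <- function(p0, p1, alpha, power) {
  if (!(p0 > 0 && p0 < 1 && p1 > 0 && p1 < 1)) stop("proportions must be in (0,1)")
  if (p1 <= p0) stop("p1 must exceed p0 for an upper-tail test")
  za <- stats::qnorm(1 - alpha); zb <- stats::qnorm(power)
  n_norm <- ceiling(((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) /
                       (p1 - p0))^2)
  n_exact <- NA_integer_
  for (n in seq_len(4L * n_norm + 100L)) {
    kcrit <- stats::qbinom(1 - alpha, n, p0) + 1L   # smallest k with P(X>=k|p0)<=alpha
    if (stats::pbinom(kcrit - 1L, n, p0, lower.tail = FALSE) > alpha) next
    pw <- stats::pbinom(kcrit - 1L, n, p1, lower.tail = FALSE)
    if (pw >= power) { n_exact <- n; break }
  }
  structure(list(n = as.integer(n_norm), n_exact = n_exact,
                 p0 = p0, p1 = p1, alpha = alpha, power = power,
                 sidedness = "one", design = "one_sample_binomial"),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("required sample size: n = %d (%s", x$n, x$design))
  if (!is.null(x$n_exact) && !is.na(x$n_exact)) {
    cat(sprintf("; exact search: %d", x$n_exact))
  }
  cat(")\n")
  invisible(x)
}

# noncentral-t power of a t test at per-group (or single-group) size n
t_power <- function(n, d, alpha, sidedness, design) {
  if (design == "two_sample") { df <- 2 * n - 2; ncp <- d * sqrt(n / 2) }
  else { df <- n - 1; ncp <- d * sqrt(n) }
  if (df < 1) return(0)
  crit <- if (sidedness == "one") stats::qt(1 - alpha, df) else stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Sample size for a t test via noncentral-t power iteration
#'
#' Smallest (total, for two-sample equal-allocation designs) sample size whose
#' noncentral-t power reaches the target.
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level. @param power target power.
#' @param sidedness `"one"` or `"two"`.
#' @param design `"two_sample"` (equal groups; default) or `"one_sample"`.
#' @return list with `n` (total), `n_per_group`, parameters; class
#'   `sample_size_result`.
#' @export
t_test_sample_size <- function(d, alpha = 0.05, power = 0.95,
                               sidedness = c("one", "two"),
                               design = c("two_sample", "one_sample")) {
  sidedness <- match.arg(sidedness); design <- match.arg(design)
  if (d <= 0) stop("d must be positive")
  n <- 2L
  while (t_power(n, d, alpha, sidedness, design) < power) {
    n <- n + 1L
    if (n > 1e7) stop("sample size search did not converge")
  }
  total <- if (design == "two_sample") 2L * n else n
  structure(list(n = total, n_per_group = n, d = d, alpha = alpha,
                 power = power, sidedness = sidedness, design = design),
            class = "sample_size_result")
}

#' Two-sample t test, Pearson correlation, OLS and KS wrappers
#'
#' Thin wrappers returning flat result lists in the shape the analysis
#' reports use. `t_test_one_sided` is the pooled-variance (Student) test by
#' default, upper tail for `mean(x) > mean(y)`.
#'
#' @param x,y numeric samples / vectors.
#' @param var_equal pooled variance (default `TRUE`) or Welch.
#' @return list with `t`, `df`, `p_value`.
#' @export
t_test_one_sided <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("degenerate (zero-variance) samples")
    return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
  }
  res <- stats::t.test(x, y, alternative = "greater", var.equal = var_equal)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' @rdname t_test_one_sided
#' @export
pearson_r <- function(x, y) {
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p_value = res$p.value,
       df = unname(res$parameter))
}

#' @rdname t_test_one_sided
#' @export
ks_2samp <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  res <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Ordinary least squares of y on x
#'
#' Returns the slope/intercept/R-squared/F/p bundle (a "trend result") used
#' for the order-trend and area-on-similarity regressions.
#' @param x predictor. @param y response.
#' @return list with `slope`, `intercept`, `r_squared`, `f_statistic`,
#'   `df1`, `df2`, `p_value`, `n`.
#' @export
ols_trend <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                f_statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p_value = NA_real_, n = length(x), degenerate = TRUE))
  }
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1L], r_squared = 0,
                f_statistic = NA_real_, df1 = 1, df2 = length(x) - 2,
                p_value = NA_real_, n = length(x), degenerate = FALSE))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate case here
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  if (is.null(fs)) {       # zero-variance predictor
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                f_statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p_value = NA_real_, n = length(x), degenerate = TRUE))
  }
  p <- stats::pf(fs[[1L]], fs[[2L]], fs[[3L]], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared, f_statistic = unname(fs[[1L]]),
       df1 = unname(fs[[2L]]), df2 = unname(fs[[3L]]),
       p_value = p, n = length(x), degenerate = FALSE)
}
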