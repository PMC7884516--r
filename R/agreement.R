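# Agreement statistics: intraclass correlation (absolute agreement, single
# and average measures) with McGraw & Wong F-based confidence intervals,
# paired and independent t-tests, Shapiro-Wilk normality check, and mean
# absolute differences.

icc_mean_squares <- function(values) {
  n <- nrow(values); k <- ncol(values)
  g <- mean(values)
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  resid <- values - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

icc_result <- function(estimate, ci, model, ms) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 model = model, n = ms$n, k = ms$k,
                 mean_squares = list(MSR = ms$msr, MSC = ms$msc, MSE = ms$mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f (95%% CI %.3f-%.3f), n = %d subjects, k = %d raters\n",
              x$model, x$estimate, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

icc_single_ci <- function(est, ms, conf = 0.95) {
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  if (1 - est < 1e-12) return(c(1, 1))
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  # the F-based interval is undefined for degenerate (e.g. negative-
  # agreement) tables where the Satterthwaite degrees of freedom collapse
  if (!is.finite(v) || v <= 0) return(c(NA_real_, NA_real_))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  c(lower, upper)
}

as_rater_values <- function(table) {
  if (inherits(table, "rater_table")) return(table$values)
  v <- as.matrix(table)
  storage.mode(v) <- "double"
  if (nrow(v) < 2 || ncol(v) < 2 || anyNA(v)) {
    stop("rater table must be a complete n >= 2 by k >= 2 matrix", call. = FALSE)
  }
  v
}

#' Intraclass correlation, absolute agreement, single measures
#'
#' Two-way random effects model, absolute agreement of single measures
#' (ICC(A,1)): from the two-way ANOVA mean squares (rows = subjects MSR,
#' columns = raters MSC, error MSE),
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#' McGraw & Wong F-based 95% confidence interval.
#'
#' @param table a [rater_table()] or complete n x k numeric matrix.
#' @param conf confidence level (default 0.95).
#' @return An `icc_result` with `estimate`, `ci_low`, `ci_high`, `model`,
#'   dimensions and mean squares.
#' @export
icc_agreement_single <- function(table, conf = 0.95) {
  v <- as_rater_values(table)
  ms <- icc_mean_squares(v)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (abs(denom) < 1e-300 || (ms$msr < 1e-300 && ms$msc < 1e-300 && ms$mse < 1e-300)) {
    stop("ICC: the table has zero total variance", call. = FALSE)
  }
  est <- (ms$msr - ms$mse) / denom
  icc_result(est, icc_single_ci(est, ms, conf), "A,1", ms)
}

#' Intraclass correlation, absolute agreement, average measures
#'
#' Two-way model, absolute agreement of average measures (ICC(A,k)):
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)`; the confidence bounds are the
#' single-measures bounds stepped up with the Spearman-Brown relation, as
#' in McGraw & Wong.
#'
#' @inheritParams icc_agreement_single
#' @return An `icc_result`.
#' @export
icc_agreement_average <- function(table, conf = 0.95) {
  v <- as_rater_values(table)
  ms <- icc_mean_squares(v)
  denom <- ms$msr + (ms$msc - ms$mse) / ms$n
  if (abs(denom) < 1e-300 || (ms$msr < 1e-300 && ms$msc < 1e-300 && ms$mse < 1e-300)) {
    stop("ICC: the table has zero total variance", call. = FALSE)
  }
  est <- (ms$msr - ms$mse) / denom
  ci1 <- icc_single_ci(icc_agreement_single(v, conf)$estimate, ms, conf)
  sb <- function(r) ms$k * r / (1 + (ms$k - 1) * r)
  icc_result(est, sb(ci1), "A,k", ms)
}

#' Paired-samples t-test with mean difference summary
#'
#' Two-sided paired t-test on `a - b`, reported with the mean difference
#' and its standard deviation (the "MD +/- SD" style used for
#' between-method comparisons).  Identical inputs give t = 0, p = 1;
#' constant nonzero differences are degenerate.
#'
#' @param a,b paired measurement vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_difference`, `sd_difference`.
#' @export
paired_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2) {
    stop("paired_t needs two equal-length vectors of length >= 2", call. = FALSE)
  }
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    if (abs(md) < 1e-12) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_difference = 0, sd_difference = 0))
    }
    stop("paired_t: zero-variance differences with nonzero mean (degenerate)", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = md, sd_difference = sdd)
}

#' Independent-samples t-test
#'
#' Two-sided two-sample t-test, pooled variance by default (`welch =
#' TRUE` switches to the Welch correction).
#'
#' @param a,b group vectors, each of length >= 2.
#' @param welch use the Welch (unequal variance) form.
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("independent_t needs two groups of length >= 2", call. = FALSE)
  }
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
    if (abs(mean(a) - mean(b)) < 1e-12) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("independent_t: zero pooled variance (degenerate)", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Shapiro-Wilk normality check
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000) {
    stop("normality_check requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12) stop("normality_check: constant input", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Mean absolute difference
#'
#' @param a,b equal-length measurement vectors.
#' @return Mean of `abs(a - b)`, degrees.
#' @export
mean_abs_diff <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 1) {
    stop("mean_abs_diff needs two equal-length nonempty vectors", call. = FALSE)
  }
  mean(abs(a - b))
}

#' Pairwise inter-method agreement report
#'
#' For every pair of methods measured on common subjects: intraclass
#' correlation (average-measures absolute-agreement model, the model used
#' for inter-method agreement), paired t-test with mean difference +/-
#' SD and range, mean absolute difference, Shapiro-Wilk p of the
#' difference vector, and a significance flag at p <= 0.05.
#'
#' @param tables an n x m matrix, data frame or [rater_table()] with one
#'   column per method and one row per subject (complete cases).
#' @return Data frame with one row per method pair.
#' @export
method_comparison_report <- function(tables) {
  v <- as_rater_values(tables)
  m <- ncol(v)
  if (m < 2) stop("method_comparison_report needs at least 2 methods", call. = FALSE)
  if (nrow(v) < 2) stop("method_comparison_report needs at least 2 common subjects", call. = FALSE)
  nms <- colnames(v)
  if (is.null(nms)) nms <- paste0("method", seq_len(m))
  rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- v[, i]; b <- v[, j]
      d <- a - b
      icc <- tryCatch(icc_agreement_average(cbind(a, b))$estimate, error = function(e) NA_real_)
      tt <- tryCatch(paired_t(a, b), error = function(e) NULL)
      swp <- tryCatch(normality_check(d)$p, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        method_a = nms[i], method_b = nms[j],
        icc_average = icc,
        mean_difference = mean(d), sd_difference = stats::sd(d),
        min_difference = min(d), max_difference = max(d),
        mad = mean(abs(d)),
        t = if (is.null(tt)) NA_real_ else tt$t,
        df = if (is.null(tt)) NA_real_ else tt$df,
        p = if (is.null(tt)) NA_real_ else tt$p,
        shapiro_p = swp,
        significant = if (is.null(tt)) FALSE else tt$p <= 0.05)
    }
  }
  do.call(rbind, rows)
}
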