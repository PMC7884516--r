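# independent ICC oracle used by several test files: two-way ANOVA mean
# squares via stats::aov, combined per the agreement formulas
aov_mean_squares <- function(values) {
  n <- nrow(values); k <- ncol(values)
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  rownames(tab) <- trimws(rownames(tab))
  list(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"], n = n, k = k)
}

oracle_icc <- function(values, model = c("single", "average")) {
  model <- match.arg(model)
  ms <- aov_mean_squares(values)
  if (model == "single") {
    (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse))
  } else {
    (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / ms$n)
  }
}

random_table <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:20, 1); k <- sample(2:4, 1)
    subj <- stats::rnorm(n, 25, 8)
    rater <- stats::rnorm(k, 0, 2)
    outer(subj, rep(1, k)) + outer(rep(1, n), rater) + matrix(stats::rnorm(n * k, 0, 3), n)
  })
}
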