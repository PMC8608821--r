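# Study-level statistics: coefficient-of-variation screening, paired t,
# repeated-measures ANOVA with Bonferroni post-hoc, Pearson correlation, and
# the slope/intercept F tests comparing two regression lines. All p-values
# are two-tailed.

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean`; used to screen the three isometric peak-torque
#' repetitions (a CV below 10% is required).
#'
#' @param values Numeric vector (>= 2 values, non-zero mean).
#' @return CV in percent.
#' @examples
#' cv_percent(c(9, 10, 11))   # 10
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Paired-samples t test
#'
#' Standard paired t on the differences, two-tailed. Zero-variance
#' differences are guarded: identical samples give `t = 0, p = 1`; a
#' constant non-zero difference gives `t = +/-Inf, p = 0`.
#'
#' @param a,b Paired samples of equal length (>= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  n <- length(a)
  if (n < 2 || length(b) != n) stopf("'a' and 'b' must have equal length >= 2")
  d <- a - b
  sd_d <- stats::sd(d)
  m <- mean(d)
  if (sd_d == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, mean_diff = m))
  }
  t <- m / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = m)
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Paired samples (>= 3 points, non-zero variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stopf("'x' and 'y' must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for zero variance")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Repeated-measures ANOVA across conditions with Bonferroni post-hoc
#'
#' One-way repeated-measures F test across the columns of a complete
#' subjects-by-conditions matrix (every subject observed in every
#' condition), with pairwise paired t post-hoc tests Bonferroni-corrected
#' over the number of pairs and flagged at 0.05 and 0.01. Setting
#' `method = "independent"` instead runs a one-way between-groups ANOVA.
#'
#' @param values Numeric matrix or data frame, subjects in rows, conditions
#'   in columns (complete blocks; >= 2 conditions, >= 2 subjects).
#' @param method `"repeated"` (default) or `"independent"`.
#' @return List with `F`, `df1`, `df2`, `p`, and `posthoc` (data frame with
#'   one row per condition pair: `t`, `p_raw`, Bonferroni `p_adj`, `sig05`,
#'   `sig01`).
#' @export
rm_anova <- function(values, method = c("repeated", "independent")) {
  method <- match.arg(method)
  M <- as.matrix(values)
  if (any(!is.finite(M))) stopf("complete blocks required (no missing values)")
  n <- nrow(M)
  k <- ncol(M)
  if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 conditions")
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  df1 <- k - 1
  if (method == "repeated") {
    ss_subj <- k * sum((rowMeans(M) - grand)^2)
    ss_tot <- sum((M - grand)^2)
    ss_err <- ss_tot - ss_subj - ss_cond
    df2 <- (k - 1) * (n - 1)
  } else {
    ss_err <- sum(sweep(M, 2, colMeans(M))^2)
    df2 <- k * (n - 1)
  }
  ss_err <- max(ss_err, 0)
  Fstat <- if (ss_cond <= .Machine$double.eps * n * k * max(abs(M))^2) {
    0
  } else if (ss_err == 0) {
    Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  cond_names <- colnames(M)
  if (is.null(cond_names)) cond_names <- paste0("cond", seq_len(k))
  posthoc <- do.call(rbind, lapply(seq_len(npairs), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    tt <- paired_t(M[, i1], M[, i2])
    p_adj <- min(1, tt$p * npairs)
    data.frame(pair = paste(cond_names[i1], "vs", cond_names[i2]),
               t = tt$t, p_raw = tt$p, p_adj = p_adj,
               sig05 = p_adj < 0.05, sig01 = p_adj < 0.01,
               stringsAsFactors = FALSE)
  }))
  list(F = Fstat, df1 = df1, df2 = df2, p = p, posthoc = posthoc,
       method = method)
}

.lm_sse <- function(fit) sum(stats::residuals(fit)^2)

#' Compare two regression lines (slope and intercept F tests)
#'
#' Tests slope equality by comparing the separate-slopes model against the
#' common-slope (separate-intercepts) model,
#' `F = (SSE_common_slope - SSE_separate) / (SSE_separate / df)`; if slopes
#' do not differ, intercept equality is tested under the common slope by
#' comparing against the single-line model. Symmetric in the two datasets.
#'
#' @param x1,y1 First dataset (>= 3 points).
#' @param x2,y2 Second dataset (>= 3 points).
#' @return An object of class `line_comparison`: `F_slope`, `p_slope`,
#'   `F_intercept`, `p_intercept`, plus the residual sums of squares and
#'   degrees of freedom of the three nested models.
#' @export
compare_regression_lines <- function(x1, y1, x2, y2) {
  if (length(x1) != length(y1) || length(x2) != length(y2)) {
    stopf("x/y lengths must match within each dataset")
  }
  if (length(x1) < 3 || length(x2) < 3) stopf("need >= 3 points per line")
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    stopf("degenerate x values")
  }
  n1 <- length(x1)
  n2 <- length(x2)
  x <- c(x1, x2)
  y <- c(y1, y2)
  g <- factor(rep(c(1, 2), c(n1, n2)))

  sse_sep <- .lm_sse(stats::lm(y1 ~ x1)) + .lm_sse(stats::lm(y2 ~ x2))
  df_sep <- n1 + n2 - 4
  sse_cs <- .lm_sse(stats::lm(y ~ x + g))       # common slope
  df_cs <- n1 + n2 - 3
  sse_pool <- .lm_sse(stats::lm(y ~ x))         # single line

  d_slope <- max(0, sse_cs - sse_sep)
  F_slope <- if (d_slope == 0) 0 else if (sse_sep == 0) Inf else {
    d_slope / (sse_sep / df_sep)
  }
  p_slope <- stats::pf(F_slope, 1, df_sep, lower.tail = FALSE)
  d_int <- max(0, sse_pool - sse_cs)
  F_int <- if (d_int == 0) 0 else if (sse_cs == 0) Inf else {
    d_int / (sse_cs / df_cs)
  }
  p_int <- stats::pf(F_int, 1, df_cs, lower.tail = FALSE)

  structure(list(F_slope = F_slope, p_slope = p_slope,
                 F_intercept = F_int, p_intercept = p_int,
                 sse_separate = sse_sep, df_separate = df_sep,
                 sse_common_slope = sse_cs, df_common_slope = df_cs,
                 sse_pooled = sse_pool),
            class = "line_comparison")
}

#' @export
print.line_comparison <- function(x, ...) {
  cat(sprintf(
    "<line_comparison> slope F = %.3f (p = %.4g), intercept F = %.3f (p = %.4g)\n",
    x$F_slope, x$p_slope, x$F_intercept, x$p_intercept))
  invisible(x)
}
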