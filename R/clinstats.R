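#' One-way ANOVA from group summary statistics
#'
#' Computes the fixed-effects one-way ANOVA F statistic from per-group
#' means, standard deviations and sizes alone:
#' \deqn{F = \frac{\sum_i n_i(\bar x_i - \bar x)^2 / (k-1)}
#'            {\sum_i (n_i - 1) s_i^2 / (N-k)}}
#' This is identical to the raw-data ANOVA whenever the raw data have
#' exactly these moments, which makes published mean +/- sd tables
#' re-checkable without the underlying data.
#'
#' @param means,sds,ns numeric vectors, one entry per group.
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k, all(ns >= 2),
            all(sds >= 0))
  n <- sum(ns)
  grand <- sum(ns * means) / n
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (n - k)
  if (msw == 0) stop("zero within-group variance in all groups")
  f <- msb / msw
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k)
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t by default; Welch optional.
#'
#' @param mean_a,sd_a,n_a first group's moments.
#' @param mean_b,sd_b,n_b second group's moments.
#' @param pooled pooled-variance (\code{TRUE}) or Welch (\code{FALSE}).
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           pooled = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2)
  if (sd_a == 0 && sd_b == 0) stop("zero variance in both groups")
  if (pooled) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    tv <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    tv <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  list(t = tv, p = 2 * stats::pt(-abs(tv), df), df = df)
}

#' Pearson chi-square test on a contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the
#' margins; no continuity correction by default.
#'
#' @param counts r x c matrix of counts.
#' @param correct Yates continuity correction (2x2 only).
#' @return list with \code{chisq}, \code{p}, \code{df},
#'   \code{expected}.
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row/column")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  if (any(ht$expected <= 0)) stop("nonpositive expected count")
  list(chisq = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Benjamini-Hochberg q values and rejection set
#'
#' Step-up FDR adjustment (monotone-enforced), plus the rejection set at
#' level \code{alpha}.
#'
#' @param p vector of p values in \[0, 1\].
#' @param alpha FDR level.
#' @return list with \code{q} (same order as \code{p}) and
#'   \code{rejected} (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, rejected = q < alpha)
}

#' Two-sided p value of a correlation coefficient
#'
#' Analytic p from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @return two-sided p value.
#' @export
cor_p_value <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  tv <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tv), n - 2)
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk tests (alpha = 0.05) on both variables choose the
#' method: Pearson when neither rejects normality, Spearman otherwise.
#' The two-sided p value follows the t transform of the coefficient.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param gate_alpha normality-test level.
#' @return list with \code{r}, \code{p}, \code{method}, \code{n}.
#' @export
correlate_gated <- function(x, y, gate_alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  normal <- stats::shapiro.test(x)$p.value > gate_alpha &&
    stats::shapiro.test(y)$p.value > gate_alpha
  method <- if (normal) "pearson" else "spearman"
  r <- stats::cor(x, y, method = method)
  list(r = r, p = cor_p_value(r, length(x)), method = method,
       n = length(x))
}

#' Exclude outliers before a correlation
#'
#' Default rule: studentized residuals of the simple regression of
#' \code{y} on \code{x} with \eqn{|z| > threshold} are excluded
#' (\code{threshold} defaults to 3).  With \code{rule = "iqr"}, points
#' whose residual lies beyond 1.5 IQR outside the residual quartiles are
#' excluded.  Refuses to drop more than half the data.
#'
#' @param x,y paired observations (length >= 4).
#' @param rule \code{"zscore"} or \code{"iqr"}.
#' @param threshold z threshold for the default rule.
#' @return list with \code{keep} (logical), \code{excluded} (indices),
#'   \code{x}, \code{y} (retained values).
#' @export
exclude_outliers <- function(x, y, rule = c("zscore", "iqr"),
                             threshold = 3) {
  rule <- match.arg(rule)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: outlier rule undefined")
  fit <- stats::lm(y ~ x)
  res <- stats::rstudent(fit)
  keep <- if (rule == "zscore") {
    abs(res) <= threshold
  } else {
    qs <- stats::quantile(res, c(0.25, 0.75))
    iqr <- diff(qs)
    res >= qs[1] - 1.5 * iqr & res <= qs[2] + 1.5 * iqr
  }
  if (sum(!keep) > length(x) / 2)
    stop("outlier rule would remove more than half the data")
  keep <- unname(keep)
  list(keep = keep, excluded = which(!keep), x = x[keep], y = y[keep])
}

#' Demographic/clinical summary table with group tests
#'
#' Builds a mean +/- sd per group report for the continuous clinical
#' variables with a one-way ANOVA (from the computed moments) across
#' groups, and count rows with a chi-square test for categorical
#' variables.  With a single group, only the descriptives are reported.
#'
#' @param clinical a clinical data.frame (see
#'   \code{\link{read_clinical_csv}}).
#' @param continuous names of continuous columns to summarise.
#' @param categorical names of categorical columns.
#' @return data.frame with one row per variable: \code{variable},
#'   \code{summary} (per-group "mean +/- sd" or counts, joined by " | "),
#'   \code{statistic}, \code{test}, \code{p}.
#' @export
demographic_table <- function(clinical,
                              continuous = c("age", "height", "weight",
                                             "HAMD24", "SDSS", "MOCA",
                                             "taichi_score"),
                              categorical = c("sex")) {
  groups <- unique(clinical$group)
  k <- length(groups)
  rows <- list()
  for (v in intersect(continuous, names(clinical))) {
    ms <- tapply(clinical[[v]], clinical$group, mean)
    ss <- tapply(clinical[[v]], clinical$group, stats::sd)
    ns <- tapply(clinical[[v]], clinical$group, length)
    summ <- paste(sprintf("%.2f +/- %.2f", ms[groups], ss[groups]),
                  collapse = " | ")
    if (k >= 2) {
      a <- anova_from_summary(ms[groups], ss[groups], ns[groups])
      rows[[v]] <- data.frame(variable = v, summary = summ,
                              statistic = a$F, test = "F", p = a$p)
    } else {
      rows[[v]] <- data.frame(variable = v, summary = summ,
                              statistic = NA_real_, test = "",
                              p = NA_real_)
    }
  }
  for (v in intersect(categorical, names(clinical))) {
    tab <- table(clinical$group, clinical[[v]])
    summ <- paste(apply(tab[groups, , drop = FALSE], 1, paste,
                        collapse = "/"), collapse = " | ")
    if (k >= 2) {
      ct <- chi_square_test(tab)
      rows[[v]] <- data.frame(variable = v, summary = summ,
                              statistic = ct$chisq, test = "chisq",
                              p = ct$p)
    } else {
      rows[[v]] <- data.frame(variable = v, summary = summ,
                              statistic = NA_real_, test = "",
                              p = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published group summary statistics of the study cohort
#'
#' The mean +/- sd (or count) rows of the three-group clinical
#' characteristics table that the synthetic generator is calibrated to,
#' together with the test statistics printed alongside them.  Group
#' order: T2DM_MDD, T2DM, HEALTHY.  The frequency rows are consistent
#' with n = 20 per group, which is the size used for summary-statistic
#' reproduction (the accompanying narrative reports 30 enrolled per
#' group; both sizes are supported downstream).
#'
#' @return list of data.frames: \code{continuous} (\code{variable, mean_1,
#'   sd_1, mean_2, sd_2, mean_3, sd_3, printed_F}), \code{duration}
#'   (two-group row with \code{printed_t}), \code{n_per_group}.
#' @export
table1_reference <- function() {
  continuous <- data.frame(
    variable = c("age", "height", "weight", "HAMD24", "SDSS", "MOCA",
                 "taichi_score"),
    mean_1 = c(68.85, 163.1, 55.85, 22.90, 4.45, 27.75, 83.40),
    sd_1   = c(3.67, 7.06, 10.28, 2.67, 2.50, 0.55, 1.05),
    mean_2 = c(67.90, 164.65, 60.60, 3.25, 1.00, 27.60, 83.30),
    sd_2   = c(7.74, 6.89, 7.37, 2.43, 1.45, 0.68, 1.08),
    mean_3 = c(65.85, 161.45, 58.40, 3.75, 0.35, 27.70, 83.20),
    sd_3   = c(3.18, 5.54, 6.85, 1.45, 0.59, 0.66, 1.11),
    printed_F = c(1.69, 1.20, 1.64, 498.04, 33.45, 0.29, 0.17),
    stringsAsFactors = FALSE
  )
  duration <- data.frame(variable = "t2dm_duration",
                         mean_1 = 10.08, sd_1 = 4.77,
                         mean_2 = 12.20, sd_2 = 3.98,
                         printed_t = -1.53, stringsAsFactors = FALSE)
  list(continuous = continuous, duration = duration, n_per_group = 20L)
}
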