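test_that("summary ANOVA equals raw-data ANOVA on moment-matched samples", {
  # force a sample to exact moments, then compare the two routes
  moment_match <- function(n, mean, sd) {
    x <- stats::rnorm(n)
    x <- (x - mean(x)) / stats::sd(x)
    x * sd + mean
  }
  set.seed(1)
  for (k in c(2, 3, 5)) {
    ns <- 4 + seq_len(k) * 3          # unequal group sizes
    ms <- stats::runif(k, -1, 1)
    ss <- stats::runif(k, 0.5, 2)
    x <- unlist(mapply(moment_match, ns, ms, ss, SIMPLIFY = FALSE))
    g <- factor(rep(seq_len(k), ns))
    f_raw <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
    f_sum <- anova_from_summary(ms, ss, ns)$F
    expect_equal(f_sum, f_raw, tolerance = 1e-9)
  }
  # identical groups: F = 0
  expect_equal(anova_from_summary(c(1, 1, 1), c(1, 1, 1), c(5, 5, 5))$F, 0)
  expect_error(anova_from_summary(c(1, 2), c(0, 0), c(5, 5)),
               "zero within-group variance")
})

test_that("summary t test matches t.test on moment-matched samples", {
  moment_match <- function(n, mean, sd) {
    x <- stats::rnorm(n)
    (x - mean(x)) / stats::sd(x) * sd + mean
  }
  set.seed(2)
  a <- moment_match(12, 1.3, 0.7); b <- moment_match(9, 0.8, 1.1)
  pooled <- t_from_summary(1.3, 0.7, 12, 0.8, 1.1, 9, pooled = TRUE)
  raw <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$t, unname(raw$statistic), tolerance = 1e-9)
  expect_equal(pooled$p, raw$p.value, tolerance = 1e-9)
  welch <- t_from_summary(1.3, 0.7, 12, 0.8, 1.1, 9, pooled = FALSE)
  raww <- stats::t.test(a, b)
  expect_equal(welch$t, unname(raww$statistic), tolerance = 1e-9)
  expect_equal(welch$df, unname(raww$parameter), tolerance = 1e-9)
  expect_equal(t_from_summary(1, 1, 5, 1, 1, 5)$t, 0)
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5), "zero variance")
})

test_that("chi-square test matches the hand formula", {
  prop <- matrix(c(10, 20, 5, 10), 2, 2)    # proportional rows
  expect_equal(chi_square_test(prop)$chisq, 0, tolerance = 1e-12)
  tab <- matrix(c(10, 20, 10, 0), 2, 2)     # [[10,10],[20,0]] by rows
  res <- chi_square_test(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chisq, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$chisq, 40 * (10 * 0 - 10 * 20)^2 / (20 * 20 * 30 * 10),
               tolerance = 1e-12)            # 13.33
  expect_equal(res$df, 1)
  bad <- matrix(c(5, 5, 0, 0), 2, 2)
  expect_error(chi_square_test(bad), "zero marginal")
})

test_that("BH q-values match an exhaustive step-up computation", {
  expect_equal(fdr_bh(0.03)$q, 0.03)
  expect_equal(fdr_bh(rep(0.2, 7))$q, rep(0.2, 7))
  p <- c(0.01, 0.02, 0.03, 0.20)
  # brute-force step-up: q_(i) = min over j >= i of p_(j) * m / j
  m <- length(p)
  o <- order(p)
  q_oracle <- numeric(m)
  for (i in seq_len(m))
    q_oracle[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  expect_equal(fdr_bh(p)$q, q_oracle, tolerance = 1e-12)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # BH rejections contain the Bonferroni rejections
  set.seed(3)
  pv <- stats::runif(100)^3
  bh <- fdr_bh(pv, alpha = 0.05)$rejected
  bonf <- pv < 0.05 / length(pv)
  expect_true(all(bh[bonf]))
})

test_that("correlation p-values follow the t transform", {
  expect_equal(cor_p_value(-0.45, 30), 0.0126, tolerance = 1e-3)
  expect_equal(cor_p_value(-0.02, 27), 0.921, tolerance = 1e-3)
  expect_equal(cor_p_value(1, 10), 0)
  expect_equal(cor_p_value(0, 20), 1)
  set.seed(4)
  x <- stats::rnorm(30)
  y <- 2 * x + 1
  cg <- correlate_gated(x, y)
  expect_equal(cg$r, 1)
  expect_equal(cg$method, "pearson")
  # heavy-tailed data falls back to Spearman
  xs <- stats::rcauchy(50)
  cgs <- correlate_gated(xs, xs^3 + stats::rnorm(50, 0, 1e-4))
  expect_equal(cgs$method, "spearman")
  expect_error(correlate_gated(rep(1, 10), stats::rnorm(10)),
               "zero variance")
})

test_that("outlier exclusion removes exactly the injected point", {
  set.seed(5)
  x <- stats::rnorm(30)
  y <- 0.5 * x + stats::rnorm(30, 0, 0.2)
  clean <- exclude_outliers(x, y)
  expect_length(clean$excluded, 0)
  y2 <- y; y2[17] <- y2[17] + 10 * stats::sd(y)
  out <- exclude_outliers(x, y2)
  expect_equal(out$excluded, 17L)
  expect_error(exclude_outliers(rep(1, 10), rep(1, 10)), "zero variance")
  # refuse to discard most of the data
  expect_error(exclude_outliers(1:6, c(0, 100, 0, 100, 0, 100),
                                threshold = 0.1), "half")
})

test_that("demographic table reproduces the published significance pattern", {
  set.seed(6)
  groups <- rep(group_labels(), each = 20)
  cl <- simulate_clinical(groups, paste0("s", seq_along(groups)))
  tab <- demographic_table(cl)
  expect_lt(tab$p[tab$variable == "HAMD24"], 0.01)
  expect_lt(tab$p[tab$variable == "SDSS"], 0.01)
  expect_gt(tab$p[tab$variable == "MOCA"], 0.05)
  expect_gt(tab$p[tab$variable == "taichi_score"], 0.05)
  expect_equal(tab$test[tab$variable == "sex"], "chisq")
  # single group: descriptives only
  one <- demographic_table(cl[cl$group == "T2DM", ])
  expect_true(all(is.na(one$p)))
})

test_that("published summary rows are reproduced from their moments", {
  t1 <- table1_reference()
  n <- t1$n_per_group
  for (i in seq_len(nrow(t1$continuous))) {
    r <- t1$continuous[i, ]
    f <- anova_from_summary(c(r$mean_1, r$mean_2, r$mean_3),
                            c(r$sd_1, r$sd_2, r$sd_3), rep(n, 3))$F
    ok <- abs(f - r$printed_F) / r$printed_F <= 0.005 ||
      abs(f - r$printed_F) <= 0.005
    expect_true(ok, label = paste("F for", r$variable))
  }
  d <- t1$duration
  tv <- t_from_summary(d$mean_1, d$sd_1, n, d$mean_2, d$sd_2, n)$t
  expect_equal(tv, d$printed_t, tolerance = 0.005)
})
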