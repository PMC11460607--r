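test_that("design matrix has the typed structure and full rank", {
  p <- task_paradigm()
  x <- build_design(p)
  expect_equal(dim(x), c(750L, 3L))
  expect_equal(colnames(x), c("task", "intercept", "drift"))
  expect_equal(qr(x)$rank, 3L)
  # task column is zero during pre-rest and peaks after block onset
  expect_equal(max(abs(x[1:150, "task"])), 0)
  expect_gt(which.max(x[, "task"]), 150 + 6 * 5)  # after the HRF delay
  expect_equal(max(x[, "task"]), 1)               # unit peak
  # impulse HRF leaves the raw boxcar
  xb <- build_design(p, hrf = "impulse", drift = FALSE)
  tt <- (0:749) / 5
  expect_equal(as.vector(xb[, "task"]),
               as.numeric(tt >= 30 & tt < 90), tolerance = 1e-12)
  # separate-blocks design: 4 task columns, still full rank
  x4 <- build_design(p, blocks = "separate")
  expect_equal(length(attr(x4, "task_cols")), 4L)
  expect_equal(qr(x4)$rank, ncol(x4))
})

test_that("OLS recovers exact coefficients and scales linearly", {
  x <- build_design()
  y <- as.vector(x %*% c(2, 1, 0))
  expect_lt(abs(fit_glm(y, x)$beta - 2), 1e-10)
  expect_error(fit_glm(y[1:700], x), "length")
  # linearity in the evoked amplitude
  sp <- quiet_spec(seed = 41, laterality_factor = c(T2DM_MDD = 1,
                                                    T2DM = 1, HEALTHY = 1))
  betas <- vapply(c(0.5, 1, 2), function(a) {
    spa <- quiet_spec(seed = 41, effect_amplitude = flat_amplitude(a),
                      laterality_factor = c(T2DM_MDD = 1, T2DM = 1,
                                            HEALTHY = 1))
    s <- simulate_subject(spa, "T2DM", seed = 42)
    h <- preprocess_recording(s$recording)
    fit_glm(h$hbo2[1, ], build_design(filter = default_band_filter()))$beta
  }, 0)
  expect_equal(betas[2] / betas[1], 2, tolerance = 0.01)
  expect_equal(betas[3] / betas[2], 2, tolerance = 0.01)
})

test_that("pure-noise betas are centred at zero (Monte Carlo)", {
  set.seed(5)
  x <- build_design()
  n_rep <- 1000
  xtx <- solve(crossprod(x))
  hat <- xtx %*% t(x)
  y <- matrix(stats::rnorm(750 * n_rep), 750, n_rep)
  betas <- (hat %*% y)[1, ]
  se <- stats::sd(betas) / sqrt(n_rep)
  expect_lt(abs(mean(betas)), 3 * se)
})

test_that("one-sample t per group matches the textbook formula", {
  b <- data.frame(subject_id = paste0("s", 1:5), group = "T2DM",
                  channel_id = 1L, beta = 1:5)
  res <- group_one_sample_t(b)
  expect_equal(res$t, mean(1:5) / (stats::sd(1:5) / sqrt(5)))
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), 4))
  b2 <- b; b2$beta <- c(-1, 1, -1, 1, 0)[1:5] * c(1, 1, 1, 1, 0)
  b2$beta <- c(-1, 1, -1, 1, 0)
  expect_equal(group_one_sample_t(b2)$t, 0)
  b3 <- b; b3$beta <- rep(2, 5)
  expect_error(group_one_sample_t(b3), "zero variance")
})

test_that("channel ANOVA: nulls, power, and summary-statistic consistency", {
  mk_betas <- function(means, n, sd = 0.1, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(means), function(g) {
      do.call(rbind, lapply(seq_len(n), function(i)
        data.frame(subject_id = sprintf("g%d_s%d", g, i),
                   group = group_labels()[g], channel_id = 1:40,
                   beta = stats::rnorm(40, means[g], sd))))
    }))
  }
  # equal group means: rejections stay rare
  b0 <- mk_betas(c(1, 1, 1), n = 30, sd = 0.1)
  ca0 <- channel_anova(b0)
  expect_lt(mean(ca0$omnibus$significant), 0.2)
  # configured separation: all three contrasts significant
  hits <- vapply(1:10, function(r) {
    b <- mk_betas(c(0.4, 0.7, 1.0), n = 30, sd = 0.1, seed = r)
    ca <- channel_anova(b)
    ph <- ca$posthoc
    all(ca$omnibus$significant) && all(ph$q < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # raw-data F equals the summary-statistic F to 1e-9
  b <- mk_betas(c(0.4, 0.7, 1.0), n = 7, sd = 0.3, seed = 3)
  ca <- channel_anova(b)
  v <- b[b$channel_id == 17, ]
  ms <- tapply(v$beta, v$group, mean)
  ss <- tapply(v$beta, v$group, stats::sd)
  ns <- tapply(v$beta, v$group, length)
  f_sum <- anova_from_summary(ms, ss, ns)$F
  expect_equal(ca$omnibus$F[ca$omnibus$channel_id == 17], f_sum,
               tolerance = 1e-9)
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(8)
  y <- matrix(stats::rnorm(90 * 5), 90, 5)
  g <- rep(group_labels(), each = 30)
  f0 <- anova_oneway_matrix(y, g)$F
  expect_equal(anova_oneway_matrix(y + 13.7, g)$F, f0, tolerance = 1e-9)
  expect_equal(anova_oneway_matrix(y * 3.1, g)$F, f0, tolerance = 1e-9)
})

test_that("BH q-values are monotone in the raw p ordering", {
  set.seed(9)
  p <- stats::runif(40)^2
  q <- fdr_bh(p)$q
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("roi_summary averages channel t within ROI", {
  ct <- data.frame(group = "T2DM", channel_id = 1:40, n = 10,
                   mean_beta = 0, t = stats::rnorm(40), p = 0.5)
  lay <- probe_layout()
  rs <- roi_summary(ct, lay)
  # STG has exactly one left and one right channel: 39 and 29
  expect_equal(rs$mean_t[rs$roi == "STG"], mean(ct$t[c(29, 39)]))
  # brute-force group-by oracle over all ROIs
  oracle <- tapply(ct$t, lay$channels$roi, mean)
  expect_equal(rs$mean_t, as.vector(oracle[rs$roi]), tolerance = 1e-12)
})
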