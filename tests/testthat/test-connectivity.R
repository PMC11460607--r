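test_that("instantaneous phase matches analytic identities", {
  n <- 750
  k <- 15                      # 15 cycles in 150 s -> 0.1 Hz exactly
  idx <- 0:(n - 1)
  x <- cos(2 * pi * k * idx / n + 0.3)
  ph <- instantaneous_phase(x)
  truth <- Arg(exp(1i * (2 * pi * k * idx / n + 0.3)))
  expect_lt(max(abs(Arg(exp(1i * (ph - truth))))), 1e-9)
  # unwrapped phase increases linearly at 2 pi f
  up <- unwrap_phase(instantaneous_phase(sin(2 * pi * 0.05 * idx / 5)))
  slope <- stats::coef(stats::lm(up[100:650] ~ idx[100:650]))[2] * 5
  expect_equal(unname(slope), 2 * pi * 0.05, tolerance = 0.01)
  # sin lags cos by pi/2
  d <- Arg(exp(1i * (instantaneous_phase(cos(2 * pi * k * idx / n)) -
                       instantaneous_phase(sin(2 * pi * k * idx / n)))))
  expect_equal(mean(d[100:650]), pi / 2, tolerance = 1e-6)
  expect_error(instantaneous_phase(rep(1, 100)), "constant")
})

test_that("phase via an independent spectral quadrature oracle", {
  set.seed(4)
  n <- 750
  idx <- 0:(n - 1)
  # band-limited signal from integer-frequency sinusoids
  ks <- c(3, 7, 11)
  amps <- c(1, 0.6, 0.3)
  phs <- c(0.2, 1.1, -0.7)
  x <- colSums(amps * t(sapply(seq_along(ks), function(j)
    cos(2 * pi * ks[j] * idx / n + phs[j]))))
  quad <- colSums(amps * t(sapply(seq_along(ks), function(j)
    sin(2 * pi * ks[j] * idx / n + phs[j]))))
  oracle <- atan2(quad, x)
  ph <- instantaneous_phase(x)
  expect_lt(max(abs(Arg(exp(1i * (ph - oracle))))), 1e-9)
})

test_that("PLV of locked, lagged, and independent phases", {
  ph <- stats::runif(300, 0, 2 * pi)
  expect_equal(plv_pair(ph, ph), 1)
  expect_equal(plv_pair(ph, ph - pi / 3), 1, tolerance = 1e-12)
  expect_error(plv_pair(ph, ph[-1]), "length")
  set.seed(11)
  pl <- replicate(300, plv_pair(stats::runif(300, 0, 2 * pi),
                                stats::runif(300, 0, 2 * pi)))
  expect_lt(abs(mean(pl) - sqrt(pi) / (2 * sqrt(300))),
            3 * stats::sd(pl) / sqrt(300))
})

test_that("PLV matrix invariants on a synthetic subject", {
  sp <- cohort_spec(n_per_group = 2, seed = 61)
  s <- simulate_subject(sp, "HEALTHY", seed = 62)
  h <- preprocess_recording(s$recording)
  pm <- plv_matrix(h)
  m <- pm$plv
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 40))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(nrow(channel_pairs(40)), 780L)
  # identical channels give PLV 1
  h2 <- h
  for (ch in 2:40) h2$hbo2[ch, ] <- h2$hbo2[1, ]
  expect_equal(min(plv_matrix(h2)$plv), 1, tolerance = 1e-12)
})

test_that("PLV is invariant to a constant phase offset of one signal", {
  set.seed(13)
  ph_a <- cumsum(stats::rnorm(300, 0.1, 0.05))
  ph_b <- cumsum(stats::rnorm(300, 0.1, 0.05))
  expect_equal(plv_pair(ph_a, ph_b), plv_pair(ph_a + 1.234, ph_b),
               tolerance = 1e-12)
})

test_that("PLV grows monotonically with the generator's mixing coefficient", {
  # paired design: the same noise components across the mixing grid; the
  # replicate-mean PLV curve must increase strictly with m
  set.seed(14)
  ms <- c(0, 0.25, 0.5, 0.75, 1)
  res <- vapply(1:200, function(r) {
    common <- narrowband_noise(750)
    ea <- narrowband_noise(750)
    eb <- narrowband_noise(750)
    vapply(ms, function(m) {
      a <- m * common + sqrt(1 - m^2) * ea
      b <- m * common + sqrt(1 - m^2) * eb
      plv_pair(instantaneous_phase(a)[76:675],
               instantaneous_phase(b)[76:675])
    }, 0)
  }, numeric(5))
  expect_true(all(diff(rowMeans(res)) > 0))
  expect_equal(mean(res[5, ]), 1, tolerance = 1e-9)  # m = 1: locked
})

test_that("coupling blocks separate and group comparison flags them", {
  # replicate = small cohort; statistic = cohort-mean within-block PLV
  stronger <- vapply(1:10, function(r) {
    sp <- cohort_spec(n_per_group = 2, seed = 700 + r)
    co <- simulate_cohort(sp)
    res <- analyze_cohort(co$recordings, what = "plv",
                          motion_correct = FALSE)
    b1 <- mean(vapply(res$plv, function(p)
      mean(p$plv[1:5, 1:5][upper.tri(diag(5))]), 0))
    b2 <- mean(vapply(res$plv, function(p)
      mean(p$plv[21:25, 21:25][upper.tri(diag(5))]), 0))
    b1 > b2
  }, TRUE)
  expect_gte(mean(stronger), 0.95)
  sp <- cohort_spec(n_per_group = 4, seed = 71)
  co <- simulate_cohort(sp)
  res <- analyze_cohort(co$recordings, what = "plv")
  pc <- pairwise_group_compare(res$plv)
  expect_equal(nrow(pc$omnibus), 780L)
  expect_true(all(pc$omnibus$q >= pc$omnibus$p - 1e-15))
})
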