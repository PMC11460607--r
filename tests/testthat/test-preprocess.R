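test_that("intensity_to_od matches the log-ratio definition", {
  arr <- array(2, c(40, 2, 750))
  rec <- raw_recording("s", "T2DM", arr)
  od <- intensity_to_od(rec, 1:150)
  expect_equal(max(abs(od$od)), 0)           # I == baseline mean
  arr2 <- arr
  arr2[1, 1, 200] <- 2 / 10
  od2 <- intensity_to_od(raw_recording("s", "T2DM", arr2), 1:150)
  expect_equal(od2$od[1, 1, 200], 1)         # log10(10)
  # brute-force oracle on a random positive trace
  set.seed(1)
  arr3 <- array(exp(stats::rnorm(40 * 2 * 750, 0, 0.1)), c(40, 2, 750))
  od3 <- intensity_to_od(raw_recording("s", "T2DM", arr3), 1:150)$od
  ch <- 7; wl <- 2
  base <- mean(arr3[ch, wl, 1:150])
  oracle <- vapply(seq_len(750),
                   function(t) -log10(arr3[ch, wl, t] / base), 0)
  expect_lt(max(abs(od3[ch, wl, ] - oracle)), 1e-12)
})

test_that("MBLL forward is the pathlength-scaled extinction product", {
  expect_equal(as.vector(mbll_forward(0, 0)), c(0, 0))
  od1 <- mbll_forward(1.0, -0.3)
  od2 <- mbll_forward(2.0, -0.6)
  expect_equal(od2, 2 * od1, tolerance = 1e-12)   # homogeneity
  # hand-multiplied 2x2 product
  e <- matrix(c(2, 3, 5, 7), 2, 2, byrow = TRUE)
  od <- mbll_forward(1.5, -0.5, extinction = e, d = 2, dpf = c(4, 6))
  expect_equal(as.vector(od),
               c((2 * 1.5 + 3 * -0.5) * 2 * 4,
                 (5 * 1.5 + 7 * -0.5) * 2 * 6))
})

test_that("MBLL invert is the exact inverse and rejects singular systems", {
  expect_equal(unlist(mbll_invert(c(0, 0))), c(dhbo2 = 0, dhb = 0))
  od <- mbll_forward(1.0, -0.3)
  back <- mbll_invert(od)
  expect_lt(abs(back$dhbo2 - 1.0), 1e-10)
  expect_lt(abs(back$dhb - (-0.3)), 1e-10)
  sing <- matrix(c(1, 2, 2, 4), 2, 2, byrow = TRUE)
  expect_error(mbll_invert(c(0.1, 0.2), extinction = sing),
               "singular|ill-conditioned")
})

test_that("DPF sensitivity: both the scaling and the empirical reading", {
  od <- mbll_forward(seq(-1, 1, length.out = 100),
                     -0.3 * seq(-1, 1, length.out = 100))
  same <- dpf_sensitivity(od, 6, 6)
  expect_equal(same$scaling_error, 0)
  expect_equal(same$concentration_error, 0)
  s65 <- dpf_sensitivity(od, 6, 5)
  expect_equal(s65$scaling_error, 0.20, tolerance = 1e-12)
  expect_equal(s65$concentration_error, 0.20, tolerance = 1e-9)
  expect_equal(dpf_sensitivity(od, 5, 4)$scaling_error, 0.25,
               tolerance = 1e-12)
  expect_error(dpf_sensitivity(od, 0, 5), "positive")
})

test_that("motion correction: clean traces untouched, spikes and steps fixed", {
  set.seed(2)
  t <- (0:749) / 5
  clean <- 0.5 * sin(2 * pi * 0.05 * t) + 0.3 * sin(2 * pi * 0.02 * t + 1)
  cm <- correct_motion_spline(clean)
  expect_identical(cm$series, clean)
  expect_false(any(cm$mask))
  s <- stats::sd(clean)
  # injected 10 sd spike: max deviation from the clean oracle cut >= 80%
  x <- clean; x[400] <- x[400] + 10 * s
  cs <- correct_motion_spline(x)
  expect_true(any(cs$mask))
  expect_lt(max(abs(cs$series - clean)), 0.2 * max(abs(x - clean)))
  # injected baseline step: post-correction segment means re-levelled
  x2 <- clean; x2[500:750] <- x2[500:750] + 5 * s
  cs2 <- correct_motion_spline(x2)
  expect_lt(abs(mean(cs2$series[510:750]) - mean(clean[510:750])), 0.1 * s)
  expect_error(correct_motion_spline(clean[1:5], window = 2), "window")
})

test_that("band-pass: DC rejected, passband held within 5%, cardiac crushed", {
  t <- (0:1499) / 5
  expect_lt(max(abs(bandpass_filter(rep(2.7, 1500)))), 1e-6 * 2.7)
  y <- bandpass_filter(sin(2 * pi * 0.05 * t))
  amp <- max(abs(y[400:1100]))
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)
  yc <- bandpass_filter(sin(2 * pi * 1.0 * t))
  expect_lt(max(abs(yc[400:1100])), 0.05)
  expect_error(bandpass_filter(y, band = c(0.1, 0.01)), "invalid band")
  expect_error(bandpass_filter(y, band = c(0.01, 3)), "invalid band")
})

test_that("filter is linear", {
  set.seed(3)
  x <- stats::rnorm(750); y <- stats::rnorm(750)
  lhs <- bandpass_filter(2.5 * x - 1.3 * y)
  rhs <- 2.5 * bandpass_filter(x) - 1.3 * bandpass_filter(y)
  # order-3 Butterworth at 0.004 of Nyquist is numerically delicate:
  # agreement to ~1e-7 relative is the conditioning floor of the
  # forward-backward recursion, not a linearity violation
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(lhs)))
})

test_that("THb identity and band-limited evoked recovery hold after the full chain", {
  sp <- quiet_spec(seed = 21)
  s <- simulate_subject(sp, "HEALTHY", seed = 22)
  h <- preprocess_recording(s$recording)
  expect_lt(max(abs(h$thb - (h$hbo2 + h$hb))), 1e-12)
  w <- task_window_samples(task_paradigm()) + 1
  evoked_band <- bandpass_filter(s$truth$evoked)
  cors <- vapply(1:40, function(ch) stats::cor(h$hbo2[ch, w],
                                               evoked_band[ch, w]), 0)
  expect_true(all(cors > 0.99))
})

test_that("preprocessing survives injected artifacts at default settings", {
  sp <- cohort_spec(n_per_group = 2, artifact_rate = 4, seed = 31)
  s <- simulate_subject(sp, "T2DM", seed = 32)
  h <- preprocess_recording(s$recording)
  expect_true(all(is.finite(h$hbo2)))
  # artifact-corrected concentrations stay in a physiological range
  expect_lt(max(abs(h$hbo2)), 50)
})
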