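#' Specification of a synthetic three-group cohort
#'
#' Defines the generative model of a synthetic cohort mirroring a
#' three-group (T2DM with depression, T2DM, healthy) block-design fNIRS
#' study: group- and ROI-dependent task-evoked \eqn{\Delta HbO_2}
#' amplitudes, a hemispheric left/right amplitude ratio per group,
#' phase-coupling blocks with group-dependent strength, physiological
#' noise (cardiac, respiratory, Mayer waves, white noise, linear drift),
#' motion artifacts, and clinical scores calibrated to the published
#' group summary table.
#'
#' Default effect amplitudes put the healthy group highest and the
#' depressed group lowest (1.0 / 0.7 / 0.4 umol/L) in the six ROIs where
#' the study reports group differences (FPA, DLPFC, Broca, PMC, STG,
#' SMA), with a common 0.5 umol/L response elsewhere.  Default
#' laterality ratios are 1.2 (healthy), 1.1 (T2DM) and 0.8 (depressed,
#' i.e. right-dominant).  Default coupling blocks: channels 1-5 share an
#' oscillator at strength 0.9 (reduced to 0.5 in the depressed group),
#' channels 21-25 at strength 0.1 in all groups.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect_amplitude 3 x 10 matrix (groups x ROIs) of evoked
#'   \eqn{\Delta HbO_2} peaks, umol/L.
#' @param laterality_factor named numeric: left/right amplitude ratio per
#'   group.
#' @param coupling_blocks list of \code{list(channels =, strength =)}
#'   where \code{strength} is a named per-group mixing coefficient in
#'   \[0, 1\].
#' @param noise list of noise parameters, see \code{\link{default_noise}}.
#' @param artifact_rate motion-artifact events per minute.
#' @param hb_ratio \eqn{\Delta Hb = -r\,\Delta HbO_2}; default 0.3.
#' @param i0 baseline detector intensity (arbitrary units).
#' @param clinical per-group clinical score distributions, see
#'   \code{\link{default_clinical}}.
#' @param seed RNG seed (required: generation must be reproducible).
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 20L,
                        effect_amplitude = default_effect_amplitude(),
                        laterality_factor = c(T2DM_MDD = 0.8,
                                              T2DM = 1.1,
                                              HEALTHY = 1.2),
                        coupling_blocks = default_coupling_blocks(),
                        noise = default_noise(),
                        artifact_rate = 0.5,
                        hb_ratio = 0.3,
                        i0 = 1.0,
                        clinical = default_clinical(),
                        seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_per_group >= 2, all(is.finite(effect_amplitude)))
  for (b in coupling_blocks)
    stopifnot(all(b$strength >= 0), all(b$strength <= 1))
  out <- list(n_per_group = as.integer(n_per_group),
              effect_amplitude = effect_amplitude,
              laterality_factor = laterality_factor,
              coupling_blocks = coupling_blocks, noise = noise,
              artifact_rate = artifact_rate, hb_ratio = hb_ratio,
              i0 = i0, clinical = clinical, seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' @rdname cohort_spec
#' @export
default_effect_amplitude <- function() {
  rois <- roi_labels()
  m <- matrix(0.5, 3, length(rois),
              dimnames = list(group_labels(), rois))
  graded <- c("FPA", "DLPFC", "Broca", "PMC", "STG", "SMA")
  m["HEALTHY", graded] <- 1.0
  m["T2DM", graded] <- 0.7
  m["T2DM_MDD", graded] <- 0.4
  m
}

#' @rdname cohort_spec
#' @export
default_coupling_blocks <- function() {
  list(
    list(channels = 1:5,
         strength = c(T2DM_MDD = 0.5, T2DM = 0.9, HEALTHY = 0.9)),
    list(channels = 21:25,
         strength = c(T2DM_MDD = 0.1, T2DM = 0.1, HEALTHY = 0.1))
  )
}

#' Physiological noise parameters of the generator
#'
#' Amplitudes are in umol/L of \eqn{\Delta HbO_2}.  \code{between_sd} is
#' the relative between-subject sd of the evoked amplitude (a
#' multiplicative subject gain ~ N(1, between_sd)); \code{osc_amp} the sd
#' of the in-band oscillatory component carrying the phase-coupling
#' structure; \code{drift_amp} the linear drift over the whole record.
#'
#' @param cardiac_hz,respiratory_hz,mayer_hz oscillation frequencies, Hz.
#' @param cardiac_amp,respiratory_amp,mayer_amp sinusoid amplitudes.
#' @param white_sd white-noise sd.
#' @param drift_amp drift magnitude over the record (random sign).
#' @param between_sd relative between-subject amplitude sd.
#' @param osc_amp sd of the band-limited coupling oscillation.
#' @return named list.
#' @export
default_noise <- function(cardiac_hz = 1.0, cardiac_amp = 0.2,
                          respiratory_hz = 0.25, respiratory_amp = 0.15,
                          mayer_hz = 0.1, mayer_amp = 0.1,
                          white_sd = 0.1, drift_amp = 0.2,
                          between_sd = 0.15, osc_amp = 0.4) {
  list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
       respiratory_hz = respiratory_hz, respiratory_amp = respiratory_amp,
       mayer_hz = mayer_hz, mayer_amp = mayer_amp, white_sd = white_sd,
       drift_amp = drift_amp, between_sd = between_sd, osc_amp = osc_amp)
}

#' @rdname default_noise
#' @export
quiet_noise <- function() {
  default_noise(cardiac_amp = 0, respiratory_amp = 0, mayer_amp = 0,
                white_sd = 0, drift_amp = 0, between_sd = 0, osc_amp = 0)
}

#' Clinical score distributions per group
#'
#' Per-group (mean, sd) of each clinical/demographic variable, calibrated
#' to the published cohort summary (\code{\link{table1_reference}}), plus
#' plausible instrument bounds used to truncate the sampled normals and
#' the per-group male proportion.
#'
#' @return list with \code{moments} (data.frame), \code{bounds},
#'   \code{male_prop}.
#' @export
default_clinical <- function() {
  t1 <- table1_reference()$continuous
  moments <- data.frame(
    variable = rep(t1$variable, each = 3),
    group = rep(group_labels(), nrow(t1)),
    mean = as.vector(rbind(t1$mean_1, t1$mean_2, t1$mean_3)),
    sd = as.vector(rbind(t1$sd_1, t1$sd_2, t1$sd_3)),
    stringsAsFactors = FALSE
  )
  dur <- table1_reference()$duration
  moments <- rbind(moments, data.frame(
    variable = "t2dm_duration",
    group = c("T2DM_MDD", "T2DM"),
    mean = c(dur$mean_1, dur$mean_2),
    sd = c(dur$sd_1, dur$sd_2)))
  bounds <- list(age = c(55, 80), height = c(140, 190),
                 weight = c(35, 120), HAMD24 = c(0, 76),
                 SDSS = c(0, 20), MOCA = c(0, 30),
                 taichi_score = c(0, 100), t2dm_duration = c(0.5, 40))
  male_prop <- c(T2DM_MDD = 12 / 30, T2DM = 15 / 30, HEALTHY = 13 / 30)
  list(moments = moments, bounds = bounds, male_prop = male_prop)
}

#' Band-limited unit-variance noise
#'
#' White Gaussian noise band-passed to the hemodynamic band and
#' standardized to unit sd; the carrier of the generator's
#' phase-coupling structure.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param band pass band, Hz.
#' @return numeric vector of length \code{n}, sd 1.
#' @export
narrowband_noise <- function(n, fs = 5, band = c(0.01, 0.1)) {
  x <- bandpass_filter(stats::rnorm(n), band = band, fs = fs)
  x / stats::sd(x)
}

#' Simulate one subject's raw recording with known ground truth
#'
#' Forward model: evoked \eqn{\Delta HbO_2} = task boxcar convolved with
#' the canonical HRF (unit peak) times the group/ROI amplitude times the
#' hemispheric factor times a subject gain; channels in a coupling block
#' mix a shared band-limited oscillator at the block's strength
#' \eqn{m} (amplitude-preserving: \eqn{m\,c + \sqrt{1-m^2}\,e});
#' physiological noise and drift are added; \eqn{\Delta Hb = -r\,\Delta
#' HbO_2}; concentrations map to optical density through the MBLL
#' forward model and to intensity as \eqn{I_0\,10^{-\Delta OD}}.
#' Poisson-timed motion artifacts (1-sample spikes of 10 trace-sd,
#' baseline steps of 5 trace-sd lasting to the end of the record) are
#' injected in the OD domain.
#'
#' @param spec a \code{cohort_spec}.
#' @param group group label.
#' @param seed integer seed (required).
#' @param subject_id label.
#' @param layout,paradigm montage and paradigm.
#' @param config an \code{analysis_config} (extinction/DPF of the
#'   forward model).
#' @return list with \code{recording} (a \code{raw_recording}) and
#'   \code{truth} (list: \code{true_beta} per channel, \code{subject_gain},
#'   \code{true_li}, \code{evoked} channel x time matrix,
#'   \code{hbo2} the complete noiseless+noise concentration matrix).
#' @export
simulate_subject <- function(spec, group, seed, subject_id = NULL,
                             layout = probe_layout(),
                             paradigm = task_paradigm(),
                             config = analysis_config()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  group <- match.arg(group, group_labels())
  set.seed(seed)
  if (is.null(subject_id)) subject_id <- sprintf("%s_s%06d", group, seed %% 1e6)
  n <- paradigm$n_samples
  fs <- paradigm$fs
  tt <- (seq_len(n) - 1) / fs
  nz <- spec$noise
  reg <- build_design(paradigm, drift = FALSE)[, "task"]

  roi <- layout$channels$roi
  hemi <- layout$channels$hemisphere
  n_ch <- nrow(layout$channels)
  ratio <- spec$laterality_factor[[group]]
  f_left <- 2 * ratio / (1 + ratio)
  f_right <- 2 / (1 + ratio)
  hemi_f <- ifelse(hemi == "left", f_left, f_right)
  gain <- max(0.1, 1 + stats::rnorm(1, 0, nz$between_sd))
  amp <- spec$effect_amplitude[group, roi] * hemi_f * gain
  evoked <- outer(amp, reg)

  # band-limited oscillation carrying the coupling structure
  osc <- matrix(0, n_ch, n)
  if (nz$osc_amp > 0) {
    in_block <- rep(FALSE, n_ch)
    for (b in spec$coupling_blocks) {
      m <- unname(b$strength[group])
      common <- narrowband_noise(n, fs)
      for (ch in b$channels) {
        osc[ch, ] <- nz$osc_amp *
          (m * common + sqrt(1 - m^2) * narrowband_noise(n, fs))
        in_block[ch] <- TRUE
      }
    }
    for (ch in which(!in_block))
      osc[ch, ] <- nz$osc_amp * narrowband_noise(n, fs)
  }

  sinus <- function(a, f) {
    if (a == 0) return(numeric(n))
    a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }
  noise <- t(vapply(seq_len(n_ch), function(ch) {
    v <- sinus(nz$cardiac_amp, nz$cardiac_hz) +
      sinus(nz$respiratory_amp, nz$respiratory_hz) +
      sinus(nz$mayer_amp, nz$mayer_hz)
    if (nz$white_sd > 0) v <- v + stats::rnorm(n, 0, nz$white_sd)
    if (nz$drift_amp > 0)
      v <- v + sample(c(-1, 1), 1) * nz$drift_amp * (tt / max(tt) - 0.5)
    v
  }, numeric(n)))

  hbo2 <- evoked + osc + noise
  hb <- -spec$hb_ratio * hbo2

  seps <- layout$channels$separation
  od <- array(0, c(n_ch, 2L, n))
  for (ch in seq_len(n_ch))
    od[ch, , ] <- mbll_forward(hbo2[ch, ], hb[ch, ], config$extinction,
                               d = seps[ch], dpf = config$dpf)

  if (spec$artifact_rate > 0) {
    n_art <- stats::rpois(1, spec$artifact_rate * (n / fs) / 60)
    for (a in seq_len(n_art)) {
      ch <- sample.int(n_ch, 1)
      at <- sample.int(n, 1)
      spike <- stats::runif(1) < 0.7
      for (wl in 1:2) {
        s <- stats::sd(od[ch, wl, ])
        if (s == 0) s <- 1e-3
        if (spike) {
          od[ch, wl, at] <- od[ch, wl, at] + sample(c(-1, 1), 1) * 10 * s
        } else {
          od[ch, wl, at:n] <- od[ch, wl, at:n] + sample(c(-1, 1), 1) * 5 * s
        }
      }
    }
  }

  intensity <- spec$i0 * 10^(-od)
  rec <- raw_recording(subject_id, group, intensity, fs = fs,
                       events = as.integer(round(paradigm$block_onsets * fs)),
                       layout = layout)
  truth <- list(subject_id = subject_id, group = group,
                true_beta = amp, subject_gain = gain,
                true_li = (f_left - f_right) / (f_left + f_right),
                evoked = evoked, hbo2 = hbo2)
  list(recording = rec, truth = truth)
}

truncnorm1 <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate clinical scores for a cohort
#'
#' Scores are drawn from per-group normals (means/sds calibrated to the
#' published cohort table) truncated at plausible instrument bounds; sex
#' is Bernoulli with the published per-group male proportion; T2DM
#' duration is only defined for the diabetic groups.
#'
#' @param groups character vector of group labels (one per subject).
#' @param subject_ids subject labels.
#' @param clinical a \code{\link{default_clinical}}-shaped list.
#' @return clinical data.frame.
#' @export
simulate_clinical <- function(groups, subject_ids,
                              clinical = default_clinical()) {
  n <- length(groups)
  out <- data.frame(subject_id = subject_ids, group = groups,
                    stringsAsFactors = FALSE)
  mom <- clinical$moments
  for (v in unique(mom$variable)) {
    col <- rep(NA_real_, n)
    for (g in unique(groups)) {
      row <- mom[mom$variable == v & mom$group == g, ]
      if (nrow(row) == 0) next
      b <- clinical$bounds[[v]]
      sel <- groups == g
      col[sel] <- truncnorm1(sum(sel), row$mean, row$sd, b[1], b[2])
    }
    out[[v]] <- col
  }
  out$sex <- ifelse(stats::runif(n) <
                      clinical$male_prop[out$group], "male", "female")
  out
}

#' Simulate a full three-group cohort with ground truth
#'
#' @param spec a \code{cohort_spec} (its \code{seed} drives everything).
#' @param layout,paradigm,config forwarded to
#'   \code{\link{simulate_subject}}.
#' @return list with \code{recordings} (list of \code{raw_recording}),
#'   \code{truth} (list with \code{betas} data.frame
#'   \code{(subject_id, group, channel_id, true_beta)}, \code{li}
#'   data.frame, \code{coupling_blocks}), and \code{clinical}
#'   (data.frame).
#' @export
simulate_cohort <- function(spec, layout = probe_layout(),
                            paradigm = task_paradigm(),
                            config = analysis_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(group_labels(), each = spec$n_per_group)
  n_sub <- length(groups)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sub)
  ids <- sprintf("%s_%02d", groups, sequence(rep(spec$n_per_group, 3)))
  recs <- vector("list", n_sub)
  beta_rows <- vector("list", n_sub)
  li_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sim <- simulate_subject(spec, groups[i], seed = seeds[i],
                            subject_id = ids[i], layout = layout,
                            paradigm = paradigm, config = config)
    recs[[i]] <- sim$recording
    beta_rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                                 channel_id = seq_along(sim$truth$true_beta),
                                 true_beta = sim$truth$true_beta,
                                 stringsAsFactors = FALSE)
    li_rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                               true_li = sim$truth$true_li,
                               stringsAsFactors = FALSE)
  }
  set.seed(seeds[n_sub] + 1L)
  clinical <- simulate_clinical(groups, ids, spec$clinical)
  truth <- list(betas = do.call(rbind, beta_rows),
                li = do.call(rbind, li_rows),
                coupling_blocks = spec$coupling_blocks)
  list(recordings = recs, truth = truth, clinical = clinical)
}

#' Write a cohort's ground truth as a sidecar CSV
#' @param truth the \code{truth} element of \code{\link{simulate_cohort}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth$betas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
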