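#' Probe layout for the 16x16, 40-channel prefrontal/motor montage
#'
#' Describes the optode geometry of a continuous-wave fNIRS montage with 16
#' sources, 16 detectors and 40 measurement channels, each a source-detector
#' pair at (by default) 2.5 cm separation, measured at 760 and 850 nm.
#' Channels CH1-CH9, CH11 and CH31-CH40 lie over the left hemisphere and
#' CH10, CH12-CH30 over the right, 20 channels per side.
#'
#' Each channel carries a region-of-interest (ROI) label.  The shipped
#' default map assigns the ten ROI labels (DLPFC, Broca, FPA, OA over the
#' prefrontal cortex; FEF, SMA, PMC, PSC, STG, Wernicke over the motor
#' strip and surroundings) to contiguous channel blocks, bilaterally, so
#' that every ROI has channels on both sides of the hemispheric split.
#' The map is configuration: pass \code{roi_map} to override it.
#'
#' @param separation source-detector separation in cm (scalar or length 40).
#' @param roi_map character vector of length 40 naming the ROI of each
#'   channel, or \code{NULL} for the shipped default.
#' @param wavelengths the two measurement wavelengths in nm.
#' @return an object of class \code{probe_layout}: list with
#'   \code{n_sources}, \code{n_detectors}, \code{channels} (data.frame with
#'   \code{channel_id}, \code{source_id}, \code{detector_id},
#'   \code{separation}, \code{hemisphere}, \code{roi}), \code{wavelengths}.
#' @export
probe_layout <- function(separation = 2.5, roi_map = NULL,
                         wavelengths = c(760, 850)) {
  n_ch <- 40L
  left <- c(1:9, 11, 31:40)
  hemisphere <- ifelse(seq_len(n_ch) %in% left, "left", "right")
  if (is.null(roi_map)) roi_map <- default_roi_map()
  roi_map <- as.character(roi_map)
  if (length(roi_map) != n_ch)
    stop("roi_map must name an ROI for each of the 40 channels")
  bad <- setdiff(unique(roi_map), roi_labels())
  if (length(bad))
    stop("unknown ROI label(s): ", paste(bad, collapse = ", "))
  separation <- rep_len(separation, n_ch)
  if (any(!is.finite(separation) | separation <= 0))
    stop("separations must be positive")
  if (length(wavelengths) != 2L)
    stop("exactly two wavelengths are required")
  channels <- data.frame(
    channel_id  = seq_len(n_ch),
    source_id   = ((seq_len(n_ch) - 1L) %% 16L) + 1L,
    detector_id = ((seq_len(n_ch) - 1L) %/% 16L + seq_len(n_ch) - 1L) %% 16L + 1L,
    separation  = separation,
    hemisphere  = hemisphere,
    roi         = roi_map,
    stringsAsFactors = FALSE
  )
  out <- list(n_sources = 16L, n_detectors = 16L, channels = channels,
              wavelengths = as.numeric(wavelengths))
  class(out) <- "probe_layout"
  stopifnot(sum(channels$hemisphere == "left") == 20L,
            sum(channels$hemisphere == "right") == 20L)
  out
}

#' @rdname probe_layout
#' @export
roi_labels <- function() {
  c("DLPFC", "Broca", "FPA", "OA", "FEF", "SMA", "PMC", "PSC",
    "STG", "Wernicke")
}

#' Default channel-to-ROI assignment
#'
#' Channels 1-20 cover the prefrontal cortex (DLPFC, FPA, Broca, OA) and
#' 21-40 the motor area (FEF, SMA, PMC, PSC, STG, Wernicke); blocks are
#' mirrored across the hemispheric partition so each ROI is bilateral.
#'
#' @return character vector of length 40.
#' @export
default_roi_map <- function() {
  m <- character(40)
  # prefrontal: left channels {1-9,11}, right {10,12-20}
  m[c(1:3, 12:14)]    <- "DLPFC"
  m[c(4:6, 15:17)]    <- "FPA"
  m[c(7:8, 18:19)]    <- "Broca"
  m[c(9, 11, 10, 20)] <- "OA"
  # motor: left channels {31-40}, right {21-30}
  m[c(31:32, 21:22)]  <- "FEF"
  m[c(33:34, 23:24)]  <- "SMA"
  m[c(35:36, 25:26)]  <- "PMC"
  m[c(37:38, 27:28)]  <- "PSC"
  m[c(39, 29)]        <- "STG"
  m[c(40, 30)]        <- "Wernicke"
  m
}

#' Which anatomical region (prefrontal vs motor) an ROI belongs to
#' @param roi character vector of ROI labels.
#' @return character vector, "prefrontal" or "motor".
#' @export
roi_region <- function(roi) {
  ifelse(roi %in% c("DLPFC", "Broca", "FPA", "OA"), "prefrontal", "motor")
}

#' Block-design task paradigm
#'
#' The default paradigm is 30 s of pre-task rest, four consecutive 15 s
#' task blocks (a 60 s task window) and 60 s of post-task rest, sampled
#' at 5 Hz: 150 s, 750 samples, task window samples [150, 450) (0-based).
#'
#' @param pre_rest pre-task rest duration, s.
#' @param task_blocks durations of the consecutive task blocks, s.
#' @param post_rest post-task rest duration, s.
#' @param fs sampling rate, Hz.
#' @return object of class \code{task_paradigm}.
#' @export
task_paradigm <- function(pre_rest = 30, task_blocks = rep(15, 4),
                          post_rest = 60, fs = 5) {
  stopifnot(pre_rest >= 0, all(task_blocks > 0), post_rest >= 0, fs > 0)
  total <- pre_rest + sum(task_blocks) + post_rest
  onsets <- pre_rest + cumsum(c(0, head(task_blocks, -1)))
  out <- list(pre_rest = pre_rest, task_blocks = as.numeric(task_blocks),
              post_rest = post_rest, fs = fs,
              total_duration = total,
              n_samples = as.integer(round(total * fs)),
              task_start = pre_rest,
              task_end = pre_rest + sum(task_blocks),
              block_onsets = onsets)
  class(out) <- "task_paradigm"
  out
}

#' Sample indices (0-based) of the task window
#' @param paradigm a \code{task_paradigm}.
#' @return integer vector of 0-based sample indices.
#' @export
task_window_samples <- function(paradigm) {
  i0 <- as.integer(round(paradigm$task_start * paradigm$fs))
  i1 <- as.integer(round(paradigm$task_end * paradigm$fs))
  seq.int(i0, i1 - 1L)
}

#' Extract the task window from a time series
#'
#' Returns the samples in the half-open window \[task start, task end)
#' (for the default paradigm: 300 samples covering 30-90 s).  Input already
#' of exactly the task-window length is returned unchanged, making the
#' operation idempotent; any other length short of the full paradigm is
#' rejected.
#'
#' @param series numeric vector, or matrix with time in columns.
#' @param paradigm a \code{task_paradigm}.
#' @return the windowed series (same type as input).
#' @export
extract_task_window <- function(series, paradigm) {
  idx <- task_window_samples(paradigm) + 1L   # to 1-based
  n_needed <- paradigm$n_samples
  len <- if (is.matrix(series)) ncol(series) else length(series)
  if (len == length(idx)) return(series)
  if (len < n_needed)
    stop("series has ", len, " samples; paradigm requires ", n_needed)
  if (is.matrix(series)) series[, idx, drop = FALSE] else series[idx]
}

#' Analysis configuration
#'
#' Bundles the constants of the concentration-recovery and inference
#' chain: per-wavelength differential pathlength factors (DPF), the
#' extinction-coefficient matrix, the hemodynamic band, filter order,
#' spline motion-correction parameters, the FDR level and the laterality
#' threshold.
#'
#' The default DPFs are 6 at 760 nm and 5 at 850 nm (DPF decreases with
#' wavelength in adult head tissue).  The default extinction coefficients
#' are the standard compiled molar extinction values for HbO2 and Hb
#' (Prahl/OMLC tabulation), expressed in cm^-1 per (umol/L):
#' rows = wavelengths (760, 850 nm), columns = (HbO2, Hb).
#'
#' @param dpf length-2 numeric, DPF at each wavelength (760, 850 nm).
#' @param extinction 2x2 matrix, cm^-1 (umol/L)^-1; rows wavelengths,
#'   columns (HbO2, Hb).
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param spline_window moving-sd window for motion detection, s.
#' @param spline_threshold detection threshold, multiples of the median
#'   moving sd.
#' @param fdr_alpha FDR level for group inference.
#' @param li_threshold laterality classification threshold.
#' @param li_floor smallest |L+R| (umol/L) for which LI is defined.
#' @param seed default RNG seed for stochastic helpers.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(dpf = c(6, 5),
                            extinction = default_extinction(),
                            band = c(0.01, 0.1),
                            filter_order = 3,
                            spline_window = 2,
                            spline_threshold = 3,
                            fdr_alpha = 0.05,
                            li_threshold = 0.1,
                            li_floor = 1e-3,
                            seed = 1L) {
  extinction <- as.matrix(extinction)
  stopifnot(length(dpf) == 2, all(dpf > 0), all(dim(extinction) == c(2, 2)))
  if (abs(det(extinction)) < 1e-12 * max(abs(extinction))^2)
    stop("extinction matrix is singular")
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("band must satisfy 0 < low < high")
  out <- list(dpf = as.numeric(dpf), extinction = extinction, band = band,
              filter_order = filter_order, spline_window = spline_window,
              spline_threshold = spline_threshold, fdr_alpha = fdr_alpha,
              li_threshold = li_threshold, li_floor = li_floor,
              seed = as.integer(seed))
  class(out) <- "analysis_config"
  out
}

#' @rdname analysis_config
#' @export
default_extinction <- function() {
  # molar extinction (cm^-1 M^-1) scaled to umol/L: Prahl/OMLC compilation
  e <- matrix(c(586,  1548.52,    # 760 nm: HbO2, Hb
                1058,  691.32),   # 850 nm: HbO2, Hb
              nrow = 2, byrow = TRUE,
              dimnames = list(c("760", "850"), c("HbO2", "Hb")))
  e * 1e-6
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror the arguments of \code{\link{analysis_config}};
#' \code{extinction} is given as a 2x2 row-major list.  Missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return an \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("dpf", "band", "filter_order", "spline_window",
              "spline_threshold", "fdr_alpha", "li_threshold",
              "li_floor", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  if (!is.null(y$extinction))
    args$extinction <- matrix(unlist(y$extinction), nrow = 2, byrow = TRUE)
  do.call(analysis_config, args)
}

#' Construct and validate a raw recording
#'
#' @param subject_id subject label.
#' @param group one of \code{"T2DM_MDD"}, \code{"T2DM"}, \code{"HEALTHY"}.
#' @param intensity numeric array \code{[channel x wavelength x time]} of
#'   strictly positive detector units.
#' @param fs sampling rate, Hz.
#' @param events 0-based sample indices of task-block onsets.
#' @param layout a \code{probe_layout} (channel count is checked).
#' @return object of class \code{raw_recording}.
#' @export
raw_recording <- function(subject_id, group, intensity, fs = 5,
                          events = NULL, layout = probe_layout()) {
  group <- match.arg(group, group_labels())
  if (length(dim(intensity)) != 3L)
    stop("intensity must be a [channel x wavelength x time] array")
  if (dim(intensity)[1] != nrow(layout$channels))
    stop("layout mismatch: recording has ", dim(intensity)[1],
         " channels, layout defines ", nrow(layout$channels))
  if (dim(intensity)[2] != 2L)
    stop("two wavelengths are required")
  bad <- which(!(is.finite(intensity) & intensity > 0))
  if (length(bad)) {
    ix <- arrayInd(bad[1], dim(intensity))
    stop(sprintf(
      "nonpositive or non-finite intensity at channel %d, wavelength %d, sample %d (%d offending values)",
      ix[1], ix[2], ix[3], length(bad)))
  }
  out <- list(subject_id = subject_id, group = group, intensity = intensity,
              fs = fs, events = events)
  class(out) <- "raw_recording"
  out
}

#' @rdname raw_recording
#' @export
group_labels <- function() c("T2DM_MDD", "T2DM", "HEALTHY")

#' Per-channel signal validity
#'
#' Splits each channel's trace into consecutive non-overlapping windows and
#' reports, per channel, the fraction of windows that are finite, strictly
#' positive, and have a coefficient of variation at most \code{cv_max}; the
#' per-channel validity is the minimum over the two wavelengths.  Channels
#' with validity below 0.9 are flagged, mirroring the acquisition-time
#' quality requirement that channel validity exceed 90%.
#'
#' @param rec a \code{raw_recording}.
#' @param window window length in samples (>= 2).
#' @param cv_max maximum admissible coefficient of variation per window.
#' @param saturation detector ceiling: windows containing values at or
#'   above it are invalid (default \code{Inf}, i.e. no ceiling).
#' @return data.frame with \code{channel_id}, \code{validity}, \code{valid}.
#' @export
signal_validity <- function(rec, window = 25L, cv_max = 0.5,
                            saturation = Inf) {
  stopifnot(inherits(rec, "raw_recording"), window >= 2)
  dims <- dim(rec$intensity)
  if (dims[3] < window) stop("recording shorter than one window")
  n_win <- dims[3] %/% window
  validity <- matrix(NA_real_, dims[1], dims[2])
  for (ch in seq_len(dims[1])) {
    for (wl in seq_len(dims[2])) {
      x <- rec$intensity[ch, wl, seq_len(n_win * window)]
      if (!any(is.finite(x) & x > 0))
        stop("channel ", ch, " wavelength ", wl,
             " has no positive finite samples")
      m <- matrix(x, nrow = window)
      mu <- colMeans(m)
      sdv <- apply(m, 2, stats::sd)
      ok <- apply(m, 2, function(v) all(is.finite(v) & v > 0 &
                                          v < saturation)) &
        (sdv / mu) <= cv_max
      validity[ch, wl] <- mean(ok)
    }
  }
  v <- apply(validity, 1, min)
  data.frame(channel_id = seq_len(dims[1]), validity = v, valid = v >= 0.9)
}
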