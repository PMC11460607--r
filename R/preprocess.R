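#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth band-pass,
#' by default order 3 over 0.01-0.1 Hz, the band that isolates the
#' task-evoked hemodynamic response from cardiac (~1 Hz), respiratory
#' (~0.25 Hz) and very-low-frequency drift components.  DC is removed;
#' passband amplitude is preserved within 5%.
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param band numeric length-2, (low, high) in Hz; 0 < low < high < fs/2.
#' @param order Butterworth order.
#' @param fs sampling rate, Hz.
#' @return filtered series, same shape as \code{x}.
#' @export
bandpass_filter <- function(x, band = c(0.01, 0.1), order = 3, fs = 5) {
  if (!(length(band) == 2 && band[1] > 0 && band[1] < band[2] &&
        band[2] < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt1 <- function(v) {
    mu <- mean(v)
    signal::filtfilt(bf, v - mu)
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

moving_sd <- function(x, w) {
  # centered moving standard deviation via cumulative sums
  n <- length(x)
  k <- rep(1 / w, w)
  m1 <- stats::filter(x, k, sides = 2)
  m2 <- stats::filter(x^2, k, sides = 2)
  v <- pmax(as.numeric(m2 - m1^2), 0)
  out <- sqrt(v * w / (w - 1))
  # extend to the edges with the nearest defined value
  idx <- which(!is.na(out))
  out[seq_len(idx[1] - 1)] <- out[idx[1]]
  if (idx[length(idx)] < n)
    out[(idx[length(idx)] + 1):n] <- out[idx[length(idx)]]
  out
}

#' Spline-based motion-artifact correction
#'
#' Detects motion-contaminated segments as runs where the moving standard
#' deviation of the first difference exceeds \code{threshold} times a
#' robust reference level (the 90th percentile of the statistic over the
#' numerically non-flat part of the trace, so that up to ~10% of
#' contaminated samples cannot drag the reference up, while ordinary
#' signal transitions -- which live below that percentile -- never
#' trigger), then corrects each flagged segment in the
#' derivative domain: the trace derivative inside the segment (which
#' carries the artifact excursion) is replaced by a natural cubic spline
#' interpolated from the neighbouring clean samples, and the trace is
#' re-integrated.  Equivalently, the spline-modelled artifact excursion
#' is subtracted and every later segment is re-levelled so that levels
#' join continuously: transient spikes are removed in place and baseline
#' steps are undone for the remainder of the record.  Clean traces are
#' returned unchanged (empty mask).
#'
#' @param x numeric vector (a single channel/wavelength trace).
#' @param fs sampling rate, Hz.
#' @param window moving-sd window, s (>= 3 samples after conversion).
#' @param threshold detection threshold, multiples of the reference
#'   (90th-percentile) moving sd.
#' @return list with \code{series} (corrected trace) and \code{mask}
#'   (logical, TRUE at samples flagged as artifact).
#' @export
correct_motion_spline <- function(x, fs = 5, window = 2, threshold = 3) {
  n <- length(x)
  w <- max(3L, as.integer(round(window * fs)))
  if (w > n) stop("window longer than series")
  dx <- c(0, diff(x))
  ms <- moving_sd(dx, w)
  # reference over numerically non-flat samples: an exactly flat stretch
  # (e.g. a noiseless rest period) must not drag the reference to the
  # quantization floor and turn ordinary signal transitions into flags
  act <- ms > 1e-9 * max(ms)
  ref <- stats::quantile(ms[act], 0.9, names = FALSE)
  if (!is.finite(ref) || ref <= 0)
    return(list(series = x, mask = rep(FALSE, n)))
  mask <- ms > threshold * ref
  if (!any(mask)) return(list(series = x, mask = mask))
  # dilate by half a window so the excursion edges fall inside the run
  half <- w %/% 2
  dil <- mask
  for (i in which(mask)) dil[max(1, i - half):min(n, i + half)] <- TRUE
  # a diff d[i] connects samples i and i+1: contaminated if either is
  bad_d <- dil[-n] | dil[-1]
  good <- which(!bad_d)
  if (length(good) < 2)
    stop("artifact mask covers almost the whole trace; cannot correct")
  d <- diff(x)
  # bridge each contaminated run with a cubic spline through windowed
  # means of the neighbouring clean derivative (stable under noise)
  side_anchors <- function(idx, n_anchor = 3) {
    # windowed means of the clean derivative, nearest-first
    out_x <- numeric(0); out_y <- numeric(0)
    for (a in seq_len(n_anchor)) {
      sel <- idx[((a - 1) * w + 1):min(a * w, length(idx))]
      sel <- sel[!is.na(sel)]
      if (!length(sel)) break
      out_x <- c(out_x, mean(sel)); out_y <- c(out_y, mean(d[sel]))
      if (length(idx) <= a * w) break
    }
    list(x = out_x, y = out_y)
  }
  r <- rle(bad_d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (s in which(r$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    la <- side_anchors(rev(good[good < i0]))
    ra <- side_anchors(good[good > i1])
    ax <- c(rev(la$x), ra$x); ay <- c(rev(la$y), ra$y)
    gap <- i0:i1
    d[gap] <- if (length(ax) >= 2) {
      stats::spline(ax, ay, xout = gap, method = "natural")$y
    } else rep(if (length(ay)) ay else 0, length(gap))
  }
  list(series = x[1] + c(0, cumsum(d)), mask = mask)
}

#' Full preprocessing chain: raw intensity to hemoglobin concentrations
#'
#' Runs, in order: optical-density conversion against the pre-task rest
#' baseline, spline motion correction of each OD trace, MBLL inversion to
#' \eqn{\Delta HbO_2}/\eqn{\Delta Hb}, and zero-phase band-pass filtering.
#' Total hemoglobin is the sum \eqn{\Delta THbO_2 = \Delta HbO_2 + \Delta
#' Hb}, an identity preserved by every (linear) step.
#'
#' @param rec a \code{raw_recording}.
#' @param config an \code{analysis_config}.
#' @param layout a \code{probe_layout} (channel separations).
#' @param paradigm a \code{task_paradigm} (baseline window).
#' @param motion_correct logical; apply spline motion correction.
#' @param filter logical; apply the band-pass.
#' @return object of class \code{hemoglobin_series}: list with
#'   \code{hbo2}, \code{hb}, \code{thb} (channel x time matrices, umol/L),
#'   \code{fs}, \code{subject_id}, \code{group}, \code{artifact_mask}.
#' @export
preprocess_recording <- function(rec, config = analysis_config(),
                                 layout = probe_layout(),
                                 paradigm = task_paradigm(),
                                 motion_correct = TRUE, filter = TRUE) {
  baseline <- seq_len(as.integer(round(paradigm$pre_rest * paradigm$fs)))
  ods <- intensity_to_od(rec, baseline)
  od <- ods$od
  dims <- dim(od)
  mask <- matrix(FALSE, dims[1], dims[3])
  if (motion_correct) {
    for (ch in seq_len(dims[1])) {
      for (wl in 1:2) {
        cm <- correct_motion_spline(od[ch, wl, ], fs = rec$fs,
                                    window = config$spline_window,
                                    threshold = config$spline_threshold)
        od[ch, wl, ] <- cm$series
        mask[ch, ] <- mask[ch, ] | cm$mask
      }
    }
  }
  n_ch <- dims[1]; n_t <- dims[3]
  hbo2 <- matrix(0, n_ch, n_t)
  hb <- matrix(0, n_ch, n_t)
  seps <- layout$channels$separation
  for (ch in seq_len(n_ch)) {
    conc <- mbll_invert(od[ch, , ], config$extinction, d = seps[ch],
                        dpf = config$dpf)
    hbo2[ch, ] <- conc$dhbo2
    hb[ch, ] <- conc$dhb
  }
  if (filter) {
    hbo2 <- bandpass_filter(hbo2, config$band, config$filter_order, rec$fs)
    hb <- bandpass_filter(hb, config$band, config$filter_order, rec$fs)
  }
  out <- list(hbo2 = hbo2, hb = hb, thb = hbo2 + hb, fs = rec$fs,
              subject_id = rec$subject_id, group = rec$group,
              artifact_mask = mask)
  class(out) <- "hemoglobin_series"
  out
}
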