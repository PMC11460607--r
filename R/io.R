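#' Write a raw recording to the long-format CSV dialect
#'
#' Columns: \code{subject_id, group, channel, wavelength_nm, sample_index,
#' intensity}; UTF-8 with header.  \code{sample_index} is 0-based.  Block
#' onsets are written to a sidecar \code{<stem>_events.csv} with a single
#' \code{onset_sample} column.
#'
#' @param rec a \code{raw_recording}.
#' @param path output CSV path.
#' @param layout the \code{probe_layout} (wavelength labels).
#' @return \code{path}, invisibly.
#' @export
write_recording_csv <- function(rec, path, layout = probe_layout()) {
  stopifnot(inherits(rec, "raw_recording"))
  dims <- dim(rec$intensity)
  n_ch <- dims[1]; n_t <- dims[3]
  wl <- layout$wavelengths
  df <- data.frame(
    subject_id = rec$subject_id,
    group = rec$group,
    channel = rep(seq_len(n_ch), times = 2 * n_t),
    wavelength_nm = rep(rep(wl, each = n_ch), times = n_t),
    sample_index = rep(seq_len(n_t) - 1L, each = 2 * n_ch),
    stringsAsFactors = FALSE
  )
  df$intensity <- rec$intensity[cbind(df$channel,
                                      match(df$wavelength_nm, wl),
                                      df$sample_index + 1L)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(rec$events))
    utils::write.csv(data.frame(onset_sample = rec$events),
                     events_sidecar_path(path), row.names = FALSE)
  invisible(path)
}

events_sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_events.csv")
}

#' Load a raw recording from the CSV dialect
#'
#' Validates channel count against the layout, strict positivity of every
#' intensity sample, and consistency of the time axis with the paradigm.
#' Block-onset events are taken from the paradigm; if an events sidecar is
#' present and disagrees, the paradigm wins and a warning is emitted.
#'
#' @param path CSV file written by \code{\link{write_recording_csv}} (or
#'   any file in the same dialect).
#' @param layout a \code{probe_layout}.
#' @param paradigm a \code{task_paradigm} used to validate length and as
#'   the source of truth for events.
#' @return a \code{raw_recording}.
#' @export
load_recording <- function(path, layout = probe_layout(),
                           paradigm = task_paradigm()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "channel", "wavelength_nm",
            "sample_index", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  chs <- sort(unique(df$channel))
  n_ch <- nrow(layout$channels)
  if (!identical(as.integer(chs), seq_len(n_ch)))
    stop("layout mismatch: file has channels {",
         paste(range(chs), collapse = ".."), "} (", length(chs),
         " channels), layout defines ", n_ch)
  wl <- sort(unique(df$wavelength_nm))
  if (!isTRUE(all.equal(wl, sort(layout$wavelengths))))
    stop("wavelengths in file (", paste(wl, collapse = ", "),
         ") do not match layout")
  n_t <- max(df$sample_index) + 1L
  if (nrow(df) != n_ch * 2L * n_t)
    stop("incomplete grid: expected ", n_ch * 2L * n_t, " rows, found ",
         nrow(df))
  bad <- which(!(is.finite(df$intensity) & df$intensity > 0))
  if (length(bad))
    stop(sprintf(
      "nonpositive intensity at channel %d, wavelength %g nm, sample %d",
      df$channel[bad[1]], df$wavelength_nm[bad[1]], df$sample_index[bad[1]]))
  if (n_t != paradigm$n_samples)
    stop("file has ", n_t, " samples; paradigm requires ",
         paradigm$n_samples)
  arr <- array(NA_real_, c(n_ch, 2L, n_t))
  arr[cbind(df$channel, match(df$wavelength_nm, layout$wavelengths),
            df$sample_index + 1L)] <- df$intensity
  events <- as.integer(round(paradigm$block_onsets * paradigm$fs))
  ev_path <- events_sidecar_path(path)
  if (file.exists(ev_path)) {
    ev <- utils::read.csv(ev_path)$onset_sample
    if (!identical(as.integer(ev), events))
      warning("events sidecar disagrees with paradigm; using paradigm")
  }
  raw_recording(subject_id = df$subject_id[1], group = df$group[1],
                intensity = arr, fs = paradigm$fs, events = events,
                layout = layout)
}

#' Write hemoglobin concentration series as tidy CSV
#'
#' Long format: \code{subject_id, channel, sample_index, hbo2, hb, thb}
#' (umol/L), with the artifact mask in a sidecar
#' \code{<stem>_artifacts.csv} (\code{channel, sample_index} rows).
#'
#' @param hemo a \code{hemoglobin_series} (see
#'   \code{\link{preprocess_recording}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_hemoglobin_csv <- function(hemo, path) {
  n_ch <- nrow(hemo$hbo2); n_t <- ncol(hemo$hbo2)
  df <- data.frame(
    subject_id = hemo$subject_id,
    channel = rep(seq_len(n_ch), times = n_t),
    sample_index = rep(seq_len(n_t) - 1L, each = n_ch),
    hbo2 = as.vector(hemo$hbo2),
    hb = as.vector(hemo$hb),
    thb = as.vector(hemo$thb)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(hemo$artifact_mask) && any(hemo$artifact_mask)) {
    w <- which(hemo$artifact_mask, arr.ind = TRUE)
    utils::write.csv(
      data.frame(channel = w[, 1], sample_index = w[, 2] - 1L),
      sub("\\.csv$", "_artifacts.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read/write the per-subject clinical table
#'
#' Columns: \code{subject_id, group, age, sex, height, weight,
#' t2dm_duration, HAMD24, SDSS, MOCA, taichi_score}.
#'
#' @param x data.frame (for writing).
#' @param path CSV path.
#' @return the clinical data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$group), group_labels())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_clinical_csv
#' @export
write_clinical_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
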