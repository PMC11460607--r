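#' Run the full analysis chain on a set of recordings
#'
#' For each raw recording: preprocessing (OD conversion, motion
#' correction, MBLL inversion, band-pass), then any of (i) per-channel
#' GLM betas against the canonical-HRF design (whose task regressor is
#' passed through the same band-pass as the data, so that the filter does
#' not bias the estimate), (ii) per-region laterality records, and
#' (iii) the subject's phase-locking matrix.
#'
#' @param recordings list of \code{raw_recording}.
#' @param config an \code{analysis_config}.
#' @param layout,paradigm montage and paradigm.
#' @param what subset of \code{c("betas", "laterality", "plv")}.
#' @param motion_correct apply spline motion correction.
#' @param prewhiten AR(1) prewhitening in the GLM.
#' @return list with (depending on \code{what}) \code{betas} (beta
#'   table), \code{laterality} (row-bound records), \code{plv} (list of
#'   \code{plv_matrix}), and always \code{design}.
#' @export
analyze_cohort <- function(recordings, config = analysis_config(),
                           layout = probe_layout(),
                           paradigm = task_paradigm(),
                           what = c("betas", "laterality", "plv"),
                           motion_correct = TRUE, prewhiten = FALSE) {
  design <- build_design(paradigm,
                         filter = function(v)
                           bandpass_filter(v, config$band,
                                           config$filter_order,
                                           paradigm$fs))
  betas <- list(); lat <- list(); plvs <- list()
  for (i in seq_along(recordings)) {
    h <- preprocess_recording(recordings[[i]], config, layout, paradigm,
                              motion_correct = motion_correct)
    if ("betas" %in% what)
      betas[[i]] <- beta_table(list(h), design, prewhiten)
    if ("laterality" %in% what)
      lat[[i]] <- laterality_records(h, layout, paradigm,
                                     eps = config$li_floor,
                                     threshold = config$li_threshold)
    if ("plv" %in% what)
      plvs[[i]] <- plv_matrix(h, paradigm)
  }
  out <- list(design = design)
  if ("betas" %in% what) out$betas <- do.call(rbind, betas)
  if ("laterality" %in% what) out$laterality <- do.call(rbind, lat)
  if ("plv" %in% what) out$plv <- plvs
  out
}
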