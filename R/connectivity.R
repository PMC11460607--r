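#' Instantaneous phase via the analytic signal
#'
#' Builds the analytic signal \eqn{x + i\,\hat x} by the frequency-domain
#' construction (positive frequencies doubled, negative zeroed) and
#' returns its argument.  Intended for band-limited input: apply the
#' hemodynamic band-pass first.
#'
#' @param x numeric vector, band-limited series (mean is removed).
#' @return phase series in radians, in (-pi, pi\].
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 4) stop("series too short for phase extraction")
  x <- x - mean(x)
  if (max(abs(x)) == 0) stop("constant series: phase undefined")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  Arg(z)
}

#' Unwrap a phase series
#' @param phi phase series, radians.
#' @return unwrapped phase (no jumps larger than pi between samples).
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + c(0, cumsum(d))
}

#' Phase-locking value of one channel pair
#'
#' \eqn{PLV = |\,\mathrm{mean}_t\, e^{i(\phi_a(t) - \phi_b(t))}|}: 1 for
#' a constant phase lag, near \eqn{\sqrt{\pi}/(2\sqrt{N})} in expectation
#' for independent uniform phases.
#'
#' @param phase_a,phase_b phase series, radians, equal length >= 2.
#' @return PLV in \[0, 1\].
#' @export
plv_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("phase series lengths differ")
  if (length(phase_a) < 2) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Phase-locking matrix over all channel pairs
#'
#' Extracts the instantaneous phase of every channel's band-passed
#' \eqn{\Delta HbO_2} (computed on the full record to limit transform
#' edge effects), restricts to the task window with the first and last
#' \code{trim} fraction of samples dropped, and computes the PLV of all
#' pairs.  The result is symmetric with unit diagonal and entries in
#' \[0, 1\]; a 40-channel montage yields 780 unique pairs.
#'
#' @param hemo a \code{hemoglobin_series} (band-passed).
#' @param paradigm a \code{task_paradigm}.
#' @param trim fraction of task-window samples trimmed at each end.
#' @return \code{plv_matrix} object: list with \code{plv} (channels x
#'   channels), \code{subject_id}, \code{group}.
#' @export
plv_matrix <- function(hemo, paradigm = task_paradigm(), trim = 0.1) {
  n_ch <- nrow(hemo$hbo2)
  phases <- t(apply(hemo$hbo2, 1, instantaneous_phase))
  win <- task_window_samples(paradigm) + 1L
  k <- floor(length(win) * trim)
  win <- win[(k + 1):(length(win) - k)]
  u <- exp(1i * phases[, win, drop = FALSE])
  m <- Mod(u %*% Conj(t(u))) / length(win)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  out <- list(plv = m, subject_id = hemo$subject_id, group = hemo$group)
  class(out) <- "plv_matrix"
  out
}

#' Indices of the unique off-diagonal channel pairs
#' @param n_ch channel count.
#' @return data.frame with \code{ch_i < ch_j} rows.
#' @export
channel_pairs <- function(n_ch = 40L) {
  p <- utils::combn(n_ch, 2)
  data.frame(ch_i = p[1, ], ch_j = p[2, ])
}

#' Flatten subjects' PLV matrices to a subjects x pairs matrix
#' @param plvs list of \code{plv_matrix}.
#' @return matrix with attributes \code{"groups"} and \code{"pairs"}.
#' @export
plv_pair_matrix <- function(plvs) {
  n_ch <- nrow(plvs[[1]]$plv)
  pairs <- channel_pairs(n_ch)
  idx <- cbind(pairs$ch_i, pairs$ch_j)
  y <- t(vapply(plvs, function(p) p$plv[idx], numeric(nrow(pairs))))
  attr(y, "groups") <- vapply(plvs, function(p) p$group, character(1))
  attr(y, "pairs") <- pairs
  y
}

#' Pair-wise three-group comparison of PLV with FDR over all pairs
#'
#' One-way ANOVA per channel pair across groups, BH-corrected over the
#' full pair family (780 pairs for 40 channels); Welch post hoc contrasts
#' for surviving pairs, corrected within pair.
#'
#' @param plvs list of per-subject \code{plv_matrix} objects.
#' @param alpha FDR level.
#' @return list with \code{omnibus} (\code{ch_i, ch_j, F, p, q,
#'   significant}) and \code{posthoc} data.frames.
#' @export
pairwise_group_compare <- function(plvs, alpha = 0.05) {
  y <- plv_pair_matrix(plvs)
  groups <- attr(y, "groups")
  if (min(table(groups)) < 2) stop("need >= 2 subjects per group")
  pairs <- attr(y, "pairs")
  a <- anova_oneway_matrix(y, groups)
  om <- data.frame(ch_i = pairs$ch_i, ch_j = pairs$ch_j, F = a$F, p = a$p)
  om$q <- stats::p.adjust(om$p, method = "BH")
  om$significant <- om$q < alpha
  ph <- list()
  gl <- unique(groups)
  gp <- utils::combn(gl, 2)
  for (i in which(om$significant)) {
    v <- y[, i]
    rows <- lapply(seq_len(ncol(gp)), function(j) {
      tt <- stats::t.test(v[groups == gp[1, j]], v[groups == gp[2, j]])
      data.frame(ch_i = om$ch_i[i], ch_j = om$ch_j[i],
                 group_a = gp[1, j], group_b = gp[2, j],
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$q <- stats::p.adjust(d$p, method = "BH")
    ph[[length(ph) + 1]] <- d
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else
    data.frame(ch_i = integer(), ch_j = integer(), group_a = character(),
               group_b = character(), t = numeric(), p = numeric(),
               q = numeric())
  rownames(posthoc) <- NULL
  list(omnibus = om, posthoc = posthoc)
}
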