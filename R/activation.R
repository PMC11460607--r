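#' Canonical double-gamma hemodynamic response function
#'
#' The standard SPM-style double-gamma impulse response: a positive gamma
#' density peaking at \code{peak} s minus an undershoot gamma peaking at
#' \code{undershoot} s scaled by \code{ratio}.
#'
#' @param t time points, s.
#' @param peak time-to-peak of the positive lobe, s.
#' @param undershoot time-to-peak of the undershoot, s.
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector, the HRF sampled at \code{t}.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1/6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h
}

#' Build the GLM design matrix for the block paradigm
#'
#' Columns: the task regressor (boxcar over the task blocks convolved
#' with the canonical HRF, normalised to unit peak), an intercept, and
#' (optionally) a centred linear drift.  With \code{blocks = "separate"}
#' each 15 s block gets its own regressor.  An \code{hrf = "impulse"}
#' setting skips the convolution, leaving the raw boxcar.  If
#' \code{filter} is supplied, it is applied to the task column(s) so that
#' data and design are seen through the same band-pass (the intercept and
#' drift stay unfiltered).
#'
#' @param paradigm a \code{task_paradigm}.
#' @param hrf \code{"canonical"}, \code{"impulse"}, or a numeric kernel
#'   sampled at the paradigm rate.
#' @param drift include a linear drift column.
#' @param blocks \code{"single"} (one regressor over the whole 60 s task)
#'   or \code{"separate"} (one per block).
#' @param hrf_peak,hrf_undershoot,hrf_ratio canonical-HRF parameters.
#' @param filter optional function applied to the task column(s), e.g.
#'   \code{function(x) bandpass_filter(x, ...)}.
#' @return matrix with named columns; attribute \code{"task_cols"} gives
#'   the task-column indices.
#' @export
build_design <- function(paradigm = task_paradigm(), hrf = "canonical",
                         drift = TRUE, blocks = c("single", "separate"),
                         hrf_peak = 6, hrf_undershoot = 16,
                         hrf_ratio = 1/6, filter = NULL) {
  blocks <- match.arg(blocks)
  fs <- paradigm$fs
  n <- paradigm$n_samples
  tt <- (seq_len(n) - 1) / fs
  kern <- if (is.numeric(hrf)) {
    hrf
  } else if (identical(hrf, "impulse")) {
    1
  } else {
    canonical_hrf(seq(0, 30, by = 1 / fs), hrf_peak, hrf_undershoot,
                  hrf_ratio)
  }
  mk_reg <- function(onset, dur) {
    box <- as.numeric(tt >= onset & tt < onset + dur)
    r <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)]
    if (max(abs(r)) > 0 && !identical(hrf, "impulse"))
      r <- r / max(r)
    r
  }
  if (blocks == "single") {
    task <- mk_reg(paradigm$task_start,
                   paradigm$task_end - paradigm$task_start)
    taskm <- matrix(task, ncol = 1,
                    dimnames = list(NULL, "task"))
  } else {
    onsets <- paradigm$block_onsets
    durs <- paradigm$task_blocks
    taskm <- sapply(seq_along(onsets),
                    function(i) mk_reg(onsets[i], durs[i]))
    colnames(taskm) <- paste0("task_block", seq_along(onsets))
  }
  if (!is.null(filter)) taskm <- apply(taskm, 2, filter)
  x <- cbind(taskm, intercept = 1)
  if (drift) x <- cbind(x, drift = scale(tt, scale = FALSE)[, 1])
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  attr(x, "task_cols") <- seq_len(ncol(taskm))
  x
}

#' Ordinary least squares GLM fit for one channel
#'
#' Fits \code{y = X b + e} by OLS and reports the task-regressor
#' coefficient (the activation beta), its standard error, and the
#' residual variance.  Optional AR(1) prewhitening estimates the lag-1
#' residual autocorrelation and refits on quasi-differenced data
#' (Cochrane-Orcutt).
#'
#' @param y numeric response (one channel's \eqn{\Delta HbO_2}).
#' @param x design matrix from \code{\link{build_design}}.
#' @param prewhiten logical; AR(1) prewhitening.
#' @return list with \code{beta} (task coefficient; sum over task columns
#'   when blocks are separate), \code{coef} (all coefficients),
#'   \code{se}, \code{sigma2}, \code{rho}, \code{df}.
#' @export
fit_glm <- function(y, x, prewhiten = FALSE) {
  if (length(y) != nrow(x))
    stop("series length (", length(y), ") != design rows (", nrow(x), ")")
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("singular normal equations")
  rho <- 0
  if (prewhiten) {
    res0 <- qr.resid(qx, y)
    rho <- sum(res0[-1] * res0[-length(res0)]) / sum(res0^2)
    rho <- max(min(rho, 0.99), -0.99)
    n <- length(y)
    y <- y[-1] - rho * y[-n]
    x <- x[-1, , drop = FALSE] - rho * x[-n, , drop = FALSE]
    qx <- qr(x)
  }
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- nrow(x) - ncol(x)
  sigma2 <- sum(res^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtxinv) * sigma2)
  names(se) <- colnames(x)
  tc <- attr(x, "task_cols")
  if (is.null(tc)) tc <- 1L
  list(beta = sum(coefs[tc]) / length(tc), coef = coefs, se = se,
       sigma2 = sigma2, rho = rho, df = df)
}

#' Per-channel GLM betas for a set of preprocessed subjects
#'
#' @param hemos list of \code{hemoglobin_series}.
#' @param design design matrix (shared across subjects).
#' @param prewhiten passed to \code{\link{fit_glm}}.
#' @return a beta table: data.frame with \code{subject_id}, \code{group},
#'   \code{channel_id}, \code{beta}.
#' @export
beta_table <- function(hemos, design, prewhiten = FALSE) {
  rows <- lapply(hemos, function(h) {
    betas <- apply(h$hbo2, 1, function(y) fit_glm(y, design,
                                                  prewhiten)$beta)
    data.frame(subject_id = h$subject_id, group = h$group,
               channel_id = seq_len(nrow(h$hbo2)), beta = betas,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-sample t test of channel betas against zero, per group
#'
#' @param betas a beta table (see \code{\link{beta_table}}).
#' @return data.frame with \code{group}, \code{channel_id}, \code{n},
#'   \code{mean_beta}, \code{t}, \code{p} (two-sided, df = n-1).
#' @export
group_one_sample_t <- function(betas) {
  out <- do.call(rbind, lapply(split(betas, betas[c("group", "channel_id")],
                                     drop = TRUE), function(d) {
    n <- nrow(d)
    if (n < 2) stop("need at least 2 subjects per group")
    s <- stats::sd(d$beta)
    if (s == 0) stop("zero variance in channel ", d$channel_id[1],
                     " group ", d$group[1])
    tv <- mean(d$beta) / (s / sqrt(n))
    data.frame(group = d$group[1], channel_id = d$channel_id[1], n = n,
               mean_beta = mean(d$beta), t = tv,
               p = 2 * stats::pt(-abs(tv), n - 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$channel_id), ]
}

#' Vectorised one-way ANOVA across many features
#'
#' One-way fixed-effects ANOVA computed column-wise on a subjects x
#' features matrix: the workhorse behind channel-wise and pair-wise group
#' comparison.
#'
#' @param y numeric matrix, subjects in rows, features in columns.
#' @param groups factor/character of length \code{nrow(y)}.
#' @return data.frame with \code{F}, \code{p}, \code{df1}, \code{df2}
#'   per feature.
#' @export
anova_oneway_matrix <- function(y, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- nrow(y)
  if (k < 2) stop("need at least 2 groups")
  ns <- as.vector(table(groups))
  gm <- rowsum(y, groups) / ns
  grand <- colMeans(y)
  ssb <- colSums(ns * (gm - matrix(grand, k, ncol(y), byrow = TRUE))^2)
  sst <- colSums((y - matrix(grand, n, ncol(y), byrow = TRUE))^2)
  ssw <- sst - ssb
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  data.frame(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
             df1 = df1, df2 = df2)
}

#' Channel-wise three-group ANOVA with FDR and post hoc contrasts
#'
#' Per channel: omnibus one-way ANOVA of betas across groups with
#' Benjamini-Hochberg correction over the channel family; Welch pairwise
#' t tests are run for channels whose omnibus survives FDR, corrected
#' within channel over the pairwise family.
#'
#' @param betas a beta table.
#' @param alpha FDR level.
#' @return list with \code{omnibus} (data.frame: \code{channel_id},
#'   \code{F}, \code{p}, \code{q}, \code{significant}) and \code{posthoc}
#'   (data.frame: \code{channel_id}, \code{group_a}, \code{group_b},
#'   \code{t}, \code{p}, \code{q}).
#' @export
channel_anova <- function(betas, alpha = 0.05) {
  wide <- beta_matrix(betas)
  groups <- attr(wide, "groups")
  if (nlevels(factor(groups)) < 2) stop("need >= 2 groups")
  om <- anova_oneway_matrix(wide, groups)
  om <- data.frame(channel_id = as.integer(colnames(wide)), F = om$F,
                   p = om$p)
  om$q <- stats::p.adjust(om$p, method = "BH")
  om$significant <- om$q < alpha
  ph <- list()
  gl <- unique(groups)
  pairs <- utils::combn(gl, 2)
  for (ch in om$channel_id[om$significant]) {
    v <- wide[, as.character(ch)]
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- v[groups == pairs[1, j]]
      b <- v[groups == pairs[2, j]]
      tt <- stats::t.test(a, b)
      data.frame(channel_id = ch, group_a = pairs[1, j],
                 group_b = pairs[2, j], t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$q <- stats::p.adjust(d$p, method = "BH")
    ph[[as.character(ch)]] <- d
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else
    data.frame(channel_id = integer(), group_a = character(),
               group_b = character(), t = numeric(), p = numeric(),
               q = numeric())
  rownames(posthoc) <- NULL
  list(omnibus = om, posthoc = posthoc)
}

#' Reshape a beta table to a subjects x channels matrix
#' @param betas a beta table.
#' @return matrix with attribute \code{"groups"} (one label per row).
#' @export
beta_matrix <- function(betas) {
  subj <- unique(betas$subject_id)
  chs <- sort(unique(betas$channel_id))
  m <- matrix(NA_real_, length(subj), length(chs),
              dimnames = list(subj, chs))
  m[cbind(match(betas$subject_id, subj),
          match(betas$channel_id, chs))] <- betas$beta
  if (anyNA(m)) stop("beta table is not a complete subject x channel grid")
  attr(m, "groups") <- betas$group[match(subj, betas$subject_id)]
  m
}

#' Mean channel t statistic per ROI and group
#'
#' @param channel_t output of \code{\link{group_one_sample_t}}.
#' @param layout a \code{probe_layout} carrying the channel-to-ROI map.
#' @return data.frame with \code{group}, \code{roi}, \code{mean_t},
#'   \code{n_channels}.
#' @export
roi_summary <- function(channel_t, layout = probe_layout()) {
  roi <- layout$channels$roi[match(channel_t$channel_id,
                                   layout$channels$channel_id)]
  if (anyNA(roi)) stop("ROI map does not cover all channels")
  agg <- stats::aggregate(channel_t$t,
                          by = list(group = channel_t$group, roi = roi),
                          FUN = mean)
  cnt <- stats::aggregate(channel_t$t,
                          by = list(group = channel_t$group, roi = roi),
                          FUN = length)
  data.frame(group = agg$group, roi = agg$roi, mean_t = agg$x,
             n_channels = cnt$x, stringsAsFactors = FALSE)
}
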