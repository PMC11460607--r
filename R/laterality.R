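#' Laterality index
#'
#' \eqn{LI = (L - R) / (L + R)} of the mean task-window \eqn{\Delta
#' HbO_2} of left vs right channels.  Concentration changes can be
#' negative, so the index is only reported when the denominator is
#' positive and above a floor \code{eps}: records with \eqn{L + R \le
#' \epsilon} are returned as \code{NA} (undefined) rather than a
#' sign-flipped index, and excluded from group statistics.
#'
#' @param l,r mean left / right concentrations, umol/L.
#' @param eps smallest admissible denominator.
#' @return LI in \[-1, 1\] when both inputs are positive; \code{NA} when
#'   undefined.
#' @export
laterality_index <- function(l, r, eps = 1e-3) {
  den <- l + r
  ifelse(is.finite(den) & den > eps, (l - r) / den, NA_real_)
}

#' Classify a laterality index
#'
#' \code{LI >= 0.1}: left-lateralized; \code{LI <= -0.1}: right;
#' in between: symmetric; \code{NA}: undefined.
#'
#' @param li numeric LI value(s).
#' @param threshold classification threshold.
#' @return character vector: "left", "right", "symmetric" or "undefined".
#' @export
classify_li <- function(li, threshold = 0.1) {
  ifelse(!is.finite(li), "undefined",
         ifelse(li >= threshold, "left",
                ifelse(li <= -threshold, "right", "symmetric")))
}

#' Per-subject laterality records over prefrontal and motor regions
#'
#' For each region (prefrontal = DLPFC/Broca/FPA/OA channels, motor = the
#' rest), averages the band-passed task-window \eqn{\Delta HbO_2} over
#' left and right channels and computes LI and its classification.
#'
#' @param hemo a \code{hemoglobin_series}.
#' @param layout a \code{probe_layout}.
#' @param paradigm a \code{task_paradigm}.
#' @param eps denominator floor for \code{\link{laterality_index}}.
#' @param threshold classification threshold.
#' @return data.frame with \code{subject_id}, \code{group},
#'   \code{region}, \code{L_hbo2}, \code{R_hbo2}, \code{LI},
#'   \code{classification}.
#' @export
laterality_records <- function(hemo, layout = probe_layout(),
                               paradigm = task_paradigm(), eps = 1e-3,
                               threshold = 0.1) {
  win <- extract_task_window(hemo$hbo2, paradigm)
  region <- roi_region(layout$channels$roi)
  hemi <- layout$channels$hemisphere
  rows <- lapply(c("prefrontal", "motor"), function(rg) {
    lmean <- mean(win[region == rg & hemi == "left", , drop = FALSE])
    rmean <- mean(win[region == rg & hemi == "right", , drop = FALSE])
    li <- laterality_index(lmean, rmean, eps)
    data.frame(subject_id = hemo$subject_id, group = hemo$group,
               region = rg, L_hbo2 = lmean, R_hbo2 = rmean, LI = li,
               classification = classify_li(li, threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lateralization-class proportions per group and region
#'
#' Proportions of left / right / symmetric classifications among the
#' classified (defined-LI) subjects; undefined records are excluded and
#' counted separately.
#'
#' @param records row-bound \code{\link{laterality_records}} of a cohort.
#' @return data.frame with \code{group}, \code{region}, \code{left},
#'   \code{right}, \code{symmetric}, \code{n_classified},
#'   \code{n_undefined}.
#' @export
lateralization_ratio <- function(records) {
  out <- do.call(rbind, lapply(
    split(records, records[c("group", "region")], drop = TRUE),
    function(d) {
      cls <- d$classification
      def <- cls != "undefined"
      if (!any(def)) stop("all LI undefined in group ", d$group[1],
                          " region ", d$region[1])
      n <- sum(def)
      data.frame(group = d$group[1], region = d$region[1],
                 left = sum(cls == "left") / n,
                 right = sum(cls == "right") / n,
                 symmetric = sum(cls == "symmetric") / n,
                 n_classified = n, n_undefined = sum(!def),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Group comparison of laterality indices per region
#'
#' One-way ANOVA of the defined LIs across groups within each region,
#' with BH correction over the region family and Welch post hoc
#' contrasts (corrected within region) where the omnibus survives.
#'
#' @param records cohort laterality records.
#' @param alpha FDR level.
#' @return list with \code{omnibus} and \code{posthoc} data.frames.
#' @export
group_li_compare <- function(records, alpha = 0.05) {
  records <- records[is.finite(records$LI), ]
  regions <- unique(records$region)
  om <- do.call(rbind, lapply(regions, function(rg) {
    d <- records[records$region == rg, ]
    if (length(unique(d$group)) < 2 || min(table(d$group)) < 2)
      stop("need >= 2 groups with >= 2 defined LIs in region ", rg)
    a <- anova_oneway_matrix(matrix(d$LI, ncol = 1), d$group)
    data.frame(region = rg, F = a$F, p = a$p, stringsAsFactors = FALSE)
  }))
  om$q <- stats::p.adjust(om$p, method = "BH")
  om$significant <- om$q < alpha
  ph <- list()
  for (rg in om$region[om$significant]) {
    d <- records[records$region == rg, ]
    pairs <- utils::combn(unique(d$group), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      tt <- stats::t.test(d$LI[d$group == pairs[1, j]],
                          d$LI[d$group == pairs[2, j]])
      data.frame(region = rg, group_a = pairs[1, j],
                 group_b = pairs[2, j], t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    dd <- do.call(rbind, rows)
    dd$q <- stats::p.adjust(dd$p, method = "BH")
    ph[[rg]] <- dd
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else
    data.frame(region = character(), group_a = character(),
               group_b = character(), t = numeric(), p = numeric(),
               q = numeric())
  rownames(posthoc) <- NULL
  list(omnibus = om, posthoc = posthoc)
}
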