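# Test-retest reproducibility analytics: CSF masking, scaled-MAD outlier
# rejection, Bland-Altman limits of agreement, between/within-subject
# coefficients of variation (ROI and voxel-wise), sample-size
# estimation, and SNR maps.

#' CSF exclusion mask from the 0 Hz MD map
#'
#' Voxels with MD(0 Hz) strictly greater than the threshold are excluded
#' from all scalar-map analyses (partial-volume mitigation); the mask is
#' TRUE where a voxel is kept.
#'
#' @param md0_map MD map at f = 0, um^2/ms.
#' @param threshold exclusion threshold, um^2/ms (default 0.9).
#' @return logical array, TRUE = retained.
#' @export
csf_mask <- function(md0_map, threshold = 0.9) {
  m <- !(md0_map > threshold)
  m[is.na(md0_map)] <- FALSE
  m
}

#' Scaled-MAD outlier removal
#'
#' Removes values more than `k` scaled median absolute deviations
#' (MAD x 1.4826, a consistent estimate of the SD under normality) from
#' the median. A zero MAD with any deviating point removes all deviating
#' points (degenerate case, warned).
#'
#' @param values numeric vector (NAs are ignored and never removed by the
#'   rule).
#' @param k threshold in scaled MADs (default 3).
#' @return list with `kept` (values), `removed` (indices into `values`)
#'   and `keep` (logical vector).
#' @export
remove_outliers <- function(values, k = 3) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 finite values")
  med <- stats::median(values[ok])
  smad <- stats::mad(values[ok])  # constant = 1.4826 by default
  dev <- abs(values - med)
  if (smad == 0) {
    out <- ok & dev > 0
    if (any(out)) warning("zero MAD: all deviating points removed")
  } else {
    out <- ok & dev > k * smad
  }
  keep <- ok & !out
  list(kept = values[keep], removed = which(out), keep = keep)
}

#' Bland-Altman analysis of paired sessions
#'
#' diffs = test - retest; bias = mean(diffs); limits of agreement =
#' bias +/- 1.96 SD(diffs) (sample SD).
#'
#' @param test,retest paired numeric vectors.
#' @return list with `bias`, `loa_low`, `loa_high`, `means`, `diffs`.
#' @export
bland_altman <- function(test, retest) {
  ok <- is.finite(test) & is.finite(retest)
  if (sum(ok) < 2L) stop("Bland-Altman needs at least 2 finite pairs")
  d <- test[ok] - retest[ok]
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       means = (test[ok] + retest[ok]) / 2, diffs = d)
}

#' Between-subject coefficient of variation
#'
#' CV = 100 x SD / mean across subjects, computed separately within the
#' test and retest sessions, then averaged.
#'
#' @param test,retest per-subject values for the two sessions.
#' @return percent CV.
#' @export
cv_between <- function(test, retest) {
  one <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m <= 0) stop("undefined CV: non-positive mean")
    100 * stats::sd(x) / m
  }
  mean(c(one(test), one(retest)))
}

#' Within-subject coefficient of variation
#'
#' Per subject, CV = 100 x SD(test, retest) / mean(test, retest) with the
#' two-point sample SD |test - retest| / sqrt(2); averaged over subjects.
#' Subjects missing a session are dropped.
#'
#' @param test,retest per-subject values for the two sessions.
#' @return percent CV.
#' @export
cv_within <- function(test, retest) {
  ok <- is.finite(test) & is.finite(retest)
  if (!any(ok)) return(NA_real_)
  m <- (test[ok] + retest[ok]) / 2
  if (any(m <= 0)) stop("undefined CV: non-positive subject mean")
  s <- abs(test[ok] - retest[ok]) / sqrt(2)
  mean(100 * s / m)
}

#' Voxel-wise between/within-subject CV maps
#'
#' Applies the CV definitions per voxel across a cohort's maps, with
#' voxel-wise scaled-MAD outlier removal (per session for the between
#' map; on subject means for the within map) and optional masking.
#'
#' @param test,retest lists of per-subject 3D metric maps (equal grids).
#' @param mask optional logical array; masked-out voxels are NaN.
#' @param mad_k scaled-MAD threshold; `Inf` disables outlier removal.
#' @return list with `between` and `within` CV maps (percent).
#' @export
voxelwise_cv <- function(test, retest, mask = NULL, mad_k = 3) {
  Tm <- vapply(test, as.numeric, numeric(length(test[[1]])))     # vox x subj
  Rm <- vapply(retest, as.numeric, numeric(length(retest[[1]])))
  dims <- dim(test[[1]])
  nvox <- nrow(Tm)
  btw <- wth <- rep(NaN, nvox)
  keep <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  drop_out <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L || !is.finite(mad_k)) return(x)
    med <- stats::median(x); smad <- stats::mad(x)
    if (smad == 0) x[abs(x - med) == 0] else x[abs(x - med) <= mad_k * smad]
  }
  cv_of <- function(x) {
    x <- drop_out(x)
    if (length(x) < 2L || mean(x) == 0) return(NaN)
    100 * stats::sd(x) / mean(x)
  }
  for (v in which(keep)) {
    btw[v] <- mean(c(cv_of(Tm[v, ]), cv_of(Rm[v, ])))
    pm <- (Tm[v, ] + Rm[v, ]) / 2
    ps <- abs(Tm[v, ] - Rm[v, ]) / sqrt(2)
    ok <- is.finite(pm) & pm != 0
    keep_s <- drop_out(pm)
    ok <- ok & pm %in% keep_s
    wth[v] <- if (any(ok)) mean(100 * ps[ok] / pm[ok]) else NaN
  }
  list(between = array(btw, dims), within = array(wth, dims))
}

z_alpha <- function(p) stats::qnorm(p)

#' Sample size per group from a between-subject CV
#'
#' Normal-approximation two-group formula
#' n = ceil(2 (z_{1-alpha/2} + z_{1-beta})^2 (CV / delta)^2); at CV =
#' delta and the default alpha/power the coefficient is 15.7, i.e. the
#' van Belle "16" rule of thumb.
#'
#' @param cv between-subject CV as a fraction (e.g. 0.10).
#' @param delta detectable effect size as a fraction of the mean.
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @return integer sample size per group (floored at 2).
#' @export
sample_size_between <- function(cv, delta, alpha = 0.05, power = 0.80) {
  if (delta <= 0) stop("delta must be > 0")
  if (cv <= 0) stop("cv must be > 0")
  n <- ceiling(2 * (z_alpha(1 - alpha / 2) + z_alpha(power))^2 *
                 (cv / delta)^2)
  max(2L, as.integer(n))
}

#' Sample size for a paired (within-subject) design
#'
#' Normal approximation to the paired t-test:
#' n = ceil((z_{1-alpha/2} + z_{1-beta})^2 sd_diff^2 /
#' (delta * mean_value)^2).
#'
#' @param sd_diff SD of the test-retest differences across subjects.
#' @param mean_value mean metric value (sets the effect scale).
#' @param delta detectable effect size as a fraction of `mean_value`.
#' @param alpha,power as in [sample_size_between()].
#' @return integer sample size (floored at 2).
#' @export
sample_size_within <- function(sd_diff, mean_value, delta,
                               alpha = 0.05, power = 0.80) {
  if (delta <= 0) stop("delta must be > 0")
  if (sd_diff < 0 || mean_value <= 0) stop("invalid sd_diff / mean_value")
  n <- ceiling((z_alpha(1 - alpha / 2) + z_alpha(power))^2 * sd_diff^2 /
                 (delta * mean_value)^2)
  max(2L, as.integer(n))
}

#' SNR map from complex multi-average data
#'
#' SNR = powder-averaged magnitude of the combined averages divided by
#' the combined noise level: sigma is estimated separately from the real
#' and imaginary background of a single average of a single direction,
#' averaged over the two channels, and divided by
#' sqrt(n_averages * n_directions).
#'
#' @param complex_data 5D complex array (x, y, z, direction, average).
#' @param background_mask logical 3D array marking signal-free voxels.
#' @return list with the 3D `snr` map, `sigma_single` (per-channel sigma
#'   of one average/direction) and `sigma_combined`.
#' @export
snr_map <- function(complex_data, background_mask) {
  d <- dim(complex_data)
  stopifnot(length(d) == 5)
  if (!any(background_mask)) stop("background mask is empty")
  one <- complex_data[, , , 1, 1]
  bg <- which(as.logical(background_mask))
  sigma_single <- (stats::sd(Re(one)[bg]) + stats::sd(Im(one)[bg])) / 2
  n_dir <- d[4]; n_avg <- d[5]
  sigma_combined <- sigma_single / sqrt(n_avg * n_dir)
  combined <- apply(complex_data, 1:4, mean)        # average over averages
  mag <- Mod(combined)
  powder <- apply(mag, 1:3, mean)                   # average over directions
  list(snr = powder / sigma_combined,
       sigma_single = sigma_single, sigma_combined = sigma_combined)
}

# One-voxel 6-connectivity binary erosion of a 3D mask.
erode6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (ax in 1:3) {
    if (d[ax] == 1L) next  # single-slice axis: no erosion along it
    out <- out & shift(mask, ax, 1) & shift(mask, ax, -1)
  }
  out
}

#' Per-ROI means with one-voxel erosion
#'
#' Each ROI mask is eroded by one voxel (6-connectivity, skipping any
#' axis of thickness 1), except for labels named in `exempt` (the corpus
#' callosum in the study, to preserve its thin geometry), then
#' intersected with `mask` before averaging.
#'
#' @param metric_map 3D metric array.
#' @param labels integer label array.
#' @param roi_names named integer vector of label values.
#' @param mask optional logical array (e.g. CSF mask).
#' @param exempt character vector of ROI names exempt from erosion.
#' @param erode whether to erode at all.
#' @return data.frame with `roi`, `n_voxels`, `mean`; ROIs empty after
#'   erosion/masking are reported with `n_voxels = 0` and `mean = NA`.
#' @export
roi_means <- function(metric_map, labels, roi_names, mask = NULL,
                      exempt = "CC", erode = TRUE) {
  keep <- if (is.null(mask)) array(TRUE, dim(labels)) else mask
  out <- NULL
  for (nm in names(roi_names)) {
    m <- labels == roi_names[[nm]]
    if (erode && !(nm %in% exempt)) m <- erode6(m)
    m <- m & keep & is.finite(metric_map)
    n <- sum(m)
    out <- rbind(out, data.frame(
      roi = nm, n_voxels = n,
      mean = if (n > 0) mean(metric_map[m]) else NA_real_))
  }
  out
}

#' Reproducibility report for one metric's test-retest table
#'
#' Applies animal-wise scaled-MAD outlier removal per ROI, then
#' Bland-Altman, between/within CVs and sample sizes over a grid of
#' effect sizes.
#'
#' @param table data.frame with columns `subject`, `session` (`"test"` /
#'   `"retest"`), `roi`, `value`.
#' @param effect_sizes fractions of the mean to power for.
#' @param alpha,power significance level and power.
#' @param mad_k scaled-MAD threshold for animal-wise outlier removal;
#'   `Inf` disables.
#' @return data.frame with one row per ROI: Bland-Altman bias and limits,
#'   percent CVs, outlier count and sample sizes `n_between_<pct>` /
#'   `n_within_<pct>`.
#' @export
repro_report <- function(table, effect_sizes = c(0.04, 0.06, 0.08, 0.10, 0.12),
                         alpha = 0.05, power = 0.80, mad_k = 3) {
  stopifnot(all(c("subject", "session", "roi", "value") %in% names(table)))
  out <- NULL
  for (r in unique(table$roi)) {
    tt <- table[table$roi == r & table$session == "test", ]
    rr <- table[table$roi == r & table$session == "retest", ]
    subj <- intersect(tt$subject, rr$subject)
    x <- tt$value[match(subj, tt$subject)]
    y <- rr$value[match(subj, rr$subject)]
    n_out <- 0L
    if (is.finite(mad_k) && length(subj) >= 3L) {
      kx <- remove_outliers(x, mad_k)$keep
      ky <- remove_outliers(y, mad_k)$keep
      keep <- kx & ky
      n_out <- sum(!keep)
      x <- x[keep]; y <- y[keep]
    }
    ba <- bland_altman(x, y)
    cvb <- cv_between(x, y) / 100
    cvw <- cv_within(x, y)
    sdd <- stats::sd(x - y)
    mv <- mean(c(x, y))
    row <- data.frame(roi = r, n_subjects = length(x),
                      n_outliers_removed = n_out,
                      bias = ba$bias, loa_low = ba$loa_low,
                      loa_high = ba$loa_high,
                      cv_between = 100 * cvb, cv_within = cvw)
    for (d in effect_sizes) {
      # degenerate (zero-variability) tables floor at the minimum n
      row[[sprintf("n_between_%g", 100 * d)]] <-
        if (cvb > 0) sample_size_between(cvb, d, alpha, power) else 2L
      row[[sprintf("n_within_%g", 100 * d)]] <-
        sample_size_within(sdd, mv, d, alpha, power)
    }
    out <- rbind(out, row)
  }
  out
}
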