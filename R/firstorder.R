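#' First-order (histogram) features
#'
#' 46 statistics of the in-mask intensity distribution. The first 27 are
#' computed on raw intensities; the remaining 19 on the discretized gray
#' levels (prefix `hist_`). Moments use n-denominators. Statistics whose
#' formula divides by zero on a constant ROI (coefficient of variation,
#' skewness, kurtosis, ...) are returned as `NA` ("undefined"), never as
#' an arbitrary number.
#'
#' @param volume a `VolumeWithMask` with >= 10 in-mask voxels.
#' @param disc the matching `DiscretizedROI` (for the `hist_*` block).
#' @return named numeric vector of length 46.
#' @export
firstorder_features <- function(volume, disc) {
  stopifnot(inherits(volume, "VolumeWithMask"),
            inherits(disc, "DiscretizedROI"))
  check_min_roi(volume$mask)
  x <- volume$intensities[volume$mask != 0]
  n <- length(x)
  qs <- stats::quantile(x, c(.05, .10, .25, .50, .75, .90, .95),
                        names = FALSE, type = 7)
  m <- mean(x)
  m2 <- mean((x - m)^2)                     # n-denominator variance
  sdev <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else NA_real_
  robust <- x[x >= qs[2] & x <= qs[6]]      # values within [p10, p90]
  voxvol <- prod(volume$spacing)
  raw <- c(
    mean = m, median = qs[4], minimum = min(x), maximum = max(x),
    range = max(x) - min(x),
    percentile05 = qs[1], percentile10 = qs[2], percentile25 = qs[3],
    percentile75 = qs[5], percentile90 = qs[6], percentile95 = qs[7],
    interquartile_range = qs[5] - qs[3], decile_range = qs[6] - qs[2],
    variance = m2, standard_deviation = sdev,
    coeff_variation = if (m != 0) sdev / m else NA_real_,
    skewness = skew, kurtosis = kurt,
    mean_absolute_deviation = mean(abs(x - m)),
    robust_mean_absolute_deviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else NA_real_,
    median_absolute_deviation = stats::median(abs(x - qs[4])),
    root_mean_square = sqrt(mean(x^2)),
    energy = sum(x^2), total_energy = sum(x^2) * voxvol, sum = sum(x),
    quartile_dispersion =
      if ((qs[5] + qs[3]) != 0) (qs[5] - qs[3]) / (qs[5] + qs[3])
      else NA_real_,
    mid_range = (min(x) + max(x)) / 2
  )
  lev <- disc$levels[disc$mask != 0]
  p <- tabulate(lev, nbins = disc$ng) / length(lev)
  occ <- p > 0
  hq <- stats::quantile(lev, c(.10, .25, .50, .75, .90), names = FALSE,
                        type = 7)
  hm <- mean(lev)
  hm2 <- mean((lev - hm)^2)
  hist <- c(
    hist_mean = hm, hist_median = hq[3],
    hist_mode = which.max(p),
    hist_variance = hm2, hist_sd = sqrt(hm2),
    hist_skewness = if (hm2 > 0) mean((lev - hm)^3) / hm2^1.5 else NA_real_,
    hist_kurtosis = if (hm2 > 0) mean((lev - hm)^4) / hm2^2 else NA_real_,
    hist_entropy = -sum(p[occ] * log2(p[occ])),
    hist_uniformity = sum(p^2),
    hist_p10 = hq[1], hist_p25 = hq[2], hist_p75 = hq[4], hist_p90 = hq[5],
    hist_iqr = hq[4] - hq[2],
    hist_range = max(lev) - min(lev),
    hist_mean_absolute_deviation = mean(abs(lev - hm)),
    hist_cv = if (hm != 0) sqrt(hm2) / hm else NA_real_,
    hist_max_probability = max(p),
    hist_occupied_levels = sum(occ)
  )
  out <- c(raw, hist)
  stopifnot(length(out) == 46L)
  names(out) <- .firstorder_names
  out
}

# Minimum ROI size gate shared by the extraction entry points: texture
# matrices on fewer than 10 voxels are degenerate.
check_min_roi <- function(mask, min_voxels = 10L) {
  n <- sum(mask != 0)
  if (n < min_voxels) {
    stop("ROI too small for extraction: ", n, " voxel(s) < ",
         min_voxels, " (minimum ROI size)")
  }
  invisible(n)
}
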