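#' @title The 595-feature catalog
#' @description The extractor's feature registry: 46 first-order features,
#' 61 spatial-domain texture features (5 second-order co-occurrence
#' summaries, 22 GLCM, 11 GLRLM, 5 LBP, 13 GLSZM, 5 NGTDM) and 488
#' wavelet-domain texture features (the same 61 on each of 8 undecimated
#' wavelet subbands). 46 + 61 + 8 x 61 = 595.
#' @name feature-catalog
NULL

.firstorder_names <- c(
  # raw-intensity statistics
  "mean", "median", "minimum", "maximum", "range",
  "percentile05", "percentile10", "percentile25", "percentile75",
  "percentile90", "percentile95", "interquartile_range", "decile_range",
  "variance", "standard_deviation", "coeff_variation",
  "skewness", "kurtosis",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "root_mean_square",
  "energy", "total_energy", "sum", "quartile_dispersion", "mid_range",
  # binned-histogram statistics (on discretized levels)
  "hist_mean", "hist_median", "hist_mode", "hist_variance", "hist_sd",
  "hist_skewness", "hist_kurtosis", "hist_entropy", "hist_uniformity",
  "hist_p10", "hist_p25", "hist_p75", "hist_p90", "hist_iqr",
  "hist_range", "hist_mean_absolute_deviation", "hist_cv",
  "hist_max_probability", "hist_occupied_levels"
)

.secondorder_names <- c(
  "dissimilarity", "pair_average", "joint_maximum_complement",
  "difference_uniformity", "sum_uniformity"
)

.glcm_names <- c(
  "autocorrelation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "energy", "entropy",
  "homogeneity", "inverse_difference", "imc1", "imc2",
  "inverse_variance", "joint_average", "joint_variance",
  "maximum_probability", "sum_average", "sum_entropy", "sum_variance"
)

.glrlm_names <- c(
  "sre", "lre", "gln", "rln", "rp",
  "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge"
)

.lbp_names <- c(
  "hist_energy", "hist_entropy", "code_mean", "code_variance",
  "uniform_fraction"
)

.glszm_names <- c(
  "sae", "lae", "gln", "szn", "zp",
  "lgze", "hgze", "salge", "sahge", "lalge", "lahge",
  "gray_level_variance", "zone_size_variance"
)

.ngtdm_names <- c(
  "coarseness", "contrast", "busyness", "complexity", "strength"
)

.texture_families <- list(
  secondorder = .secondorder_names,
  glcm        = .glcm_names,
  glrlm       = .glrlm_names,
  lbp         = .lbp_names,
  glszm       = .glszm_names,
  ngtdm       = .ngtdm_names
)

.subband_names <- c("LL", "LH", "HL", "HH", "LL2", "LH2", "HL2", "HH2")

#' The ordered 595-entry feature catalog
#'
#' @return data frame with columns `name` (unique), `family` (firstorder,
#'   secondorder, glcm, glrlm, lbp, glszm, ngtdm) and `transform` ("none"
#'   or one of the 8 wavelet subband labels). Exactly 595 rows: 46
#'   first-order + 61 spatial texture + 8 x 61 wavelet texture.
#' @export
feature_catalog <- function() {
  rows <- list(
    data.frame(name = paste0("original_firstorder_", .firstorder_names),
               family = "firstorder", transform = "none",
               stringsAsFactors = FALSE)
  )
  for (fam in names(.texture_families)) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0("original_", fam, "_",
                               .texture_families[[fam]]),
                 family = fam, transform = "none",
                 stringsAsFactors = FALSE)
  }
  for (sb in .subband_names) {
    for (fam in names(.texture_families)) {
      rows[[length(rows) + 1L]] <-
        data.frame(name = paste0("wavelet_", sb, "_", fam, "_",
                                 .texture_families[[fam]]),
                   family = fam, transform = paste0("wavelet_", sb),
                   stringsAsFactors = FALSE)
    }
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(nrow(cat) == 595L, !anyDuplicated(cat$name))
  cat
}

#' Structural counts of the feature catalog
#'
#' @return named list with the total and the per-block counts used by the
#'   acceptance checks: 595 total, 46 first-order, 61 spatial-domain
#'   texture, 488 wavelet, and per-family spatial counts 5/22/11/5/13/5.
#' @export
catalog_counts <- function() {
  cat <- feature_catalog()
  spatial <- cat[cat$transform == "none", ]
  fam <- table(spatial$family)
  list(
    total = nrow(cat),
    firstorder = sum(spatial$family == "firstorder"),
    texture_spatial = sum(spatial$family != "firstorder"),
    wavelet = sum(cat$transform != "none"),
    per_family = c(secondorder = unname(fam[["secondorder"]]),
                   glcm = unname(fam[["glcm"]]),
                   glrlm = unname(fam[["glrlm"]]),
                   lbp = unname(fam[["lbp"]]),
                   glszm = unname(fam[["glszm"]]),
                   ngtdm = unname(fam[["ngtdm"]]))
  )
}

#' Write the catalog as a reference CSV
#'
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(path) {
  utils::write.csv(feature_catalog(), path, row.names = FALSE)
  invisible(path)
}
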