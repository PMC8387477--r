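#' The 61 texture features of one intensity field
#'
#' Shared by the spatial domain and every wavelet subband: discretizes the
#' in-mask intensities to `ng` levels and computes 5 second-order + 22
#' GLCM + 11 GLRLM + 5 LBP + 13 GLSZM + 5 NGTDM features, in catalog
#' order. Names carry the `<family>_<feature>` part only; callers add the
#' transform prefix. A failing family yields NA for its entries (with a
#' warning) rather than aborting the block.
#'
#' @param volume a `VolumeWithMask`.
#' @param ng gray-level count.
#' @return named numeric vector of length 61.
#' @export
texture_features_61 <- function(volume, ng = 32L) {
  disc <- discretize_fixed_bins(volume, ng = ng)
  run <- function(fam, fun) {
    res <- tryCatch(fun(), error = function(e) {
      warning(fam, " features failed: ", conditionMessage(e),
              call. = FALSE)
      stats::setNames(rep(NA_real_, length(.texture_families[[fam]])),
                      .texture_families[[fam]])
    })
    stats::setNames(res, paste0(fam, "_", names(res)))
  }
  m <- glcm_matrix(disc)
  out <- c(
    run("secondorder", function() secondorder_features(m)),
    run("glcm", function() glcm_features(m)),
    run("glrlm", function() glrlm_features(disc)),
    run("lbp", function() lbp_features(volume)),
    run("glszm", function() glszm_features(disc)),
    run("ngtdm", function() ngtdm_features(disc))
  )
  stopifnot(length(out) == 61L)
  out
}

#' Extract the full 595-feature vector
#'
#' Runs discretization, the 46 first-order features, the 61 spatial-domain
#' texture features and the 488 wavelet-subband texture features, aligned
#' to [feature_catalog()]. Undefined entries are carried as `NA`, never
#' silently zero. Deterministic: the same volume yields a bit-identical
#' vector.
#'
#' @param volume a `VolumeWithMask` with a mask of >= 10 voxels.
#' @param config configuration list; see [default_config()]. Uses
#'   `discretization$ng` and `wavelet$family`.
#' @return object of class `FeatureVector`: named numeric vector of length
#'   595 with attributes `provenance` (the volume's `meta`) and `n_voxels`.
#' @export
extract_all <- function(volume, config = default_config()) {
  stopifnot(inherits(volume, "VolumeWithMask"))
  if (is.null(volume$mask)) stop("extraction requires a mask")
  n_vox <- check_min_roi(volume$mask)
  ng <- config$discretization$ng
  disc <- discretize_fixed_bins(volume, ng = ng)
  fo <- tryCatch(firstorder_features(volume, disc), error = function(e) {
    warning("firstorder features failed: ", conditionMessage(e),
            call. = FALSE)
    stats::setNames(rep(NA_real_, 46L), .firstorder_names)
  })
  names(fo) <- paste0("original_firstorder_", names(fo))
  tex <- texture_features_61(volume, ng = ng)
  names(tex) <- paste0("original_", names(tex))
  sb <- wavelet_decompose(volume, family = config$wavelet$family)
  wv <- wavelet_feature_block(sb, volume$mask, volume$spacing, ng = ng)
  out <- c(fo, tex, wv)
  cat_names <- feature_catalog()$name
  stopifnot(identical(names(out), cat_names))
  structure(out, class = "FeatureVector",
            provenance = volume$meta, n_voxels = n_vox)
}

#' @export
print.FeatureVector <- function(x, ...) {
  cat("<FeatureVector> ", length(x), " features, ",
      sum(is.na(x)), " undefined\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("  provenance: ", paste(names(prov), unlist(prov), sep = "=",
                                collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Feature vector as a long-form data frame
#'
#' @param fv a `FeatureVector`.
#' @param task optional list/row with `subject_id`, `group`,
#'   `lesion_class`, `sequence`, `mask_kind`, `pairing`.
#' @return data frame with one row per feature: task columns,
#'   `feature_name`, `family`, `transform`, `value`.
#' @export
feature_vector_to_long <- function(fv, task = NULL) {
  cat <- feature_catalog()
  base <- data.frame(feature_name = cat$name, family = cat$family,
                     transform = cat$transform,
                     value = as.numeric(fv), stringsAsFactors = FALSE)
  if (!is.null(task)) {
    for (col in c("subject_id", "group", "lesion_class", "sequence",
                  "mask_kind", "pairing")) {
      if (!is.null(task[[col]])) base[[col]] <- task[[col]]
    }
    base <- base[, c(intersect(c("subject_id", "group", "lesion_class",
                                 "sequence", "mask_kind", "pairing"),
                               names(base)),
                     "feature_name", "family", "transform", "value")]
  }
  base
}
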