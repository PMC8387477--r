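#' Two-level undecimated 2D wavelet decomposition
#'
#' Per-slice separable stationary (undecimated) wavelet transform. Level 1
#' applies the analysis pair along x and y giving subbands LL, LH, HL, HH
#' (first letter = filter along x, L = low-pass); level 2 applies the
#' zero-upsampled filters to the level-1 LL band giving LL2, LH2, HL2,
#' HH2. No subsampling occurs, so all 8 subbands keep the source grid and
#' the original ROI mask applies unchanged. Boundaries are handled by
#' half-sample symmetric reflection. Haar is the default mother wavelet;
#' on a constant slice every detail subband is identically zero.
#'
#' @param volume a `VolumeWithMask` (or plain 3D array).
#' @param family mother wavelet; currently `"haar"`.
#' @return list of class `SubbandSet`: 8 named 3D arrays (LL, LH, HL, HH,
#'   LL2, LH2, HL2, HH2) with the same dimensions as the input.
#' @export
wavelet_decompose <- function(volume, family = "haar") {
  x <- if (inherits(volume, "VolumeWithMask")) volume$intensities
       else volume
  dims <- dim(x)
  if (dims[1L] < 8L || dims[2L] < 8L) {
    stop("in-plane dimensions too small for the wavelet transform (need >= 8)")
  }
  f <- .wavelet_filters(family)
  h1 <- f$lo; g1 <- f$hi
  up <- function(v) {  # insert zeros between taps (a-trous, level 2)
    out <- numeric(2L * length(v) - 1L)
    out[seq(1L, length(out), by = 2L)] <- v
    out
  }
  h2 <- up(h1); g2 <- up(g1)
  sb <- list(LL = x, LH = x, HL = x, HH = x,
             LL2 = x, LH2 = x, HL2 = x, HH2 = x)
  for (k in seq_len(dims[3L])) {
    sl <- x[, , k]
    lx <- .filt_cols(.filt_rows(sl, h1), h1)   # rows = along x (dim 1)
    sb$LL[, , k] <- lx
    sb$LH[, , k] <- .filt_cols(.filt_rows(sl, h1), g1)
    sb$HL[, , k] <- .filt_cols(.filt_rows(sl, g1), h1)
    sb$HH[, , k] <- .filt_cols(.filt_rows(sl, g1), g1)
    sb$LL2[, , k] <- .filt_cols(.filt_rows(lx, h2), h2)
    sb$LH2[, , k] <- .filt_cols(.filt_rows(lx, h2), g2)
    sb$HL2[, , k] <- .filt_cols(.filt_rows(lx, g2), h2)
    sb$HH2[, , k] <- .filt_cols(.filt_rows(lx, g2), g2)
  }
  structure(sb, class = "SubbandSet")
}

.wavelet_filters <- function(family) {
  switch(family,
    haar = list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2)),
    stop("unsupported wavelet family: ", family)
  )
}

# Half-sample symmetric index for positions 1..n extended to 1..n+m-1.
.sym_index <- function(n, m) {
  idx <- seq_len(n + m - 1L)
  idx[idx > n] <- 2L * n + 1L - idx[idx > n]
  idx
}

# Filter along dim 1 of a matrix: y[i, ] = sum_k f[k] x_sym[i + k - 1, ].
.filt_rows <- function(mat, f) {
  n <- nrow(mat)
  m <- length(f)
  ext <- mat[.sym_index(n, m), , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (k in seq_len(m)) {
    if (f[k] != 0) out <- out + f[k] * ext[seq_len(n) + k - 1L, ,
                                           drop = FALSE]
  }
  out
}

.filt_cols <- function(mat, f) t(.filt_rows(t(mat), f))

#' The 488 wavelet-domain texture features
#'
#' For each of the 8 undecimated subbands, re-discretizes the subband
#' intensities within the (unchanged) ROI mask and computes the same 61
#' texture features as the spatial domain (5 second-order + 22 GLCM + 11
#' GLRLM + 5 LBP + 13 GLSZM + 5 NGTDM). A degenerate subband (e.g. all
#' zero detail coefficients on a constant lesion) yields NA for its
#' variance-dependent features via the degenerate-discretization path.
#'
#' @param subbands a `SubbandSet` from [wavelet_decompose()].
#' @param mask 3D binary mask on the source grid.
#' @param spacing voxel spacing in mm.
#' @param ng gray-level count for the per-subband re-discretization.
#' @return named numeric vector of length 488 (8 x 61), names prefixed
#'   `wavelet_<subband>_`.
#' @export
wavelet_feature_block <- function(subbands, mask, spacing, ng = 32L) {
  stopifnot(inherits(subbands, "SubbandSet"))
  out <- numeric(0)
  for (sbname in .subband_names) {
    vol <- volume_with_mask(subbands[[sbname]], spacing, mask = mask)
    feats <- texture_features_61(vol, ng = ng)
    names(feats) <- paste0("wavelet_", sbname, "_", names(feats))
    out <- c(out, feats)
  }
  stopifnot(length(out) == 488L)
  out
}
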