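#' Fixed-bin-number gray-level discretization
#'
#' Maps in-mask intensities to integer levels 1..Ng with
#' `level = min(Ng, floor(Ng * (x - min) / (max - min)) + 1)`, the
#' fixed-bin-number scheme. Min and max are computed within the mask only.
#' Fixed bin number (rather than fixed bin width) is used because the two
#' sequences of a pair sit on different intensity scales, and the scheme is
#' invariant to positive affine rescaling. A constant ROI (max == min) maps
#' every voxel to level 1 and is flagged degenerate so texture features can
#' report undefined instead of arbitrary numbers.
#'
#' @param volume a `VolumeWithMask` with a nonempty mask, or a plain 3D
#'   array if `mask` is supplied.
#' @param ng number of gray levels (>= 2); default 32.
#' @param mask optional mask when `volume` is a plain array.
#' @return an object of class `DiscretizedROI`: list with `levels` (3D
#'   integer array, `NA` outside the mask), `ng`, `mask`, `spacing`,
#'   `bin_edges` (ng + 1 ascending values spanning the in-mask range) and
#'   `degenerate` flag.
#' @export
discretize_fixed_bins <- function(volume, ng = 32L, mask = NULL) {
  if (inherits(volume, "VolumeWithMask")) {
    x <- volume$intensities
    mask <- volume$mask
    spacing <- volume$spacing
  } else {
    x <- volume
    spacing <- c(1, 1, 1)
  }
  ng <- as.integer(ng)
  if (is.na(ng) || ng < 2L) stop("ng must be an integer >= 2")
  if (is.null(mask) || sum(mask != 0) == 0L) {
    stop("discretization requires a nonempty mask")
  }
  inmask <- mask != 0
  vals <- x[inmask]
  if (any(!is.finite(vals))) stop("non-finite intensities inside the mask")
  lo <- min(vals); hi <- max(vals)
  degenerate <- (hi == lo)
  lev <- array(NA_integer_, dim = dim(x))
  if (degenerate) {
    lev[inmask] <- 1L
    edges <- seq(lo, lo + 1, length.out = ng + 1L)
  } else {
    lev[inmask] <- pmin(ng, floor(ng * (vals - lo) / (hi - lo)) + 1L)
    edges <- seq(lo, hi, length.out = ng + 1L)
  }
  structure(list(levels = lev, ng = ng,
                 mask = array(as.integer(inmask), dim = dim(x)),
                 spacing = spacing, bin_edges = edges,
                 degenerate = degenerate),
            class = "DiscretizedROI")
}

#' @export
print.DiscretizedROI <- function(x, ...) {
  cat("<DiscretizedROI> Ng=", x$ng, ", ", sum(x$mask),
      " in-mask voxels", if (x$degenerate) " (degenerate: constant ROI)",
      "\n", sep = "")
  invisible(x)
}

# Crop the level array to the mask bounding box (features are unchanged;
# texture builders get much smaller slices to scan).
crop_to_mask <- function(disc) {
  idx <- which(disc$mask != 0, arr.ind = TRUE)
  rng <- apply(idx, 2L, range)
  lev <- disc$levels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                     rng[1, 3]:rng[2, 3], drop = FALSE]
  lev
}

# Extract slice k of a 3D array as a matrix without dimension dropping.
slice_mat <- function(arr, k) {
  matrix(arr[, , k], nrow = dim(arr)[1L], ncol = dim(arr)[2L])
}
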