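#' Rotation-invariant uniform local binary pattern features
#'
#' Per slice, each in-mask voxel with a complete in-plane 8-neighbourhood
#' (neighbours may lie outside the mask; they only need to exist on the
#' grid) receives the P=8, R=1 rotation-invariant uniform LBP code of the
#' raw intensities: neighbours >= centre set their bit. Uniform codes (at
#' most two 0/1 transitions around the circle) map to bins 0..8 by their
#' number of set bits; all non-uniform codes share bin 9. The 10-bin code
#' histogram is summarized by 5 statistics: energy, entropy (bits), mean
#' code bin, code-bin variance, and the fraction of uniform patterns.
#'
#' @param volume a `VolumeWithMask` (raw intensities are used).
#' @return named numeric vector of length 5.
#' @export
lbp_features <- function(volume) {
  stopifnot(inherits(volume, "VolumeWithMask"))
  h <- lbp_histogram(volume)
  if (sum(h) == 0) {
    out <- rep(NA_real_, 5L); names(out) <- .lbp_names; return(out)
  }
  p <- h / sum(h)
  bins <- 0:9
  mu <- sum(bins * p)
  out <- c(
    hist_energy = sum(p^2),
    hist_entropy = -sum(.xlog2(p)),
    code_mean = mu,
    code_variance = sum((bins - mu)^2 * p),
    uniform_fraction = sum(p[1:9])
  )
  names(out) <- .lbp_names
  out
}

#' 10-bin riu2 LBP code histogram
#'
#' @param volume a `VolumeWithMask`.
#' @return integer vector of length 10 (bins 0..8 = uniform patterns by
#'   number of set bits, bin 10 = non-uniform).
#' @export
lbp_histogram <- function(volume) {
  x <- volume$intensities
  mask <- volume$mask
  if (is.null(mask)) stop("LBP requires a mask")
  counts <- integer(10L)
  # neighbours in circular order: E, NE, N, NW, W, SW, S, SE
  circ <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  for (k in seq_len(dim(x)[3L])) {
    sl <- slice_mat(x, k)
    msk <- slice_mat(mask, k)
    nx <- nrow(sl); ny <- ncol(sl)
    if (nx < 3L || ny < 3L) next
    ctr_x <- 2:(nx - 1); ctr_y <- 2:(ny - 1)
    inm <- msk[ctr_x, ctr_y, drop = FALSE] != 0
    if (!any(inm)) next
    centre <- sl[ctr_x, ctr_y, drop = FALSE]
    bits <- vapply(circ, function(d) {
      as.vector(sl[ctr_x + d[1], ctr_y + d[2], drop = FALSE] >= centre)
    }, logical(length(centre)))
    bits <- matrix(bits, ncol = 8L)[as.vector(inm), , drop = FALSE]
    trans <- rowSums(abs(bits - bits[, c(2:8, 1), drop = FALSE]))
    ones <- rowSums(bits)
    bin <- ifelse(trans <= 2L, ones, 9L)
    counts <- counts + tabulate(bin + 1L, nbins = 10L)
  }
  counts
}
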