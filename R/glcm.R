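#' Gray-level co-occurrence matrix
#'
#' Counts in-mask voxel pairs at distance 1 along the four in-plane
#' directions (1,0), (0,1), (1,1), (1,-1), per slice, with both endpoints
#' inside the mask. Counts are symmetrized (transpose added) and pooled
#' over slices and directions before normalization; pooling is the more
#' stable choice for small ROIs than per-direction feature averaging.
#' Matrices are built in 2D (in-plane) because thick, gapped slices make
#' through-plane co-occurrence physically inhomogeneous.
#'
#' @param disc a `DiscretizedROI`.
#' @param distance pair offset in voxels (default 1).
#' @param directions list of in-plane integer offsets `(dx, dy)`.
#' @return list of class `TextureMatrix` with `kind = "GLCM"`, `counts`
#'   (symmetric Ng x Ng integer counts), `p` (normalized probabilities,
#'   sums to 1) and `ng`. `p` is `NULL` when no valid pair exists.
#' @export
glcm_matrix <- function(disc, distance = 1L,
                        directions = list(c(1L, 0L), c(0L, 1L),
                                          c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(disc, "DiscretizedROI"))
  lev <- crop_to_mask(disc)
  ng <- disc$ng
  counts <- matrix(0, ng, ng)
  d <- as.integer(distance)
  for (k in seq_len(dim(lev)[3L])) {
    sl <- slice_mat(lev, k)
    nx <- nrow(sl); ny <- ncol(sl)
    for (dir in directions) {
      dx <- dir[1L] * d; dy <- dir[2L] * d
      xs <- seq_len(nx - abs(dx)); ys <- seq_len(ny - abs(dy))
      if (!length(xs) || !length(ys)) next
      x2 <- xs + abs(dx)
      y2 <- if (dy >= 0) ys + dy else ys
      y1 <- if (dy >= 0) ys else ys + abs(dy)
      a <- sl[xs, y1, drop = FALSE]
      b <- sl[x2, y2, drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      counts <- counts + matrix(
        tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng), ng, ng,
        byrow = TRUE)
    }
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  structure(list(kind = "GLCM", counts = counts,
                 p = if (tot > 0) counts / tot else NULL,
                 ng = ng),
            class = "TextureMatrix")
}

# Marginal machinery shared by glcm_features and secondorder_features.
.glcm_margins <- function(p) {
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p)                  # symmetric: px == py
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  dvals <- 0:(ng - 1L)
  pd <- vapply(dvals, function(k) sum(p[abs(ii - jj) == k]), 0)
  svals <- 2:(2L * ng)
  ps <- vapply(svals, function(k) sum(p[(ii + jj) == k]), 0)
  list(ng = ng, i = i, px = px, mu = mu, sig2 = sig2,
       ii = ii, jj = jj, dvals = dvals, pd = pd, svals = svals, ps = ps)
}

.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' The 22 GLCM features
#'
#' Standard co-occurrence statistics of the normalized symmetric GLCM:
#' autocorrelation, cluster prominence/shade/tendency, contrast,
#' correlation, difference average/entropy/variance, energy (angular
#' second moment), entropy, homogeneity (inverse difference moment),
#' inverse difference, the two informational measures of correlation,
#' inverse variance, joint average/variance, maximum probability, and sum
#' average/entropy/variance. Entropies are in bits. `correlation` is
#' undefined (NA) when the marginal variance is zero; `imc1`/`imc2` when
#' the marginal entropy is zero.
#'
#' @param m a `TextureMatrix` from [glcm_matrix()].
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "TextureMatrix"), m$kind == "GLCM")
  if (is.null(m$p)) {
    out <- rep(NA_real_, 22L); names(out) <- .glcm_names; return(out)
  }
  p <- m$p
  g <- .glcm_margins(p)
  ii <- g$ii; jj <- g$jj
  autoc <- sum(ii * jj * p)
  corr <- if (g$sig2 > 0) (autoc - g$mu^2) / g$sig2 else NA_real_
  da <- sum(g$dvals * g$pd)
  sa <- sum(g$svals * g$ps)
  hxy <- -sum(.xlog2(p))
  hx <- -sum(.xlog2(g$px))
  pxpy <- outer(g$px, g$px)
  hxy1 <- -sum(p * ifelse(pxpy > 0, log2(pxpy), 0))
  hxy2 <- -sum(.xlog2(pxpy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- if (hx > 0) sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
          else NA_real_
  off <- ii != jj
  out <- c(
    autocorrelation = autoc,
    cluster_prominence = sum((ii + jj - 2 * g$mu)^4 * p),
    cluster_shade = sum((ii + jj - 2 * g$mu)^3 * p),
    cluster_tendency = sum((ii + jj - 2 * g$mu)^2 * p),
    contrast = sum((ii - jj)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(.xlog2(g$pd)),
    difference_variance = sum((g$dvals - da)^2 * g$pd),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity = sum(p / (1 + (ii - jj)^2)),
    inverse_difference = sum(p / (1 + abs(ii - jj))),
    imc1 = imc1, imc2 = imc2,
    inverse_variance = sum(p[off] / (ii[off] - jj[off])^2),
    joint_average = g$mu,
    joint_variance = sum((ii - g$mu)^2 * p),
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = -sum(.xlog2(g$ps)),
    sum_variance = sum((g$svals - sa)^2 * g$ps)
  )
  names(out) <- .glcm_names
  out
}

#' The 5 second-order co-occurrence summaries
#'
#' A five-feature family of co-occurrence statistics disjoint from the
#' 22-entry GLCM list: dissimilarity, average intensity of co-occurring
#' pairs, the complement of the joint maximum, and the uniformities of the
#' difference and sum distributions. Computed from the same distance-1
#' direction-pooled matrix as [glcm_features()].
#'
#' @param m a `TextureMatrix` from [glcm_matrix()].
#' @return named numeric vector of length 5.
#' @export
secondorder_features <- function(m) {
  stopifnot(inherits(m, "TextureMatrix"), m$kind == "GLCM")
  if (is.null(m$p)) {
    out <- rep(NA_real_, 5L); names(out) <- .secondorder_names
    return(out)
  }
  p <- m$p
  g <- .glcm_margins(p)
  out <- c(
    dissimilarity = sum(abs(g$ii - g$jj) * p),
    pair_average = sum((g$ii + g$jj) / 2 * p),
    joint_maximum_complement = 1 - max(p),
    difference_uniformity = sum(g$pd^2),
    sum_uniformity = sum(g$ps^2)
  )
  names(out) <- .secondorder_names
  out
}
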