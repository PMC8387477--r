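#' Neighbouring gray tone difference features
#'
#' For each in-mask voxel with at least one in-mask in-plane 8-neighbour,
#' the absolute difference between its level and the mean level of those
#' neighbours is accumulated per level: `s(i)`. With `p(i)` the fraction
#' of valid voxels at level i, the five Amadasun-King statistics are
#' returned: coarseness (capped at 1e6 when the denominator vanishes, the
#' constant-ROI case), contrast, busyness (NA when only one level is
#' present), complexity and strength (0 when all `s(i)` are 0).
#'
#' @param disc a `DiscretizedROI`.
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(disc) {
  stopifnot(inherits(disc, "DiscretizedROI"))
  tab <- ngtdm_table(disc)
  n <- sum(tab$n)
  if (n == 0) {
    out <- rep(NA_real_, 5L); names(out) <- .ngtdm_names; return(out)
  }
  p <- tab$n / n
  s <- tab$s
  lv <- seq_along(p)
  occ <- which(p > 0)
  ngp <- length(occ)
  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse > 0) min(1e6, 1 / denom_coarse) else 1e6
  contrast <- if (ngp > 1) {
    grid <- expand.grid(i = occ, j = occ)
    sum(p[grid$i] * p[grid$j] * (grid$i - grid$j)^2) /
      (ngp * (ngp - 1)) * sum(s) / n
  } else 0
  if (ngp > 1) {
    grid <- expand.grid(i = occ, j = occ)
    grid <- grid[grid$i != grid$j, ]
    busy_den <- sum(abs(grid$i * p[grid$i] - grid$j * p[grid$j]))
    busyness <- if (busy_den > 0) denom_coarse / busy_den else NA_real_
    complexity <- sum(abs(grid$i - grid$j) *
                      (p[grid$i] * s[grid$i] + p[grid$j] * s[grid$j]) /
                      (p[grid$i] + p[grid$j])) / n
    strength <- if (sum(s) > 0) {
      sum((p[grid$i] + p[grid$j]) * (grid$i - grid$j)^2) / sum(s)
    } else 0
  } else {
    busyness <- NA_real_
    complexity <- 0
    strength <- 0
  }
  out <- c(coarseness = coarseness, contrast = contrast,
           busyness = busyness, complexity = complexity,
           strength = strength)
  names(out) <- .ngtdm_names
  out
}

#' NGTDM occurrence/deviation table
#'
#' @param disc a `DiscretizedROI`.
#' @return list with `n` (valid-voxel count per level) and `s` (summed
#'   absolute deviation from the in-mask 8-neighbourhood mean per level),
#'   both of length Ng.
#' @export
ngtdm_table <- function(disc) {
  lev <- crop_to_mask(disc)
  ng <- disc$ng
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  for (k in seq_len(dim(lev)[3L])) {
    sl <- slice_mat(lev, k)
    nx <- nrow(sl); ny <- ncol(sl)
    padded <- matrix(NA_integer_, nx + 2L, ny + 2L)
    padded[2:(nx + 1), 2:(ny + 1)] <- sl
    ssum <- matrix(0, nx, ny)
    scnt <- matrix(0L, nx, ny)
    for (r in seq_len(nrow(shifts))) {
      nb <- padded[2:(nx + 1) + shifts$dx[r], 2:(ny + 1) + shifts$dy[r],
                   drop = FALSE]
      ok <- !is.na(nb)
      ssum[ok] <- ssum[ok] + nb[ok]
      scnt <- scnt + ok
    }
    valid <- !is.na(sl) & scnt > 0L
    if (!any(valid)) next
    dev <- abs(sl[valid] - ssum[valid] / scnt[valid])
    g <- sl[valid]
    n_i <- n_i + tabulate(g, nbins = ng)
    s_i <- s_i + as.vector(tapply(dev, factor(g, levels = seq_len(ng)),
                                  sum, default = 0))
  }
  list(n = n_i, s = s_i)
}
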