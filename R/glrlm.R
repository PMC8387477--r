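#' Gray-level run-length features
#'
#' Builds the run-length matrix per slice along the in-plane directions
#' (runs are maximal constant-level in-mask segments; out-of-mask voxels
#' break runs), pools counts over slices and directions, and returns 11
#' standard statistics: short/long run emphasis (SRE/LRE), gray-level and
#' run-length nonuniformity (GLN/RLN), run percentage (RP, runs per voxel
#' per direction), low/high gray-level run emphasis (LGRE/HGRE) and the
#' four joint emphases (SRLGE, SRHGE, LRLGE, LRHGE).
#'
#' @param disc a `DiscretizedROI`.
#' @param directions subset of `c("x", "y", "diag", "antidiag")`; default
#'   all four in-plane directions.
#' @return named numeric vector of length 11.
#' @export
glrlm_features <- function(disc,
                           directions = c("x", "y", "diag", "antidiag")) {
  stopifnot(inherits(disc, "DiscretizedROI"))
  R <- glrlm_matrix(disc, directions)$counts
  np <- sum(disc$mask != 0) * length(directions)
  nr <- sum(R)
  if (nr == 0) {
    out <- rep(NA_real_, 11L); names(out) <- .glrlm_names; return(out)
  }
  i <- seq_len(nrow(R))
  l <- seq_len(ncol(R))
  ri <- rowSums(R)
  rl <- colSums(R)
  il2 <- outer(i^2, l^2)
  out <- c(
    sre = sum(sweep(R, 2L, l^2, "/")) / nr,
    lre = sum(sweep(R, 2L, l^2, "*")) / nr,
    gln = sum(ri^2) / nr,
    rln = sum(rl^2) / nr,
    rp = nr / np,
    lgre = sum(ri / i^2) / nr,
    hgre = sum(ri * i^2) / nr,
    srlge = sum(R / il2) / nr,
    srhge = sum(R * outer(i^2, 1 / l^2)) / nr,
    lrlge = sum(R * outer(1 / i^2, l^2)) / nr,
    lrhge = sum(R * il2) / nr
  )
  names(out) <- .glrlm_names
  out
}

#' Run-length matrix (counts by level and run length)
#'
#' @inheritParams glrlm_features
#' @return list with `counts`, an Ng x Lmax matrix of run counts pooled
#'   over slices and the requested in-plane directions.
#' @export
glrlm_matrix <- function(disc,
                         directions = c("x", "y", "diag", "antidiag")) {
  directions <- match.arg(directions, several.ok = TRUE)
  lev <- crop_to_mask(disc)
  ng <- disc$ng
  dims <- dim(lev)
  lmax <- max(dims[1L], dims[2L])
  counts <- matrix(0, ng, lmax)
  add_line <- function(v) {
    if (!length(v)) return()
    r <- rle(ifelse(is.na(v), 0L, v))
    keep <- r$values > 0L
    if (any(keep)) {
      vals <- r$values[keep]; lens <- r$lengths[keep]
      for (q in seq_along(vals)) {
        counts[vals[q], lens[q]] <<- counts[vals[q], lens[q]] + 1
      }
    }
  }
  for (k in seq_len(dims[3L])) {
    sl <- slice_mat(lev, k)
    nx <- nrow(sl); ny <- ncol(sl)
    if ("x" %in% directions) {
      for (y in seq_len(ny)) add_line(sl[, y])
    }
    if ("y" %in% directions) {
      for (x in seq_len(nx)) add_line(sl[x, ])
    }
    if ("diag" %in% directions) {
      for (d in (1 - ny):(nx - 1)) {
        x <- seq(max(1, 1 + d), min(nx, ny + d))
        add_line(sl[cbind(x, x - d)])
      }
    }
    if ("antidiag" %in% directions) {
      for (s in 2:(nx + ny)) {
        x <- seq(max(1, s - ny), min(nx, s - 1))
        add_line(sl[cbind(x, s - x)])
      }
    }
  }
  list(counts = counts)
}
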