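#' Gray-level size-zone features
#'
#' Zones are in-plane 8-connected components of equal gray level within
#' the mask, pooled over slices. Returns 13 standard statistics:
#' small/large area emphasis (SAE/LAE), gray-level nonuniformity (GLN),
#' zone-size nonuniformity (SZN), zone percentage (ZP = zones per in-mask
#' voxel), low/high gray-level zone emphasis (LGZE/HGZE), the four joint
#' emphases (SALGE, SAHGE, LALGE, LAHGE), and the gray-level and
#' zone-size variances of the zone distribution.
#'
#' @param disc a `DiscretizedROI`.
#' @return named numeric vector of length 13.
#' @export
glszm_features <- function(disc) {
  stopifnot(inherits(disc, "DiscretizedROI"))
  Z <- glszm_matrix(disc)$counts
  np <- sum(disc$mask != 0)
  nz <- sum(Z)
  if (nz == 0) {
    out <- rep(NA_real_, 13L); names(out) <- .glszm_names; return(out)
  }
  i <- seq_len(nrow(Z))
  s <- seq_len(ncol(Z))
  zi <- rowSums(Z)
  zs <- colSums(Z)
  pz <- Z / nz
  mu_i <- sum(sweep(pz, 1L, i, "*"))
  mu_s <- sum(sweep(pz, 2L, s, "*"))
  out <- c(
    sae = sum(sweep(Z, 2L, s^2, "/")) / nz,
    lae = sum(sweep(Z, 2L, s^2, "*")) / nz,
    gln = sum(zi^2) / nz,
    szn = sum(zs^2) / nz,
    zp = nz / np,
    lgze = sum(zi / i^2) / nz,
    hgze = sum(zi * i^2) / nz,
    salge = sum(Z / outer(i^2, s^2)) / nz,
    sahge = sum(Z * outer(i^2, 1 / s^2)) / nz,
    lalge = sum(Z * outer(1 / i^2, s^2)) / nz,
    lahge = sum(Z * outer(i^2, s^2)) / nz,
    gray_level_variance = sum(sweep(pz, 1L, (i - mu_i)^2, "*")),
    zone_size_variance = sum(sweep(pz, 2L, (s - mu_s)^2, "*"))
  )
  names(out) <- .glszm_names
  out
}

#' Size-zone matrix (zone counts by level and size)
#'
#' @param disc a `DiscretizedROI`.
#' @return list with `counts`, an Ng x Smax matrix of zone counts.
#' @export
glszm_matrix <- function(disc) {
  lev <- crop_to_mask(disc)
  ng <- disc$ng
  np <- sum(!is.na(lev))
  counts <- matrix(0, ng, max(np, 1L))
  for (k in seq_len(dim(lev)[3L])) {
    sl <- slice_mat(lev, k)
    for (g in sort(unique(sl[!is.na(sl)]))) {
      sizes <- .component_sizes_8(!is.na(sl) & sl == g)
      for (sz in sizes) counts[g, sz] <- counts[g, sz] + 1
    }
  }
  smax <- max(which(colSums(counts) > 0), 1L)
  list(counts = counts[, seq_len(smax), drop = FALSE])
}

# Sizes of 8-connected components of a logical matrix (iterative flood
# fill over linear indices; slices are cropped to the mask bounding box,
# so these stay small).
.component_sizes_8 <- function(b) {
  nx <- nrow(b); ny <- ncol(b)
  todo <- which(b)
  if (!length(todo)) return(integer())
  seen <- logical(length(b))
  sizes <- integer()
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  for (start in todo) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      x <- (cur - 1L) %% nx + 1L
      y <- (cur - 1L) %/% nx + 1L
      nxts <- x + offs$dx + (y + offs$dy - 1L) * nx
      ok <- x + offs$dx >= 1L & x + offs$dx <= nx &
            y + offs$dy >= 1L & y + offs$dy <= ny
      nxts <- nxts[ok]
      nxts <- nxts[b[nxts] & !seen[nxts]]
      if (length(nxts)) {
        seen[nxts] <- TRUE
        stack <- c(stack, nxts)
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}
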