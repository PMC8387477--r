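# Independent brute-force oracles for the texture-matrix builders, written
# as plain voxel loops (no shared code with the implementation), plus tiny
# fixture constructors.

# Build a DiscretizedROI directly from a 3D level array (NA = out of mask).
disc_from_levels <- function(lev, ng = max(lev, na.rm = TRUE),
                             spacing = c(1, 1, 1)) {
  lev <- array(as.integer(lev), dim = dim(lev))
  mask <- array(as.integer(!is.na(lev)), dim = dim(lev))
  structure(list(levels = lev, ng = as.integer(ng), mask = mask,
                 spacing = spacing,
                 bin_edges = seq(0, 1, length.out = ng + 1),
                 degenerate = FALSE),
            class = "DiscretizedROI")
}

# Random small discretized ROI (6 x 6 x 2 by default), ~75% mask coverage.
random_disc <- function(seed, dims = c(6, 6, 2), ng = 4) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  drop_out <- array(runif(prod(dims)) < 0.25, dim = dims)
  lev[drop_out] <- NA_integer_
  if (all(is.na(lev))) lev[1, 1, 1] <- 1L
  disc_from_levels(lev, ng = ng)
}

# --- brute-force GLCM: loop every voxel and direction ---------------------
bf_glcm_counts <- function(lev, ng) {
  dims <- dim(lev)
  counts <- matrix(0, ng, ng)
  dirs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in seq_len(dims[3])) {
    for (x in seq_len(dims[1])) {
      for (y in seq_len(dims[2])) {
        a <- lev[x, y, k]
        if (is.na(a)) next
        for (d in dirs) {
          x2 <- x + d[1]; y2 <- y + d[2]
          if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2]) next
          b <- lev[x2, y2, k]
          if (is.na(b)) next
          counts[a, b] <- counts[a, b] + 1
          counts[b, a] <- counts[b, a] + 1
        }
      }
    }
  }
  counts
}

# --- brute-force GLRLM: walk each line voxel by voxel ---------------------
bf_glrlm_counts <- function(lev, ng) {
  dims <- dim(lev)
  lmax <- max(dims[1], dims[2])
  counts <- matrix(0, ng, lmax)
  scan_line <- function(coords) {
    run_val <- NA; run_len <- 0
    flush <- function() {
      if (!is.na(run_val) && run_len > 0) {
        counts[run_val, run_len] <<- counts[run_val, run_len] + 1
      }
    }
    for (r in seq_len(nrow(coords))) {
      v <- lev[coords[r, 1], coords[r, 2], coords[r, 3]]
      if (is.na(v)) {
        flush(); run_val <- NA; run_len <- 0
      } else if (!is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        flush(); run_val <- v; run_len <- 1
      }
    }
    flush()
  }
  nx <- dims[1]; ny <- dims[2]
  for (k in seq_len(dims[3])) {
    for (y in seq_len(ny)) scan_line(cbind(seq_len(nx), y, k))
    for (x in seq_len(nx)) scan_line(cbind(x, seq_len(ny), k))
    for (d in (1 - ny):(nx - 1)) {                # direction (1, 1)
      xs <- seq(max(1, 1 + d), min(nx, ny + d))
      scan_line(cbind(xs, xs - d, k))
    }
    for (s in 2:(nx + ny)) {                      # direction (1, -1)
      xs <- seq(max(1, s - ny), min(nx, s - 1))
      scan_line(cbind(xs, s - xs, k))
    }
  }
  counts
}

# --- brute-force GLSZM: region growing by repeated sweeps -----------------
bf_glszm_counts <- function(lev, ng) {
  dims <- dim(lev)
  sizes_by_level <- list()
  for (k in seq_len(dims[3])) {
    sl <- lev[, , k]
    labels <- matrix(0L, dims[1], dims[2])
    next_label <- 0L
    for (x in seq_len(dims[1])) {
      for (y in seq_len(dims[2])) {
        if (is.na(sl[x, y]) || labels[x, y] != 0L) next
        next_label <- next_label + 1L
        labels[x, y] <- next_label
        changed <- TRUE
        while (changed) {       # naive fixed-point region growing
          changed <- FALSE
          for (xx in seq_len(dims[1])) {
            for (yy in seq_len(dims[2])) {
              if (labels[xx, yy] != next_label) next
              for (dx in -1:1) for (dy in -1:1) {
                x2 <- xx + dx; y2 <- yy + dy
                if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2]) next
                if (!is.na(sl[x2, y2]) && sl[x2, y2] == sl[xx, yy] &&
                    labels[x2, y2] == 0L) {
                  labels[x2, y2] <- next_label
                  changed <- TRUE
                }
              }
            }
          }
        }
        g <- sl[x, y]
        sizes_by_level[[length(sizes_by_level) + 1L]] <-
          c(g, sum(labels == next_label))
      }
    }
  }
  np <- sum(!is.na(lev))
  counts <- matrix(0, ng, max(np, 1))
  for (z in sizes_by_level) counts[z[1], z[2]] <- counts[z[1], z[2]] + 1
  smax <- max(which(colSums(counts) > 0), 1)
  counts[, seq_len(smax), drop = FALSE]
}

# --- brute-force NGTDM table ---------------------------------------------
bf_ngtdm <- function(lev, ng) {
  dims <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (k in seq_len(dims[3])) {
    for (x in seq_len(dims[1])) {
      for (y in seq_len(dims[2])) {
        v <- lev[x, y, k]
        if (is.na(v)) next
        nb <- c()
        for (dx in -1:1) for (dy in -1:1) {
          if (dx == 0 && dy == 0) next
          x2 <- x + dx; y2 <- y + dy
          if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2]) next
          u <- lev[x2, y2, k]
          if (!is.na(u)) nb <- c(nb, u)
        }
        if (!length(nb)) next
        n_i[v] <- n_i[v] + 1
        s_i[v] <- s_i[v] + abs(v - mean(nb))
      }
    }
  }
  list(n = n_i, s = s_i)
}

# --- brute-force separable wavelet filtering on one slice -----------------
bf_filter2_sym <- function(sl, fx, fy) {
  nx <- nrow(sl); ny <- ncol(sl)
  refl <- function(i, n) { if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i }
  out <- matrix(0, nx, ny)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      acc <- 0
      for (a in seq_along(fx)) {
        for (b in seq_along(fy)) {
          acc <- acc + fx[a] * fy[b] *
            sl[refl(x + a - 1, nx), refl(y + b - 1, ny)]
        }
      }
      out[x, y] <- acc
    }
  }
  out
}

# Quick phantom for end-to-end tests: small grid, binary-exact spacing.
tiny_phantom <- function(seed, shape = c(32, 32, 4),
                         spacing = c(4, 4, 7), radius = 10,
                         meta = list()) {
  ctr <- (shape - 1) / 2
  spec <- lesion_spec(center = ctr, radius_mm = radius,
                      texture_amplitude = 12,
                      texture_correlation_length_mm = 6, contrast = 60)
  make_phantom(spec, shape, spacing, seed = seed, meta = meta)
}
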