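#' @title Synthetic paired-acquisition cohort
#' @description Phantom and cohort generators standing in for the
#' undeposited patient registry: textured hyperintense lesions on a darker
#' background, rendered twice (or more) through acquisition profiles that
#' differ in matrix, blur and noise, with imperfect per-acquisition masks,
#' so whole vs intersection ROIs genuinely differ downstream.
#' @name synthetic-cohort
NULL

#' Acquisition degradation profile
#'
#' The parameters one synthetic "sequence" applies to the ground-truth
#' volume: acquisition matrix (in-plane), additive Gaussian noise as a
#' fraction of the lesion-background contrast, in-plane Gaussian blur
#' FWHM in mm, a per-profile seed offset, and the mask boundary jitter
#' radius in voxels (0 = exact mask transfer).
#'
#' @param name sequence label.
#' @param matrix integer length-2 acquisition matrix, both components
#'   >= 16.
#' @param noise_sigma additive Gaussian noise scale, >= 0 (fraction of
#'   lesion-background contrast).
#' @param blur_fwhm in-plane Gaussian blur FWHM in mm, >= 0.
#' @param seed_offset integer mixed into per-subject seeds.
#' @param mask_jitter one-voxel boundary erosion/dilation jitter (0 or 1).
#' @return list of class `AcquisitionProfile`.
#' @export
acquisition_profile <- function(name, matrix, noise_sigma = 0,
                                blur_fwhm = 0, seed_offset = 0L,
                                mask_jitter = 1L) {
  matrix <- as.integer(matrix)
  if (length(matrix) != 2L || any(matrix < 16L)) {
    stop("acquisition matrix must be two integers >= 16")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (blur_fwhm < 0) stop("blur_fwhm must be >= 0")
  structure(list(name = name, matrix = matrix,
                 noise_sigma = noise_sigma, blur_fwhm = blur_fwhm,
                 seed_offset = as.integer(seed_offset),
                 mask_jitter = as.integer(mask_jitter)),
            class = "AcquisitionProfile")
}

#' Default acquisition profiles
#'
#' Four profiles parameterized after the study protocols' acquisition
#' matrices (conventional 256x218, EPI 128x128, ETL 192x192, TR 256x256).
#' Noise and blur magnitudes are free simulator knobs drawn from the
#' documented default grids noise_sigma in {0, 0.05, 0.15} and blur_fwhm
#' in {0, 1.5} mm, with ETL given the largest noise; which degradation
#' (matrix reduction vs noise) dominates feature stability depends on the
#' grid scale, so the relative ordering of the fast sequences is a
#' property of these knobs, not a reproduction of the clinical result.
#' `scale` shrinks the matrices (floor, minimum 16) so desk-scale runs
#' stay fast; the physical field of view is preserved by the degradation
#' step.
#'
#' @param scale matrix scale factor in (0, 1]; default 1 keeps the
#'   protocol matrices.
#' @return named list of four `AcquisitionProfile` objects.
#' @export
acquisition_profiles <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  sc <- function(m) pmax(16L, as.integer(floor(m * scale)))
  list(
    conventional = acquisition_profile("conventional", sc(c(256L, 218L)),
                                       noise_sigma = 0.02, blur_fwhm = 0,
                                       seed_offset = 0L),
    EPI = acquisition_profile("EPI", sc(c(128L, 128L)),
                              noise_sigma = 0.05, blur_fwhm = 1.5,
                              seed_offset = 1L),
    ETL = acquisition_profile("ETL", sc(c(192L, 192L)),
                              noise_sigma = 0.15, blur_fwhm = 1.5,
                              seed_offset = 2L),
    TR = acquisition_profile("TR", sc(c(256L, 256L)),
                             noise_sigma = 0.05, blur_fwhm = 0,
                             seed_offset = 3L)
  )
}

#' Identity profile (null experiment)
#'
#' Matrix equal to the truth grid, no blur, no noise, no mask jitter: the
#' degraded rendition equals the truth bit-for-bit, so every well-defined
#' feature attains CCC = 1 downstream.
#'
#' @param truth_dim in-plane dimensions of the truth grid.
#' @param name sequence label (default "identity").
#' @return an `AcquisitionProfile`.
#' @export
identity_profile <- function(truth_dim, name = "identity") {
  acquisition_profile(name, truth_dim[1:2], noise_sigma = 0,
                      blur_fwhm = 0, seed_offset = 0L, mask_jitter = 0L)
}

#' Lesion specification
#'
#' @param center lesion centre in 0-based voxel coordinates (x, y, slice).
#' @param radius_mm lesion radius in mm, > 0.
#' @param texture_amplitude amplitude of the correlated lesion texture
#'   field (intensity units).
#' @param texture_correlation_length_mm correlation length of the texture
#'   field in mm.
#' @param contrast lesion-minus-background mean intensity, > 0
#'   (hyperintense lesion).
#' @return list of class `LesionSpec`.
#' @export
lesion_spec <- function(center, radius_mm, texture_amplitude = 10,
                        texture_correlation_length_mm = 6,
                        contrast = 60) {
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  if (contrast <= 0) stop("contrast must be > 0 (hyperintense lesion)")
  structure(list(center = as.double(center), radius_mm = radius_mm,
                 texture_amplitude = texture_amplitude,
                 texture_correlation_length_mm =
                   texture_correlation_length_mm,
                 contrast = contrast),
            class = "LesionSpec")
}

# Separable Gaussian smoothing; sigma in mm per axis, reflect boundary.
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  out <- arr
  for (a in 1:3) {
    sg <- sigma_mm[a] / spacing[a]
    if (sg < 1e-6) next
    r <- max(1L, ceiling(3 * sg))
    kern <- exp(-0.5 * ((-r:r) / sg)^2)
    kern <- kern / sum(kern)
    n <- dim(out)[a]
    full <- (1L - r):(n + r)
    full[full < 1L] <- 1L - full[full < 1L]
    full[full > n] <- 2L * n + 1L - full[full > n]
    full <- pmin(pmax(full, 1L), n)
    perm <- switch(a, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    v <- aperm(out, perm)
    d <- dim(v)
    ext <- v[full, , , drop = FALSE]
    acc <- array(0, d)
    for (k in seq_along(kern)) {
      acc <- acc + kern[k] * ext[seq_len(d[1]) + k - 1L, , , drop = FALSE]
    }
    out <- aperm(acc, order(perm))
  }
  out
}

# Smooth unit-variance Gaussian-correlated random field.
correlated_field <- function(dims, spacing, corr_length_mm) {
  z <- array(stats::rnorm(prod(dims)), dim = dims)
  sg <- corr_length_mm / 2
  f <- gaussian_smooth(z, rep(sg, 3), spacing)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f
}

#' Generate a textured lesion phantom
#'
#' Background = constant (100) plus a smooth Gaussian-correlated field;
#' lesion voxels (centres within `radius_mm` of the lesion centre) get the
#' added contrast plus their own correlated texture field. The mask is the
#' exact lesion sphere. Deterministic given `seed`.
#'
#' @param spec a `LesionSpec`.
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param seed integer seed.
#' @param background_mean background intensity (default 100).
#' @param background_amplitude amplitude of the background field (default
#'   5% of the lesion contrast).
#' @param meta metadata list stored on the result.
#' @return a `VolumeWithMask` (mask = lesion sphere).
#' @export
make_phantom <- function(spec, shape, spacing, seed,
                         background_mean = 100,
                         background_amplitude = 0.05 * spec$contrast,
                         meta = list()) {
  stopifnot(inherits(spec, "LesionSpec"), length(shape) == 3L)
  shape <- as.integer(shape)
  ctr_mm <- spec$center * spacing
  lo <- ctr_mm - spec$radius_mm
  hi <- ctr_mm + spec$radius_mm
  if (any(lo < 0) || any(hi > (shape - 1) * spacing)) {
    stop("lesion sphere does not fit inside the grid")
  }
  set.seed(seed)
  bg <- background_mean +
    background_amplitude *
      correlated_field(shape, spacing, spec$texture_correlation_length_mm)
  tex <- correlated_field(shape, spacing,
                          spec$texture_correlation_length_mm)
  gx <- (seq_len(shape[1]) - 1) * spacing[1]
  gy <- (seq_len(shape[2]) - 1) * spacing[2]
  gz <- (seq_len(shape[3]) - 1) * spacing[3]
  d2 <- outer(outer((gx - ctr_mm[1])^2, (gy - ctr_mm[2])^2, "+"),
              (gz - ctr_mm[3])^2, "+")
  mask <- array(as.integer(d2 <= spec$radius_mm^2), dim = shape)
  x <- bg
  x[mask == 1] <- x[mask == 1] + spec$contrast +
    spec$texture_amplitude * tex[mask == 1]
  volume_with_mask(x, spacing, mask = mask, meta = meta)
}

# Seeded one-voxel boundary erosion/dilation of a mask (in-plane
# 4-neighbourhood); emulates per-sequence manual segmentation differences.
jitter_mask <- function(mask, seed, flip_prob = 0.25, min_voxels = 10L) {
  set.seed(seed)
  dims <- dim(mask)
  out <- mask
  for (k in seq_len(dims[3L])) {
    m <- mask[, , k]
    if (!any(m != 0)) next
    nx <- nrow(m); ny <- ncol(m)
    pad <- matrix(0L, nx + 2L, ny + 2L)
    pad[2:(nx + 1), 2:(ny + 1)] <- m
    nb4 <- pad[1:nx, 2:(ny + 1)] + pad[3:(nx + 2), 2:(ny + 1)] +
           pad[2:(nx + 1), 1:ny] + pad[2:(nx + 1), 3:(ny + 2)]
    inner_boundary <- m == 1L & nb4 < 4L
    outer_boundary <- m == 0L & nb4 > 0L
    flips_in <- inner_boundary &
      array(stats::runif(nx * ny) < flip_prob, dim = c(nx, ny))
    flips_out <- outer_boundary &
      array(stats::runif(nx * ny) < flip_prob, dim = c(nx, ny))
    mk <- m
    mk[flips_in] <- 0L
    mk[flips_out] <- 1L
    out[, , k] <- mk
  }
  if (sum(out) < min_voxels) mask else out
}

#' Degrade a ground-truth volume through an acquisition profile
#'
#' Pipeline: in-plane Gaussian blur (`blur_fwhm`) -> linear down-sampling
#' to the profile matrix (physical extent preserved; slice count
#' unchanged) -> additive Gaussian noise with sd = `noise_sigma` x the
#' truth's lesion-background contrast -> nearest-neighbour mask transfer,
#' optionally perturbed by seeded one-voxel boundary erosion/dilation so
#' whole and intersection masks differ. With the identity profile the
#' output equals the input exactly. Deterministic given `seed`.
#'
#' @param truth a `VolumeWithMask` with mask (the ground truth).
#' @param profile an `AcquisitionProfile`; its matrix must not exceed the
#'   truth grid in-plane.
#' @param seed integer seed.
#' @return a `VolumeWithMask` on the profile's grid, `meta$sequence` set
#'   to the profile name.
#' @export
degrade_acquisition <- function(truth, profile, seed) {
  stopifnot(inherits(truth, "VolumeWithMask"),
            inherits(profile, "AcquisitionProfile"))
  if (is.null(truth$mask)) stop("truth volume must carry a mask")
  tdim <- dim(truth$intensities)
  if (any(profile$matrix > tdim[1:2])) {
    stop("profile matrix ", paste(profile$matrix, collapse = "x"),
         " exceeds the truth grid ", paste(tdim[1:2], collapse = "x"))
  }
  x <- truth$intensities
  if (profile$blur_fwhm > 0) {
    sg <- profile$blur_fwhm / (2 * sqrt(2 * log(2)))
    x <- gaussian_smooth(x, c(sg, sg, 0), truth$spacing)
  }
  new_dim <- c(profile$matrix, tdim[3L])
  extent <- tdim * truth$spacing
  new_spacing <- extent / new_dim
  if (!identical(new_dim, tdim)) {
    x <- resample_linear(x, truth$spacing, new_dim, new_spacing)
    mask <- resample_nn(truth$mask, truth$spacing, new_dim, new_spacing)
  } else {
    mask <- truth$mask
  }
  set.seed(seed)
  if (profile$noise_sigma > 0) {
    inm <- truth$mask != 0
    contrast <- mean(truth$intensities[inm]) -
                mean(truth$intensities[!inm])
    x <- x + stats::rnorm(length(x),
                          sd = profile$noise_sigma * abs(contrast))
  }
  if (profile$mask_jitter > 0L) {
    mask <- jitter_mask(mask, seed = seed + 1L)
  }
  meta <- truth$meta
  meta$sequence <- profile$name
  volume_with_mask(array(x, dim = new_dim), new_spacing,
                   mask = mask, meta = meta)
}

#' Simulate per-feature paired measurements with known concordance
#'
#' For each feature, draws `n_subjects` pairs from a bivariate normal with
#' equal means (0), unit variances and correlation `target_ccc`; with
#' equal moments Lin's population CCC equals the correlation, so the
#' estimator can be tested for parameter recovery. Deterministic given
#' `seed`.
#'
#' @param n_subjects number of pairs, >= 3.
#' @param n_features number of simulated features.
#' @param target_ccc scalar or length-`n_features` vector in \[0, 1\].
#' @param seed integer seed.
#' @return object of class `PairedFeatureTable`: list with `x`, `y`
#'   (n_subjects x n_features matrices), `features`, `target_ccc` and
#'   `stratum`.
#' @export
simulate_feature_pairs <- function(n_subjects, n_features, target_ccc,
                                   seed) {
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  if (any(target_ccc < 0 | target_ccc > 1)) {
    stop("target_ccc must lie in [0, 1]")
  }
  rho <- rep_len(target_ccc, n_features)
  set.seed(seed)
  z1 <- matrix(stats::rnorm(n_subjects * n_features), n_subjects)
  z2 <- matrix(stats::rnorm(n_subjects * n_features), n_subjects)
  x <- z1
  y <- sweep(z1, 2L, rho, "*") +
       sweep(z2, 2L, sqrt(1 - rho^2), "*")
  feats <- sprintf("feature_%04d", seq_len(n_features))
  colnames(x) <- colnames(y) <- feats
  structure(list(x = x, y = y, features = feats, target_ccc = rho,
                 stratum = list(source = "simulate_feature_pairs")),
            class = "PairedFeatureTable")
}

#' Write a demo cohort to disk
#'
#' Mirrors the two-group design: group 1 subjects get conventional + EPI +
#' ETL renditions, group 2 get conventional + ETL + TR renditions. Each
#' subject carries one lesion labelled acute or chronic (alternating).
#' Volumes and masks are written as NIfTI, plus a cohort manifest CSV
#' (subject_id, group, lesion_class, sequence, volume_path, mask_path).
#' All randomness flows from `seed` via per-subject/per-profile offsets;
#' reruns are byte-identical.
#'
#' @param n_per_group subjects per group (0 allowed: empty manifest).
#' @param seed integer cohort seed.
#' @param outdir output directory (created if needed).
#' @param scale acquisition-matrix scale factor passed to
#'   [acquisition_profiles()]; default 0.25 for desk-scale runs.
#' @param n_slices slice count of the truth grid (default 6).
#' @param fov_mm in-plane field of view in mm (default 210).
#' @return the manifest data frame, invisibly; also written to
#'   `outdir/manifest.csv`.
#' @export
build_demo_cohort <- function(n_per_group, seed, outdir, scale = 0.25,
                              n_slices = 6L, fov_mm = 210) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  profiles <- acquisition_profiles(scale)
  groups <- list(first = c("conventional", "EPI", "ETL"),
                 second = c("conventional", "ETL", "TR"))
  truth_n <- max(vapply(profiles, function(p) max(p$matrix), 0L))
  shape <- c(truth_n, truth_n, as.integer(n_slices))
  spacing <- c(fov_mm / truth_n, fov_mm / truth_n, 7)  # 5 mm + 2 mm gap
  rows <- list()
  subj <- 0L
  for (gname in names(groups)) {
    for (j in seq_len(n_per_group)) {
      subj <- subj + 1L
      sid <- sprintf("sub-%03d", subj)
      lesion_class <- if (subj %% 2L == 1L) "acute" else "chronic"
      sseed <- (seed * 7919L + subj * 1009L) %% 2000000000L
      set.seed(sseed)
      radius <- stats::runif(1, 10, 13)
      ctr <- (shape - 1) / 2 +
        stats::runif(3, -2, 2) * c(1, 1, 0.2)
      spec <- lesion_spec(center = ctr, radius_mm = radius,
                          texture_amplitude = 12,
                          texture_correlation_length_mm = 6,
                          contrast = 60)
      truth <- make_phantom(spec, shape, spacing, seed = sseed + 1L,
                            meta = list(subject_id = sid, group = gname,
                                        lesion_class = lesion_class))
      sdir <- file.path(outdir, sid)
      dir.create(sdir, showWarnings = FALSE)
      for (sq in groups[[gname]]) {
        prof <- profiles[[sq]]
        dseed <- (sseed + 37L * prof$seed_offset + 11L) %% 2000000000L
        rendition <- degrade_acquisition(truth, prof, seed = dseed)
        vpath <- file.path(sdir, paste0(sid, "_", sq, ".nii.gz"))
        mpath <- file.path(sdir, paste0(sid, "_", sq, "_mask.nii.gz"))
        write_volume(rendition, vpath, mask_path = mpath)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = gname, lesion_class = lesion_class,
          sequence = sq, volume_path = vpath, mask_path = mpath,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               lesion_class = character(), sequence = character(),
               volume_path = character(), mask_path = character(),
               stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
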