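#' Volume-with-mask container
#'
#' The atomic extraction input: a 3D intensity grid, its voxel spacing in
#' mm, an optional binary region-of-interest mask on the same grid, and
#' provenance metadata (subject id, sequence label, lesion class, group).
#' Grids are indexed `(x, y, slice)`, 0-based in all voxel-coordinate
#' arguments; physical extents derive from `dim * spacing`.
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in mm, all > 0.
#' @param mask optional 3D array of the same shape; any nonzero voxel is
#'   foreground.
#' @param meta named list; recognised entries: `subject_id`, `sequence`,
#'   `lesion_class` ("acute" or "chronic"), `group`.
#' @return an object of class `VolumeWithMask`.
#' @export
volume_with_mask <- function(intensities, spacing, mask = NULL,
                             meta = list()) {
  if (length(dim(intensities)) != 3L) {
    stop("expected 3D volume, got array with ",
         length(dim(intensities)), " dimension(s)")
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (mm)")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensities))) {
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match volume shape ",
           paste(dim(intensities), collapse = "x"))
    }
    mask <- array(as.integer(mask != 0), dim = dim(mask))
  }
  structure(list(intensities = intensities, spacing = spacing,
                 mask = mask, meta = meta),
            class = "VolumeWithMask")
}

#' @export
print.VolumeWithMask <- function(x, ...) {
  cat("<VolumeWithMask> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  if (!is.null(x$mask)) {
    cat("  mask: ", sum(x$mask), " foreground voxels\n", sep = "")
  }
  if (length(x$meta)) {
    cat("  meta: ", paste(names(x$meta), unlist(x$meta), sep = "=",
                          collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read the intensity part of a VolumeWithMask from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz) holding a 3D image.
#' @param meta optional metadata list, stored as-is.
#' @return a `VolumeWithMask` with `mask = NULL`.
#' @export
read_volume <- function(path, meta = list()) {
  nii <- read_nifti(path)
  volume_with_mask(nii$data, nii$spacing, mask = NULL, meta = meta)
}

#' Write a volume (and optionally its mask) to NIfTI
#'
#' Intensities are stored as float64; masks as uint8.
#'
#' @param volume a `VolumeWithMask`.
#' @param path output path for the intensities.
#' @param mask_path optional output path for the mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, mask_path = NULL) {
  stopifnot(inherits(volume, "VolumeWithMask"))
  write_nifti(volume$intensities, path, spacing = volume$spacing,
              datatype = 64L)
  if (!is.null(mask_path)) {
    if (is.null(volume$mask)) stop("volume carries no mask to write")
    write_nifti(volume$mask, mask_path, spacing = volume$spacing,
                datatype = 2L)
  }
  invisible(path)
}

#' Read a binary ROI mask aligned to a reference volume
#'
#' Any nonzero voxel becomes foreground. When the mask grid differs from
#' the reference grid, the two must cover the same physical extent (within
#' half a reference voxel per axis) and the mask is resampled to the
#' reference grid by nearest neighbour, which preserves binarity. An
#' all-zero mask is accepted here; feature extraction refuses it later.
#'
#' @param path NIfTI mask file.
#' @param reference `VolumeWithMask` defining the target grid.
#' @return 3D integer array of 0/1 on the reference grid.
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "VolumeWithMask"))
  nii <- read_nifti(path)
  m <- array(as.integer(nii$data != 0), dim = dim(nii$data))
  ref_dim <- dim(reference$intensities)
  if (!identical(dim(m), ref_dim)) {
    ext_m <- dim(m) * nii$spacing
    ext_r <- ref_dim * reference$spacing
    if (any(abs(ext_m - ext_r) > reference$spacing / 2)) {
      stop("mask geometry ", paste(dim(m), collapse = "x"), " @ ",
           paste(signif(nii$spacing, 4), collapse = "x"),
           " mm is incompatible with reference ",
           paste(ref_dim, collapse = "x"), " @ ",
           paste(signif(reference$spacing, 4), collapse = "x"), " mm")
    }
    m <- resample_nn(m, nii$spacing, ref_dim, reference$spacing)
  }
  m
}

# Continuous source index of each target voxel centre along one axis.
.axis_map <- function(n_target, d_target, d_source) {
  (seq_len(n_target) - 0.5) * d_target / d_source - 0.5
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Grids are assumed co-aligned in physical space with matching extents;
#' each target voxel takes the value of the source voxel whose centre is
#' nearest to its own. Used for binary masks.
#'
#' @param arr 3D array.
#' @param src_spacing,target_spacing voxel sizes in mm.
#' @param target_dim integer length-3.
#' @return resampled 3D array.
#' @export
resample_nn <- function(arr, src_spacing, target_dim, target_spacing) {
  src_dim <- dim(arr)
  idx <- lapply(1:3, function(a) {
    u <- round(.axis_map(target_dim[a], target_spacing[a], src_spacing[a]))
    pmin(pmax(as.integer(u), 0L), src_dim[a] - 1L) + 1L
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Trilinear resampling onto a target grid
#'
#' Separable linear interpolation between voxel centres, with edge
#' clamping. Used for intensity volumes by the synthetic acquisition
#' degradation.
#'
#' @inheritParams resample_nn
#' @return resampled 3D double array.
#' @export
resample_linear <- function(arr, src_spacing, target_dim, target_spacing) {
  src_dim <- dim(arr)
  ax <- lapply(1:3, function(a) {
    u <- .axis_map(target_dim[a], target_spacing[a], src_spacing[a])
    i0 <- floor(u)
    w <- u - i0
    i0 <- pmin(pmax(as.integer(i0), 0L), src_dim[a] - 1L)
    i1 <- pmin(i0 + 1L, src_dim[a] - 1L)
    w[i1 == i0] <- 0
    list(i0 = i0 + 1L, i1 = i1 + 1L, w = w)
  })
  a1 <- ax[[1]]; a2 <- ax[[2]]; a3 <- ax[[3]]
  # axis 1: weights vary along dim 1, where recycling is direct
  v <- arr[a1$i0, , , drop = FALSE] * (1 - a1$w) +
       arr[a1$i1, , , drop = FALSE] * a1$w
  v <- sweep(v[, a2$i0, , drop = FALSE], 2L, 1 - a2$w, "*") +
       sweep(v[, a2$i1, , drop = FALSE], 2L, a2$w, "*")
  v <- sweep(v[, , a3$i0, drop = FALSE], 3L, 1 - a3$w, "*") +
       sweep(v[, , a3$i1, drop = FALSE], 3L, a3$w, "*")
  v
}

#' Voxelwise intersection of two binary masks
#'
#' Both masks must already live on the same grid (resample first if not).
#' The result is a subset of both inputs; the operation is commutative,
#' associative and idempotent.
#'
#' @param a,b 3D binary arrays of identical shape.
#' @return 3D integer 0/1 array.
#' @export
intersect_masks <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("cannot intersect masks of shape ",
         paste(dim(a), collapse = "x"), " and ",
         paste(dim(b), collapse = "x"))
  }
  array(as.integer(a != 0 & b != 0), dim = dim(a))
}

#' Enumerate extraction tasks over a cohort manifest
#'
#' Mirrors the study's 14-mask design. Per subject, the conventional
#' sequence contributes a whole-ROI task, each fast sequence contributes a
#' whole-ROI task, and each (conventional, fast) pair contributes two
#' intersection-ROI tasks: the intersection mask applied on the
#' conventional image and on the fast image. With two fast sequences per
#' group that is 3 whole + 4 intersection = 7 mask roles per group, 14
#' across two groups.
#'
#' @param manifest data frame with columns `subject_id`, `group`,
#'   `lesion_class`, `sequence`, `volume_path`, `mask_path` (one row per
#'   subject x sequence).
#' @param reference label of the reference sequence (default
#'   "conventional").
#' @return data frame of tasks with columns `subject_id`, `group`,
#'   `lesion_class`, `sequence` (the image the features are read from),
#'   `mask_kind` ("whole" or "intersection"), `pairing` (for intersection
#'   tasks, the fast sequence whose mask is intersected with the
#'   reference; for whole tasks, equal to `sequence`) and `role`
#'   (the distinct (group, sequence, mask_kind, pairing) label).
#' @export
enumerate_mask_set <- function(manifest, reference = "conventional") {
  cols <- c("subject_id", "group", "lesion_class", "sequence")
  missing_cols <- setdiff(cols, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- list()
  for (sid in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == sid, , drop = FALSE]
    seqs <- unique(rows$sequence)
    if (!reference %in% seqs) {
      warning("subject ", sid, " lacks the reference sequence '",
              reference, "'; skipped")
      next
    }
    fast <- setdiff(seqs, reference)
    grp <- rows$group[1L]
    lc <- rows$lesion_class[1L]
    add <- function(sequence, mask_kind, pairing) {
      data.frame(subject_id = sid, group = grp, lesion_class = lc,
                 sequence = sequence, mask_kind = mask_kind,
                 pairing = pairing, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- add(reference, "whole", reference)
    for (f in fast) {
      out[[length(out) + 1L]] <- add(f, "whole", f)
      out[[length(out) + 1L]] <- add(reference, "intersection", f)
      out[[length(out) + 1L]] <- add(f, "intersection", f)
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), group = character(),
                      lesion_class = character(), sequence = character(),
                      mask_kind = character(), pairing = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  tasks <- do.call(rbind, out)
  tasks$role <- paste(tasks$group, tasks$sequence, tasks$mask_kind,
                      tasks$pairing, sep = "|")
  rownames(tasks) <- NULL
  tasks
}
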