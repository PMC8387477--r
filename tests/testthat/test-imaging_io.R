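test_that("NIfTI write-then-read round-trips intensities and spacing", {
  arr <- array(as.double(1:32), dim = c(4, 4, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(arr, path, spacing = c(1, 1, 5))
  nii <- read_nifti(path)
  expect_identical(nii$data, arr)          # float64: bit-exact
  expect_equal(nii$spacing, c(1, 1, 5))

  vol <- volume_with_mask(arr, c(1, 1, 5),
                          mask = array(rep(0:1, 16), dim = c(4, 4, 2)))
  vpath <- withr::local_tempfile(fileext = ".nii")
  mpath <- withr::local_tempfile(fileext = ".nii")
  write_volume(vol, vpath, mask_path = mpath)
  back <- read_volume(vpath)
  expect_identical(back$intensities, arr)
  expect_identical(read_mask(mpath, back), vol$mask)
})

test_that("read_volume rejects non-3D images and missing files", {
  path <- withr::local_tempfile(fileext = ".nii")
  # hand-build a 2D file by writing a 3D one and patching dim[0] and dim[3]
  write_nifti(array(0, dim = c(4, 4, 1)), path)
  raw_bytes <- readBin(path, "raw", file.size(path))
  raw_bytes[41:42] <- writeBin(2L, raw(), size = 2, endian = "little")
  writeBin(raw_bytes, path)
  expect_error(read_volume(path), "expected 3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
})

test_that("volume_with_mask enforces its invariants", {
  arr <- array(0, dim = c(3, 3, 2))
  expect_error(volume_with_mask(matrix(0, 3, 3), c(1, 1, 1)), "3D")
  expect_error(volume_with_mask(arr, c(1, -1, 1)), "positive")
  expect_error(volume_with_mask(arr, c(1, 1, 1),
                                mask = array(0, dim = c(3, 3, 3))),
               "shape")
  v <- volume_with_mask(arr, c(1, 1, 1),
                        mask = array(255, dim = c(3, 3, 2)))
  expect_true(all(v$mask %in% 0:1))
})

test_that("read_mask binarizes and nearest-neighbour resamples", {
  m <- array(0L, dim = c(4, 4, 2))
  m[2, 3, 1] <- 255L                        # nonzero values become 1
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(m, path, spacing = c(1, 1, 5), datatype = 2L)
  ref <- volume_with_mask(array(0, dim = c(4, 4, 2)), c(1, 1, 5))
  got <- read_mask(path, ref)
  expect_identical(sort(unique(as.vector(got))), 0:1)
  expect_equal(sum(got), 1)

  # 2x2 source mask on the extent of a 4x4 reference: every source voxel
  # maps to a 2x2 block, so the foreground count quadruples
  m2 <- array(0L, dim = c(2, 2, 1)); m2[1, 2, 1] <- 1L
  p2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(m2, p2, spacing = c(2, 2, 5), datatype = 2L)
  ref2 <- volume_with_mask(array(0, dim = c(4, 4, 1)), c(1, 1, 5))
  up <- read_mask(p2, ref2)
  expect_equal(sum(up), 4)
  expect_equal(up[1:2, 3:4, 1], matrix(1L, 2, 2))

  # incompatible physical extents must fail loudly
  ref3 <- volume_with_mask(array(0, dim = c(4, 4, 1)), c(3, 3, 5))
  expect_error(read_mask(p2, ref3), "incompatible")

  # all-zero masks are accepted at read time
  z <- withr::local_tempfile(fileext = ".nii")
  write_nifti(array(0L, dim = c(4, 4, 2)), z, spacing = c(1, 1, 5),
              datatype = 2L)
  expect_equal(sum(read_mask(z, ref)), 0)
})

test_that("intersect_masks matches hand enumeration and its algebra", {
  plus <- array(0L, dim = c(3, 3, 1))
  plus[2, , 1] <- 1L; plus[, 2, 1] <- 1L     # 5-voxel plus sign
  square <- array(1L, dim = c(3, 3, 1))
  expect_identical(intersect_masks(plus, square), plus)
  expect_equal(sum(intersect_masks(plus, square)), 5)

  expect_identical(intersect_masks(plus, plus), plus)      # idempotent
  a <- array(c(1L, 0L), dim = c(3, 3, 1))
  b <- array(c(0L, 1L), dim = c(3, 3, 1))
  expect_equal(sum(intersect_masks(a, b)), 0)              # disjoint
  expect_error(intersect_masks(plus, array(1L, dim = c(2, 2, 1))),
               "shape")

  # commutative/associative/bounded on random grids
  for (s in 1:10) {
    set.seed(s)
    g <- function() array(as.integer(runif(27) < .5), dim = c(3, 3, 3))
    x <- g(); y <- g(); z <- g()
    expect_identical(intersect_masks(x, y), intersect_masks(y, x))
    expect_identical(intersect_masks(intersect_masks(x, y), z),
                     intersect_masks(x, intersect_masks(y, z)))
    expect_lte(sum(intersect_masks(x, y)), min(sum(x), sum(y)))
  }
})

test_that("enumerate_mask_set reproduces the 14-role design", {
  mk <- function(sid, grp, seqs) {
    data.frame(subject_id = sid, group = grp, lesion_class = "acute",
               sequence = seqs, volume_path = "v", mask_path = "m",
               stringsAsFactors = FALSE)
  }
  two_group <- rbind(mk("s1", "first", c("conventional", "EPI", "ETL")),
                     mk("s2", "second", c("conventional", "ETL", "TR")))
  tasks <- enumerate_mask_set(two_group)
  expect_equal(length(unique(tasks$role)), 14)
  expect_equal(nrow(tasks[tasks$subject_id == "s1", ]), 7)
  expect_equal(sum(tasks$mask_kind == "whole"), 6)
  expect_equal(sum(tasks$mask_kind == "intersection"), 8)

  # single group, one fast sequence: 2 whole + 2 intersection roles
  one_fast <- mk("s1", "first", c("conventional", "EPI"))
  expect_equal(length(unique(enumerate_mask_set(one_fast)$role)), 4)

  empty <- two_group[0, ]
  expect_equal(nrow(enumerate_mask_set(empty)), 0)

  no_ref <- mk("s9", "first", c("EPI", "ETL"))
  expect_warning(t9 <- enumerate_mask_set(no_ref), "lacks the reference")
  expect_equal(nrow(t9), 0)
})

test_that("resample_linear agrees with hand interpolation on a ramp", {
  # 4x4 ramp slice, halved matrix: each output voxel centre sits midway
  # between two source centres along x and y
  ramp <- array(0, dim = c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) ramp[x, y, 1] <- x + 10 * y
  out <- resample_linear(ramp, c(1, 1, 1), c(2, 2, 1), c(2, 2, 1))
  # target centre (0.5*2 = 1.0 physical) -> source index u = 0.5 (0-based)
  # between source voxels 1 and 2 -> mean of the 2x2 corner block
  expect_equal(out[1, 1, 1], mean(ramp[1:2, 1:2, 1]))
  expect_equal(out[2, 2, 1], mean(ramp[3:4, 3:4, 1]))
  expect_equal(out[1, 2, 1], mean(ramp[1:2, 3:4, 1]))
})
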