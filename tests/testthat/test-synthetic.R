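test_that("make_phantom is deterministic and its mask matches enumeration", {
  spec <- lesion_spec(center = c(15, 15, 2), radius_mm = 10,
                      contrast = 60)
  shape <- c(32, 32, 5); spacing <- c(2, 2, 5)
  a <- make_phantom(spec, shape, spacing, seed = 7)
  b <- make_phantom(spec, shape, spacing, seed = 7)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$mask, b$mask)

  # brute-force voxel-centre enumeration of the sphere
  cnt <- 0
  for (x in 0:31) for (y in 0:31) for (k in 0:4) {
    d2 <- (2 * (x - 15))^2 + (2 * (y - 15))^2 + (5 * (k - 2))^2
    if (d2 <= 100) cnt <- cnt + 1
  }
  expect_equal(sum(a$mask), cnt)

  expect_error(make_phantom(spec, c(8, 8, 2), c(1, 1, 1), seed = 1),
               "does not fit")
  expect_error(lesion_spec(c(1, 1, 1), radius_mm = -1), "radius")
  expect_error(lesion_spec(c(1, 1, 1), 5, contrast = 0), "contrast")
})

test_that("constant lesion hits every degenerate path but still extracts", {
  spec <- lesion_spec(center = c(15, 15, 2), radius_mm = 10,
                      texture_amplitude = 0, contrast = 60)
  ph <- make_phantom(spec, c(32, 32, 5), c(2, 2, 5), seed = 3,
                     background_amplitude = 0)
  vals <- ph$intensities[ph$mask == 1]
  expect_equal(length(unique(vals)), 1)      # constant lesion
  disc <- discretize_fixed_bins(ph)
  expect_true(disc$degenerate)
  fv <- extract_all(ph)
  expect_length(fv, 595)
  # degenerate statistics are NA, defined ones finite
  expect_true(is.na(fv[["original_firstorder_skewness"]]))
  expect_true(is.na(fv[["original_glcm_correlation"]]))
  expect_equal(fv[["original_glcm_contrast"]], 0)
  expect_true(all(is.finite(fv[!is.na(fv)])))
})

test_that("degrade_acquisition: identity profile is exact, seeds reproduce", {
  ph <- tiny_phantom(seed = 11)
  idp <- identity_profile(dim(ph$intensities))
  out <- degrade_acquisition(ph, idp, seed = 5)
  expect_identical(out$intensities, ph$intensities)
  expect_identical(out$mask, ph$mask)

  prof <- acquisition_profile("noisy", dim(ph$intensities)[1:2],
                              noise_sigma = 0.1)
  n1 <- degrade_acquisition(ph, prof, seed = 5)
  n2 <- degrade_acquisition(ph, prof, seed = 5)
  n3 <- degrade_acquisition(ph, prof, seed = 6)
  expect_identical(n1$intensities, n2$intensities)
  expect_false(identical(n1$intensities, n3$intensities))

  big <- acquisition_profile("big", c(64, 64))
  expect_error(degrade_acquisition(ph, big, seed = 1), "exceeds")
})

test_that("matrix halving equals hand linear interpolation (no blur/noise)", {
  # ramp truth so interpolation is exactly computable
  prof <- acquisition_profile("half", c(16, 16), mask_jitter = 0L)
  arr16 <- array(0, dim = c(32, 32, 1))
  for (x in 1:32) for (y in 1:32) arr16[x, y, 1] <- x + 100 * y
  mask16 <- array(1L, dim = c(32, 32, 1))
  truth16 <- volume_with_mask(arr16, c(1, 1, 5), mask = mask16)
  got <- degrade_acquisition(truth16, prof, seed = 1)
  expect_equal(dim(got$intensities), c(16, 16, 1))
  # output voxel i covers source centres 2i-1, 2i: linear interp midway
  manual <- outer(seq(1.5, 31.5, by = 2), 100 * seq(1.5, 31.5, by = 2),
                  "+")
  expect_equal(got$intensities[, , 1], manual)
  expect_equal(got$spacing[1:2], c(2, 2))
})

test_that("mask jitter perturbs only the boundary and respects the seed", {
  ph <- tiny_phantom(seed = 21)
  prof <- acquisition_profile("jit", dim(ph$intensities)[1:2],
                              mask_jitter = 1L)
  j1 <- degrade_acquisition(ph, prof, seed = 9)
  j2 <- degrade_acquisition(ph, prof, seed = 9)
  expect_identical(j1$mask, j2$mask)
  expect_identical(j1$intensities, ph$intensities)  # no noise/blur
  expect_false(identical(j1$mask, ph$mask))         # masks differ
  changed <- which(j1$mask != ph$mask, arr.ind = TRUE)
  # every changed voxel touches the original boundary (4-neighbourhood)
  for (r in seq_len(nrow(changed))) {
    x <- changed[r, 1]; y <- changed[r, 2]; k <- changed[r, 3]
    nb <- c()
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      x2 <- x + d[1]; y2 <- y + d[2]
      if (x2 >= 1 && x2 <= dim(ph$mask)[1] &&
          y2 >= 1 && y2 <= dim(ph$mask)[2]) {
        nb <- c(nb, ph$mask[x2, y2, k])
      }
    }
    expect_true(length(unique(c(nb, ph$mask[x, y, k]))) > 1)
  }
})

test_that("simulate_feature_pairs recovers the target concordance", {
  # degenerate target: identical columns
  p1 <- simulate_feature_pairs(10, 3, target_ccc = 1, seed = 2)
  expect_identical(p1$x, p1$y)
  expect_equal(lin_ccc(p1$x[, 1], p1$y[, 1]), 1, ignore_attr = TRUE)

  expect_error(simulate_feature_pairs(2, 3, 0.5, seed = 1), ">= 3")
  expect_error(simulate_feature_pairs(10, 3, 1.2, seed = 1), "\\[0, 1\\]")

  # large-n consistency of Lin's estimator (tolerance 0.02)
  for (target in c(0.5, 0.85, 0.95)) {
    pp <- simulate_feature_pairs(5000, 4, target_ccc = target, seed = 101)
    est <- vapply(1:4, function(j) lin_ccc(pp$x[, j], pp$y[, j]), 0)
    expect_true(all(abs(est - target) < 0.02),
                info = paste("target", target))
  }

  # determinism
  a <- simulate_feature_pairs(50, 5, 0.7, seed = 3)
  b <- simulate_feature_pairs(50, 5, 0.7, seed = 3)
  expect_identical(a$x, b$x); expect_identical(a$y, b$y)
})

test_that("build_demo_cohort writes the expected tree deterministically", {
  d1 <- withr::local_tempdir()
  m1 <- build_demo_cohort(1, seed = 5, outdir = d1, scale = 0.125)
  expect_equal(nrow(m1), 6)                 # 2 subjects x 3 sequences
  expect_true(all(file.exists(m1$volume_path)))
  expect_true(all(file.exists(m1$mask_path)))
  expect_setequal(unique(m1$group), c("first", "second"))
  expect_setequal(m1$sequence[m1$group == "first"],
                  c("conventional", "EPI", "ETL"))
  expect_setequal(m1$sequence[m1$group == "second"],
                  c("conventional", "ETL", "TR"))

  d2 <- withr::local_tempdir()
  m2 <- build_demo_cohort(1, seed = 5, outdir = d2, scale = 0.125)
  # same seed: identical image payloads
  for (i in seq_len(nrow(m1))) {
    a <- read_nifti(m1$volume_path[i]); b <- read_nifti(m2$volume_path[i])
    expect_identical(a$data, b$data)
  }
  d3 <- withr::local_tempdir()
  expect_equal(nrow(build_demo_cohort(0, seed = 1, outdir = d3)), 0)
})

test_that("noise monotonically degrades the median feature CCC", {
  # 3 noise levels x fixed seeds; median CCC across features should fall
  n_sub <- 4
  phs <- lapply(seq_len(n_sub), function(i)
    tiny_phantom(seed = 300 + i,
                 meta = list(subject_id = paste0("s", i))))
  ref <- lapply(seq_len(n_sub), function(i) {
    extract_all(degrade_acquisition(
      phs[[i]], identity_profile(c(32, 32)), seed = 1))
  })
  xm <- do.call(rbind, lapply(ref, as.numeric))
  med_ccc <- vapply(c(0, 0.05, 0.25), function(ns) {
    prof <- acquisition_profile("n", c(32, 32), noise_sigma = ns,
                                mask_jitter = 0L)
    fast <- lapply(seq_len(n_sub), function(i) {
      extract_all(degrade_acquisition(phs[[i]], prof, seed = 400 + i))
    })
    ym <- do.call(rbind, lapply(fast, as.numeric))
    ccc <- vapply(seq_len(ncol(xm)),
                  function(j) as.numeric(lin_ccc(xm[, j], ym[, j])), 0)
    stats::median(ccc, na.rm = TRUE)
  }, 0)
  expect_equal(med_ccc[1], 1)
  expect_true(med_ccc[2] >= med_ccc[3])
  expect_lt(med_ccc[3], 1)
})
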