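test_that("constant slice: LL preserves the constant, details vanish", {
  arr <- array(3, dim = c(8, 8, 2))
  sb <- wavelet_decompose(arr)
  expect_length(sb, 8)
  expect_identical(names(sb), c("LL", "LH", "HL", "HH",
                                "LL2", "LH2", "HL2", "HH2"))
  expect_equal(sb$LL, array(6, dim = c(8, 8, 2)))    # gain 2 = sqrt(2)^2
  for (nm in c("LH", "HL", "HH", "LH2", "HL2", "HH2")) {
    expect_equal(max(abs(sb[[nm]])), 0, info = nm)
  }
  expect_error(wavelet_decompose(array(0, dim = c(4, 4, 1))), "small")
})

test_that("subbands match a brute-force separable convolution", {
  set.seed(42)
  arr <- array(rnorm(8 * 8), dim = c(8, 8, 1))
  sb <- wavelet_decompose(arr)
  h <- c(1, 1) / sqrt(2); g <- c(1, -1) / sqrt(2)
  up <- function(v) { o <- numeric(2 * length(v) - 1)
                      o[seq(1, length(o), 2)] <- v; o }
  expect_equal(sb$LL[, , 1], bf_filter2_sym(arr[, , 1], h, h))
  expect_equal(sb$LH[, , 1], bf_filter2_sym(arr[, , 1], h, g))
  expect_equal(sb$HL[, , 1], bf_filter2_sym(arr[, , 1], g, h))
  expect_equal(sb$HH[, , 1], bf_filter2_sym(arr[, , 1], g, g))
  ll <- bf_filter2_sym(arr[, , 1], h, h)
  expect_equal(sb$LL2[, , 1], bf_filter2_sym(ll, up(h), up(h)))
  expect_equal(sb$HH2[, , 1], bf_filter2_sym(ll, up(g), up(g)))
})

test_that("horizontal step: x-detail energy concentrates at the step", {
  arr <- array(0, dim = c(8, 8, 1))
  arr[5:8, , 1] <- 10                      # step along x between 4 and 5
  sb <- wavelet_decompose(arr)
  hl <- sb$HL[, , 1]                       # high-pass along x
  expect_true(all(abs(hl[4, ]) > 0))
  expect_equal(max(abs(hl[c(1:3, 5:8), ])), 0)
  expect_equal(max(abs(sb$LH[, , 1])), 0)  # no variation along y
})

test_that("the transform is linear per subband", {
  set.seed(7)
  x <- array(rnorm(128), dim = c(8, 8, 2))
  y <- array(rnorm(128), dim = c(8, 8, 2))
  a <- 2.5; b <- -1.25
  sb_mix <- wavelet_decompose(a * x + b * y)
  sb_x <- wavelet_decompose(x); sb_y <- wavelet_decompose(y)
  for (nm in names(sb_mix)) {
    expect_equal(sb_mix[[nm]], a * sb_x[[nm]] + b * sb_y[[nm]], info = nm)
  }
})

test_that("undecimated transform commutes with in-plane translation", {
  ph <- tiny_phantom(seed = 77)
  shift <- function(arr, dx, dy) {
    out <- array(0, dim = dim(arr))
    n <- dim(arr)
    out[(1 + dx):n[1], (1 + dy):n[2], ] <-
      arr[1:(n[1] - dx), 1:(n[2] - dy), , drop = FALSE]
    out
  }
  dx <- 2L; dy <- 3L
  vol_t <- volume_with_mask(shift(ph$intensities, dx, dy), ph$spacing,
                            mask = shift(ph$mask, dx, dy))
  f0 <- texture_features_61(ph, ng = 16)
  # the interior lesion is far from the boundary, so translated features
  # computed on translated subbands must agree
  sb0 <- wavelet_decompose(ph)
  sb1 <- wavelet_decompose(vol_t)
  w0 <- wavelet_feature_block(sb0, ph$mask, ph$spacing, ng = 16)
  w1 <- wavelet_feature_block(sb1, vol_t$mask, vol_t$spacing, ng = 16)
  expect_equal(w0, w1, tolerance = 1e-10)
  expect_length(w0, 488)
})

test_that("wavelet block structure: 8 x 61 named features", {
  ph <- tiny_phantom(seed = 5)
  sb <- wavelet_decompose(ph)
  w <- wavelet_feature_block(sb, ph$mask, ph$spacing)
  expect_length(w, 488)
  for (nm in names(sb)) {
    sel <- startsWith(names(w), paste0("wavelet_", nm, "_"))
    expect_equal(sum(sel), 61, info = nm)
    fams <- sub(paste0("^wavelet_", nm, "_([a-z]+)_.*$"), "\\1",
                names(w)[sel])
    expect_equal(as.vector(table(fams)[c("secondorder", "glcm", "glrlm",
                                         "lbp", "glszm", "ngtdm")]),
                 c(5, 22, 11, 5, 13, 5))
  }
})
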