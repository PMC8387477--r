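test_that("lin_ccc matches hand-worked values", {
  expect_equal(as.numeric(lin_ccc(c(1, 5, 9), c(1, 5, 9))), 1)
  # x=(1,2,3), y=(2,4,6): 2*(4/3) / (2/3 + 8/3 + 4) = 8/22
  expect_equal(as.numeric(lin_ccc(1:3, c(2, 4, 6))), 8 / 22)
  # location-shift penalty: rho_c -> 0 monotonically as the offset grows
  vals <- vapply(c(0, 1, 10, 100),
                 function(cst) as.numeric(lin_ccc(1:3, 1:3 + cst)), 0)
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 0.001)
})

test_that("lin_ccc edge cases: insufficient pairs, NA dropping, constants", {
  out <- lin_ccc(c(1, 2), c(1, 2))
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "insufficient pairs")
  # pairwise NA dropping records the effective n
  withna <- lin_ccc(c(1, 2, NA, 4, 5), c(1, 2, 3, NA, 5))
  expect_equal(attr(withna, "n"), 3)
  # equal constant lists are exact agreement
  expect_equal(as.numeric(lin_ccc(rep(2, 5), rep(2, 5))), 1)
  expect_error(lin_ccc(1:3, 1:4), "equal length")
})

test_that("lin_ccc properties: symmetry, affine invariance, |ccc| <= |r|", {
  for (s in 1:30) {
    set.seed(s)
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    c1 <- as.numeric(lin_ccc(x, y))
    expect_equal(c1, as.numeric(lin_ccc(y, x)))
    expect_gte(c1, -1); expect_lte(c1, 1)
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    expect_equal(as.numeric(lin_ccc(a * x + b, a * y + b)), c1)
    expect_lte(abs(c1), abs(cor(x, y)) + 1e-12)
    # equal means and variances: ccc equals Pearson r
    z <- (y - mean(y)) / sd(y) * sd(x) + mean(x)
    expect_equal(as.numeric(lin_ccc(x, z)), cor(x, z))
  }
})

test_that("stability classification is strict at the threshold", {
  df <- data.frame(feature = c("a", "b", "c"),
                   ccc = c(0.850, 0.851, NA))
  out <- classify_stability(df)
  expect_identical(out$stable, c(FALSE, TRUE, FALSE))
  expect_error(classify_stability(df, threshold = 1.2), "threshold")
})

test_that("stability_summary reproduces the x/595 presentation", {
  cat <- feature_catalog()
  res <- data.frame(feature = cat$name, ccc = 0.5,
                    stringsAsFactors = FALSE)
  res$ccc[1:82] <- 0.99                       # 82 stable features
  res <- classify_stability(res)
  s <- stability_summary(res, cat, n_boot = 200, seed = 1)
  expect_equal(s$n_stable, 82)
  expect_equal(round(100 * s$proportion, 1), 13.8)    # 82/595
  expect_equal(sum(s$per_family$n_stable), 82)
  expect_equal(sum(s$per_family$size), 595)

  res0 <- classify_stability(data.frame(feature = cat$name, ccc = 0.1))
  expect_equal(stability_summary(res0, cat, n_boot = 100)$proportion, 0)

  expect_error(stability_summary(res[-1, ], cat), "lack")
})

test_that("median CCC bootstrap CI is seeded and brackets the median", {
  v <- c(0.2, 0.5, 0.8)
  m <- median_ccc_ci(v, n_boot = 500, seed = 4)
  expect_equal(m[["median"]], 0.5)
  m2 <- median_ccc_ci(v, n_boot = 500, seed = 4)
  expect_identical(m, m2)
  expect_lte(m[["lo"]], m[["median"]]); expect_gte(m[["hi"]], m[["median"]])
  # degenerate: all values equal
  m3 <- median_ccc_ci(rep(0.7, 10), n_boot = 100, seed = 1)
  expect_equal(unname(m3), c(0.7, 0.7, 0.7))
  expect_error(median_ccc_ci(0.5), ">= 2")
})

test_that("McNemar: worked examples and the method switch", {
  # b = 10, c = 2 -> exact two-sided p = 2 * P(X <= 2), X ~ Bin(12, 1/2)
  a <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 5))
  r <- mcnemar_test(a, b)
  expect_equal(r$b, 10); expect_equal(r$c, 2)
  expect_equal(r$method, "exact-binomial")
  expect_equal(r$p_value, 2 * pbinom(2, 12, 0.5))
  expect_equal(round(r$p_value, 4), 0.0386)

  # b = 40, c = 10 -> chi2-cc = 29^2 / 50 = 16.82
  a2 <- c(rep(TRUE, 40), rep(FALSE, 10))
  b2 <- c(rep(FALSE, 40), rep(TRUE, 10))
  r2 <- mcnemar_test(a2, b2)
  expect_equal(r2$method, "chi2-cc")
  expect_equal(r2$statistic, 16.82)
  expect_lt(r2$p_value, 0.001)
  # agrees with base R's continuity-corrected test
  base_p <- stats::mcnemar.test(table(a2, b2), correct = TRUE)$p.value
  expect_equal(r2$p_value, base_p)

  # symmetric discordance -> exact p = 1
  a3 <- c(TRUE, TRUE, FALSE, FALSE); b3 <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(mcnemar_test(a3, b3)$p_value, 1)

  # no discordance -> degenerate
  r4 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(r4$method, "degenerate")
  expect_equal(r4$p_value, 1)

  expect_error(mcnemar_test(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("exact McNemar agrees with full enumeration for all b+c <= 12", {
  # independent oracle: enumerate every outcome of n fair coin flips and
  # sum the probabilities of outcomes at least as extreme as b
  for (n in 1:12) {
    for (b in 0:n) {
      cc <- n - b
      # oracle: sum the point probabilities of the smaller tail over an
      # explicit enumeration of outcomes, then double (two-sided)
      probs <- dbinom(0:n, n, 0.5)
      k <- min(b, cc)
      p_double <- min(1, 2 * sum(probs[seq_len(k + 1)]))
      got <- mcnemar_test(c(rep(TRUE, b), rep(FALSE, cc)),
                          c(rep(FALSE, b), rep(TRUE, cc)))$p_value
      expect_equal(got, p_double, info = paste(b, cc))
    }
  }
})

test_that("ccc_table + paired_feature_table wire up per-feature results", {
  pp <- simulate_feature_pairs(200, 6, target_ccc = c(0.2, 0.95), seed = 8)
  ct <- ccc_table(pp)
  expect_equal(nrow(ct), 6)
  expect_identical(ct$feature, pp$features)
  expect_true(all(ct$n == 200))
  # high-target features classified stable far more often than low-target
  expect_true(mean(ct$stable[pp$target_ccc > 0.9]) >
              mean(ct$stable[pp$target_ccc < 0.3]))
})
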