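test_that("quantization bins equal-width over [0,1] with background zero", {
  v <- matrix(seq(0.05, 0.95, by = 0.1), 2, 5)
  q <- quantize(as_windowed(v), 10)
  expect_identical(sort(as.integer(q$levels)), 1:10)
  expect_identical(quantize(as_windowed(matrix(1, 2, 2)), 10)$levels[1, 1], 10L)
  bg <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  q2 <- quantize(as_windowed(matrix(0.5, 2, 2), bg), 10)
  expect_identical(q2$levels[1, 1], 0L)
  expect_error(quantize(as_windowed(v), 1), "n_grey")

  set.seed(12)
  u <- matrix(runif(1e5), 250, 400)
  qq <- quantize(as_windowed(u), 10)
  freq <- tabulate(qq$levels, 10) / 1e5
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("GLCM matches hand-enumerated pair counts", {
  q <- as_quantized(matrix(c(1L, 2L, 1L, 2L), 2, 2), 2) # rows [[1,1],[2,2]]
  g <- compute_glcm(q, 1, c(0, 45, 90, 135))
  # 12 ordered symmetric pairs: 0deg gives (1,1) and (2,2) twice each,
  # 90deg gives 2x(1,2)+2x(2,1), both diagonals give (1,2)/(2,1) once each
  expect_equal(g$p, matrix(c(2, 4, 4, 2) / 12, 2, 2))
  expect_equal(sum(g$p), 1)
  expect_true(isSymmetric(g$p))

  gc <- compute_glcm(as_quantized(matrix(3L, 4, 4), 5))
  expect_equal(gc$p[3, 3], 1)
  expect_equal(sum(gc$p), 1)

  expect_error(compute_glcm(as_quantized(matrix(0L, 3, 3), 5)), "background")
})

test_that("sum average follows the Haralick diagonal-sum definition", {
  q <- as_quantized(matrix(c(1L, 2L, 1L, 2L), 2, 2), 2)
  expect_equal(sum_average(compute_glcm(q)), 3.0)
  for (g in 1:5)
    expect_equal(sum_average(compute_glcm(as_quantized(matrix(g, 4, 4), 5))),
                 2 * g)
  for (s in 1:5) {
    q <- random_quantized(12, 12, 10, seed = s)
    sa <- sum_average(compute_glcm(q))
    expect_gte(sa, 2); expect_lte(sa, 20)
  }
  # shifting every level up by one adds exactly 2
  q1 <- random_quantized(15, 15, 10, seed = 9)
  q1$levels[q1$levels == 10L] <- 9L
  q2 <- q1; q2$levels <- q2$levels + 1L
  expect_equal(sum_average(compute_glcm(q2)),
               sum_average(compute_glcm(q1)) + 2, tolerance = 1e-12)
})

test_that("the GLCM suite matches the naive double-loop oracle", {
  gc <- glcm_features(compute_glcm(as_quantized(matrix(4L, 6, 6), 10)))
  expect_equal(unname(gc["energy"]), 1)
  expect_equal(unname(gc["contrast"]), 0)
  expect_equal(unname(gc["homogeneity"]), 1)
  expect_true(is.na(gc["correlation"]))

  cb <- as_quantized(outer(1:6, 1:6, function(r, c) ((r + c) %% 2) + 1L), 2)
  contrast_cb <- glcm_features(compute_glcm(cb, 1, c(0, 90)))[["contrast"]]
  expect_equal(contrast_cb, 1)

  for (s in 1:5) {
    q <- random_quantized(20, 20, 8, bg_frac = 0.1, seed = 100 + s)
    got <- glcm_features(compute_glcm(q))
    want <- oracle_glcm_features(oracle_glcm(q$levels, 8))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("GLCM features are invariant to transposition with pooled directions", {
  q <- random_quantized(18, 14, 10, bg_frac = 0.05, seed = 77)
  qt <- as_quantized(t(q$levels), 10)
  expect_equal(glcm_features(compute_glcm(q)), glcm_features(compute_glcm(qt)),
               tolerance = 1e-12)
})

test_that("NGTDM features match hand enumeration and the naive oracle", {
  const <- ngtdm_features(as_quantized(matrix(3L, 5, 5), 10))
  expect_equal(unname(const["coarseness"]), 1e12)
  expect_equal(unname(const["contrast"]), 0)

  # 3x3 with a single differing centre: one interior pixel, A = 2, s(5) = 3
  L <- matrix(2L, 3, 3); L[2, 2] <- 5L
  t5 <- ngtdm(as_quantized(L, 10))
  expect_equal(t5$s[5], 3)
  expect_equal(t5$n[5], 1)
  expect_equal(sum(t5$n), 1)
  f5 <- ngtdm_features(as_quantized(L, 10))
  expect_equal(unname(f5["coarseness"]), 1 / (1e-12 + 3))

  for (s in 1:5) {
    q <- random_quantized(20, 20, 6, bg_frac = 0.1, seed = 200 + s)
    expect_equal(ngtdm_features(q), oracle_ngtdm_features(q$levels, 6),
                 tolerance = 1e-10)
  }
  expect_error(ngtdm(as_quantized(matrix(1L, 2, 5), 5)), "3x3")
})

test_that("run-length and size-zone matrices match scan/flood-fill oracles", {
  row4 <- as_quantized(matrix(c(1L, 1L, 1L, 2L), 1, 4), 2)
  rl <- runlength_matrix(row4)
  expect_equal(rl[1, 3], 1) # 0-degree run of three 1s
  expect_equal(rl[1, 1], 9) # vertical + both diagonal singletons
  expect_equal(rl[2, 1], 4)

  glz <- glszm_matrix(as_quantized(matrix(7L, 9, 9), 10))
  expect_equal(sum(glz), 1)
  expect_equal(glz[7, 81], 1) # one zone of size N^2

  for (s in 1:5) {
    q <- random_quantized(20, 20, 5, bg_frac = 0.15, seed = 300 + s)
    expect_identical(runlength_matrix(q), oracle_rlm(q$levels, 5))
    expect_identical(glszm_matrix(q), oracle_glszm(q$levels, 5))
  }
  # background breaks runs and zones
  L <- matrix(1L, 1, 5); L[1, 3] <- 0L
  expect_equal(oracle_rlm(L, 1)[1, 2], runlength_matrix(as_quantized(L, 1))[1, 2])
  expect_equal(runlength_matrix(as_quantized(L, 1))[1, 2], 2)
})

test_that("histogram moments use n-1 sd and flag degenerate shapes", {
  w <- as_windowed(matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2))
  m <- histogram_moments(w)
  expect_equal(unname(m["mean"]), 0.5)
  expect_equal(unname(m["sd"]), sqrt(0.2 / 3), tolerance = 1e-12)
  expect_equal(unname(m["skewness"]), 0)

  mc <- histogram_moments(as_windowed(matrix(0.4, 3, 3)))
  expect_equal(unname(mc["sd"]), 0)
  expect_true(is.na(mc["skewness"]) && is.na(mc["kurtosis"]))

  set.seed(2)
  v <- matrix(pmin(pmax(rnorm(1e5, 0.5, 0.1), 0), 1), 250, 400)
  ms <- histogram_moments(as_windowed(v))
  expect_lt(abs(ms[["skewness"]]), 0.03)

  bg <- matrix(TRUE, 2, 2); bg[1, 1] <- FALSE
  expect_error(histogram_moments(as_windowed(matrix(0.5, 2, 2), bg)),
               "at least 2")
})

test_that("form features recover analytic disc geometry and scale with spacing", {
  rr <- outer(1:201, 1:201, function(r, c) (r - 101)^2 + (c - 101)^2)
  disc <- rr <= 50^2
  f <- form_features(disc, 1)
  expect_lt(abs(f[["equivalent_diameter_mm"]] - 100), 1)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  f1 <- form_features(single, 1)
  expect_equal(f1[["area_mm2"]], 1)
  expect_equal(f1[["equivalent_diameter_mm"]], 2 / sqrt(pi))

  f2 <- form_features(disc, 2)
  expect_equal(f2[["area_mm2"]], 4 * f[["area_mm2"]])
  expect_error(form_features(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("extract_features is deterministic with the documented name scheme", {
  ph <- generate_phantom(shape = c(256L, 256L), seed = 21)
  fv1 <- extract_features(ph$image, ph$mask, factors = c(1, 2, 16, 32))
  fv2 <- extract_features(ph$image, ph$mask, factors = c(1, 2, 16, 32))
  expect_identical(fv1, fv2)
  expect_true(all(paste0("glcm.sum_average@", c(1, 2, 16, 32)) %in% names(fv1)))
  expect_true(all(c("hist.sd@1", "form.area_mm2") %in% names(fv1)))
  expect_true(all(is.finite(fv1)))

  tab <- feature_table(list(fv1, fv2))
  expect_equal(ncol(tab), length(fv1) + 1)
  names(fv2)[2] <- "oops"
  expect_error(feature_table(list(fv1, fv2)), "differ")
})
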