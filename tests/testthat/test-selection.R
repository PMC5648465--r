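test_that("correlation screening removes exactly the redundant features", {
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x <- cbind(x, dup = x[, "f1"])
  sr <- correlation_screen(x, seed = 3)
  expect_equal(length(sr$kept), 5)
  expect_equal(sum(c("f1", "dup") %in% sr$kept), 1)
  expect_equal(sr$dropped$r[1], 1, tolerance = 1e-12)

  # three mutually near-duplicate columns: exactly one survives
  z <- rnorm(200)
  x3 <- cbind(a = z, b = z + rnorm(200, 0, 0.01), c = z + rnorm(200, 0, 0.01),
              d = rnorm(200))
  sr3 <- correlation_screen(x3, seed = 5)
  expect_equal(sum(c("a", "b", "c") %in% sr3$kept), 1)
  expect_true("d" %in% sr3$kept)

  # deterministic given the seed
  expect_identical(correlation_screen(x3, seed = 5)$kept, sr3$kept)

  # constant features are dropped with a logged reason
  xc <- cbind(x3, k = rep(2, 200))
  src <- correlation_screen(xc, seed = 5)
  expect_false("k" %in% src$kept)
  expect_true("k" %in% src$dropped$dropped)
  expect_true(is.na(src$dropped$r[src$dropped$dropped == "k"]))

  # subjects with missing values are dropped with a message
  xm <- x3; xm[1, 1] <- NA
  expect_message(srm <- correlation_screen(xm, seed = 5), "1 subject")
  expect_equal(srm$n_subjects_dropped, 1)
})

test_that("independent features survive the null screen", {
  d <- generate_feature_table(500, 20, seed = 11)
  sr <- correlation_screen(d$x, seed = 1)
  expect_equal(length(sr$kept), 20)
})

test_that("the lasso path honours its penalty-limit and oracle contracts", {
  d <- generate_feature_table(300, 10, k_informative = 2, effect = 0.5,
                              seed = 4)
  set.seed(8)
  z <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("age", "bmi")))
  f <- lasso_path(d$y, d$x, z)
  # largest lambda: all penalized coefficients zero, adjusters = glm fit
  expect_true(all(f$beta[f$penalized, 1] == 0))
  zs <- apply(z, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  g0 <- glm(d$y ~ zs, family = binomial)
  expect_equal(unname(f$beta[f$adjusters, 1]), unname(coef(g0)[-1]),
               tolerance = 1e-6)

  # lambda = 0 with p < n matches straight Newton-Raphson
  f0 <- lasso_path(d$y, d$x, z, lambda = c(0.05, 0.01, 0))
  xs <- apply(cbind(d$x, z), 2,
              function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  bref <- oracle_newton_logistic(xs, d$y)
  expect_equal(unname(coef(f0, 0)), unname(bref), tolerance = 1e-6)
})

test_that("every path point satisfies the exact KKT conditions", {
  d <- generate_feature_table(250, 15, k_informative = 3, effect = 0.5,
                              seed = 14)
  f <- lasso_path(d$y, d$x, nlambda = 40)
  xs <- apply(d$x, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  n <- length(d$y)
  for (l in seq_along(f$lambda)) {
    eta <- f$beta0[l] + xs %*% f$beta[, l]
    g <- crossprod(xs, plogis(eta) - d$y) / n
    act <- f$beta[, l] != 0
    if (any(!act))
      expect_lt(max(abs(g[!act])), f$lambda[l] + 1e-6)
    if (any(act))
      expect_lt(max(abs(g[act] + f$lambda[l] * sign(f$beta[act, l]))), 1e-4)
  }
  # active-set size is non-increasing in lambda
  nact <- colSums(f$beta != 0)
  expect_true(all(diff(nact) >= 0)) # lambda is decreasing along the path
})

test_that("a single feature enters at lambda = |score|/n", {
  d <- generate_feature_table(400, 1, k_informative = 1, effect = 0.6,
                              seed = 3)
  n <- 400
  xs <- (d$x - mean(d$x)) / sqrt(mean((d$x - mean(d$x))^2))
  entry <- abs(sum(xs * (d$y - mean(d$y)))) / n
  f <- lasso_path(d$y, d$x, lambda = entry * c(1.01, 0.99))
  expect_equal(unname(f$beta[1, 1]), 0)
  expect_true(f$beta[1, 2] != 0)
})

test_that("selection is invariant to affine rescaling of inputs", {
  d <- generate_feature_table(200, 8, k_informative = 2, effect = 0.6,
                              seed = 21)
  x2 <- d$x
  x2[, 3] <- 1000 * x2[, 3] + 5
  f1 <- lasso_path(d$y, d$x, nlambda = 30)
  f2 <- lasso_path(d$y, x2, nlambda = 30)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-10)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("cv_one_se applies the one-standard-error rule", {
  d <- generate_feature_table(120, 6, k_informative = 2, effect = 0.9,
                              seed = 31)
  cv <- cv_one_se(d$y, d$x, nlambda = 50)
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_true(all(cv$selected %in% colnames(d$x)))
  i1 <- which.min(abs(cv$lambda - cv$lambda_1se))
  imin <- which.min(abs(cv$lambda - cv$lambda_min))
  expect_lte(cv$cvm[i1], cv$cvm[imin] + cv$cvse[imin] + 1e-12)
  # largest lambda inside the band is chosen
  if (i1 > 1)
    expect_gt(cv$cvm[i1 - 1], cv$cvm[imin] + cv$cvse[imin])
  expect_error(cv_one_se(d$y[1:5], d$x[1:5, ]), "too few")
})

test_that("constant or missing inputs are rejected before fitting", {
  d <- generate_feature_table(100, 4, seed = 2)
  xc <- d$x; xc[, 2] <- 3
  expect_error(lasso_path(d$y, xc), "constant column")
  xm <- d$x; xm[5, 1] <- NA
  expect_error(lasso_path(d$y, xm), "missing")
})
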