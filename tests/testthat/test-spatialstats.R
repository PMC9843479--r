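test_that("great_circle_distances matches spherical geometry", {
  expect_equal(great_circle_distances(c(5, 5), c(10, 10))[1, 2], 0)
  d <- great_circle_distances(c(0, 1), c(0, 0))[1, 2]
  expect_equal(d, 111.2, tolerance = 0.5 / 111.2)
  set.seed(61)
  D <- great_circle_distances(runif(8, -170, 170), runif(8, -80, 80))
  expect_equal(D, t(D), tolerance = 1e-10)
  expect_error(great_circle_distances(200, 10), "out of range")
})

test_that("build_weights produces documented structures", {
  # 3 (near-)equidistant sites: row-standardized off-diagonals are 0.5
  lon <- c(0, 1, 0.5); lat <- c(0, 0, sqrt(3) / 2)
  D <- great_circle_distances(lon, lat)
  W <- build_weights(D, "inverse_distance")
  expect_equal(W$W[1, 2], 0.5, tolerance = 0.01)
  expect_equal(unname(rowSums(W$W)), rep(1, 3))

  set.seed(62)
  D8 <- great_circle_distances(runif(8, 0, 5), runif(8, 0, 5))
  Wk <- build_weights(D8, "knn", k = 7, row_standardize = FALSE)
  expect_true(all(Wk$W[upper.tri(Wk$W)] == 1))   # k = n-1 is fully connected
  expect_equal(unname(rowSums(build_weights(D8, "knn", k = 3)$W)), rep(1, 8))

  D0 <- D8; D0[1, 2] <- D0[2, 1] <- 0
  expect_error(build_weights(D0, "inverse_distance"), "coincident")
})

test_that("morans_i matches the closed forms and the ape oracle", {
  set.seed(63)
  D <- great_circle_distances(runif(11, 0, 5), runif(11, 0, 5))
  W <- build_weights(D, "inverse_distance")
  m <- morans_i(rnorm(11), W)
  expect_equal(m$expectation, -0.1)          # -1/(n-1) at n = 11

  x <- rnorm(11)
  am <- ape::Moran.I(x, W$W)
  mm <- morans_i(x, W)
  expect_equal(mm$I, am$observed, tolerance = 1e-10)
  expect_equal(mm$p, am$p.value, tolerance = 0.05)

  # affine invariance
  m2 <- morans_i(10 - 3 * x, W)
  expect_equal(m2$I, mm$I, tolerance = 1e-10)

  expect_error(morans_i(rep(1, 11), W), "constant")
})

test_that("checkerboard on a rook lattice gives negative Moran's I", {
  n <- 4
  coords <- expand.grid(row = 1:n, col = 1:n)
  Wm <- matrix(0, n^2, n^2)
  for (i in 1:(n^2)) for (j in 1:(n^2))
    if (abs(coords$row[i] - coords$row[j]) + abs(coords$col[i] - coords$col[j]) == 1)
      Wm[i, j] <- 1
  x <- (-1)^(coords$row + coords$col)
  expect_lt(morans_i(x, Wm)$I, 0)
})

test_that("permutation and analytic Moran p agree on noise", {
  set.seed(64)
  D <- great_circle_distances(runif(60, 0, 5), runif(60, 0, 5))
  W <- build_weights(D, "knn", k = 4)
  for (r in 1:3) {
    x <- rnorm(60)
    m <- morans_i(x, W, n_perm = 2000, seed = 640 + r)
    expect_lt(abs(m$p - m$p_perm), 0.05)
  }
})

test_that("ols_standardized equals the Pearson correlation", {
  set.seed(65)
  x <- rnorm(30); y <- x
  o <- suppressWarnings(ols_standardized(y, x))   # lm warns on a perfect fit
  expect_equal(o$coef, 1, tolerance = 1e-12)
  expect_equal(o$r2, 1, tolerance = 1e-12)

  y2 <- 0.4 * x + rnorm(30)
  o2 <- ols_standardized(y2, x)
  expect_equal(o2$coef, cor(x, y2), tolerance = 1e-12)
  expect_equal(o2$r2, o2$coef^2, tolerance = 1e-10)
  expect_equal(o2$coef_xstd, o2$coef * sd(y2), tolerance = 1e-10)

  yind <- rnorm(10000); xind <- rnorm(10000)
  expect_lt(abs(ols_standardized(yind, xind)$coef), 0.05)
  expect_error(ols_standardized(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("sar_error_ml satisfies its identities", {
  st <- simulate_site_table(60, lambda_spatial = 0.5, seed = 66)
  W <- attr(st, "truth")$weights
  f <- sar_error_ml(st$response, st$Plant.ric, W)
  expect_equal(f$AIC, 2 * f$k - 2 * f$logLik, tolerance = 1e-8)

  # lambda fixed at 0 reproduces OLS
  f0 <- sar_error_ml(st$response, st$Plant.ric, W, lambda_fixed = 0)
  o <- ols_standardized(st$response, st$Plant.ric)
  expect_equal(unname(f0$coef), o$coef, tolerance = 1e-6)
})

test_that("sar_error_ml recovers lambda = 0 and reduces residual Moran", {
  st <- simulate_site_table(200, lambda_spatial = 0, seed = 67)
  W <- attr(st, "truth")$weights
  f <- sar_error_ml(st$response, st$Plant.ric, W)
  expect_lt(abs(f$lambda), 0.15)
  o <- ols_standardized(st$response, st$Plant.ric)
  expect_equal(unname(f$coef), o$coef, tolerance = 0.02)

  # with real spatial error the SAR filtered residuals lose autocorrelation
  ok <- logical(10)
  for (r in 1:10) {
    st2 <- simulate_site_table(80, lambda_spatial = 0.6, seed = 670 + r)
    W2 <- attr(st2, "truth")$weights
    f2 <- sar_error_ml(st2$response, st2$Plant.ric, W2)
    o2 <- ols_standardized(st2$response, st2$Plant.ric, W2)
    ok[r] <- abs(f2$moran$I) <= abs(o2$moran$I)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("vif flags collinearity as documented", {
  set.seed(68)
  n <- 50
  Q <- unclass(stats::poly(1:n, 3))   # orthogonal to each other and to 1
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-8)

  X <- cbind(a = rnorm(n), b = rnorm(n))
  X2 <- cbind(X, adup = X[, "a"])
  expect_true(is.infinite(vif(X2)["adup"]))

  X3 <- cbind(x1 = rnorm(n))
  X3 <- cbind(X3, x2 = X3[, "x1"] + rnorm(n, sd = 0.01), x3 = rnorm(n))
  expect_gt(vif(X3)["x2"], 10)
})

test_that("regression_table produces the full grid with stars", {
  st <- simulate_site_table(25, effect_spec = c(Plant.ric = 1.5), seed = 69)
  W <- attr(st, "truth")$weights
  resp <- data.frame(Y = st$response)
  pred <- st[, c("Plant.ric", "MAT", "Area")]
  tab <- regression_table(resp, pred, W)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("coef_ols", "r2_ols", "I_ols", "coef_sar", "AIC", "I_sar")
                  %in% names(tab)))
  best <- tab$predictor[which.max(tab$r2_ols)]
  expect_equal(best, "Plant.ric")
  expect_equal(tab$stars[tab$predictor == "Plant.ric"], "**")
})
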