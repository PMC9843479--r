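# Spatially explicit regression: great-circle distances, spatial weights,
# Moran's I, standardized bivariate OLS, maximum-likelihood spatial-error SAR,
# and VIF collinearity screening. The weights matrix is the main modelling
# choice; default is row-standardized inverse distance on haversine km.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance matrix
#'
#' @param lon,lat decimal degrees; or pass a data.frame with
#'   `longitude`/`latitude` columns as `lon`.
#' @return symmetric site x site distance matrix in km.
#' @export
great_circle_distances <- function(lon, lat = NULL) {
  if (is.data.frame(lon)) {
    lat <- lon$latitude
    lon <- lon$longitude
  }
  if (any(abs(lon) > 180) || any(abs(lat) > 90) || anyNA(lon) || anyNA(lat))
    stopf("coordinates out of range")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Build a spatial weights matrix
#'
#' `inverse_distance`: `w_ij = 1/d_ij` (zero diagonal). `knn`: binary k
#' nearest neighbours, symmetrized by max. Row standardization (default)
#' rescales rows to sum to 1; the symmetric pre-standardization matrix is kept
#' for the SAR eigenvalue computation.
#'
#' @param distances symmetric distance matrix.
#' @param style `"inverse_distance"` or `"knn"`.
#' @param k neighbours for knn.
#' @param row_standardize logical.
#' @return a `spatial_weights` list: `W` (possibly row-standardized), `S`
#'   (symmetric base), `style`, `row_standardized`.
#' @export
build_weights <- function(distances, style = c("inverse_distance", "knn"),
                          k = NULL, row_standardize = TRUE) {
  style <- match.arg(style)
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8) stopf("invalid distance matrix")
  off <- D[upper.tri(D)]
  if (style == "inverse_distance") {
    if (any(off == 0))
      stopf("coincident sites: inverse-distance weights undefined; jitter coordinates or use knn")
    S <- 1 / D
    diag(S) <- 0
  } else {
    if (is.null(k) || k < 1 || k > n - 1) stopf("knn needs k in [1, n-1]")
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(k)]
      nb <- seq_len(n)[-i][nb]
      S[i, nb] <- 1
    }
    S <- pmax(S, t(S))                       # symmetrize by max
  }
  rs <- rowSums(S)
  if (any(rs == 0)) warnf("%d isolated site(s) (zero weight row)", sum(rs == 0))
  W <- if (row_standardize) S / ifelse(rs > 0, rs, 1) else S
  structure(list(W = W, S = S, style = style, row_standardized = row_standardize),
            class = "spatial_weights")
}

as_weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

# eigenvalues of W; exploits similarity to a symmetric matrix when W is a
# row-standardized symmetric base (real spectrum, cheap and stable)
weights_eigenvalues <- function(W) {
  if (inherits(W, "spatial_weights") && W$row_standardized) {
    rs <- rowSums(W$S)
    rs[rs == 0] <- 1
    A <- W$S / sqrt(outer(rs, rs))
    eigen(A, symmetric = TRUE, only.values = TRUE)$values
  } else {
    Re(eigen(as_weights_matrix(W), only.values = TRUE)$values)
  }
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered values;
#' `E[I] = -1/(n-1)`. The analytic p uses the normal approximation under the
#' normality assumption; `n_perm > 0` adds a permutation p.
#'
#' @param x numeric values (non-constant).
#' @param W weights (matrix or [build_weights()] result).
#' @param n_perm permutation replicates (0 = analytic only).
#' @param seed seed for permutations.
#' @return list: `I`, `expectation`, `variance`, `z`, `p` (two-sided normal),
#'   `p_perm` (or `NA`).
#' @export
morans_i <- function(x, W, n_perm = 0, seed = NULL) {
  W <- as_weights_matrix(W)
  n <- length(x)
  if (nrow(W) != n) stopf("length(x) != nrow(W)")
  if (stats::sd(x) == 0) stopf("constant input: Moran's I undefined")
  z <- x - mean(x)
  S0 <- sum(W)
  istat <- function(z) n / S0 * sum(W * outer(z, z)) / sum(z^2)
  I <- istat(z)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  zs <- (I - EI) / sqrt(VI)
  p <- 2 * stats::pnorm(-abs(zs))
  p_perm <- NA_real_
  if (n_perm > 0) {
    sims <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) istat(sample(z)), 0))
    p_perm <- 2 * min((sum(sims >= I) + 1) / (n_perm + 1),
                      (sum(sims <= I) + 1) / (n_perm + 1))
    p_perm <- min(p_perm, 1)
  }
  list(I = I, expectation = EI, variance = VI, z = zs, p = p, p_perm = p_perm)
}

#' Standardized bivariate OLS
#'
#' Both variables are z-scored, so the slope equals the Pearson correlation
#' and r-squared its square. `coef_xstd` additionally reports the slope with
#' only the predictor standardized (response on its raw scale), since some
#' published tables use that scaling.
#'
#' @param y response; `x` predictor; optional `W` to report residual Moran's I.
#' @return list: `coef`, `coef_xstd`, `r2`, `p`, `residuals` (of the
#'   standardized fit), `moran` (or NULL).
#' @export
ols_standardized <- function(y, x, W = NULL) {
  if (length(y) != length(x)) stopf("length mismatch")
  if (length(y) < 3L) stopf("need n >= 3")
  zy <- zscore(y, "response"); zx <- zscore(x, "predictor")
  fit <- stats::lm(zy ~ zx)
  sm <- summary(fit)
  res <- list(coef = unname(stats::coef(fit)[2L]),
              coef_xstd = unname(stats::coef(fit)[2L]) * stats::sd(y),
              r2 = sm$r.squared,
              p = sm$coefficients[2L, 4L],
              residuals = unname(stats::residuals(fit)),
              moran = NULL)
  if (!is.null(W)) res$moran <- morans_i(res$residuals, W)
  res
}

#' Maximum-likelihood spatial-error SAR
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps` by profile maximum
#' likelihood: for each `lambda` the concentrated log-likelihood uses the
#' log-determinant `ln|I - lambda W| = sum ln(1 - lambda w_i)` from the
#' precomputed eigenvalues of W, and beta/sigma^2 come from OLS on the
#' spatially filtered variables. AIC = 2k - 2 logL with k = #beta + 2
#' (lambda, sigma^2).
#'
#' @param y response; `x` predictor vector (or matrix of predictors); `W`
#'   weights from [build_weights()] (row-standardized recommended).
#' @param standardize z-score y and x first (default TRUE, matching the
#'   standardized-coefficient reporting convention).
#' @param intercept include an intercept (default TRUE).
#' @param lambda_fixed fix lambda instead of profiling it (`lambda_fixed = 0`
#'   reproduces OLS).
#' @return list: `coef` (named slopes), `intercept`, `lambda`, `sigma2`,
#'   `logLik`, `AIC`, `k`, `residuals` (spatially filtered innovations),
#'   `moran` (Moran's I of those residuals), `lambda_range`.
#' @export
sar_error_ml <- function(y, x, W, standardize = TRUE, intercept = TRUE,
                         lambda_fixed = NULL) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (standardize) {
    y <- zscore(y, "response")
    X <- apply(X, 2L, zscore, label = "predictor")
  }
  Wm <- as_weights_matrix(W)
  n <- length(y)
  ev <- weights_eigenvalues(W)
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  eps <- 1e-6
  rng <- c(max(lo, -1e3) + eps, min(hi, 1e3) - eps)
  Xf <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  cll <- function(lambda) {
    A <- diag(n) - lambda * Wm
    ya <- A %*% y
    Xa <- A %*% Xf
    fit <- stats::lm.fit(Xa, ya)
    s2 <- sum(fit$residuals^2) / n
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) + sum(log(1 - lambda * ev))
  }
  if (is.null(lambda_fixed)) {
    opt <- stats::optimize(cll, interval = rng, maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    ll <- opt$objective
    if (min(abs(lambda - rng)) < 1e-4)
      warnf("lambda at interval boundary (%.4f)", lambda)
  } else {
    lambda <- lambda_fixed
    ll <- cll(lambda)
  }
  A <- diag(n) - lambda * Wm
  fit <- stats::lm.fit(A %*% Xf, A %*% y)
  beta <- fit$coefficients
  if (anyNA(beta)) stopf("singular SAR design matrix")
  resid <- as.numeric(A %*% (y - Xf %*% beta))   # filtered innovations
  k <- length(beta) + 2L
  list(coef = beta[colnames(X)],
       intercept = if (intercept) unname(beta["(Intercept)"]) else 0,
       lambda = lambda, sigma2 = sum(fit$residuals^2) / n,
       logLik = ll, AIC = 2 * k - 2 * ll, k = k,
       residuals = resid, moran = morans_i(resid, W),
       lambda_range = rng)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on the remaining
#' columns; perfectly collinear columns report `Inf`.
#'
#' @param X data.frame or matrix of predictors (>= 2 columns).
#' @return named numeric vector.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stopf("need >= 2 columns")
  if (nrow(X) <= p + 1L) stopf("need n > columns + 1")
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0, USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Bivariate OLS + SAR grid across responses and predictors
#'
#' One row per response x predictor cell, with standardized OLS coefficient,
#' r-squared, residual Moran's I, SAR coefficient, lambda, AIC, and SAR
#' residual Moran's I — the shape of a published diversity-vs-environment
#' table. Stars: * p < .05, ** p < .01.
#'
#' @param responses data.frame of response columns.
#' @param predictors data.frame of predictor columns.
#' @param W spatial weights.
#' @return data.frame.
#' @export
regression_table <- function(responses, predictors, W) {
  out <- NULL
  for (rv in names(responses)) for (pv in names(predictors)) {
    y <- responses[[rv]]; x <- predictors[[pv]]
    if (anyNA(y) || anyNA(x)) {
      out <- rbind(out, data.frame(response = rv, predictor = pv,
        coef_ols = NA, coef_xstd = NA, r2_ols = NA, p_ols = NA, I_ols = NA,
        p_I_ols = NA, coef_sar = NA, lambda = NA, AIC = NA, I_sar = NA,
        stars = ""))
      next
    }
    o <- ols_standardized(y, x, W)
    s <- sar_error_ml(y, x, W)
    stars <- if (o$p < 0.01) "**" else if (o$p < 0.05) "*" else ""
    out <- rbind(out, data.frame(response = rv, predictor = pv,
      coef_ols = o$coef, coef_xstd = o$coef_xstd, r2_ols = o$r2, p_ols = o$p,
      I_ols = o$moran$I, p_I_ols = o$moran$p,
      coef_sar = unname(s$coef[1L]), lambda = s$lambda, AIC = s$AIC,
      I_sar = s$moran$I, stars = stars))
  }
  out
}
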