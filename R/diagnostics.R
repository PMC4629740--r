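#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' of predictor `j` regressed (with intercept) on the other predictors of the
#' design. A single-column design has VIF 1 by convention; perfect
#' collinearity is reported as `Inf`.
#'
#' @param design data.frame or matrix of the fitted model's predictor columns
#'   (no intercept column).
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' vif(data.frame(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5)))
vif <- function(design) {
  x <- as.data.frame(design)
  p <- ncol(x)
  if (p == 0) return(numeric(0))
  if (p == 1) return(setNames(1, names(x)))
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    r2 <- quiet_summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(x))
}

#' Cook's distances of a fitted LUR model
#'
#' Per-site influence of each observation on the fitted coefficients.
#' Following the campaign protocol, a maximum Cook's D above 1 flags the
#' model for closer examination but does not modify it. Observations with
#' leverage 1 (undefined distance) are reported as `Inf`.
#'
#' @param model A [lur_model] (or plain `lm` fit).
#' @return List with `d` (named per-site distances), `max`, and `flag`
#'   (`TRUE` when `max > 1`).
#' @export
cooks_d <- function(model) {
  fit <- if (inherits(model, "lur_model")) model$fit else model
  if (is.null(fit)) stop("model has no underlying fit (empty model)")
  d <- cooks.distance(fit)
  h <- stats::hatvalues(fit)
  ## an exact (zero-residual) fit has no influential points: D is 0, not 0/0
  if (sum(residuals(fit)^2) <= 1e-24 * max(1, sum(fitted(fit)^2))) {
    d[] <- 0
  }
  d[h >= 1 - 1e-12] <- Inf
  if (inherits(model, "lur_model")) names(d) <- model$site_ids
  list(d = d, max = max(d), flag = max(d) > 1)
}

#' Spatial weight matrix for Moran's I
#'
#' @param sites Site roster with planar `x`, `y` (meters).
#' @param scheme `"idw"` for inverse-distance weights (1/d, zero diagonal,
#'   row-standardized) or `"knn"` for binary k-nearest-neighbour adjacency.
#' @param k Number of neighbours for `scheme = "knn"`.
#' @param row_standardize Scale each row to sum to 1 (default for both
#'   schemes).
#' @return n x n numeric weight matrix with zero diagonal.
#' @export
spatial_weights <- function(sites, scheme = c("idw", "knn"), k = 5,
                            row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(sites)
  d <- as.matrix(dist(cbind(sites$x, sites$y)))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident sites: spatial weights undefined at distance 0")
  }
  w <- switch(scheme,
    idw = {
      w <- 1 / d
      diag(w) <- 0
      w
    },
    knn = {
      k <- min(k, n - 1)
      w <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(k + 1)]
        w[i, nb] <- 1
      }
      w
    }
  )
  if (row_standardize) w <- w / rowSums(w)
  dimnames(w) <- NULL
  w
}

#' Moran's I of model residuals
#'
#' Tests residual spatial autocorrelation under the randomization assumption.
#' `I = (n / S0) * sum_ij(w_ij e_i e_j) / sum_i(e_i^2)` with `e` the
#' mean-centred residuals, `E[I] = -1/(n-1)`, and the randomization variance
#' giving a normal-approximation z and two-sided p.
#'
#' @param residuals Numeric residual vector (one per site).
#' @param sites Site roster aligned with `residuals` (used when `weights` is
#'   a scheme name).
#' @param weights Either an n x n weight matrix (nonnegative, zero diagonal)
#'   or a scheme name passed to [spatial_weights()].
#' @param k Neighbours for the `"knn"` scheme.
#' @return List with `I`, `expectation`, `variance`, `z`, `p`.
#' @export
morans_i <- function(residuals, sites = NULL, weights = "idw", k = 5) {
  e <- residuals - mean(residuals)
  n <- length(e)
  if (n < 5) stop("need >= 5 sites for Moran's I")
  if (sum(e^2) == 0) stop("residuals have zero variance; Moran's I undefined")
  w <- if (is.matrix(weights)) {
    weights
  } else {
    if (is.null(sites)) stop("sites required to build the weight scheme")
    spatial_weights(sites, scheme = weights, k = k)
  }
  if (any(dim(w) != n)) stop("weight matrix dimension mismatch")
  if (any(w < 0) || any(diag(w) != 0)) {
    stop("weights must be nonnegative with zero diagonal")
  }
  s0 <- sum(w)
  if (s0 == 0) stop("weight matrix sums to zero")
  I <- (n / s0) * as.numeric(t(e) %*% w %*% e) / sum(e^2)
  EI <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(e^4) / (sum(e^2)^2)
  varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
  z <- (I - EI) / sqrt(varI)
  list(I = I, expectation = EI, variance = varI, z = z,
       p = 2 * pnorm(-abs(z)))
}
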