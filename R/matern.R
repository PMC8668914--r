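#' Matern (nu = 1) covariance function
#'
#' Stationary spatial covariance used for the latent random effect:
#' \deqn{Cov(d) = \sigma^2 (\kappa d) K_1(\kappa d), \qquad \kappa = \sqrt{8}/\rho,}
#' where \eqn{K_1} is the modified Bessel function of the second kind of
#' order 1 and \eqn{\rho} is the practical range in km: the distance at
#' which the correlation has dropped to \eqn{\sqrt{8} K_1(\sqrt{8}) \approx
#' 0.14}, i.e. become negligible.
#'
#' @param d numeric vector of non-negative distances (km).
#' @param sigma field standard deviation (logit scale), \code{sigma >= 0}.
#' @param range_rho practical range \eqn{\rho} in km, \code{> 0}.
#' @return covariance values, same length as \code{d}; \code{sigma^2} at
#'   \code{d == 0} (the \eqn{x K_1(x) \to 1} limit).
#' @examples
#' matern_cov(0, 1, 30)            # 1
#' matern_cov(30, 1, 30)           # ~0.14: correlation at one range
#' @export
matern_cov <- function(d, sigma, range_rho) {
  stopifnot(is.numeric(d), all(is.finite(d)), all(d >= 0))
  if (sigma < 0) stop("sigma must be >= 0")
  if (range_rho <= 0) stop("range_rho must be > 0")
  kappa <- sqrt(8) / range_rho
  x <- kappa * d
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- sigma^2 * x[pos] * besselK(x[pos], nu = 1)
  out[!pos] <- sigma^2
  # besselK underflows to 0 for very large x; x * 0 is already 0
  out[!is.finite(out)] <- 0
  out
}

#' Pairwise Euclidean distance matrix
#'
#' @param xy n x 2 matrix of coordinates (km).
#' @param xy2 optional second set; if given, returns the n x m cross matrix.
#' @return distance matrix in km.
#' @keywords internal
pairwise_dist <- function(xy, xy2 = NULL) {
  xy <- as.matrix(xy)
  if (is.null(xy2)) {
    d <- as.matrix(stats::dist(xy))
    dimnames(d) <- NULL
    return(d)
  }
  xy2 <- as.matrix(xy2)
  dx <- outer(xy[, 1], xy2[, 1], "-")
  dy <- outer(xy[, 2], xy2[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Dense Matern covariance matrix of a point set
#'
#' Applies \code{\link{matern_cov}} to all pairwise Euclidean distances and
#' adds a small diagonal jitter so the matrix stays positive definite when
#' locations coincide or nearly coincide (households can be metres apart).
#'
#' @param locations n x 2 matrix/data.frame of coordinates in km.
#' @param sigma field SD; @param range_rho practical range (km).
#' @param jitter relative diagonal jitter; the default \code{1e-8} is in
#'   units of \code{sigma^2}.
#' @param dense_limit refuse larger point sets (dense factorization only).
#' @return n x n positive-definite covariance matrix. A warning is issued
#'   when duplicated locations are present (jitter carries the factorization).
#' @export
build_covariance <- function(locations, sigma, range_rho, jitter = 1e-8,
                             dense_limit = 5000) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2, all(is.finite(locations)))
  n <- nrow(locations)
  if (n > dense_limit) {
    stop("point set of size ", n, " exceeds the dense factorization limit (",
         dense_limit, "); thin the locations or tie the field to knots")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  D <- pairwise_dist(locations)
  if (n > 1 && any(D[upper.tri(D)] < 1e-12)) {
    warning("duplicate (or near-duplicate) locations: relying on diagonal jitter")
  }
  S <- matern_cov(D, sigma, range_rho)
  dim(S) <- c(n, n)
  S + diag(jitter * max(sigma^2, 1e-12), n)
}

#' Simulate a Matern (nu = 1) Gaussian random field
#'
#' Draws one realization of a zero-mean Gaussian field with the Matern
#' covariance of \code{\link{matern_cov}} at the given locations, by dense
#' Cholesky factorization.
#'
#' @inheritParams build_covariance
#' @param seed optional integer; when supplied the draw is reproducible.
#' @return numeric vector of field values, one per location.
#' @export
simulate_matern_grf <- function(locations, sigma, range_rho, seed = NULL,
                                jitter = 1e-8, dense_limit = 5000) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(numeric(n))
  S <- build_covariance(locations, sigma, range_rho, jitter = jitter,
                        dense_limit = dense_limit)
  L <- chol(S)   # upper triangular, S = t(L) %*% L
  drop(t(L) %*% stats::rnorm(n))
}
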