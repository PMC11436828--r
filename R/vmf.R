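#' @importFrom stats rnorm runif rbeta integrate
NULL

# Run code with a temporary RNG state when a seed is given; leaves the
# caller's RNG untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log I_nu(x), evaluated in the log domain. Uses the exponentially scaled
# Bessel function where it does not underflow; falls back to the uniform
# asymptotic expansion for large order (Abramowitz & Stegun 9.7.7).
log_bessel_i <- function(nu, x) {
  if (x == 0) return(if (nu == 0) 0 else -Inf)
  if (nu < 100) {
    # the uniform expansion needs a large order; below it besselI is exact
    s <- suppressWarnings(besselI(x, nu, expon.scaled = TRUE))
    if (is.finite(s) && s > 0) return(log(s) + x)
    if (nu == 0) stop("numeric overflow in normalizer")
  }
  # uniform asymptotic expansion in the order
  z <- x / nu
  r <- sqrt(1 + z^2)
  eta <- r + log(z / (1 + r))
  t <- 1 / r
  u1 <- (3 * t - 5 * t^3) / 24
  nu * eta - 0.5 * log(2 * pi * nu) + 0.5 * log(t) + log1p(u1 / nu)
}

#' Log normalizing constant of the von Mises-Fisher density
#'
#' For unit vectors in `dim` dimensions the vMF density is
#' `C_d(kappa) * exp(kappa * t(mu) %*% y)` with
#' `C_d(kappa) = kappa^(d/2-1) / ((2*pi)^(d/2) * I_(d/2-1)(kappa))`.
#' Evaluated in the log domain so concentrations up to about `1e5` and
#' dimensions in the hundreds stay finite.
#'
#' @param dim ambient dimension (>= 2); the sphere is S^(dim-1).
#' @param kappa concentration, >= 0. `kappa = 0` gives the uniform density.
#' @return `log C_d(kappa)`, a scalar.
#' @examples
#' vmf_log_norm_const(3, 0)  # -log(4*pi)
#' @export
vmf_log_norm_const <- function(dim, kappa) {
  stopifnot(dim >= 2, kappa >= 0)
  if (kappa == 0) {
    # reciprocal surface area of S^(dim-1)
    out <- lgamma(dim / 2) - log(2) - (dim / 2) * log(pi)
  } else {
    nu <- dim / 2 - 1
    out <- nu * log(kappa) - (dim / 2) * log(2 * pi) - log_bessel_i(nu, kappa)
  }
  if (!is.finite(out)) stop("numeric overflow in normalizer")
  out
}

#' Mean resultant length of the vMF distribution
#'
#' The expected resultant length `A_d(kappa) = I_(d/2)(kappa) / I_(d/2-1)(kappa)`,
#' i.e. the expectation of the projection of a vMF draw onto its mean
#' direction. Used by the concentration estimator and as the reference for
#' sampler-fidelity checks.
#'
#' @param dim ambient dimension.
#' @param kappa concentration, >= 0.
#' @return `A_d(kappa)` in `[0, 1)`.
#' @export
vmf_mean_resultant <- function(dim, kappa) {
  stopifnot(dim >= 2, kappa >= 0)
  if (kappa == 0) return(0)
  exp(log_bessel_i(dim / 2, kappa) - log_bessel_i(dim / 2 - 1, kappa))
}

#' Sample from the von Mises-Fisher distribution
#'
#' Draws unit vectors with density proportional to
#' `exp(kappa * t(mean) %*% y)` using the Ulrich/Wood rejection scheme for
#' the radial component and a uniform tangent direction, valid in any
#' dimension >= 2. A Householder reflection rotates draws from the canonical
#' frame (mean = first basis vector) to the requested mean direction.
#'
#' @param n number of draws.
#' @param mean mean direction; normalized internally (must be nonzero when
#'   `kappa > 0`).
#' @param kappa concentration, >= 0; 0 samples uniformly on the sphere.
#' @param seed optional integer seed (local to this call).
#' @return An `n x length(mean)` matrix of unit vectors.
#' @examples
#' y <- sample_vmf(100, c(0, 0, 1), kappa = 50, seed = 1)
#' colMeans(y)
#' @export
sample_vmf <- function(n, mean, kappa, seed = NULL) {
  d <- length(mean)
  stopifnot(d >= 2, kappa >= 0, n >= 0)
  nm <- sqrt(sum(mean^2))
  if (kappa > 0 && nm < 1e-12) stop("zero-norm mean direction with kappa > 0")
  with_seed_(seed, {
    if (kappa == 0) {
      y <- matrix(rnorm(n * d), n, d)
      return(y / sqrt(rowSums(y^2)))
    }
    mu <- mean / nm
    w <- numeric(n)
    # stable form of (-2k + sqrt(4k^2 + (d-1)^2)) / (d-1): avoids the
    # catastrophic cancellation that makes b underflow at large kappa
    b <- (d - 1) / (2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2))
    x0 <- (1 - b) / (1 + b)
    c0 <- kappa * x0 + (d - 1) * log(1 - x0^2)
    got <- 0L
    while (got < n) {
      m <- n - got
      z <- rbeta(m, (d - 1) / 2, (d - 1) / 2)
      t <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      u <- runif(m)
      ok <- kappa * t + (d - 1) * log(1 - x0 * t) - c0 >= log(u)
      k <- sum(ok)
      if (k > 0) {
        w[(got + 1L):(got + k)] <- t[ok]
        got <- got + k
      }
    }
    # uniform direction in the tangent (d-1)-space
    v <- matrix(rnorm(n * (d - 1)), n, d - 1)
    v <- v / sqrt(rowSums(v^2))
    y <- cbind(w, sqrt(pmax(0, 1 - w^2)) * v)
    # reflect e1 onto mu (Householder); identity if already aligned
    e1 <- c(1, rep(0, d - 1))
    u <- e1 - mu
    un <- sqrt(sum(u^2))
    if (un > 1e-12) {
      u <- u / un
      y <- y - 2 * (y %*% u) %*% t(u)
    }
    y / sqrt(rowSums(y^2))
  })
}

# normalize rows to unit length, leaving zero rows at zero
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  pos <- nrm > 0
  m[pos, ] <- m[pos, , drop = FALSE] / nrm[pos]
  m
}
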