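# Size and orientation distributions.
#
# Sizes follow the Schulz-Zimm (Gamma) law, whose moments are Pochhammer
# ratios (z+1)_k/(z+1)^k and whose averages of trigonometric terms
# cos(c q R + phi) / (qR)^m have closed forms in cosines and arctangents.
# Orientations are uniaxial densities h(delta) on [0, pi/2] entering through
# the q-independent H-integrals and the order parameter S.

#' Schulz-Zimm size distribution
#'
#' Gamma law with mean \code{mean} and relative standard deviation
#' \code{sigma}; the polydispersity parameter is \eqn{z = 1/\sigma^2 - 1}
#' (shape \eqn{z+1}, rate \eqn{(z+1)/\bar R}).  \code{sigma = 0} denotes the
#' monodisperse (delta) limit.
#'
#' @param mean Mean size (nm), positive.
#' @param sigma Relative standard deviation in \[0, 1).
#' @param z Alternative parametrization; supply one of \code{sigma}, \code{z}.
#' @return An object of class \code{schulz_dist} with fields \code{mean},
#'   \code{sigma}, \code{z}, \code{alpha} (shape) and \code{rate}.
#' @examples
#' schulz_dist(3, sigma = 0.08)$z  # 155.25
#' @export
schulz_dist <- function(mean = 1, sigma = NULL, z = NULL) {
  stopifnot(mean > 0)
  if (is.null(sigma) && is.null(z)) stop("supply sigma or z")
  if (is.null(sigma)) {
    stopifnot(z > 0)
    sigma <- 1 / sqrt(z + 1)
  } else if (is.null(z)) {
    stopifnot(sigma >= 0, sigma < 1)
    z <- if (sigma == 0) Inf else 1 / sigma^2 - 1
  }
  structure(
    list(mean = mean, sigma = sigma, z = z,
         alpha = z + 1, rate = (z + 1) / mean),
    class = "schulz_dist"
  )
}

is_monodisperse <- function(dist) !is.finite(dist$z)

## Gamma-density evaluation on the truncated support used by the oracle.
schulz_density <- function(dist, r) {
  if (is_monodisperse(dist)) stop("monodisperse distribution has no density")
  stats::dgamma(r, shape = dist$alpha, rate = dist$rate)
}

#' Normalized size moments of the Schulz-Zimm law
#'
#' Returns \eqn{\langle R^k\rangle/\bar R^k = (z+1)_k/(z+1)^k}, the moment
#' factor that converts monodisperse series coefficients into polydisperse
#' ones.
#'
#' @param dist A [schulz_dist()].
#' @param k Non-negative integer moment order.
#' @return The moment ratio (1 for the monodisperse limit).
#' @export
moment_ratio <- function(dist, k) {
  stopifnot(inherits(dist, "schulz_dist"), k >= 0, k == round(k))
  if (k == 0 || is_monodisperse(dist)) return(1)
  pochhammer(dist$z + 1, as.integer(k)) / (dist$z + 1)^k
}

## Core closed form: < cos(freq * q * R + phase) * (q R)^(-m) > for the
## Gamma law, via the modulus-arctan representation of the complex moment
## < R^(-m) exp(i freq q R) >.  m may be any real below the shape alpha.
## Vectorized over q.  gamma_ratio = Gamma(alpha-m)/Gamma(alpha) may be
## supplied pre-computed (it is q-independent).
schulz_avg_cos <- function(dist, q, m, freq = 2, phase = 0, gamma_ratio = NULL) {
  if (is_monodisperse(dist)) {
    x <- q * dist$mean
    return(cos(freq * x + phase) / x^m)
  }
  al <- dist$alpha
  la <- dist$rate
  if (al <= m) stop("moment of order -", m, " does not exist (alpha = ", al, ")")
  if (is.null(gamma_ratio)) gamma_ratio <- exp(lgamma(al - m) - lgamma(al))
  s <- sqrt(la^2 + (freq * q)^2)
  psi <- atan2(freq * q, la)
  # (la/s)^al * s^m in log space: la^al overflows for narrow distributions
  gamma_ratio * exp(al * log(la / s) + m * log(s)) *
    cos(phase + (al - m) * psi) / q^m
}

## <(q R)^(-m)> , closed form (constant trigonometric kind).
schulz_avg_const <- function(dist, q, m, gamma_ratio = NULL) {
  if (is_monodisperse(dist)) return((q * dist$mean)^(-m))
  al <- dist$alpha
  la <- dist$rate
  if (al <= m) stop("moment of order -", m, " does not exist (alpha = ", al, ")")
  if (is.null(gamma_ratio)) gamma_ratio <- exp(lgamma(al - m) - lgamma(al))
  gamma_ratio * la^m * q^(-m)
}

#' Closed-form Schulz-Zimm averages of trigonometric terms
#'
#' Evaluates \eqn{\langle T(qR) / (qR)^k \rangle} for
#' \eqn{T \in \{\cos^2, \sin^2, \sin\cos, 1\}} over the Gamma size law,
#' by rewriting through \eqn{\cos(2qR)} and \eqn{\sin(2qR)} and using the
#' closed-form complex moment (modulus-arctan representation).  These are
#' the averaged terms of the trigonometric (Regime II) form of the
#' polydisperse form factor.
#'
#' @param dist A [schulz_dist()].
#' @param q Positive scattering vector magnitude(s) (nm^-1).
#' @param k Non-negative power of \eqn{(qR)^{-1}}; requires \eqn{z > k - 1}.
#' @param kind One of \code{"cos2"}, \code{"sin2"}, \code{"sincos"},
#'   \code{"const"}.
#' @return The averaged value(s).
#' @export
avg_trig <- function(dist, q, k, kind = c("cos2", "sin2", "sincos", "const")) {
  kind <- match.arg(kind)
  stopifnot(inherits(dist, "schulz_dist"), all(q > 0), k >= 0)
  switch(kind,
    const = schulz_avg_const(dist, q, k),
    cos2 = 0.5 * (schulz_avg_const(dist, q, k) + schulz_avg_cos(dist, q, k, freq = 2)),
    sin2 = 0.5 * (schulz_avg_const(dist, q, k) - schulz_avg_cos(dist, q, k, freq = 2)),
    sincos = 0.5 * schulz_avg_cos(dist, q, k, freq = 2, phase = -pi / 2)
  )
}

#' Uniaxial orientation distribution
#'
#' Distribution of the deviation angle \eqn{\delta \in [0, \pi/2]} of the
#' particle axis from the director, weighted by \eqn{\sin\delta}.
#' \code{"delta"} is perfect alignment (point mass at 0),
#' \code{"uniform_isotropic"} the isotropic sphere, and
#' \code{"gaussian_cone"} a wrapped Gaussian
#' \eqn{h(\delta) \propto \exp(-\delta^2 / 2 w^2)}.
#'
#' @param kind Distribution family.
#' @param width Cone width w in radians (\code{gaussian_cone} only).
#' @return An object of class \code{orientation_dist}.
#' @export
orientation_dist <- function(kind = c("delta", "uniform_isotropic", "gaussian_cone"),
                             width = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian_cone") {
    stopifnot(!is.null(width), width >= 0)
    if (width == 0) kind <- "delta"
  }
  structure(list(kind = kind, width = width), class = "orientation_dist")
}

orientation_h <- function(odist, delta) {
  switch(odist$kind,
    uniform_isotropic = rep(1, length(delta)),
    gaussian_cone = exp(-delta^2 / (2 * odist$width^2)),
    stop("no density for kind ", odist$kind)
  )
}

## Gauss-Legendre nodes of the normalized measure h(delta) sin(delta) ddelta
## on [0, pi/2]; node count doubled until the normalization integral is
## stable to 1e-10 (entries are smooth polynomials in sin/cos, so this is a
## conservative proxy for all H entries).
orientation_nodes <- function(odist, n0 = 64L) {
  if (odist$kind == "delta") return(list(delta = 0, w = 1))
  n <- n0
  prev <- NA_real_
  repeat {
    gl <- pracma::gaussLegendre(n, 0, pi / 2)
    w <- gl$w * orientation_h(odist, gl$x) * sin(gl$x)
    tot <- sum(w)
    if (!is.na(prev) && abs(tot - prev) <= 1e-10 * tot) {
      return(list(delta = gl$x, w = w / tot))
    }
    if (n >= 4096L) stop("orientation quadrature did not converge")
    prev <- tot
    n <- n * 2L
  }
}

#' Orientation H-integrals
#'
#' Pre-computes the q-independent matrix
#' \eqn{H_{2l,2m} = \langle \cos^{2l}\!\delta \, \sin^{2m}\!\delta \rangle}
#' over the normalized measure \eqn{h(\delta)\sin\delta \, d\delta} for all
#' \eqn{l + m \le n_{max}}.  These enter the averaged phase powers
#' \eqn{\langle (qL)^{2n} \rangle} of oriented anisometric particles.
#'
#' @param odist An [orientation_dist()].
#' @param n_max Maximum total order \eqn{l + m}.
#' @return Matrix \code{H} with \code{H[l+1, m+1]} = \eqn{H_{2l,2m}};
#'   rows index the cosine power.
#' @examples
#' H <- h_integrals(orientation_dist("uniform_isotropic"), 2)
#' H[2, 1]  # <cos^2> = 1/3
#' @export
h_integrals <- function(odist, n_max) {
  stopifnot(inherits(odist, "orientation_dist"), n_max >= 1)
  H <- matrix(NA_real_, n_max + 1L, n_max + 1L,
              dimnames = list(paste0("cos", 2 * (0:n_max)),
                              paste0("sin", 2 * (0:n_max))))
  if (odist$kind == "delta") {
    for (l in 0:n_max) for (m in 0:(n_max - l)) H[l + 1, m + 1] <- as.numeric(m == 0)
    return(H)
  }
  nd <- orientation_nodes(odist)
  c2 <- cos(nd$delta)^2
  s2 <- sin(nd$delta)^2
  for (l in 0:n_max) {
    for (m in 0:(n_max - l)) {
      H[l + 1, m + 1] <- sum(nd$w * c2^l * s2^m)
    }
  }
  H
}

#' Orientational order parameter
#'
#' \eqn{S = \langle (3\cos^2\delta - 1)/2 \rangle = (3 H_{2,0} - 1)/2}:
#' 1 for perfect alignment, 0 for the isotropic distribution.
#'
#' @param odist An [orientation_dist()].
#' @return S in \[-1/2, 1\].
#' @export
order_parameter <- function(odist) {
  if (odist$kind == "delta") return(1)
  if (odist$kind == "uniform_isotropic") {
    # <cos^2> over the uniform sphere octant is exactly 1/3
    return(0)
  }
  H <- h_integrals(odist, 1L)
  (3 * H[2, 1] - 1) / 2
}
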