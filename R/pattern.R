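# Detector q-mapping, intensity assembly in the decoupling approximation,
# point-spread-function convolution, and the grazing-incidence (DWBA)
# extension with Fresnel film optics.

#' Detector geometry
#'
#' @param nx,ny Pixel counts (columns, rows).
#' @param pixel_size Pixel edge (mm).
#' @param wavelength Wavelength (nm).
#' @param distance Sample-detector distance (mm).
#' @param beam_center (x, y) beam position in fractional pixels.
#' @param mode \code{"small_angle"} (flat-Ewald approximation) or
#'   \code{"exact"}.
#' @return An object of class \code{detector_geometry}.
#' @export
detector_geometry <- function(nx = 256L, ny = 256L, pixel_size = 0.5,
                              wavelength = 0.1, distance = 1000,
                              beam_center = c(nx / 2, ny / 2),
                              mode = c("small_angle", "exact")) {
  mode <- match.arg(mode)
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0, wavelength > 0, distance > 0,
            length(beam_center) == 2L)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, wavelength = wavelength,
                 distance = distance, beam_center = as.numeric(beam_center),
                 mode = mode),
            class = "detector_geometry")
}

#' Per-pixel scattering-vector map
#'
#' Maps pixel centers to scattering vectors.  In small-angle mode
#' \eqn{q = 2\pi/(\lambda d)\,(x, y, 0)}; in exact mode the full elastic
#' map \eqn{q = (2\pi/\lambda)(\sin\vartheta\, x/r, \sin\vartheta\, y/r,
#' 1-\cos\vartheta)} with \eqn{\tan\vartheta = r/d}.
#'
#' @param det A [detector_geometry()].
#' @return List of matrices \code{qx}, \code{qy}, \code{qz} (ny rows by nx
#'   columns, nm^-1) and \code{qmag}.
#' @export
q_map <- function(det) {
  stopifnot(inherits(det, "detector_geometry"))
  xs <- ((seq_len(det$nx) - 0.5) - det$beam_center[1]) * det$pixel_size
  ys <- ((seq_len(det$ny) - 0.5) - det$beam_center[2]) * det$pixel_size
  X <- matrix(xs, det$ny, det$nx, byrow = TRUE)
  Y <- matrix(ys, det$ny, det$nx)
  k <- 2 * pi / det$wavelength
  if (det$mode == "small_angle") {
    qx <- k * X / det$distance
    qy <- k * Y / det$distance
    qz <- matrix(0, det$ny, det$nx)
  } else {
    r <- sqrt(X^2 + Y^2)
    th <- atan2(r, det$distance)
    dirx <- ifelse(r > 0, X / pmax(r, 1e-300), 0)
    diry <- ifelse(r > 0, Y / pmax(r, 1e-300), 0)
    qx <- k * sin(th) * dirx
    qy <- k * sin(th) * diry
    qz <- k * (1 - cos(th))
  }
  list(qx = qx, qy = qy, qz = qz, qmag = sqrt(qx^2 + qy^2 + qz^2))
}

#' Intensity parameters
#'
#' @param contrast Scattering contrast \eqn{\Delta b} (arbitrary units).
#' @param number_density Particle number density \eqn{\rho_N} (nm^-3).
#' @param include_lattice Include the lattice correlation term.
#' @return An object of class \code{intensity_params}.
#' @export
intensity_params <- function(contrast = 1, number_density = 1e-4,
                             include_lattice = TRUE) {
  stopifnot(number_density >= 0)
  structure(list(contrast = contrast, number_density = number_density,
                 include_lattice = include_lattice),
            class = "intensity_params")
}

## shared decoupling-approximation assembly on arbitrary q arrays
intensity_core <- function(model, qx, qy, qz, params, lattice = NULL,
                           peak = NULL, basis = NULL, reflections = NULL) {
  qmag <- sqrt(qx^2 + qy^2 + qz^2)
  qv <- pmax(qmag, 1e-12)
  P <- if (!is.null(model$oriented)) {
    pq_oriented(model, as.numeric(qx), as.numeric(qy))
  } else {
    pq_iso(model, as.numeric(qv))
  }
  P <- pmax(P, 0)
  bracket <- 1
  if (isTRUE(params$include_lattice) && !is.null(reflections)) {
    Fm <- fq_mean(model, as.numeric(qv))
    beta <- ifelse(P > 0, pmin(1, pmax(0, Fm^2 / P)), 0)
    Z <- lattice_factor_2d(reflections, peak, basis,
                           as.numeric(qx), as.numeric(qy), as.numeric(qz))
    G <- debye_waller(as.numeric(qv), peak$debye_waller_sigma)
    bracket <- 1 + beta * (Z - 1) * G
  }
  I <- params$contrast^2 * params$number_density * P * bracket
  if (any(I < -1e-12 * max(abs(I)))) {
    stop("internal consistency error: negative intensity")
  }
  array(pmax(I, 0), dim = dim(qx))
}

#' 2D detector intensity pattern
#'
#' Evaluates the decoupling-approximation intensity
#' \eqn{I(q) = (\Delta b)^2 \rho_N \langle P\rangle
#'   [1 + \beta (\langle Z\rangle - 1) G(q)]},
#' \eqn{\beta = \langle F\rangle^2/\langle P\rangle}, on every detector
#' pixel using only pre-computed coefficients.
#'
#' @param model A [sas_precompute()] model (optionally oriented).
#' @param det A [detector_geometry()].
#' @param params An [intensity_params()].
#' @param cell Optional [unit_cell()] for the lattice factor.
#' @param peak A [peak_shape()] (required with \code{cell}).
#' @param qmax_lattice Reflection cutoff; defaults to the largest pixel q.
#' @return An object of class \code{sas_pattern}: list with the intensity
#'   matrix \code{I}, the q maps and the inputs.
#' @export
intensity_pattern <- function(model, det, params = intensity_params(),
                              cell = NULL, peak = NULL, qmax_lattice = NULL) {
  qm <- q_map(det)
  basis <- NULL; refl <- NULL
  if (!is.null(cell) && isTRUE(params$include_lattice)) {
    if (is.null(peak)) stop("a peak_shape is required with a lattice")
    basis <- reciprocal_basis(cell)
    if (is.null(qmax_lattice)) {
      qmax_lattice <- max(qm$qmag) + 6 * peak$sigma_q
    }
    refl <- enumerate_reflections(basis, cell, qmax_lattice)
  }
  I <- intensity_core(model, qm$qx, qm$qy, qm$qz, params,
                      peak = peak, basis = basis, reflections = refl)
  structure(list(I = I, q = qm, det = det, params = params,
                 cell = cell, peak = peak),
            class = "sas_pattern")
}

#' 1D scattering curve
#'
#' The radially sampled analogue of [intensity_pattern()]: intensity on a
#' q grid with the powder-averaged lattice factor.
#'
#' @param model A [sas_precompute()] model.
#' @param q Positive q grid (nm^-1).
#' @param params An [intensity_params()].
#' @param cell,peak Optional lattice inputs.
#' @return data.frame with q, I and the components P, Z, beta.
#' @export
intensity_curve <- function(model, q, params = intensity_params(),
                            cell = NULL, peak = NULL) {
  stopifnot(all(q > 0))
  P <- pmax(pq_iso(model, q), 0)
  Z <- rep(1, length(q))
  beta <- rep(0, length(q))
  G <- rep(1, length(q))
  if (!is.null(cell) && isTRUE(params$include_lattice)) {
    if (is.null(peak)) stop("a peak_shape is required with a lattice")
    basis <- reciprocal_basis(cell)
    refl <- enumerate_reflections(basis, cell, max(q) + 6 * peak$sigma_q)
    Z <- lattice_factor_1d_iso(refl, peak, basis, q)
    Fm <- fq_mean(model, q)
    beta <- ifelse(P > 0, pmin(1, pmax(0, Fm^2 / P)), 0)
    G <- debye_waller(q, peak$debye_waller_sigma)
  }
  I <- params$contrast^2 * params$number_density * P * (1 + beta * (Z - 1) * G)
  data.frame(q = q, I = I, P = P, Z = Z, beta = beta)
}

#' Convolve a pattern with a point-spread function
#'
#' Direct-sum 2D convolution with replicate padding at the edges; the
#' kernel must sum to one so that total intensity is conserved away from
#' the borders.
#'
#' @param pattern An \code{sas_pattern} or a numeric matrix.
#' @param psf Kernel matrix with odd dimensions, summing to 1 (tolerance
#'   1e-8).
#' @return Same type as the input with the blurred intensity.
#' @export
convolve_psf <- function(pattern, psf) {
  M <- if (inherits(pattern, "sas_pattern")) pattern$I else pattern
  psf <- as.matrix(psf)
  if (abs(sum(psf) - 1) > 1e-8) stop("PSF kernel must be normalized to unit sum")
  if (any(dim(psf) %% 2 == 0)) stop("PSF kernel dimensions must be odd")
  ry <- (nrow(psf) - 1L) %/% 2L
  rx <- (ncol(psf) - 1L) %/% 2L
  ny <- nrow(M); nx <- ncol(M)
  # replicate-pad
  yi <- pmin(pmax(seq(1 - ry, ny + ry), 1L), ny)
  xi <- pmin(pmax(seq(1 - rx, nx + rx), 1L), nx)
  P <- M[yi, xi, drop = FALSE]
  out <- matrix(0, ny, nx)
  for (i in seq_len(nrow(psf))) {
    for (j in seq_len(ncol(psf))) {
      if (psf[i, j] == 0) next
      out <- out + psf[i, j] * P[(i - 1L) + seq_len(ny), (j - 1L) + seq_len(nx)]
    }
  }
  if (inherits(pattern, "sas_pattern")) {
    pattern$I <- out
    pattern
  } else out
}

#' Gaussian PSF kernel
#'
#' @param sigma_px Width in pixels.
#' @param radius Kernel half-size in pixels (default 3 sigma).
#' @return Normalized kernel matrix.
#' @export
gaussian_psf <- function(sigma_px, radius = ceiling(3 * sigma_px)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_px^2))
  K <- outer(k, k)
  K / sum(K)
}

#' Grazing-incidence film optics
#'
#' @param alpha_i Incident grazing angle (degrees), positive.
#' @param delta,beta Refractive-index decrements of the film layer
#'   (n = 1 - delta + i beta).
#' @return An object of class \code{gisas_film}.
#' @export
gisas_film <- function(alpha_i, delta, beta = 0) {
  stopifnot(alpha_i > 0, delta >= 0, beta >= 0)
  structure(list(alpha_i = alpha_i, delta = delta, beta = beta),
            class = "gisas_film")
}

#' Fresnel coefficients at grazing incidence
#'
#' Amplitude transmission and reflection of a vacuum/medium interface with
#' refractive index \eqn{n = 1 - \delta + i\beta} at grazing angle
#' \eqn{\alpha}: \eqn{r = (k_z - k_{z,t})/(k_z + k_{z,t})},
#' \eqn{t = 2 k_z/(k_z + k_{z,t})} with \eqn{k_{z,t} =
#' k\sqrt{n^2 - \cos^2\alpha}}.  At the critical angle
#' (\eqn{\cos\alpha_c = n}, \eqn{\beta = 0}) the transmitted
#' \eqn{k_{z,t} = 0} and \eqn{|t|^2 = 4} -- the Yoneda enhancement.
#'
#' @param alpha Grazing angle(s) in degrees.
#' @param delta,beta Index decrements.
#' @return List with complex \code{T} and \code{R}.
#' @export
fresnel <- function(alpha, delta, beta = 0) {
  a <- alpha * pi / 180
  n2 <- (1 - delta + 1i * beta)^2
  kz <- sin(a)
  kzt <- sqrt(as.complex(n2 - cos(a)^2))
  # branch: transmitted wave decays into the medium
  kzt <- ifelse(Im(kzt) < 0, -kzt, kzt)
  list(T = 2 * kz / (kz + kzt), R = (kz - kzt) / (kz + kzt))
}

#' Critical grazing angle
#'
#' \eqn{\alpha_c = \arccos(1 - \delta)}, the angle of total external
#' reflection (degrees).
#'
#' @param delta Real index decrement.
#' @return Angle in degrees.
#' @export
critical_angle <- function(delta) acos(1 - delta) * 180 / pi

#' GISAS pattern in the distorted-wave Born approximation
#'
#' Four-channel DWBA sum
#' \eqn{I_G = |T_i|^2 |T_f|^2 [I(q_1) + |R_i|^2 I(q_2) + |R_f|^2 I(q_3) +
#' |R_i|^2 |R_f|^2 I(q_4)]} where the four channels share the in-plane
#' momentum transfer and differ in the sign combinations of the
#' perpendicular components \eqn{\pm k_{z,f} \mp k_{z,i}}.  The incident
#' factors are q-independent and pre-computed; the exit factors vary per
#' detector row.  The beam-center row is the sample horizon
#' (\eqn{\alpha_f = 0}); rows below it are shadowed by the film.
#'
#' With \code{film = NULL} this is exactly [intensity_pattern()].
#'
#' @param model A [sas_precompute()] model.
#' @param det A [detector_geometry()].
#' @param film A [gisas_film()] or NULL.
#' @param params An [intensity_params()].
#' @param cell,peak Optional lattice inputs.
#' @return An \code{sas_pattern}.
#' @export
gisas_intensity <- function(model, det, film, params = intensity_params(),
                            cell = NULL, peak = NULL) {
  if (is.null(film)) {
    return(intensity_pattern(model, det, params, cell = cell, peak = peak))
  }
  stopifnot(inherits(film, "gisas_film"))
  qm <- q_map(det)
  k <- 2 * pi / det$wavelength
  ys <- ((seq_len(det$ny) - 0.5) - det$beam_center[2]) * det$pixel_size
  alpha_f <- atan2(ys, det$distance) * 180 / pi   # degrees, per detector row

  fi <- fresnel(film$alpha_i, film$delta, film$beta)
  Ti2 <- Mod(fi$T)^2
  Ri2 <- Mod(fi$R)^2

  basis <- NULL; refl <- NULL
  if (!is.null(cell) && isTRUE(params$include_lattice)) {
    if (is.null(peak)) stop("a peak_shape is required with a lattice")
    basis <- reciprocal_basis(cell)
    qmax_l <- max(qm$qmag) + k * sin(film$alpha_i * pi / 180) + 6 * peak$sigma_q
    refl <- enumerate_reflections(basis, cell, qmax_l)
  }

  kzi <- k * sin(film$alpha_i * pi / 180)
  kzf_row <- k * sin(pmax(alpha_f, 0) * pi / 180)
  Tf <- fresnel(pmax(alpha_f, 1e-9), film$delta, film$beta)
  Tf2 <- ifelse(alpha_f > 0, Mod(Tf$T)^2, 0)
  Rf2 <- ifelse(alpha_f > 0, Mod(Tf$R)^2, 0)

  nx <- det$nx; ny <- det$ny
  KZF <- matrix(kzf_row, ny, nx)
  I <- matrix(0, ny, nx)
  zero <- matrix(0, ny, nx)
  # channels (+-kzf -+kzi); the vertical axis carries the channel q_z, and
  # in the lattice frame (beam parallel to the rotated uvw axis) the beam
  # component of q is ~0, so the vertical q_z maps onto the second in-plane
  # lattice coordinate -- the (hk0) fiber geometry
  chan <- list(
    list(w = rep(1, ny),   qz = KZF + kzi),
    list(w = rep(Ri2, ny), qz = KZF - kzi),
    list(w = Rf2,          qz = -KZF + kzi),
    list(w = Rf2 * Ri2,    qz = -KZF - kzi))
  for (ch in chan) {
    Ic <- intensity_core(model, qm$qx, ch$qz, zero,
                         params, peak = peak, basis = basis, reflections = refl)
    I <- I + matrix(ch$w, ny, nx) * Ic
  }
  I <- matrix(Ti2 * Tf2, ny, nx) * I
  structure(list(I = I, q = qm, det = det, params = params,
                 cell = cell, peak = peak, film = film, alpha_f = alpha_f),
            class = "sas_pattern")
}
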