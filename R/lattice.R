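# Crystallographic machinery: unit-cell to reciprocal-space transforms with
# the beam-alignment rotation, reflection enumeration under the SC/BCC/FCC
# (or custom-basis) structure-factor rules, normalized peak shapes, the
# Debye-Waller factor, and the lattice factor Z(q) in oriented-2D and
# powder-averaged 1D forms.  All reflection tables are q-independent and
# pre-computed once.

#' Unit-cell specification
#'
#' @param a,b,c Edge lengths (nm).
#' @param alpha,beta,gamma Cell angles (degrees), in (0, 180).
#' @param lattice_type \code{"SC"}, \code{"BCC"}, \code{"FCC"} or
#'   \code{"custom"}; custom cells take fractional \code{basis} positions.
#' @param uvw Integer triple: the direction (in cell coordinates) parallel
#'   to the probe beam.
#' @param basis Matrix (n x 3) of fractional coordinates for
#'   \code{lattice_type = "custom"}.
#' @return An object of class \code{unit_cell}.
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90,
                      lattice_type = c("SC", "BCC", "FCC", "custom"),
                      uvw = c(0, 0, 1), basis = NULL) {
  lattice_type <- match.arg(lattice_type)
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180, gamma > 0, gamma < 180,
            length(uvw) == 3L, any(uvw != 0))
  if (lattice_type == "custom") {
    if (is.null(basis)) stop("custom lattice needs a basis matrix")
    basis <- as.matrix(basis)
    stopifnot(ncol(basis) == 3L)
  } else {
    basis <- switch(lattice_type,
      SC = matrix(0, 1, 3),
      BCC = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
      FCC = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)))
  }
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 lattice_type = lattice_type, uvw = as.numeric(uvw),
                 basis = basis),
            class = "unit_cell")
}

## rotation taking unit vector v onto unit vector n (Rodrigues)
rotation_onto <- function(v, n) {
  v <- v / sqrt(sum(v^2)); n <- n / sqrt(sum(n^2))
  c_ <- sum(v * n)
  ax <- c(v[2] * n[3] - v[3] * n[2], v[3] * n[1] - v[1] * n[3], v[1] * n[2] - v[2] * n[1])
  s_ <- sqrt(sum(ax^2))
  if (s_ < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to v
    p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * v) * v; ax <- ax / sqrt(sum(ax^2))
    Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * Kx %*% Kx)
  }
  ax <- ax / s_
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(acos(pmin(pmax(c_, -1), 1))) * Kx +
    (1 - c_) * Kx %*% Kx
}

#' Reciprocal basis of a unit cell
#'
#' Builds the Cartesian cell vectors from (a, b, c; alpha, beta, gamma),
#' rotates them so that the (uvw) direction is parallel to the beam axis
#' (+z), and returns the 2\eqn{\pi}-convention reciprocal vectors
#' satisfying \eqn{a\cdot a^* = 2\pi} and zero cross terms.
#'
#' @param cell A [unit_cell()].
#' @return List with matrices \code{real} and \code{recip} (columns are the
#'   basis vectors, nm and nm^-1).
#' @export
reciprocal_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  # standard crystallographic Cartesian frame
  av <- cell$a * c(1, 0, 0)
  bv <- cell$b * c(cg, sg, 0)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("degenerate cell angles")
  cv <- cell$c * c(cb, (ca - cb * cg) / sg, sqrt(cz2))
  B <- cbind(av, bv, cv)
  if (abs(det(B)) < 1e-12) stop("singular cell")
  r_uvw <- B %*% cell$uvw
  R <- rotation_onto(as.numeric(r_uvw), c(0, 0, 1))
  Br <- R %*% B
  recip <- 2 * pi * t(solve(Br))
  list(real = Br, recip = recip, cell_volume = abs(det(B)))
}

## |f_hkl|^2 normalized per basis atom
structure_factor2 <- function(h, k, l, basis) {
  n <- nrow(basis)
  ph <- 2 * pi * (outer(h, basis[, 1]) + outer(k, basis[, 2]) + outer(l, basis[, 3]))
  (rowSums(cos(ph))^2 + rowSums(sin(ph))^2) / n^2
}

#' Enumerate reflections up to a q cutoff
#'
#' Lists all (hkl) with \eqn{|q^*_{hkl}| \le q_{max}} and non-vanishing
#' structure factor (FCC: h,k,l of equal parity; BCC: h+k+l even; SC: all;
#' custom: explicit basis sum).  The list is closed under Friedel
#' inversion.
#'
#' @param basis Result of [reciprocal_basis()].
#' @param cell The [unit_cell()].
#' @param qmax Cutoff (nm^-1).
#' @return data.frame with h, k, l, qx, qy, qz, qmag, f2.
#' @export
enumerate_reflections <- function(basis, cell, qmax) {
  stopifnot(qmax > 0)
  # rigorous index bounds: h = a . q* / 2pi
  hmax <- ceiling(qmax * cell$a / (2 * pi))
  kmax <- ceiling(qmax * cell$b / (2 * pi))
  lmax <- ceiling(qmax * cell$c / (2 * pi))
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  keep <- switch(cell$lattice_type,
    SC = rep(TRUE, nrow(g)),
    BCC = (g$h + g$k + g$l) %% 2 == 0,
    FCC = (g$h %% 2 == 0 & g$k %% 2 == 0 & g$l %% 2 == 0) |
          (g$h %% 2 != 0 & g$k %% 2 != 0 & g$l %% 2 != 0),
    custom = rep(TRUE, nrow(g)))
  g <- g[keep, ]
  f2 <- structure_factor2(g$h, g$k, g$l, cell$basis)
  nz <- f2 > 1e-12
  g <- g[nz, ]; f2 <- f2[nz]
  qs <- basis$recip %*% t(as.matrix(g))
  qmag <- sqrt(colSums(qs^2))
  inside <- qmag <= qmax
  data.frame(h = g$h[inside], k = g$k[inside], l = g$l[inside],
             qx = qs[1, inside], qy = qs[2, inside], qz = qs[3, inside],
             qmag = qmag[inside], f2 = f2[inside])
}

#' Peak-shape specification
#'
#' Normalized three-dimensional peak profiles for the lattice factor:
#' Gaussian, Lorentzian-squared (the normalizable 3D analogue) or their
#' pseudo-Voigt mixture, plus the Debye-Waller width.
#'
#' @param kind \code{"gaussian"}, \code{"lorentzian"} or
#'   \code{"pseudo_voigt"}.
#' @param sigma_q Peak width (nm^-1).
#' @param eta Pseudo-Voigt mixing in \[0,1\] (0 = Gaussian).
#' @param debye_waller_sigma Displacement parameter (nm) of the
#'   Debye-Waller factor.
#' @return An object of class \code{peak_shape}.
#' @export
peak_shape <- function(kind = c("gaussian", "lorentzian", "pseudo_voigt"),
                       sigma_q = 0.02, eta = 0, debye_waller_sigma = 0) {
  kind <- match.arg(kind)
  stopifnot(sigma_q > 0, eta >= 0, eta <= 1, debye_waller_sigma >= 0)
  eta <- switch(kind, gaussian = 0, lorentzian = 1, pseudo_voigt = eta)
  structure(list(kind = kind, sigma_q = sigma_q, eta = eta,
                 debye_waller_sigma = debye_waller_sigma),
            class = "peak_shape")
}

## unit-integral 3D profiles of the radial offset dq
peak3d <- function(peak, dq2) {
  s <- peak$sigma_q
  gauss <- exp(-dq2 / (2 * s^2)) / ((2 * pi)^1.5 * s^3)
  if (peak$eta == 0) return(gauss)
  lor <- s / (pi^2 * (dq2 + s^2)^2)
  (1 - peak$eta) * gauss + peak$eta * lor
}

## exact spherical (powder) average of the 3D profile centered at q0,
## evaluated on the sphere of radius q
peak3d_powder <- function(peak, q, q0) {
  s <- peak$sigma_q
  # (1/(2pi)^{3/2} s^3) * s^2/(2 q q0) * [exp(-(q-q0)^2/2s^2) - exp(-(q+q0)^2/2s^2)]
  gauss <- (exp(-(q - q0)^2 / (2 * s^2)) - exp(-(q + q0)^2 / (2 * s^2))) *
    s^2 / (2 * q * q0) / ((2 * pi)^1.5 * s^3)
  if (peak$eta == 0) return(gauss)
  A <- q^2 + q0^2 + s^2
  B <- 2 * q * q0
  lor <- s / (pi^2 * (A - B) * (A + B))
  (1 - peak$eta) * gauss + peak$eta * lor
}

#' Debye-Waller factor
#'
#' \eqn{G(q) = \exp(-\sigma_{DW}^2 q^2)}: Gaussian damping of the lattice
#' peaks by positional disorder.
#'
#' @param q Scattering-vector magnitude(s) (nm^-1).
#' @param sigma_dw Displacement parameter (nm).
#' @return Values in \[0, 1\], monotone decreasing in q.
#' @export
debye_waller <- function(q, sigma_dw) {
  stopifnot(all(q >= 0), sigma_dw >= 0)
  exp(-sigma_dw^2 * q^2)
}

## lattice factor amplitude: (2pi)^3/V_cell sets the baseline-1 convention
lattice_amplitude <- function(basis) (2 * pi)^3 / basis$cell_volume

#' Oriented 2D lattice factor
#'
#' \eqn{Z(q) = 1 + \frac{(2\pi)^3}{V}\sum_{hkl} |f_{hkl}|^2
#' L(q - q^*_{hkl})} over the pre-enumerated reflections; normalized peaks
#' make \eqn{Z \to 1} far from every reflection, so the correlation term of
#' the decoupling approximation vanishes there.
#'
#' @param reflections From [enumerate_reflections()].
#' @param peak A [peak_shape()].
#' @param basis The [reciprocal_basis()] (for the amplitude convention).
#' @param qx,qy,qz Scattering-vector components (vectors of equal length;
#'   \code{qz} defaults to 0, the detector plane).
#' @return Z values, \eqn{\ge} baseline away from peaks.
#' @export
lattice_factor_2d <- function(reflections, peak, basis, qx, qy, qz = 0) {
  if (length(qz) == 1L) qz <- rep(qz, length(qx))
  amp <- lattice_amplitude(basis)
  z <- rep(1, length(qx))
  for (i in seq_len(nrow(reflections))) {
    dq2 <- (qx - reflections$qx[i])^2 + (qy - reflections$qy[i])^2 +
      (qz - reflections$qz[i])^2
    z <- z + amp * reflections$f2[i] * peak3d(peak, dq2)
  }
  z
}

#' Powder-averaged 1D lattice factor
#'
#' Closed-form azimuthal (Debye-Scherrer) average of the 2D lattice factor:
#' reflections collapse onto rings at \eqn{|q^*_{hkl}|} with multiplicity
#' weights, each ring contributing its exact spherical peak average.
#'
#' @param reflections From [enumerate_reflections()].
#' @param peak A [peak_shape()].
#' @param basis The [reciprocal_basis()].
#' @param q Positive magnitudes (nm^-1).
#' @return Z(q) values.
#' @export
lattice_factor_1d_iso <- function(reflections, peak, basis, q) {
  stopifnot(all(q > 0))
  rings <- ring_table(reflections)
  amp <- lattice_amplitude(basis)
  z <- rep(1, length(q))
  for (i in seq_len(nrow(rings))) {
    z <- z + amp * rings$mf2[i] * peak3d_powder(peak, q, rings$q[i])
  }
  z
}

## group reflections into powder rings (multiplicity x f2 summed)
ring_table <- function(reflections) {
  key <- round(reflections$qmag, 9)
  agg <- stats::aggregate(reflections$f2, list(q = key), sum)
  data.frame(q = agg$q, mf2 = agg$x,
             multiplicity = as.integer(table(key)[as.character(agg$q)]))
}
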