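# Regime-switched, size- and orientation-averaged form factors.
#
# Every supported body is built from 0F1 amplitude "factors" of
# dimensionality d = 1 (slab axis), 2 (circular cross-section) or
# 3 (sphere-like), evaluated in the dimensionless variable x = q g s where
# g is the characteristic half-extent and s the Schulz-distributed scale.
# Each factor carries three representations of its size-averaged squared
# amplitude <f_d^2>:
#
#   Regime I   power series  sum_n p_n x^{2n}       (q-independent p_n)
#   Regime II  trigonometric closed form built from <cos(2xs + phi)(xs)^-m>
#              (exact for d = 1, 3; K-term asymptotic for d = 2)
#   Regime III its non-oscillating part (the Porod asymptote)
#
# Anisometric shapes combine factors over pre-computed orientation nodes,
# so the per-q work is a polynomial (Regime I) or a short trigonometric
# node sum (Regimes II/III) -- no numerical integration at evaluation time.

# ---------------------------------------------------------------------------
# shape specification

#' Particle shape specification
#'
#' @param kind One of \code{"sphere"}, \code{"cylinder"}, \code{"disk"},
#'   \code{"lamella"}, \code{"biaxial_ellipsoid"},
#'   \code{"triaxial_ellipsoid"}, \code{"cube"}, \code{"parallelepiped"}.
#' @param ... Named sizes in nm: sphere \code{radius}; cylinder
#'   \code{radius, length}; disk \code{thickness, diameter}; lamella
#'   \code{thickness}; biaxial ellipsoid \code{a, c} (semi-axes a = b);
#'   triaxial ellipsoid \code{a, b, c} (semi-axes); cube \code{edge};
#'   parallelepiped \code{a, b, c} (edge lengths).
#' @return An object of class \code{sas_shape}.
#' @examples
#' shape_spec("cylinder", radius = 2, length = 12)
#' @export
shape_spec <- function(kind, ...) {
  kind <- match.arg(kind, c("sphere", "cylinder", "disk", "lamella",
                            "biaxial_ellipsoid", "triaxial_ellipsoid",
                            "cube", "parallelepiped"))
  sz <- list(...)
  need <- switch(kind,
    sphere = "radius", cylinder = c("radius", "length"),
    disk = c("thickness", "diameter"), lamella = "thickness",
    biaxial_ellipsoid = c("a", "c"), triaxial_ellipsoid = c("a", "b", "c"),
    cube = "edge", parallelepiped = c("a", "b", "c"))
  if (!setequal(names(sz), need)) {
    stop(kind, " requires sizes: ", paste(need, collapse = ", "))
  }
  sz <- sz[need]
  if (any(unlist(sz) <= 0)) stop("all sizes must be positive")
  structure(list(kind = kind, sizes = sz), class = "sas_shape")
}

dist_shift <- function(dist, j) {
  # Gamma(alpha + j, rate): the s^j-weighted (e.g. intensity-weighted) law
  if (j == 0 || is_monodisperse(dist)) return(dist)
  al <- dist$alpha + j
  structure(list(mean = al / dist$rate, sigma = 1 / sqrt(al), z = al - 1,
                 alpha = al, rate = dist$rate), class = "schulz_dist")
}

# ---------------------------------------------------------------------------
# single-factor evaluator

## K-term trigonometric representations per dimensionality; d = 1 and 3 are
## exact identities, d = 2 uses five terms of the Hankel expansion
## (envelope-relative error < 2e-5 for x >= 6).
factor_K <- function(d) switch(as.character(d), "1" = 1L, "2" = 5L, "3" = 2L)

make_factor <- function(d, dist, tol = 1e-6, boundary_tol = 1e-6,
                        n_max = 160L) {
  a <- hyper_a(d)
  nu <- hyper_nu(d)
  mono <- is_monodisperse(dist)
  al <- dist$alpha
  la <- dist$rate
  mu_s <- dist$mean

  K <- factor_K(d)
  if (!mono) {
    # highest inverse moment used is m = d + 1 + 2(K-1); keep it below alpha
    while (K > 2L && al <= d + 1 + 2 * (K - 1) + 1) K <- K - 1L
    if (al <= d + 1) stop("polydispersity too broad for the trigonometric regime (z <= ", d, ")")
  }
  ck <- f01_asym_coeffs(d, K)
  G <- f01_asym_prefactor(d) * 2^(-nu)

  mom_step <- function(n) {
    if (mono) mu_s^2 else (al + 2 * n - 2) * (al + 2 * n - 1) / la^2
  }

  # Regime I coefficients by pure recursion (squared amplitude, then amplitude)
  p <- numeric(n_max + 1L); p[1] <- 1
  f <- numeric(n_max + 1L); f[1] <- 1
  tp <- 1; tf <- 1
  for (n in seq_len(n_max)) {
    ms <- mom_step(n)
    tp <- tp * (-(a - 0.5 + n - 1) / ((2 * a - 2 + n) * (a + n - 1) * n)) * ms
    tf <- tf * (-1 / (4 * (a + n - 1) * n)) * ms
    p[n + 1L] <- tp
    f[n + 1L] <- tf
  }

  # Regime II tables: <P> = G^2 sum_j [A_j <(xs)^-m_j> + C_j <cos(2xs+phi_j)(xs)^-m_j>]
  jmax <- 2L * (K - 1L)
  A <- C <- numeric(jmax + 1L)
  for (k in seq_len(K) - 1L) {
    for (kp in seq_len(K) - 1L) {
      j <- k + kp
      A[j + 1L] <- A[j + 1L] + 0.5 * ck[k + 1L] * ck[kp + 1L] * cos((kp - k) * pi / 2)
      C[j + 1L] <- C[j + 1L] + 0.5 * ck[k + 1L] * ck[kp + 1L]
    }
  }
  mj <- d + 1 + 0:jmax
  phij <- pi * nu - (0:jmax) * pi / 2
  grj <- if (mono) rep(1, jmax + 1L) else exp(lgamma(al - mj) - lgamma(al))
  mk_f <- (seq_len(K) - 1L) - nu
  grk_f <- if (mono) rep(1, K) else exp(lgamma(al - mk_f) - lgamma(al))

  pq_trig <- function(x) {
    v <- 0
    for (j in 0:jmax) {
      v <- v + A[j + 1L] * schulz_avg_const(dist, x, mj[j + 1L], grj[j + 1L]) +
        C[j + 1L] * schulz_avg_cos(dist, x, mj[j + 1L], freq = 2,
                                   phase = phij[j + 1L], gamma_ratio = grj[j + 1L])
    }
    G^2 * v
  }
  pq_nonosc <- function(x) {
    v <- 0
    for (j in 0:jmax) {
      v <- v + A[j + 1L] * schulz_avg_const(dist, x, mj[j + 1L], grj[j + 1L])
    }
    G^2 * v
  }
  fq_trig <- function(x) {
    v <- 0
    for (k in seq_len(K) - 1L) {
      v <- v + ck[k + 1L] * schulz_avg_cos(dist, x, mk_f[k + 1L], freq = 1,
                                           phase = pi * (nu - k) / 2,
                                           gamma_ratio = grk_f[k + 1L])
    }
    G * v
  }
  fq_env <- function(x) G * schulz_avg_const(dist, x, -nu)

  # series/trigonometric crossover for the squared and plain amplitude
  grid <- exp(seq(log(0.2), log(90), length.out = 420L))
  b12 <- find_regime_boundary(
    f_lo = function(x) series_scan_eval(p, x),
    f_hi = function(x) pq_trig(x),
    grid = grid, tol = boundary_tol,
    scale = function(x) pq_nonosc(x))
  b12f <- find_regime_boundary(
    f_lo = function(x) series_scan_eval(f, x),
    f_hi = function(x) fq_trig(x),
    grid = grid, tol = boundary_tol,
    scale = function(x) fq_env(x))
  x12 <- b12$boundary
  x12f <- b12f$boundary
  n_use_p <- series_n_use(p, x12)
  n_use_f <- series_n_use(f, x12f)

  pq <- function(x) {
    out <- numeric(length(x))
    lo <- x <= x12
    if (any(lo)) out[lo] <- poly_eval_x2(p, n_use_p, x[lo])
    if (any(!lo)) out[!lo] <- pq_trig(x[!lo])
    out
  }
  fq <- function(x) {
    out <- numeric(length(x))
    lo <- x <= x12f
    if (any(lo)) out[lo] <- poly_eval_x2(f, n_use_f, x[lo])
    if (any(!lo)) out[!lo] <- fq_trig(x[!lo])
    out
  }

  list(d = d, dist = dist, K = K, ck = ck, G = G, nu = nu,
       p = p, f = f, n_use_p = n_use_p, n_use_f = n_use_f,
       x12 = x12, x12f = x12f, precision12 = b12$precision,
       pq = pq, fq = fq, pq_trig = pq_trig, pq_nonosc = pq_nonosc,
       fq_trig = fq_trig)
}

## Guarded scalar series evaluation used during boundary scans: NA signals
## non-convergence or cancellation-guard firing.
series_scan_eval <- function(coef, x, tol = 1e-9, guard = 1e12) {
  u <- x^2
  s <- coef[1L]
  up <- 1
  maxt <- abs(s)
  streak <- 0L
  for (n in 2:length(coef)) {
    up <- up * u
    term <- coef[n] * up
    if (!is.finite(term)) return(NA_real_)
    s <- s + term
    maxt <- max(maxt, abs(term))
    if (abs(term) < tol * max(abs(s), 1e-300)) {
      streak <- streak + 1L
      if (streak >= 2L) {
        if (maxt > guard * max(abs(s), 1e-300)) return(NA_real_)
        return(s)
      }
    } else streak <- 0L
  }
  NA_real_
}

series_n_use <- function(coef, x_hi, tol = 1e-14) {
  u <- x_hi^2
  up <- cumprod(c(1, rep(u, length(coef) - 1L)))
  t_abs <- abs(coef) * up
  below <- which(t_abs < tol)
  below <- below[below > 5L]
  n <- if (length(below)) min(below) else length(coef)
  min(n + 2L, length(coef))
}

poly_eval_x2 <- function(coef, n_use, x) {
  u <- x^2
  acc <- rep(coef[n_use], length(x))
  for (n in seq(n_use - 1L, 1L)) acc <- acc * u + coef[n]
  acc
}

# ---------------------------------------------------------------------------
# orientation node grids (q-independent pre-computation)

gauss01 <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

## Nodes for the isotropic orientational average over the unit sphere octant.
## 1D (axisymmetric bodies): t = cos(theta) on [0,1].
## 2D: tensor (t, phi) grid on [0,1] x [0, pi/2].
iso_nodes_1d <- function(n) gauss01(n)
iso_nodes_2d <- function(nt, nphi) {
  t <- gauss01(nt)
  gp <- pracma::gaussLegendre(nphi, 0, pi / 2)
  tt <- rep(t$x, times = nphi)
  pp <- rep(gp$x, each = nt)
  ww <- rep(t$w, times = nphi) * rep(gp$w, each = nt) / (pi / 2)
  list(t = tt, phi = pp, w = ww)
}

## <t^{2m} (1-t^2)^k> on t in [0,1]: exact Beta-function moments of the
## axisymmetric orientational average.
t_moment <- function(m, k) exp(lgamma(m + 0.5) + lgamma(k + 1) - lgamma(m + k + 1.5)) / 2

## <u1^{2i} u2^{2j} u3^{2k}> over the unit sphere: the double-factorial
## closed form (2i-1)!!(2j-1)!!(2k-1)!!/(2n+1)!!, n = i+j+k.
dir_moment <- function(i, j, k) {
  n <- i + j + k
  ldf <- function(m) lgamma(2 * m + 1) - m * log(2) - lgamma(m + 1)
  exp(ldf(i) + ldf(j) + ldf(k) - (lgamma(2 * n + 2) - n * log(2) - lgamma(n + 1)))
}

# ---------------------------------------------------------------------------
# model assembly

#' Pre-compute a form-factor model
#'
#' Builds the q-independent machinery of the regime-switched form factor of
#' a polydisperse shape: series coefficients (by recursion), closed-form
#' trigonometric tables, orientation nodes and regime boundaries.  The
#' subsequent evaluation by [pq_iso()] touches only polynomials and
#' elementary trigonometric functions.
#'
#' Polydispersity conventions: spheres, ellipsoids and cubes disperse a
#' single shape-preserving scale factor; cylinders, disks, lamellae and
#' parallelepipeds disperse every characteristic dimension independently.
#' \code{sigma} may be a single relative standard deviation applied to all
#' dimensions, or a vector matching the number of independent dimensions.
#'
#' @param shape A [shape_spec()].
#' @param sigma Relative size polydispersity (0 = monodisperse).
#' @param weighting \code{"number"} (the plain size-distribution average)
#'   or \code{"intensity"} (volume-squared weighting).
#' @param tol Relative tolerance for coefficient construction.
#' @param boundary_tol Relative tolerance of the regime-overlap scans.
#' @param n_orient Orientation nodes per angle for anisometric shapes.
#' @return An object of class \code{sas_model} with elements \code{series}
#'   (coefficients \code{c}, \code{n_max}, \code{tol}), \code{boundaries}
#'   (\code{q12}, \code{q23}, \code{precision}), \code{porod_constant} and
#'   the evaluation closures used by [pq_iso()] and [fq_mean()].
#' @export
sas_precompute <- function(shape, sigma = 0, weighting = c("number", "intensity"),
                           tol = 1e-6, boundary_tol = 1e-6, n_orient = NULL) {
  stopifnot(inherits(shape, "sas_shape"))
  weighting <- match.arg(weighting)
  kind <- shape$kind
  sz <- shape$sizes

  ndim <- switch(kind, sphere = 1L, cylinder = 2L, disk = 2L, lamella = 1L,
                 biaxial_ellipsoid = 1L, triaxial_ellipsoid = 1L,
                 cube = 1L, parallelepiped = 3L)
  if (length(sigma) == 1L) sigma <- rep(sigma, ndim)
  if (length(sigma) != ndim) stop(kind, " takes ", ndim, " polydispersity value(s)")
  dists <- lapply(sigma, function(s) schulz_dist(1, sigma = s))
  if (weighting == "intensity") {
    jshift <- switch(kind,
      sphere = 6, biaxial_ellipsoid = 6, triaxial_ellipsoid = 6, cube = 6,
      cylinder = c(4, 2), disk = c(2, 4), lamella = 2, parallelepiped = c(2, 2, 2))
    dists <- Map(dist_shift, dists, as.list(jshift))
  }

  model <- switch(kind,
    sphere = model_sphere(sz, dists, tol, boundary_tol),
    lamella = model_lamella(sz, dists, tol, boundary_tol),
    cylinder = ,
    disk = model_cyl_disk(kind, sz, dists, tol, boundary_tol, n_orient),
    biaxial_ellipsoid = ,
    triaxial_ellipsoid = model_ellipsoid(kind, sz, dists, tol, boundary_tol, n_orient),
    parallelepiped = model_ppiped(sz, dists, tol, boundary_tol, n_orient),
    cube = model_cube(sz, dists, tol, boundary_tol, n_orient))

  model$shape <- shape
  model$sigma <- sigma
  model$weighting <- weighting
  model$tol <- tol
  class(model) <- "sas_model"
  model
}

## Shared post-processing: model-level regime boundaries and the Porod
## single-term asymptote K (q R_ref)^-p_exp for Regime III.
finalize_model <- function(model, tol, boundary_tol) {
  r <- model$r_ref
  p_exp <- model$porod_exponent
  hi_x <- if (is.null(model$scan_hi)) 4000 else model$scan_hi
  n_scan <- if (is.null(model$scan_n)) 700L else model$scan_n
  qgrid <- exp(seq(log(0.02 / r), log(hi_x / r), length.out = n_scan))

  b12 <- find_regime_boundary(
    f_lo = function(q) series_scan_eval(model$series$c, q),
    f_hi = function(q) model$eval_trig(q),
    grid = qgrid, tol = boundary_tol,
    scale = function(q) model$eval_nonosc(q))
  q12 <- b12$boundary
  n_use <- series_n_use(model$series$c, q12)

  # Porod constant from the high-q limit of the non-oscillating evaluator
  q_top <- utils::tail(qgrid, 1)
  K <- model$eval_nonosc(q_top) * (q_top * r)^p_exp
  # Regime II -> III transition: the full trigonometric value must stay
  # within tol of the single Porod term over the following decade
  mono_all <- all(vapply(model$dists, is_monodisperse, TRUE))
  if (mono_all) {
    q23 <- Inf
    prec23 <- NA_real_
  } else {
    hi <- qgrid[qgrid > q12]
    full <- model$eval_trig(hi)
    porod <- K / (hi * r)^p_exp
    dev <- abs(full - porod) / porod
    ok_from <- NA_integer_
    for (i in seq_along(hi)) {
      dec <- hi >= hi[i] & hi <= 10 * hi[i]
      if (all(dev[dec] < 10 * boundary_tol)) { ok_from <- i; break }
    }
    if (is.na(ok_from)) {
      q23 <- Inf
      prec23 <- NA_real_
    } else {
      q23 <- hi[ok_from]
      prec23 <- dev[ok_from]
    }
  }

  model$boundaries <- list(q12 = q12, q23 = q23,
                           precision = c(q12 = b12$precision, q23 = prec23))
  model$porod_constant <- K
  model$n_use <- n_use
  model
}

model_sphere <- function(sz, dists, tol, boundary_tol) {
  r <- sz$radius
  fac <- make_factor(3L, dists[[1L]], tol, boundary_tol)
  cs <- fac$p * cumprod(c(1, rep(r^2, length(fac$p) - 1L)))
  m <- list(
    dists = dists, factors = list(fac), r_ref = r, porod_exponent = 4,
    series = list(c = cs, n_max = length(cs) - 1L, tol = tol),
    eval_trig = function(q) fac$pq_trig(q * r),
    eval_nonosc = function(q) fac$pq_nonosc(q * r),
    eval_full = function(q) fac$pq(q * r),
    eval_fq = function(q) fac$fq(q * r))
  finalize_model(m, tol, boundary_tol)
}

model_lamella <- function(sz, dists, tol, boundary_tol) {
  g <- sz$thickness / 2
  fac <- make_factor(1L, dists[[1L]], tol, boundary_tol)
  cs <- fac$p * cumprod(c(1, rep(g^2, length(fac$p) - 1L)))
  m <- list(
    dists = dists, factors = list(fac), r_ref = g, porod_exponent = 2,
    series = list(c = cs, n_max = length(cs) - 1L, tol = tol),
    eval_trig = function(q) fac$pq_trig(q * g),
    eval_nonosc = function(q) fac$pq_nonosc(q * g),
    eval_full = function(q) fac$pq(q * g),
    eval_fq = function(q) fac$fq(q * g))
  finalize_model(m, tol, boundary_tol)
}

model_cyl_disk <- function(kind, sz, dists, tol, boundary_tol, n_orient) {
  # axial slab factor (d = 1, half-extent along the symmetry axis) times
  # circular cross-section factor (d = 2)
  if (kind == "cylinder") {
    g_ax <- sz$length / 2; g_cr <- sz$radius
  } else {
    g_ax <- sz$thickness / 2; g_cr <- sz$diameter / 2
  }
  f_ax <- make_factor(1L, dists[[if (kind == "cylinder") 2L else 1L]], tol, boundary_tol)
  f_cr <- make_factor(2L, dists[[if (kind == "cylinder") 1L else 2L]], tol, boundary_tol)

  nt <- if (is.null(n_orient)) 256L else n_orient
  nd <- iso_nodes_1d(nt)
  t <- nd$x; w <- nd$w
  st <- sqrt(pmax(0, 1 - t^2))

  # global Regime I coefficients: convolution with exact Beta-moments of t
  N <- 80L
  pa <- f_ax$p[seq_len(N + 1L)] * cumprod(c(1, rep(g_ax^2, N)))
  pc <- f_cr$p[seq_len(N + 1L)] * cumprod(c(1, rep(g_cr^2, N)))
  cs <- numeric(N + 1L)
  for (n in 0:N) {
    mm <- 0:n
    tm <- vapply(mm, function(m) t_moment(m, n - m), 0)
    cs[n + 1L] <- sum(pa[mm + 1L] * pc[n - mm + 1L] * tm)
  }

  node_sum <- function(q, f1, f2) {
    vapply(q, function(qq) sum(w * f1(qq * t * g_ax) * f2(qq * st * g_cr)), 0)
  }
  m <- list(
    dists = dists, factors = list(axial = f_ax, cross = f_cr),
    g_ax = g_ax, g_cr = g_cr, nodes = nd,
    r_ref = min(g_ax, g_cr) * 2, porod_exponent = 4, scan_hi = 500,
    series = list(c = cs, n_max = N, tol = tol),
    eval_trig = function(q) node_sum(q, f_ax$pq, f_cr$pq),
    eval_nonosc = function(q) node_sum(q, function(x) pmin(f_ax$pq_nonosc(x), 1),
                                       function(x) pmin(f_cr$pq_nonosc(x), 1)),
    eval_full = function(q) node_sum(q, f_ax$pq, f_cr$pq),
    eval_fq = function(q) node_sum(q, f_ax$fq, f_cr$fq))
  finalize_model(m, tol, boundary_tol)
}

model_ellipsoid <- function(kind, sz, dists, tol, boundary_tol, n_orient) {
  fac <- make_factor(3L, dists[[1L]], tol, boundary_tol)
  if (kind == "biaxial_ellipsoid") {
    nt <- if (is.null(n_orient)) 256L else n_orient
    nd <- iso_nodes_1d(nt)
    reff <- sqrt(sz$a^2 * (1 - nd$x^2) + sz$c^2 * nd$x^2)
    w <- nd$w
  } else {
    nt <- if (is.null(n_orient)) 96L else n_orient
    nd <- iso_nodes_2d(nt, nt)
    s2 <- 1 - nd$t^2
    reff <- sqrt(sz$a^2 * s2 * cos(nd$phi)^2 + sz$b^2 * s2 * sin(nd$phi)^2 +
                 sz$c^2 * nd$t^2)
    w <- nd$w
  }
  # orientation moments <R_eff^{2n}> are polynomials in the node variables:
  # the Gauss grid integrates them exactly up to the series order used
  N <- 80L
  reff_mom <- vapply(0:N, function(n) sum(w * reff^(2 * n)), 0)
  cs <- fac$p[seq_len(N + 1L)] * reff_mom

  node_sum <- function(q, fn) {
    vapply(q, function(qq) sum(w * fn(qq * reff)), 0)
  }
  m <- list(
    dists = dists, factors = list(fac), nodes = nd, reff = reff, w_orient = w,
    r_ref = min(unlist(sz)), porod_exponent = 4, scan_hi = 1000,
    series = list(c = cs, n_max = N, tol = tol),
    eval_trig = function(q) node_sum(q, fac$pq),
    eval_nonosc = function(q) node_sum(q, function(x) pmin(fac$pq_nonosc(x), 1)),
    eval_full = function(q) node_sum(q, fac$pq),
    eval_fq = function(q) node_sum(q, fac$fq))
  finalize_model(m, tol, boundary_tol)
}

model_ppiped <- function(sz, dists, tol, boundary_tol, n_orient) {
  g <- unlist(sz) / 2
  facs <- lapply(1:3, function(i) make_factor(1L, dists[[i]], tol, boundary_tol))
  nt <- if (is.null(n_orient)) 64L else n_orient
  nd <- iso_nodes_2d(nt, nt)
  st <- sqrt(pmax(0, 1 - nd$t^2))
  u <- rbind(st * cos(nd$phi), st * sin(nd$phi), nd$t)
  w <- nd$w

  N <- 70L
  pg <- lapply(1:3, function(i) {
    facs[[i]]$p[seq_len(N + 1L)] * cumprod(c(1, rep(g[i]^2, N)))
  })
  cs <- numeric(N + 1L)
  for (n in 0:N) {
    acc <- 0
    for (i in 0:n) for (j in 0:(n - i)) {
      k <- n - i - j
      acc <- acc + pg[[1L]][i + 1L] * pg[[2L]][j + 1L] * pg[[3L]][k + 1L] *
        dir_moment(i, j, k)
    }
    cs[n + 1L] <- acc
  }

  node_sum <- function(q, fns) {
    vapply(q, function(qq) {
      sum(w * fns[[1L]](qq * u[1L, ] * g[1L]) *
            fns[[2L]](qq * u[2L, ] * g[2L]) *
            fns[[3L]](qq * u[3L, ] * g[3L]))
    }, 0)
  }
  pq_list <- lapply(facs, `[[`, "pq")
  fq_list <- lapply(facs, `[[`, "fq")
  nn_list <- lapply(facs, function(f) function(x) pmin(f$pq_nonosc(x), 1))
  m <- list(
    dists = dists, factors = facs, nodes = nd, u_orient = u, w_orient = w,
    g_half = g, r_ref = min(g) * 2, porod_exponent = 4, scan_hi = 500,
    series = list(c = cs, n_max = N, tol = tol),
    eval_trig = function(q) node_sum(q, pq_list),
    eval_nonosc = function(q) node_sum(q, nn_list),
    eval_full = function(q) node_sum(q, pq_list),
    eval_fq = function(q) node_sum(q, fq_list))
  finalize_model(m, tol, boundary_tol)
}

#' Isotropically averaged form factor
#'
#' Evaluates the size- and orientation-averaged form factor
#' \eqn{\langle P(q)\rangle} of a pre-computed model: a polynomial in
#' \eqn{q^2} below the first regime boundary, the closed-form trigonometric
#' average up to the second, and the single-term Porod asymptote beyond.
#'
#' @param model A [sas_precompute()] model.
#' @param q Scattering-vector magnitudes (nm^-1), non-negative; vectorized.
#' @return \eqn{\langle P(q)\rangle} with \eqn{P(0) = 1}.
#' @export
pq_iso <- function(model, q) {
  stopifnot(inherits(model, "sas_model"), all(q >= 0))
  out <- numeric(length(q))
  b <- model$boundaries
  lo <- q <= b$q12
  mid <- q > b$q12 & q <= b$q23
  hi <- q > b$q23
  if (any(lo)) out[lo] <- poly_eval_x2(model$series$c, model$n_use, q[lo])
  if (any(mid)) out[mid] <- model$eval_full(q[mid])
  if (any(hi)) out[hi] <- model$porod_constant / (q[hi] * model$r_ref)^model$porod_exponent
  out
}

#' Mean scattering amplitude
#'
#' The size/orientation-averaged amplitude \eqn{\langle F(q)\rangle}
#' entering the decoupling approximation; evaluated with the same regime
#' machinery applied to the un-squared 0F1 series.
#'
#' @inheritParams pq_iso
#' @return \eqn{\langle F(q)\rangle}, with \eqn{\langle F(0)\rangle = 1}.
#' @export
fq_mean <- function(model, q) {
  stopifnot(inherits(model, "sas_model"), all(q >= 0))
  out <- numeric(length(q))
  z <- q == 0
  if (any(z)) out[z] <- 1
  if (any(!z)) out[!z] <- model$eval_fq(q[!z])
  out
}

#' Porod-asymptote constant
#'
#' Returns \eqn{K = \lim_{q\to\infty} (q R_{ref})^{p} \langle P(q)\rangle}
#' (with \eqn{p = 4} for three-dimensional bodies).  For polydisperse
#' spheres the closed form
#' \eqn{K = 9 (z+1)^4 / (2 z (z-1)(z-2)(z-3))} is returned; anisometric
#' shapes estimate K numerically from the non-oscillating high-q evaluator
#' and carry the attribute \code{estimated = TRUE}.
#'
#' @param model A [sas_precompute()] model.
#' @return The Porod constant, with attributes \code{exponent},
#'   \code{r_ref} and \code{estimated}.
#' @export
porod_limit <- function(model) {
  stopifnot(inherits(model, "sas_model"))
  if (model$shape$kind == "sphere") {
    dist <- model$dists[[1L]]
    if (is_monodisperse(dist)) {
      stop("Porod limit requires polydispersity (oscillations never die out)")
    }
    al <- dist$alpha
    z <- al - 1
    if (z <= 3) stop("Porod closed form has a pole: requires z > 3 (z = ", z, ")")
    K <- 9 * dist$rate^4 / (2 * (al - 1) * (al - 2) * (al - 3) * (al - 4))
    attr(K, "estimated") <- FALSE
  } else {
    if (all(vapply(model$dists, is_monodisperse, TRUE))) {
      stop("Porod limit requires polydispersity (oscillations never die out)")
    }
    K <- model$porod_constant
    attr(K, "estimated") <- TRUE
  }
  attr(K, "exponent") <- model$porod_exponent
  attr(K, "r_ref") <- model$r_ref
  K
}

#' @export
print.sas_model <- function(x, ...) {
  cat("<sas_model>", x$shape$kind, "\n")
  cat("  sizes (nm):", paste(names(x$shape$sizes), unlist(x$shape$sizes),
                             sep = "=", collapse = ", "), "\n")
  cat("  sigma:", paste(x$sigma, collapse = ", "),
      " weighting:", x$weighting, "\n")
  cat("  regime boundaries q12 =", signif(x$boundaries$q12, 4),
      " q23 =", signif(x$boundaries$q23, 4), "nm^-1\n")
  invisible(x)
}
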