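# Oriented anisometric particles (2D detector-plane form factors).
#
# A cylinder (or disk) whose axis deviates from the director x by an angle
# delta with density h(delta) has the axial phase
#   q.L(delta, chi) = L (qx cos(delta) - qy sin(chi) sin(delta)),
# whose even powers average to combinations of the q-independent
# H-integrals.  The longitudinal series can therefore be written
#   <P_par(qx,qy)> = sum_n a_n sum_l b_{l,n} (qx^2)^l (qy^2)^{n-l}
# with pre-computed a_n, b_{l,n}.  The full form factor couples the axial
# factor to the d = 2 cross-section through the transverse component
# q_t^2 = q^2 - (q.u)^2; its series uses the same H-moments, and beyond the
# series radius the phase average runs over pre-computed (delta, chi)
# orientation nodes with the closed-form size-averaged factors.

## <(q.u)^{2n}> coefficient matrix: entry [l+1] multiplies qx^{2l} qy^{2(n-l)}
qu_moment_coeffs <- function(n, H) {
  l <- 0:n
  (factorial2_ratio(n, l)) * vapply(l, function(ll) H[ll + 1L, n - ll + 1L], 0)
}

## (2n)!/4^n * 4^l / ((2l)! ((n-l)!)^2), computed in log space
factorial2_ratio <- function(n, l) {
  exp(lgamma(2 * n + 1) - n * log(4) + l * log(4) - lgamma(2 * l + 1) -
        2 * lgamma(n - l + 1))
}

#' Pre-compute the oriented form-factor machinery
#'
#' Attaches to a cylinder or disk model the q-independent tables needed by
#' [pq_oriented()]: the H-integral matrix of the orientation distribution,
#' the factorized longitudinal coefficients \eqn{a_n} and \eqn{b_{l,n}},
#' the coupled polynomial in \eqn{(q_x^2, q_y^2)} for the low-q regime, and
#' the (delta, chi) node grid for the trigonometric continuation.
#'
#' @param model A [sas_precompute()] model of kind cylinder or disk.
#' @param odist An [orientation_dist()] for the axis deviation from the
#'   director (the detector-plane x axis).
#' @param n_series Maximum total series order in \eqn{(q_x^2, q_y^2)}.
#' @param n_delta,n_chi Node counts of the continuation grid.
#' @return The model with an \code{oriented} component added.
#' @export
orient_precompute <- function(model, odist, n_series = 60L,
                              n_delta = 96L, n_chi = 128L) {
  stopifnot(inherits(model, "sas_model"), inherits(odist, "orientation_dist"))
  if (!model$shape$kind %in% c("cylinder", "disk")) {
    stop("oriented evaluation is implemented for cylinders and disks")
  }
  f_ax <- model$factors$axial
  f_cr <- model$factors$cross
  g_ax <- model$g_ax
  g_cr <- model$g_cr

  H <- h_integrals(odist, n_series)

  # longitudinal-only factorized coefficients: a_n = p_n g^{2n} (2n)!/4^n,
  # b_{l,n} = 4^l H_{2l,2n-2l} / ((2l)! ((n-l)!)^2)
  pax <- f_ax$p[seq_len(n_series + 1L)]
  a_n <- pax * vapply(0:n_series, function(n) {
    exp(2 * n * log(g_ax) - n * log(4) + lgamma(2 * n + 1))
  }, 0)
  b_ln <- lapply(0:n_series, function(n) {
    l <- 0:n
    exp(l * log(4) - lgamma(2 * l + 1) - 2 * lgamma(n - l + 1)) *
      vapply(l, function(ll) H[ll + 1L, n - ll + 1L], 0)
  })

  # coupled (axial x cross-section) polynomial in (qx^2, qy^2):
  # P = sum_m pax_m g_ax^{2m} (q.u)^{2m} * sum_j pcr_j g_cr^{2j} (q^2 - (q.u)^2)^j
  # expanded with <(q.u)^{2M}> -> H-moment polynomials in (qx^2, qy^2).
  pcr <- f_cr$p[seq_len(n_series + 1L)]
  paxg <- pax * cumprod(c(1, rep(g_ax^2, n_series)))
  pcrg <- pcr * cumprod(c(1, rep(g_cr^2, n_series)))
  qu_coef <- lapply(0:n_series, function(M) qu_moment_coeffs(M, H))
  # C[a+1, b+1] multiplies qx^{2a} qy^{2b}
  C <- matrix(0, n_series + 1L, n_series + 1L)
  for (m in 0:n_series) {
    for (j in 0:(n_series - m)) {
      cmj <- paxg[m + 1L] * pcrg[j + 1L]
      if (cmj == 0) next
      for (k in 0:j) {
        # (q^2)^{j-k} (-1)^k binom(j,k) (q.u)^{2(m+k)}
        M <- m + k
        base <- cmj * (-1)^k * choose(j, k)
        qu <- qu_coef[[M + 1L]]
        # (qx^2+qy^2)^{j-k} binomial
        for (r in 0:(j - k)) {
          brk <- base * choose(j - k, r)
          for (l in 0:M) {
            aa <- l + r
            bb <- (M - l) + (j - k - r)
            if (aa + bb <= n_series) {
              C[aa + 1L, bb + 1L] <- C[aa + 1L, bb + 1L] + brk * qu[l + 1L]
            }
          }
        }
      }
    }
  }

  # continuation nodes: delta weighted by h(delta) sin(delta), chi uniform
  if (odist$kind == "delta") {
    nodes <- list(ux = 1, uy = 0, w = 1)
  } else {
    nd <- orientation_nodes(odist, n0 = n_delta)
    chi <- (seq_len(n_chi) - 0.5) * 2 * pi / n_chi
    ux <- rep(cos(nd$delta), times = n_chi)
    uy <- rep(sin(nd$delta), times = n_chi) * rep(sin(chi), each = length(nd$delta))
    w <- rep(nd$w, times = n_chi) / n_chi
    nodes <- list(ux = ux, uy = uy, w = w)
  }

  # series validity: conservative worst-case |q.u| <= |q|, transverse <= |q|
  q12_or <- min(f_ax$x12 / g_ax, f_cr$x12 / g_cr)

  model$oriented <- list(
    odist = odist, H = H, a_n = a_n, b_ln = b_ln, C = C,
    nodes = nodes, q12 = q12_or, n_series = n_series,
    H20 = H[2L, 1L], H02 = H[1L, 2L])
  model
}

## Eq-16-style factorized longitudinal series only (no cross-section)
oriented_longitudinal <- function(model, qx, qy) {
  or <- model$oriented
  if (is.null(or)) stop("orient_precompute() has not been run for this model")
  out <- 0
  qx2 <- qx^2; qy2 <- qy^2
  for (n in 0:or$n_series) {
    l <- 0:n
    out <- out + or$a_n[n + 1L] *
      colSums(or$b_ln[[n + 1L]] * t(outer(qx2, l, `^`) * outer(qy2, n - l, `^`)))
  }
  out
}

#' Oriented form factor on the detector plane
#'
#' Size- and orientation-averaged form factor of an oriented cylinder or
#' disk at detector-plane coordinates \eqn{(q_x, q_y)} (the director lies
#' along x).  Below the series radius the pre-computed coupled polynomial
#' is used; beyond it the phase average runs over the pre-computed
#' orientation nodes with closed-form size averages, so the evaluation
#' remains free of numerical integration over sizes.
#'
#' @param model A [sas_precompute()] model passed through
#'   [orient_precompute()].
#' @param qx,qy Detector-plane scattering-vector components (nm^-1),
#'   equal-length vectors.
#' @return \eqn{\langle P(q_x, q_y)\rangle}, 1 at the origin.
#' @export
pq_oriented <- function(model, qx, qy) {
  stopifnot(inherits(model, "sas_model"), length(qx) == length(qy))
  or <- model$oriented
  if (is.null(or)) stop("orient_precompute() has not been run for this model")
  f_ax <- model$factors$axial
  f_cr <- model$factors$cross
  g_ax <- model$g_ax
  g_cr <- model$g_cr
  q2 <- qx^2 + qy^2
  out <- numeric(length(qx))
  lo <- sqrt(q2) <= or$q12
  if (any(lo)) {
    out[lo] <- poly_eval_qxqy(or$C, qx[lo]^2, qy[lo]^2)
  }
  if (any(!lo)) {
    idx <- which(!lo)
    nd <- or$nodes
    out[idx] <- vapply(idx, function(i) {
      qu <- qx[i] * nd$ux - qy[i] * nd$uy
      qt <- sqrt(pmax(0, q2[i] - qu^2))
      sum(nd$w * f_ax$pq(abs(qu) * g_ax) * f_cr$pq(qt * g_cr))
    }, 0)
  }
  out
}

## evaluate sum C[a+1,b+1] X^a Y^b for vectors X, Y (Horner in b, then a)
poly_eval_qxqy <- function(C, X, Y) {
  n <- nrow(C)
  acc <- 0
  for (a in seq(n, 1L)) {
    row <- C[a, ]
    racc <- 0
    for (b in seq(n, 1L)) racc <- racc * Y + row[b]
    acc <- acc * X + racc
  }
  acc
}
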