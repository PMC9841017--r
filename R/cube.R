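# Cube form factor with a common (shape-preserving) scale polydispersity.
#
# A cube of edge 2g with body axes (u1,u2,u3) has amplitude
#   F = prod_i sin(x_i s)/(x_i s),   x_i = q u_i g,
# with one Schulz scale s shared by the three axes, so the size average does
# not factorize per axis.  Products of sin/cos are expanded into single
# cosines of combined frequencies, every term being a closed-form Gamma
# moment <s^p cos(mu s)>.  Axes with tiny arguments switch to a short
# polynomial to avoid cancellation in (1 - cos)/x^2.

## <s^p>, <s^p cos(mu s)>, <s^p sin(mu s)> for the Schulz scale law;
## vectorized over mu.
gamma_mom <- function(dist, p) {
  if (is_monodisperse(dist)) return(dist$mean^p)
  exp(lgamma(dist$alpha + p) - lgamma(dist$alpha) - p * log(dist$rate))
}
gamma_mom_cos <- function(dist, p, mu) {
  if (is_monodisperse(dist)) return(dist$mean^p * cos(mu * dist$mean))
  al <- dist$alpha; la <- dist$rate
  gr <- exp(lgamma(al + p) - lgamma(al))
  s <- sqrt(la^2 + mu^2)
  gr * exp(al * log(la / s) - p * log(s)) * cos((al + p) * atan2(mu, la))
}
gamma_mom_sin <- function(dist, p, mu) {
  if (is_monodisperse(dist)) return(dist$mean^p * sin(mu * dist$mean))
  al <- dist$alpha; la <- dist$rate
  gr <- exp(lgamma(al + p) - lgamma(al))
  s <- sqrt(la^2 + mu^2)
  gr * exp(al * log(la / s) - p * log(s)) * sin((al + p) * atan2(mu, la))
}

## monodisperse sinc^2 and sinc series coefficients (v^{2n})
sinc2_series <- function(N) {
  s <- numeric(N + 1L); s[1] <- 1; t <- 1
  for (n in seq_len(N)) {
    t <- t * (-1 / ((n + 1) * (n + 0.5)))
    s[n + 1L] <- t
  }
  s
}
sinc_series <- function(N) {
  s <- numeric(N + 1L); s[1] <- 1; t <- 1
  for (n in seq_len(N)) {
    t <- t * (-1 / (2 * n * (2 * n + 1)))
    s[n + 1L] <- t
  }
  s
}

## all-trigonometric node evaluation of <prod_i (1-cos(2 x_i s))/(2 x_i^2 s^2)>
## (x_i are equal-length vectors over nodes)
cube_trig_P <- function(dist, x1, x2, x3) {
  gmc <- function(mu) gamma_mom_cos(dist, -6, mu)
  E <- gamma_mom(dist, -6) -
    (gmc(2 * x1) + gmc(2 * x2) + gmc(2 * x3)) +
    0.5 * (gmc(2 * (x1 + x2)) + gmc(2 * abs(x1 - x2)) +
           gmc(2 * (x1 + x3)) + gmc(2 * abs(x1 - x3)) +
           gmc(2 * (x2 + x3)) + gmc(2 * abs(x2 - x3))) -
    0.25 * (gmc(2 * (x1 + x2 + x3)) + gmc(2 * abs(x1 + x2 - x3)) +
            gmc(2 * abs(x1 - x2 + x3)) + gmc(2 * abs(x1 - x2 - x3)))
  E / (8 * (x1 * x2 * x3)^2)
}

cube_trig_F <- function(dist, x1, x2, x3) {
  gms <- function(mu) sign(mu) * gamma_mom_sin(dist, -3, abs(mu))
  S <- gms(x1 + x2 - x3) + gms(x1 - x2 + x3) + gms(-x1 + x2 + x3) -
    gms(x1 + x2 + x3)
  0.25 * S / (x1 * x2 * x3)
}

## Mixed small/trigonometric pattern evaluation, vectorized over the subset
## of nodes sharing a small-axis pattern `sm` (logical length 3);
## xs = matrix (axes x nodes).
cube_pattern_P <- function(dist, xs, sm, Scoef) {
  nn <- ncol(xs)
  Ns <- length(Scoef) - 1L
  # small-axis polynomial coefficients a[n+1, node] of s^{2n}
  a <- matrix(0, 1L, nn); a[1L, ] <- 1
  for (i in which(sm)) {
    ai <- vapply(seq_len(nn),
                 function(j) Scoef * xs[i, j]^(2 * (0:Ns)), numeric(Ns + 1L))
    ai <- matrix(ai, Ns + 1L, nn)
    # convolve a with ai along the power index
    na <- nrow(a)
    out <- matrix(0, na + Ns, nn)
    for (r in seq_len(na)) {
      out[r:(r + Ns), ] <- out[r:(r + Ns), ] + a[rep(r, Ns + 1L), , drop = FALSE] * ai
    }
    a <- out
  }
  tr <- which(!sm)
  n_tr <- length(tr)
  pows <- 2 * (seq_len(nrow(a)) - 1L) - 2 * n_tr
  # trigonometric term list (coef, mu) from prod over trig axes of (1 - cos(2 x s))
  terms_c <- list(1)
  terms_mu <- list(rep(0, nn))
  for (i in tr) {
    nc <- list(); nm <- list()
    for (t in seq_along(terms_c)) {
      nc <- c(nc, list(terms_c[[t]]), list(-terms_c[[t]] / 2), list(-terms_c[[t]] / 2))
      nm <- c(nm, list(terms_mu[[t]]), list(terms_mu[[t]] + 2 * xs[i, ]),
              list(abs(terms_mu[[t]] - 2 * xs[i, ])))
    }
    terms_c <- nc; terms_mu <- nm
  }
  pref <- rep(1, nn)
  for (i in tr) pref <- pref / (2 * xs[i, ]^2)
  val <- 0
  for (t in seq_along(terms_c)) {
    for (r in seq_len(nrow(a))) {
      val <- val + terms_c[[t]] * a[r, ] * gamma_mom_cos(dist, pows[r], terms_mu[[t]])
    }
  }
  pref * val
}

cube_pattern_F <- function(dist, xs, sm, Sfcoef) {
  nn <- ncol(xs)
  Ns <- length(Sfcoef) - 1L
  b <- matrix(0, 1L, nn); b[1L, ] <- 1
  for (i in which(sm)) {
    bi <- vapply(seq_len(nn),
                 function(j) Sfcoef * xs[i, j]^(2 * (0:Ns)), numeric(Ns + 1L))
    bi <- matrix(bi, Ns + 1L, nn)
    nb <- nrow(b)
    out <- matrix(0, nb + Ns, nn)
    for (r in seq_len(nb)) {
      out[r:(r + Ns), ] <- out[r:(r + Ns), ] + b[rep(r, Ns + 1L), , drop = FALSE] * bi
    }
    b <- out
  }
  tr <- which(!sm)
  n_tr <- length(tr)
  pows <- 2 * (seq_len(nrow(b)) - 1L) - n_tr
  val <- 0
  if (n_tr == 0L) {
    for (r in seq_len(nrow(b))) val <- val + b[r, ] * gamma_mom(dist, pows[r])
    return(val)
  }
  if (n_tr == 1L) {
    xA <- xs[tr[1L], ]
    for (r in seq_len(nrow(b))) {
      val <- val + b[r, ] * gamma_mom_sin(dist, pows[r], xA)
    }
    return(val / xA)
  }
  if (n_tr == 2L) {
    xA <- xs[tr[1L], ]; xB <- xs[tr[2L], ]
    for (r in seq_len(nrow(b))) {
      val <- val + b[r, ] * 0.5 *
        (gamma_mom_cos(dist, pows[r], abs(xA - xB)) -
         gamma_mom_cos(dist, pows[r], xA + xB))
    }
    return(val / (xA * xB))
  }
  cube_trig_F(dist, xs[1L, ], xs[2L, ], xs[3L, ])
}

model_cube <- function(sz, dists, tol, boundary_tol, n_orient) {
  g <- sz$edge / 2
  dist <- dists[[1L]]
  nt <- if (is.null(n_orient)) 96L else n_orient
  nd <- iso_nodes_2d(nt, nt)
  st <- sqrt(pmax(0, 1 - nd$t^2))
  u <- rbind(st * cos(nd$phi), st * sin(nd$phi), nd$t)
  w <- nd$w
  x_lo <- 0.05

  # Regime I: convolve three monodisperse sinc^2 series with the exact
  # direction moments, then fold in the common-scale size moments
  N <- 70L
  S <- sinc2_series(N)
  mom2n <- vapply(0:N, function(n) gamma_mom(dist, 2 * n), 0)
  g2n <- cumprod(c(1, rep(g^2, N)))
  cs <- numeric(N + 1L)
  for (n in 0:N) {
    acc <- 0
    for (i in 0:n) for (j in 0:(n - i)) {
      k <- n - i - j
      acc <- acc + S[i + 1L] * S[j + 1L] * S[k + 1L] * dir_moment(i, j, k)
    }
    cs[n + 1L] <- acc * mom2n[n + 1L] * g2n[n + 1L]
  }

  Ssm <- sinc2_series(4L)   # small-axis polynomial (arguments < x_lo * s)
  Sfsm <- sinc_series(4L)

  eval_nodes <- function(qq, what = c("P", "F")) {
    what <- match.arg(what)
    xs <- qq * g * u
    small <- xs < x_lo
    nsm <- colSums(small)
    out <- numeric(ncol(xs))
    fast <- nsm == 0L
    if (any(fast)) {
      out[fast] <- if (what == "P") {
        cube_trig_P(dist, xs[1L, fast], xs[2L, fast], xs[3L, fast])
      } else {
        cube_trig_F(dist, xs[1L, fast], xs[2L, fast], xs[3L, fast])
      }
    }
    if (any(!fast)) {
      pat <- small[1L, ] + 2L * small[2L, ] + 4L * small[3L, ]
      for (p in unique(pat[!fast])) {
        idx <- which(pat == p & !fast)
        sm <- c(bitwAnd(p, 1L) > 0L, bitwAnd(p, 2L) > 0L, bitwAnd(p, 4L) > 0L)
        out[idx] <- if (what == "P") {
          cube_pattern_P(dist, xs[, idx, drop = FALSE], sm, Ssm)
        } else {
          cube_pattern_F(dist, xs[, idx, drop = FALSE], sm, Sfsm)
        }
      }
    }
    out
  }

  eval_trig <- function(q) {
    vapply(q, function(qq) sum(w * eval_nodes(qq, "P")), 0)
  }
  eval_fq <- function(q) {
    vapply(q, function(qq) sum(w * eval_nodes(qq, "F")), 0)
  }
  eval_nonosc <- function(q) {
    m6 <- gamma_mom(dist, -6)
    vapply(q, function(qq) {
      xs <- qq * g * u
      sum(w * pmin(1, m6 / (8 * (xs[1L, ] * xs[2L, ] * xs[3L, ])^2)))
    }, 0)
  }

  m <- list(
    dists = dists, nodes = nd, u_orient = u, w_orient = w, g_half = g,
    r_ref = sz$edge, porod_exponent = 4, scan_hi = 400, scan_n = 300L,
    series = list(c = cs, n_max = N, tol = tol),
    eval_trig = eval_trig,
    eval_nonosc = eval_nonosc,
    eval_full = eval_trig,
    eval_fq = eval_fq)
  finalize_model(m, tol, boundary_tol)
}
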