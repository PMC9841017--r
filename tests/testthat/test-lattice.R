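# Crystallographic transforms, reflection rules and lattice factors.

fcc35 <- function() cached_model("fcc35", function() {
  cell <- unit_cell(35, lattice_type = "FCC", uvw = c(1, 1, 1))
  basis <- reciprocal_basis(cell)
  list(cell = cell, basis = basis,
       refl = enumerate_reflections(basis, cell, 1.2))
})

test_that("cubic reciprocal lengths and duality hold", {
  f <- fcc35()
  lens <- unname(apply(f$basis$recip, 2, function(v) sqrt(sum(v^2))))
  expect_equal(lens, rep(2 * pi / 35, 3), tolerance = 1e-12)
  expect_lt(max(abs(t(f$basis$real) %*% f$basis$recip - 2 * pi * diag(3))), 1e-10)
  # beam alignment: r_uvw parallel to +z after rotation
  r <- f$basis$real %*% c(1, 1, 1)
  expect_equal(as.numeric(r / sqrt(sum(r^2))), c(0, 0, 1), tolerance = 1e-12)
})

test_that("random triclinic cells satisfy the duality to 1e-10", {
  set.seed(7)
  for (i in 1:100) {
    cl <- unit_cell(runif(1, 2, 50), runif(1, 2, 50), runif(1, 2, 50),
                    runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120),
                    lattice_type = "SC", uvw = c(1, 2, 1))
    rb <- reciprocal_basis(cl)
    expect_lt(max(abs(t(rb$real) %*% rb$recip - 2 * pi * diag(3))), 1e-10)
    # independent oracle: reciprocal basis from plain matrix inversion
    expect_lt(max(abs(rb$recip - 2 * pi * t(solve(rb$real)))), 1e-10)
  }
})

test_that("FCC selection rules and ring geometry are correct", {
  f <- fcc35()
  refl <- f$refl
  # mixed-parity reflections are forbidden
  par <- cbind(refl$h %% 2, refl$k %% 2, refl$l %% 2)
  expect_true(all(apply(par, 1, function(p) all(p == 0) || all(p == 1))))
  # first ring is {111} with multiplicity 8 at 2 pi sqrt(3) / a
  first <- refl[abs(refl$qmag - min(refl$qmag)) < 1e-9, ]
  expect_equal(nrow(first), 8L)
  expect_true(all(abs(first$h) == 1 & abs(first$k) == 1 & abs(first$l) == 1))
  expect_equal(first$qmag[1], 2 * pi * sqrt(3) / 35, tolerance = 1e-12)
  # ring ordinals at sqrt(3) : sqrt(4) : sqrt(8)
  rq <- sort(unique(round(refl$qmag, 9)))
  expect_equal(rq[2] / rq[1], sqrt(4 / 3), tolerance = 1e-7)
  expect_equal(rq[3] / rq[1], sqrt(8 / 3), tolerance = 1e-7)
  # Friedel closure
  key <- paste(refl$h, refl$k, refl$l)
  expect_true(all(paste(-refl$h, -refl$k, -refl$l) %in% key))
})

test_that("BCC parity rule holds and forbidden reflections are absent", {
  cell <- unit_cell(22, lattice_type = "BCC", uvw = c(0, 0, 1))
  rb <- reciprocal_basis(cell)
  refl <- enumerate_reflections(rb, cell, 0.9)
  expect_true(all((refl$h + refl$k + refl$l) %% 2 == 0))
  expect_false(any(refl$h == 1 & refl$k == 0 & refl$l == 0))
  expect_true(any(refl$h == 1 & refl$k == 1 & refl$l == 0))
})

test_that("reflection count matches a brute-force triple loop", {
  f <- fcc35()
  a <- 35; qmax <- 1.2
  hm <- ceiling(qmax * a / (2 * pi))
  cnt <- 0L
  for (h in -hm:hm) for (k in -hm:hm) for (l in -hm:hm) {
    if (h == 0 && k == 0 && l == 0) next
    same_par <- (h %% 2 == 0 && k %% 2 == 0 && l %% 2 == 0) ||
      (h %% 2 != 0 && k %% 2 != 0 && l %% 2 != 0)
    if (same_par && 2 * pi * sqrt(h^2 + k^2 + l^2) / a <= qmax) cnt <- cnt + 1L
  }
  expect_identical(nrow(f$refl), cnt)
})

test_that("the 2D lattice factor is baseline-1, peak-centered and centrosymmetric", {
  f <- fcc35()
  pk <- peak_shape("gaussian", sigma_q = 0.01)
  # far from every reflection
  expect_equal(lattice_factor_2d(f$refl, pk, f$basis, 0.05, 0.03, 0), 1,
               tolerance = 1e-6)
  # centered: a 3x3 neighborhood around a reflection peaks at its center
  r1 <- f$refl[which.min(abs(f$refl$qz) + abs(f$refl$qmag - 0.51)), ]
  dq <- 0.004 * (-1:1)
  zz <- outer(dq, dq, function(dx, dy) {
    lattice_factor_2d(f$refl, pk, f$basis, r1$qx + dx, r1$qy + dy, r1$qz)
  })
  expect_equal(which.max(zz), 5L)
  # Friedel symmetry of Z
  qx <- runif(20, -1, 1); qy <- runif(20, -1, 1)
  expect_equal(lattice_factor_2d(f$refl, pk, f$basis, qx, qy, 0),
               lattice_factor_2d(f$refl, pk, f$basis, -qx, -qy, 0),
               tolerance = 1e-12)
})

test_that("the closed-form powder average matches the numerically averaged 2D factor", {
  f <- fcc35()
  pk <- peak_shape("gaussian", sigma_q = 0.02)
  qs <- seq(0.25, 0.7, by = 0.025)
  z1 <- lattice_factor_1d_iso(f$refl, pk, f$basis, qs)
  gl <- pracma::gaussLegendre(200, -1, 1)
  phis <- (seq_len(400) - 0.5) * 2 * pi / 400
  z2 <- vapply(qs, function(q) {
    acc <- 0
    for (i in seq_along(gl$x)) {
      ct <- gl$x[i]; st <- sqrt(1 - ct^2)
      acc <- acc + gl$w[i] / 2 *
        mean(lattice_factor_2d(f$refl, pk, f$basis,
                               q * st * cos(phis), q * st * sin(phis), q * ct))
    }
    acc
  }, 0)
  expect_lt(max(abs(z1 - z2) / z2), 0.01)
})

test_that("pseudo-Voigt and Lorentzian powder forms stay normalized and positive", {
  f <- fcc35()
  for (pk in list(peak_shape("lorentzian", sigma_q = 0.02),
                  peak_shape("pseudo_voigt", sigma_q = 0.02, eta = 0.4))) {
    z <- lattice_factor_1d_iso(f$refl, pk, f$basis, seq(0.2, 0.8, by = 0.02))
    expect_true(all(is.finite(z) & z >= 1 - 1e-9))
    expect_gt(max(z), 1.05)
  }
})

test_that("Debye-Waller damping has the Gaussian closed form", {
  expect_identical(debye_waller(0, 2), 1)
  expect_identical(debye_waller(3, 0), 1)
  expect_equal(debye_waller(1, 1), exp(-1))
  q <- seq(0, 5, by = 0.5)
  expect_true(all(diff(debye_waller(q, 0.7)) < 0))
})

test_that("custom-basis structure factors reproduce the BCC rule", {
  cB <- unit_cell(22, lattice_type = "custom", uvw = c(0, 0, 1),
                  basis = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)))
  rb <- reciprocal_basis(cB)
  refl <- enumerate_reflections(rb, cB, 0.9)
  expect_true(all((refl$h + refl$k + refl$l) %% 2 == 0))
  expect_true(all(abs(refl$f2 - 1) < 1e-9))
})
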