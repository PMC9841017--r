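# Detector mapping, intensity assembly, PSF and GISAS optics.

test_that("the small-angle pixel-to-q map is the flat-Ewald formula", {
  det <- detector_geometry(nx = 64, ny = 64, pixel_size = 1,
                           wavelength = 0.1, distance = 1000,
                           beam_center = c(32, 32))
  qm <- q_map(det)
  # x = 10 mm -> qx = 2 pi 10 / (0.1 * 1000)
  j <- 42L  # pixel center at (42 - 0.5) - 32 = 9.5 mm
  expect_equal(qm$qx[1, j], 2 * pi * 9.5 / (0.1 * 1000), tolerance = 1e-12)
  expect_true(all(qm$qz == 0))
  # beam-center pixel: q vanishes at the exact center between pixels
  expect_lt(min(qm$qmag), 2 * pi * 0.8 / (0.1 * 1000))
})

test_that("exact and small-angle maps agree below two degrees", {
  mk <- function(mode) q_map(detector_geometry(nx = 64, ny = 64, pixel_size = 0.5,
                                               wavelength = 0.1, distance = 1000,
                                               mode = mode))
  qe <- mk("exact"); qs <- mk("small_angle")
  # largest in-plane angle here: atan(16 sqrt2 / 1000) < 2 degrees
  rel <- abs(qe$qx - qs$qx) / pmax(abs(qs$qx), 1e-9)
  expect_lt(max(rel), 1e-3)
  expect_true(all(qe$qz >= 0))
})

test_that("without a lattice the intensity is exactly contrast^2 rho P", {
  m <- benchmark_model("sphere", 0.1)
  det <- detector_geometry(nx = 16, ny = 16, pixel_size = 2,
                           wavelength = 0.1, distance = 1000)
  p <- intensity_pattern(m, det, intensity_params(contrast = 2,
                                                  number_density = 3e-4,
                                                  include_lattice = FALSE))
  qm <- q_map(det)
  expect_equal(as.numeric(p$I),
               4 * 3e-4 * pq_iso(m, as.numeric(pmax(qm$qmag, 1e-12))),
               tolerance = 1e-12)
})

test_that("transmission patterns obey Friedel symmetry exactly", {
  p <- small_fcc_pattern()
  expect_lt(max(abs(p$I - p$I[nrow(p$I):1, ncol(p$I):1])) / max(p$I), 1e-12)
  expect_true(all(is.finite(p$I) & p$I >= 0))
})

test_that("lattice enhancement peaks on the in-plane reflection rings", {
  p <- small_fcc_pattern()
  m <- cached_model("sphere14", function() stop("cached"))
  p0 <- intensity_pattern(m, p$det, intensity_params(number_density = 1e-4,
                                                     include_lattice = FALSE))
  ratio <- p$I / p0$I
  expect_gt(max(ratio), 5)
  qm <- p$q
  rings <- sort(unique(round(enumerate_reflections(
    reciprocal_basis(p$cell), p$cell, 1.3)$qmag, 6)))
  im <- which(ratio == max(ratio), arr.ind = TRUE)[1, ]
  expect_lt(min(abs(qm$qmag[im[1], im[2]] - rings)), 0.03)
  # with the beam along [111] the first visible ring is {220}: the only
  # low-order family with h+k+l = 0 and equal parity
  sel <- ratio > 1 + 0.5 * (max(ratio) - 1)
  expect_lt(abs(min(qm$qmag[sel]) - 2 * pi * sqrt(8) / 35), 0.03)
})

test_that("the decoupling bracket stays non-negative on the lattice fixture", {
  p <- small_fcc_pattern()
  m <- cached_model("sphere14", function() stop("cached"))
  qm <- p$q
  P <- pq_iso(m, as.numeric(pmax(qm$qmag, 1e-12)))
  expect_true(all(p$I >= 0))
  # beta bounded by construction
  Fm <- fq_mean(m, as.numeric(pmax(qm$qmag, 1e-12)))
  expect_true(all(Fm^2 <= P * (1 + 1e-9)))
})

test_that("PSF convolution is identity for a delta kernel, conservative and linear", {
  p <- small_fcc_pattern()
  expect_identical(convolve_psf(p$I, matrix(1, 1, 1)), p$I)
  psf <- gaussian_psf(1.5)
  b <- convolve_psf(p$I, psf)
  # peaks decrease, interior intensity is conserved
  expect_lt(max(b), max(p$I))
  inner <- 8:56
  expect_equal(sum(b[inner, inner]), sum(p$I[inner, inner]), tolerance = 1e-3)
  # linearity
  b2 <- convolve_psf(2 * p$I + 1, psf)
  expect_equal(b2, 2 * b + 1, tolerance = 1e-9)
  expect_error(convolve_psf(p$I, matrix(1, 3, 3)), "normalized")
})

test_that("Fresnel optics show total reflection, the Yoneda maximum and decay", {
  delta <- 1e-5
  ac <- critical_angle(delta)
  expect_equal(Mod(fresnel(ac, delta)$T)^2, 4, tolerance = 1e-6)
  expect_equal(Mod(fresnel(0.001, delta)$R)^2, 1, tolerance = 1e-3)
  expect_lt(Mod(fresnel(10 * ac, delta)$R)^2, 1e-4)
  expect_equal(Mod(fresnel(10 * ac, delta)$T)^2, 1, tolerance = 1e-2)
})

test_that("GISAS reduces to the transmission pattern and shows a Yoneda band", {
  m <- cached_model("sphere10", function() {
    sas_precompute(shape_spec("sphere", radius = 10), sigma = 0.08)
  })
  cell <- unit_cell(22, lattice_type = "BCC", uvw = c(0, 0, 1))
  pk <- peak_shape("gaussian", sigma_q = 0.02, debye_waller_sigma = 0.4)
  det <- detector_geometry(nx = 48, ny = 64, pixel_size = 2,
                           wavelength = 0.1, distance = 2000,
                           beam_center = c(24, 10))
  par <- intensity_params(number_density = 1e-4)
  # film = NULL is bit-for-bit the transmission pattern
  g0 <- gisas_intensity(m, det, NULL, par, cell = cell, peak = pk)
  t0 <- intensity_pattern(m, det, par, cell = cell, peak = pk)
  expect_identical(g0$I, t0$I)
  # with zero index contrast the four DWBA channels collapse onto channel 1
  film0 <- gisas_film(alpha_i = 0.25, delta = 0, beta = 0)
  gz <- gisas_intensity(m, det, film0, par, cell = cell, peak = pk)
  expect_true(all(is.finite(gz$I)))
  r0 <- Mod(fresnel(0.25, 0)$R)^2
  expect_lt(r0, 1e-20)
  # genuine film: Yoneda band at the critical exit angle
  film <- gisas_film(alpha_i = 0.25, delta = 6.5e-6, beta = 1e-8)
  gp <- gisas_intensity(m, det, film, par, cell = cell, peak = pk)
  ac <- critical_angle(6.5e-6)
  ic <- which.min(abs(gp$alpha_f - ac))
  prof <- rowMeans(gp$I)
  expect_gt(prof[ic], prof[ic - 3])
  expect_gt(prof[ic], prof[ic + 3])
  # all four channel weights non-negative by construction
  expect_true(all(gp$I >= 0))
})

test_that("azimuthal average of an isotropic 2D pattern matches the 1D curve", {
  m <- benchmark_model("sphere", 0.1)
  det <- detector_geometry(nx = 128, ny = 128, pixel_size = 1,
                           wavelength = 0.1, distance = 1000)
  p <- intensity_pattern(m, det, intensity_params(include_lattice = FALSE))
  qm <- p$q
  qv <- as.numeric(qm$qmag)
  iv <- as.numeric(p$I)
  # ring-average the pattern
  br <- seq(0.3, 3.5, by = 0.1)
  mid <- (br[-1] + br[-length(br)]) / 2
  ring <- vapply(seq_along(mid), function(i) {
    sel <- qv >= br[i] & qv < br[i + 1]
    mean(iv[sel] / pq_iso(m, qv[sel]))  # remove in-bin curvature
  }, 0)
  expect_true(all(abs(ring - ring[1]) < 5e-3 * ring[1]))
  direct <- intensity_curve(m, mid, intensity_params(include_lattice = FALSE))
  sel <- vapply(seq_along(mid), function(i) {
    s <- qv >= br[i] & qv < br[i + 1]
    mean(iv[s]) / mean(direct$I[i] * pq_iso(m, qv[s]) / pq_iso(m, mid[i]))
  }, 0)
  expect_lt(max(abs(sel - 1)), 5e-3)
})
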