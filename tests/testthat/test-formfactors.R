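# Regime-switched form-factor models.

test_that("sphere series coefficients carry the Guinier and size-moment factors", {
  m0 <- cached_model("sphere_mono", function() {
    sas_precompute(shape_spec("sphere", radius = 3), sigma = 0)
  })
  expect_equal(m0$series$c[1], 1)
  expect_equal(m0$series$c[2], -3^2 / 5)           # -R^2/5
  m <- benchmark_model("sphere", 0.08)
  z <- 1 / 0.08^2 - 1
  expect_equal(m$series$c[2], -3^2 * (z + 2) / (5 * (z + 1)), tolerance = 1e-12)
})

test_that("form factors are normalized and bounded", {
  for (kind in c("sphere", "cylinder", "cube")) {
    m <- benchmark_model(kind, 0.1)
    expect_equal(pq_iso(m, 0), 1, tolerance = 1e-10)
    q <- fixture_qgrid(kind, 80)
    P <- pq_iso(m, q)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
    expect_true(all(P[q > 2] > 0))   # polydispersity fills the minima
    Fm <- fq_mean(m, q)
    expect_true(all(Fm^2 <= P * (1 + 1e-9)))
    expect_equal(fq_mean(m, 0), 1)
  }
})

test_that("monodisperse sphere evaluation equals the squared closed form", {
  m0 <- cached_model("sphere_mono", function() {
    sas_precompute(shape_spec("sphere", radius = 3), sigma = 0)
  })
  expect_equal(pq_iso(m0, pi / 3), (3 / pi^2)^2, tolerance = 1e-12)
  expect_equal(m0$boundaries$q23, Inf)   # no Porod regime without polydispersity
})

test_that("evaluation is continuous across the regime boundaries", {
  eps <- 1e-6
  for (kind in names(fixture_shapes())) {
    m <- benchmark_model(kind, 0.1)
    q12 <- m$boundaries$q12
    jump12 <- abs(pq_iso(m, q12 * (1 - eps)) / pq_iso(m, q12 * (1 + eps)) - 1)
    expect_lt(jump12, 1e-3)
    q23 <- m$boundaries$q23
    if (is.finite(q23)) {
      jump23 <- abs(pq_iso(m, q23 * (1 - eps)) / pq_iso(m, q23 * (1 + eps)) - 1)
      expect_lt(jump23, 1e-3)
    }
  }
})

test_that("low-q slope recovers the averaged squared gyration radius", {
  # -3 dlnP/dq^2 at q -> 0: (3/5)<R^2> for the number-weighted average of
  # volume-normalized amplitudes, (3/5)<R^8>/<R^6> under V^2 weighting
  d <- schulz_dist(3, sigma = 0.08)
  h <- 1e-3
  m <- benchmark_model("sphere", 0.08)
  slope <- -3 * (log(pq_iso(m, h)) - log(pq_iso(m, 0))) / h^2
  expect_equal(slope, (3 / 5) * schulz_quad(d, function(r) r^2), tolerance = 1e-4)
  mi <- cached_model("sphere_intw008", function() {
    sas_precompute(shape_spec("sphere", radius = 3), sigma = 0.08,
                   weighting = "intensity")
  })
  slope_i <- -3 * (log(pq_iso(mi, h)) - log(pq_iso(mi, 0))) / h^2
  rg2_i <- (3 / 5) * schulz_quad(d, function(r) r^8) / schulz_quad(d, function(r) r^6)
  expect_equal(slope_i, rg2_i, tolerance = 1e-4)
})

test_that("Porod constant follows the closed form and its limits", {
  for (s in c(0.05, 0.1, 0.2)) {
    m <- cached_model(paste0("sphere_", s), function() {
      sas_precompute(shape_spec("sphere", radius = 3), sigma = s)
    })
    z <- 1 / s^2 - 1
    K <- porod_limit(m)
    expect_equal(as.numeric(K), 9 * (z + 1)^4 / (2 * z * (z - 1) * (z - 2) * (z - 3)),
                 tolerance = 1e-12)
    expect_false(attr(K, "estimated"))
    # the high-q plateau of q^4 R^4 <P> approaches K within 1 percent
    qr <- exp(seq(log(30), log(200), length.out = 60)) / 3
    plateau <- pq_iso(m, qr) * (qr * 3)^4
    expect_lt(max(abs(plateau / as.numeric(K) - 1)), 0.01)
  }
  # z -> infinity limit: 9/2
  mz <- cached_model("sphere_tiny_sigma", function() {
    sas_precompute(shape_spec("sphere", radius = 3), sigma = 0.005)
  })
  expect_equal(as.numeric(porod_limit(mz)), 9 / 2, tolerance = 1e-3)
  # z <= 3 (sigma = 0.5): the trigonometric-average moments do not exist
  expect_error(sas_precompute(shape_spec("sphere", radius = 3), sigma = 0.5),
               "too broad")
  # anisometric shapes are estimated and flagged
  Ka <- porod_limit(benchmark_model("cylinder", 0.1))
  expect_true(attr(Ka, "estimated"))
  expect_gt(as.numeric(Ka), 0)
})

test_that("intensity weighting shifts the size law but keeps normalization", {
  mi <- cached_model("sphere_intw", function() {
    sas_precompute(shape_spec("sphere", radius = 3), sigma = 0.1,
                   weighting = "intensity")
  })
  mn <- benchmark_model("sphere", 0.1)
  expect_equal(pq_iso(mi, 0), 1, tolerance = 1e-10)
  # volume-squared weighting emphasises large particles: steeper Guinier
  h <- 1e-2
  expect_lt(pq_iso(mi, h) - pq_iso(mn, h), 0)
  # and matches the explicitly weighted quadrature
  d <- schulz_dist(3, sigma = 0.1)
  f3 <- function(x) ifelse(x < 1e-4, 1 - x^2 / 10,
                           3 * (sin(x) - x * cos(x)) / pmax(x, 1e-300)^3)
  q <- 1.7
  num <- schulz_quad(d, function(r) r^6 * f3(q * r)^2) /
    schulz_quad(d, function(r) r^6)
  expect_equal(pq_iso(mi, q), num, tolerance = 1e-7)
})

test_that("shape specification validates its arguments", {
  expect_error(shape_spec("sphere", r = 3), "requires sizes")
  expect_error(shape_spec("cylinder", radius = 2), "requires sizes")
  expect_error(shape_spec("sphere", radius = -1), "positive")
  expect_error(sas_precompute(shape_spec("cylinder", radius = 2, length = 12),
                              sigma = c(0.1, 0.1, 0.1)), "polydispersity value")
})
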