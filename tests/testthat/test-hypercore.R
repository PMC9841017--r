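# The 0F1 kernel: rising factorial, series, closed forms, asymptotics.

test_that("pochhammer follows the rising-factorial recursion and identities", {
  expect_identical(pochhammer(2.5, 0), 1)
  expect_equal(pochhammer(2.5, 2), 8.75)
  for (n in 0:10) expect_equal(pochhammer(1, n), factorial(n))
  # recursion (u)_{n+1} = (u)_n (u + n), exactly for representable inputs
  for (u in c(0.5, 1.5, 7, -2.5)) {
    for (n in 0:6) {
      expect_identical(pochhammer(u, n + 1L), pochhammer(u, n) * (u + n))
    }
  }
  expect_error(pochhammer(-2, 3), "pole")
  expect_error(pochhammer(0, 1), "pole")
})

test_that("series expansion reproduces the closed forms", {
  expect_identical(f01_series(3, 0), 1)
  expect_equal(f01_series(3, pi), 3 / pi^2, tolerance = 1e-12)
  expect_equal(f01_series(1, pi / 2), 2 / pi, tolerance = 1e-12)
  for (d in 1:3) {
    x <- seq(0, 10, length.out = 81)
    v <- vapply(x, function(xx) f01_series(d, xx), 0)
    ref <- f01_closed(d, x)
    expect_lt(max(abs(v - ref) / pmax(abs(ref), 1e-3)), 1e-6)
  }
})

test_that("series guards fire on cancellation and non-convergence", {
  expect_error(f01_series(2, 45), "precision loss|convergence")
  expect_error(f01_series(3, 5, n_max = 3L), "convergence")
})

test_that("closed forms hit their known zeros and limits", {
  expect_identical(f01_closed(2, 0), 1)
  expect_lt(abs(f01_closed(2, 3.8317)), 1e-4)   # first zero of J1
  expect_lt(abs(f01_closed(3, 4.4934)), 1e-4)   # smallest root of tan x = x
  # leading Guinier-like curvature: f = 1 - x^2/(2(d+2)) + O(x^4)
  h <- 1e-4
  for (d in 1:3) {
    curv <- (f01_series(d, h) - 1) / h^2
    expect_equal(curv, -1 / (2 * (d + 2)), tolerance = 1e-6)
  }
})

test_that("two-term asymptotics match the closed forms at large argument", {
  x <- seq(20, 200, length.out = 1500)
  for (d in c(1, 3)) {
    env <- hyperscatter:::f01_asym_prefactor(d) * (x / 2)^hyperscatter:::hyper_nu(d)
    expect_lt(max(abs(f01_asymptotic(d, x, 2) - f01_closed(d, x)) / env), 1e-4)
  }
  # d = 2 is a true asymptotic: two terms reach 1e-4 from x ~ 35 upward,
  # five terms from x ~ 6 (the engine's choice for cross-sections)
  x2 <- seq(35, 200, length.out = 1500)
  env2 <- hyperscatter:::f01_asym_prefactor(2) * (x2 / 2)^hyperscatter:::hyper_nu(2)
  expect_lt(max(abs(f01_asymptotic(2, x2, 2) - f01_closed(2, x2)) / env2), 1e-4)
  x5 <- seq(6, 200, length.out = 1500)
  env5 <- hyperscatter:::f01_asym_prefactor(2) * (x5 / 2)^hyperscatter:::hyper_nu(2)
  expect_lt(max(abs(f01_asymptotic(2, x5, 5) - f01_closed(2, x5)) / env5), 1e-4)
})

test_that("adding the second asymptotic term improves the sphere amplitude", {
  err <- function(k) abs(f01_asymptotic(3, 50, k) - f01_closed(3, 50))
  expect_lt(err(2), err(1))
  expect_error(f01_asymptotic(3, 1e-5), "floor")
})

test_that("regime-boundary scan finds the overlap window", {
  fac <- hyperscatter:::make_factor(3L, schulz_dist(1, sigma = 0.08))
  expect_gt(fac$x12, 1)
  expect_lt(fac$precision12, 1e-5)
  # a pair of evaluators with no overlap raises after the relaxed retry
  expect_error(
    suppressWarnings(find_regime_boundary(function(x) 1, function(x) 2,
                                          grid = 1:10, tol = 1e-6)),
    "no regime overlap")
})
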