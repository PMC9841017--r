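# Shared fixtures: pre-computed models are expensive, so they are built
# once per session and memoized here.

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, builder(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

fixture_shapes <- function() {
  list(
    sphere = shape_spec("sphere", radius = 3),
    cylinder = shape_spec("cylinder", radius = 2, length = 12),
    disk = shape_spec("disk", thickness = 2, diameter = 16),
    biaxial_ellipsoid = shape_spec("biaxial_ellipsoid", a = 2, c = 6),
    triaxial_ellipsoid = shape_spec("triaxial_ellipsoid", a = 2, b = 4, c = 6),
    cube = shape_spec("cube", edge = 4)
  )
}

fixture_qmax <- c(sphere = 25, cylinder = 25, disk = 25,
                  biaxial_ellipsoid = 25, triaxial_ellipsoid = 20, cube = 25)

benchmark_model <- function(kind, sigma = 0.1) {
  cached_model(paste0(kind, "_", sigma), function() {
    sas_precompute(fixture_shapes()[[kind]], sigma = sigma)
  })
}

## Guinier-to-Porod grid for a fixture shape
fixture_qgrid <- function(kind, n = 200L) {
  exp(seq(log(0.02), log(fixture_qmax[[kind]]), length.out = n))
}

## direct quadrature over the Schulz law, for small independent checks
schulz_quad <- function(dist, f, rel.tol = 1e-11) {
  lo <- max(0, dist$mean * (1 - 8 * dist$sigma))
  hi <- dist$mean * (1 + 8 * dist$sigma)
  stats::integrate(function(r) f(r) * hyperscatter:::schulz_density(dist, r),
                   lo, hi, rel.tol = rel.tol, subdivisions = 8000L)$value
}

## 64x64 FCC-of-spheres pattern used by several test files
small_fcc_pattern <- function() cached_model("fcc_pattern64", function() {
  m <- cached_model("sphere14", function() {
    sas_precompute(shape_spec("sphere", radius = 14), sigma = 0.08)
  })
  cell <- unit_cell(35, lattice_type = "FCC", uvw = c(1, 1, 1))
  pk <- peak_shape("gaussian", sigma_q = 0.015, debye_waller_sigma = 0.5)
  det <- detector_geometry(nx = 64, ny = 64, pixel_size = 2,
                           wavelength = 0.1, distance = 2000)
  intensity_pattern(m, det, intensity_params(number_density = 1e-4),
                    cell = cell, peak = pk)
})
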