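test_that("simplified DiA matches hand arithmetic and its limits", {
  expect_equal(dia_simplified(1e-3, 0.3e-3, 0.3e-3), 0.2768362, tolerance = 1e-6)
  expect_identical(dia_simplified(5, 5, 5), 0)          # isotropy
  expect_equal(dia_simplified(1, 0, 0), 2 / 3)          # single-axis maximum
  expect_identical(dia_simplified(0, 0, 0), 0)          # background convention
  expect_error(dia_simplified(-1, 1, 1), "non-negative")
})

test_that("simplified DiA is scale-invariant, permutation-symmetric and bounded", {
  withr::with_seed(3, {
    d <- matrix(runif(300), ncol = 3)
    base <- dia_simplified(d[, 1], d[, 2], d[, 3])
    expect_true(all(base >= 0 & base <= 2 / 3))
    for (c_ in c(1e-3, 7, 1e4))
      expect_equal(dia_simplified(c_ * d[, 1], c_ * d[, 2], c_ * d[, 3]), base,
                   tolerance = 1e-12)
    expect_equal(dia_simplified(d[, 3], d[, 1], d[, 2]), base, tolerance = 1e-12)
    # the 2/3 bound is attained only on single-axis inputs
    expect_lt(max(base), 2 / 3)
    expect_equal(dia_simplified(0, 0.4, 0), 2 / 3)
  })
})

test_that("average diffusivity is the plain mean of the three samples", {
  expect_equal(average_diffusivity(1, 1, 1), 1)
  expect_equal(average_diffusivity(1e-3, 0.3e-3, 0.3e-3), 1.6e-3 / 3)
  expect_identical(average_diffusivity(0, 0, 0), 0)
})

test_that("SH estimator reduces to the simplified form on orthogonal triplets", {
  d <- c(1, 0.3, 0.3) * 1e-3
  expect_equal(dia_sh(d, diag(3)), dia_simplified(d[1], d[2], d[3]),
               tolerance = 1e-14)
  # any orthonormal triad, not just the axes
  tn <- ref_tensor()
  withr::with_seed(5, {
    for (i in 1:25) {
      U <- rand_triad()
      s <- tensor_adc(tn, U)
      expect_equal(dia_sh(s, U), dia_simplified(s[1], s[2], s[3]),
                   tolerance = 1e-12)
    }
  })
})

test_that("SH estimator at order 4 on dense samples hits the closed form", {
  tn <- ref_tensor()
  dirs <- fibonacci_directions(100)
  got <- dia_sh(tensor_adc(tn, dirs), dirs, order = 4, lambda = 0)
  expect_equal(got, dia_closed_form(tn), tolerance = 1e-8)
  expect_equal(got, 0.1327913, tolerance = 1e-6)
  # constant samples give 0 at any order / lambda
  expect_equal(dia_sh(rep(2e-3, 100), dirs, order = 4, lambda = 0.006), 0)
})

test_that("SH estimator converges to the quadrature oracle with order", {
  withr::with_seed(9, {
    for (i in 1:5) {
      ev <- sort(runif(3, 0.1, 1.5), decreasing = TRUE) * 1e-3
      tn <- make_tensor(ev, rand_rotation())
      dirs <- fibonacci_directions(120)
      truth <- dia_quadrature(function(u) tensor_adc(tn, u))
      got <- dia_sh(tensor_adc(tn, dirs), dirs, order = 8, lambda = 0)
      expect_equal(got, truth, tolerance = 1e-3)
    }
  })
})

test_that("quadrature oracle is exact on tensors and rotation-invariant", {
  tn <- ref_tensor()
  fn <- function(u) tensor_adc(tn, u)
  expect_equal(dia_quadrature(fn), dia_closed_form(tn), tolerance = 1e-10)
  expect_equal(dia_quadrature(function(u) rep(3e-3, nrow(u))), 0,
               tolerance = 1e-12)
  withr::with_seed(13, {
    for (i in 1:10) {
      tr <- rotate_tensor(tn, rand_rotation())
      expect_equal(dia_quadrature(function(u) tensor_adc(tr, u)),
                   dia_quadrature(fn), tolerance = 1e-9)
    }
  })
})

test_that("DiA of any estimator is scale-invariant", {
  dirs <- fibonacci_directions(30)
  s <- tensor_adc(ref_tensor(), dirs)
  base <- dia_sh(s, dirs)
  for (c_ in c(0.01, 100))
    expect_equal(dia_sh(c_ * s, dirs), base, tolerance = 1e-12)
})

test_that("color code encodes axis dominance and clips", {
  # single-axis voxel: dia = 2/3, DAV = 1/3, pre-clip r = 2 -> stored (1, 0, 0)
  expect_equal(as.vector(color_code(1, 0, 0)), c(1, 0, 0))
  # isotropic voxel renders black
  expect_equal(as.vector(color_code(2, 2, 2)), c(0, 0, 0))
  # background (DAV = 0) renders black
  expect_equal(as.vector(color_code(0, 0, 0)), c(0, 0, 0))
  # reference voxel: channel = dia * D / DAV
  expect_equal(as.vector(color_code(1e-3, 0.3e-3, 0.3e-3)),
               c(0.5190678, 0.1557203, 0.1557203), tolerance = 1e-6)
})

test_that("map driver picks the simplified path iff 3 orthogonal directions", {
  ph <- axes_phantom()
  maps <- dia_compute(compute_adc(normalize_dwi(ph)))
  expect_identical(maps$estimator, "simplified")
  expect_equal(unique(as.vector(maps$dia)), 0.2768362, tolerance = 1e-6)
  expect_equal(unique(as.vector(maps$dav)), 1.6e-3 / 3, tolerance = 1e-9)
  expect_equal(maps$rgb[1, 1, 1, ], c(0.5190678, 0.1557203, 0.1557203),
               tolerance = 1e-6)

  ph6 <- synthesize_phantom(ref_tensor(), layout = array(1L, c(2, 2, 2)),
                            directions = direction_scheme(6))
  maps6 <- dia_compute(compute_adc(normalize_dwi(ph6)))
  expect_identical(maps6$estimator, "sh")
  expect_null(maps6$rgb)
  expect_equal(unique(round(as.vector(maps6$dia), 10)), 0.1327913,
               tolerance = 1e-6)
  expect_error(dia_compute(compute_adc(normalize_dwi(ph6)), estimator = "simplified"),
               "3 mutually orthogonal")
})
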