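test_that("tensors assemble, decompose and report FA correctly", {
  expect_equal(make_tensor(rep(1e-3, 3))$matrix, 1e-3 * diag(3))
  tn <- ref_tensor()
  expect_equal(tn$matrix, diag(c(1, 0.3, 0.3)) * 1e-3)
  expect_equal(tensor_fa(tn), 0.6444, tolerance = 1e-4)
  expect_equal(tensor_fa(make_tensor(c(1, 1, 1))), 0)
  expect_equal(tensor_fa(make_tensor(c(1, 0, 0))), 1)
  expect_error(tensor_fa(make_tensor(c(0, 0, 0))), "zero tensor")
  expect_error(make_tensor(c(1, 1, 1), matrix(1, 3, 3)), "orthonormal")

  # eigen round trip under random orthonormal frames
  withr::with_seed(21, {
    for (i in 1:10) {
      V <- rand_rotation()
      ev <- sort(runif(3), decreasing = TRUE)
      tn <- make_tensor(ev, V)
      e <- eigen(tn$matrix, symmetric = TRUE)
      expect_equal(e$values, ev, tolerance = 1e-12)
      expect_equal(tn$eigenvectors %*% diag(tn$eigenvalues) %*% t(tn$eigenvectors),
                   tn$matrix, tolerance = 1e-12)
    }
  })
})

test_that("rotation matrices are proper and match their defining geometry", {
  expect_equal(rotation_matrix("plane", 0), diag(3))
  # plane rotation sends e1 to (0, 0, -1) at 90 degrees
  expect_equal(rotation_matrix("plane", pi / 2) %*% c(1, 0, 0),
               cbind(c(0, 0, -1)), tolerance = 1e-12)
  # spatial rotation by 120 degrees about (1,1,1)/sqrt(3) permutes coordinates
  P <- rotation_matrix("spatial", 2 * pi / 3)
  expect_equal(P, rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12)
  # diagonal of the spatial rotation is 1/3 + (2/3) cos(theta)
  th <- 0.83
  expect_equal(diag(rotation_matrix("spatial", th)),
               rep(1 / 3 + 2 / 3 * cos(th), 3), tolerance = 1e-12)

  for (th in seq(0, 2 * pi, length.out = 360)) {
    for (sch in c("plane", "spatial")) {
      R <- rotation_matrix(sch, th)
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
})

test_that("tensor rotation preserves eigenvalues and fixes isotropy", {
  iso <- make_tensor(rep(2e-3, 3))
  tn <- ref_tensor()
  withr::with_seed(31, {
    worst_iso <- 0; worst_ev <- 0
    for (i in 1:200) {
      R <- rand_rotation()
      worst_iso <- max(worst_iso, max(abs(rotate_tensor(iso, R)$matrix - iso$matrix)))
      worst_ev <- max(worst_ev, max(abs(rotate_tensor(tn, R)$eigenvalues - tn$eigenvalues)))
    }
    expect_lt(worst_iso, 1e-12)
    expect_lt(worst_ev, 1e-12)
  })
  # plane rotation by 90 degrees permutes the diagonal pattern
  Tr <- rotate_tensor(tn, rotation_matrix("plane", pi / 2))
  expect_equal(diag(Tr$matrix), c(0.3, 0.3, 1) * 1e-3, tolerance = 1e-12)
})

test_that("tensor ADC is the quadratic form u'Tu", {
  tn <- ref_tensor()
  expect_equal(tensor_adc(tn, c(1, 0, 0)), 1e-3)
  expect_equal(tensor_adc(tn, c(1, 1, 1) / sqrt(3)), 1.6e-3 / 3)
  expect_equal(tensor_adc(make_tensor(rep(5e-4, 3)), fibonacci_directions(10)),
               rep(5e-4, 10))
})

test_that("direction schemes are unit, antipodally distinct and well spread", {
  for (n in c(3, 4, 5, 6, 20, 64)) {
    dirs <- direction_scheme(n)
    expect_equal(sqrt(rowSums(dirs^2)), rep(1, n), tolerance = 1e-8)
    G <- abs(tcrossprod(dirs))
    diag(G) <- 0
    expect_lt(max(G), 1 - 1e-6)   # no duplicated or antipodal pair
  }
  # icosahedral 6-set: all pairwise antipodal angles equal (arctan 2)
  G6 <- abs(tcrossprod(direction_scheme(6)))
  diag(G6) <- NA
  expect_equal(unique(round(as.vector(G6[!is.na(G6)]), 10)), round(1 / sqrt(5), 10))
})

test_that("phantom synthesis produces the mono-exponential signal", {
  ph <- axes_phantom(dims = c(2, 2, 2))
  expect_s3_class(ph, "dwi_volume")
  # b0 first, then x-axis signal S0 exp(-b * 1e-3) = 1000 exp(-1)
  expect_equal(unique(as.vector(ph$data[, , , 1])), 1000)
  expect_equal(unique(as.vector(ph$data[, , , 2])), 1000 * exp(-1),
               tolerance = 1e-9)
  # deterministic when noiseless, regardless of seed
  ph2 <- axes_phantom(dims = c(2, 2, 2), seed = 99L)
  expect_identical(ph$data, ph2$data)
  # background voxels carry zero signal
  lay <- array(1L, c(2, 2, 2)); lay[1, 1, 1] <- 0L
  phb <- synthesize_phantom(ref_tensor(), layout = lay,
                            directions = direction_scheme("axes"))
  expect_true(all(phb$data[1, 1, 1, ] == 0))
})

test_that("Rician noise is seeded, reproducible, and median-stable at SNR 20", {
  ph1 <- axes_phantom(dims = c(3, 3, 3), noise_sigma = 50, seed = 4L)
  ph2 <- axes_phantom(dims = c(3, 3, 3), noise_sigma = 50, seed = 4L)
  expect_identical(ph1$data, ph2$data)
  ph3 <- axes_phantom(dims = c(3, 3, 3), noise_sigma = 50, seed = 5L)
  expect_false(identical(ph1$data, ph3$data))
  expect_true(all(ph1$data >= 0))
})

test_that("population phantom labels match its anisotropy gradient", {
  ph <- population_phantom(ratios = c(0.3, 0.1), voxels_per = 20, seed = 2L,
                           directions = fibonacci_directions(16))
  pop <- attr(ph, "population")
  expect_equal(dim(pop), c(20, 2, 1))
  adc <- compute_adc(normalize_dwi(ph))
  dia <- dia_compute(adc, estimator = "sh")$dia
  # higher-anisotropy population has clearly higher DiA
  expect_gt(median(dia[pop == 2]), median(dia[pop == 1]) + 0.1)
})
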