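test_that("grid-design formulas reproduce the design points", {
  expect_equal(max_supported_frequency(1500, 1e-3), 750e3)
  f_air <- max_supported_frequency(340, 1e-3)
  expect_equal(f_air, 170e3)
  expect_lt(abs(f_air / max_supported_frequency(1500, 1e-3) - 1 / 5), 0.035)
  expect_equal(max_supported_frequency(1500, 1e-3),
               max_supported_frequency(3000, 2e-3))  # scale invariance

  expect_equal(max_spatial_step(1500, 750e3), 1e-3)
  expect_equal(max_spatial_step(340, 2 * 750e3),
               max_spatial_step(340, 750e3) / 2)
  expect_equal(max_depth(4096, 1500, 750e3), 8.192)
  expect_equal(max_depth(1, 340, 750e3), 340 / 750e3)

  expect_error(max_supported_frequency(-1, 1e-3))
  expect_error(max_spatial_step(340, 0))
  expect_error(max_depth(0, 340, 750e3))
})

test_that("sensor array elements sit evenly on the half ring", {
  arr <- sensor_array()
  expect_equal(arr$n_elements, 128L)
  p <- arr$element_positions
  expect_equal(sqrt(rowSums(p^2)), rep(55, 128), tolerance = 1e-12)
  expect_true(all(p[, 2] > 0))  # arc above the phantom
  ang <- atan2(p[, 2], p[, 1])
  expect_equal(diff(range(diff(sort(ang)))), 0, tolerance = 1e-12)
})

test_that("stability bounds are enforced at construction and run time", {
  expect_error(acoustic_grid_spec(dt = 1e-6), "stability")
  g <- acoustic_grid_spec(shape = c(32, 32), dt = 12.5e-9, n_samples = 8,
                          pml_width = 4)
  expect_s3_class(g, "acoustic_grid_spec")
})

test_that("zero initial pressure yields identically zero traces", {
  n <- 64
  lab <- substrate_labels(n)
  p0 <- field_map(matrix(0, n, n), 1, quantity = "initial_pressure")
  g <- acoustic_grid_spec(shape = c(n, n), dt = 0.2e-6, n_samples = 50,
                          pml_width = 8)
  arr <- sensor_array(n_elements = 4, ring_radius = 20)
  sd <- forward_simulate(p0, lab, grid = g, array = arr)
  expect_true(all(sd$traces == 0))
  # determinism
  p0g <- gaussian_p0(n)
  s1 <- forward_simulate(p0g, lab, grid = g, array = arr)
  s2 <- forward_simulate(p0g, lab, grid = g, array = arr)
  expect_identical(s1$traces, s2$traces)
})

test_that("point-source arrival times match straight-ray travel times", {
  n <- 64
  lab <- substrate_labels(n)
  p0v <- matrix(0, n, n); p0v[33, 33] <- 1  # at (+0.5, -0.5) mm
  p0 <- field_map(p0v, 1, quantity = "initial_pressure")
  dt <- 0.45 * 1e-3 / 1500
  g <- acoustic_grid_spec(shape = c(n, n), dt = dt, n_samples = 110,
                          pml_width = 8)
  for (radius in c(15, 22)) {
    arr <- sensor_array(n_elements = 3, ring_radius = radius, arc = 120)
    sd <- forward_simulate(p0, lab, grid = g, array = arr)
    for (e in 1:3) {
      d <- sqrt(sum((arr$element_positions[e, ] - c(0.5, -0.5))^2))
      expected <- d * 1e-3 / 1500 / dt + 1
      expect_lt(abs(which.max(sd$traces[e, ]) - expected), 2)
    }
  }
})

test_that("homogeneous lossless run conserves energy within 1%", {
  n <- 64
  lab <- substrate_labels(n)
  g <- acoustic_grid_spec(shape = c(n, n), dt = 0.2e-6, n_samples = 150,
                          pml_width = 0)
  arr <- sensor_array(n_elements = 1, ring_radius = 20)
  sd <- forward_simulate(gaussian_p0(n), lab, grid = g, array = arr,
                         pml_alpha = 0, record_energy = TRUE)
  e <- attr(sd, "energy")
  expect_lt((max(e[-1]) - min(e[-1])) / e[2], 0.01)
})

test_that("spectral and FDTD solvers agree on a 64 x 64 fixture", {
  n <- 64
  lab <- substrate_labels(n)
  p0 <- gaussian_p0(n)
  g <- acoustic_grid_spec(shape = c(n, n), dt = 0.2e-6, n_samples = 200,
                          pml_width = 8)
  arr <- sensor_array(n_elements = 3, ring_radius = 20, arc = 150)
  ks <- forward_simulate(p0, lab, grid = g, array = arr)
  fd <- fdtd_simulate(p0, lab, grid = g, array = arr)
  for (e in 1:3) {
    expect_lte(abs(which.max(ks$traces[e, ]) - which.max(fd$traces[e, ])), 1)
    expect_gte(cor(ks$traces[e, ], fd$traces[e, ]), 0.99)
  }
})

test_that("grid refinement shifts arrivals by at most one coarse sample", {
  lab1 <- substrate_labels(64)
  p1 <- gaussian_p0(64, sigma_px = 2.5, pitch = 1)
  dt1 <- 0.3 * 1e-3 / 1500
  g1 <- acoustic_grid_spec(shape = c(64, 64), pitch = 1, dt = dt1,
                           n_samples = 120, pml_width = 8)
  lab2 <- substrate_labels(128, pitch = 0.5)
  p2 <- gaussian_p0(128, sigma_px = 5, pitch = 0.5)
  g2 <- acoustic_grid_spec(shape = c(128, 128), pitch = 0.5, dt = dt1 / 2,
                           n_samples = 240, pml_width = 16)
  arr <- sensor_array(n_elements = 1, ring_radius = 20)
  t_coarse <- which.max(forward_simulate(p1, lab1, grid = g1,
                                         array = arr)$traces[1, ])
  t_fine <- which.max(forward_simulate(p2, lab2, grid = g2,
                                       array = arr)$traces[1, ])
  expect_lte(abs((t_fine - 1) / 2 - (t_coarse - 1)), 1)
})

test_that("reciprocity holds for swapped source and receiver", {
  n <- 64
  lab <- substrate_labels(n)
  g <- acoustic_grid_spec(shape = c(n, n), dt = 0.2e-6, n_samples = 150,
                          pml_width = 8)
  mk_p0 <- function(r, c2) {
    v <- matrix(0, n, n); v[r, c2] <- 1
    field_map(v, 1, quantity = "initial_pressure")
  }
  pos_of <- function(r, c2) c((c2 - (n + 1) / 2), ((n + 1) / 2 - r))
  a <- c(26, 30); b <- c(40, 38)
  arr_b <- sensor_array(n_elements = 1, ring_radius = 1)
  arr_b$element_positions <- matrix(pos_of(b[1], b[2]), 1)
  arr_a <- sensor_array(n_elements = 1, ring_radius = 1)
  arr_a$element_positions <- matrix(pos_of(a[1], a[2]), 1)
  t_ab <- forward_simulate(mk_p0(a[1], a[2]), lab, grid = g,
                           array = arr_b)$traces[1, ]
  t_ba <- forward_simulate(mk_p0(b[1], b[2]), lab, grid = g,
                           array = arr_a)$traces[1, ]
  expect_gt(cor(t_ab, t_ba), 0.999)
  expect_lt(max(abs(t_ab - t_ba)) / max(abs(t_ab)), 0.01)
})

test_that("a nonzero source inside the PML triggers a warning", {
  n <- 64
  lab <- substrate_labels(n)
  v <- matrix(0, n, n); v[1, 5] <- 1
  p0 <- field_map(v, 1, quantity = "initial_pressure")
  g <- acoustic_grid_spec(shape = c(n, n), dt = 0.2e-6, n_samples = 10,
                          pml_width = 8)
  arr <- sensor_array(n_elements = 1, ring_radius = 10)
  expect_warning(forward_simulate(p0, lab, grid = g, array = arr,
                                  smooth_p0 = FALSE), "PML")
})
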