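test_that("uniform initial pressure follows P0 = gamma eta mu_a F", {
  lab <- rasterize(build_arrangement("s4"), c(61, 61), 1)
  lev <- lab$levels
  p0 <- uniform_initial_pressure(lab)
  expect_equal(p0$values[lab$values == match("blood", lev)], 3)
  expect_true(all(p0$values[lab$values != match("blood", lev)] == 0))

  p0b <- uniform_initial_pressure(lab, constants = pa_constants(gamma = 2, eta = 0.5))
  expect_equal(max(p0b$values), 3)  # scaling factors multiply linearly

  p0c <- uniform_initial_pressure(lab, fluence_value = 2)
  expect_equal(max(p0c$values), 6)

  # pointwise property map: invariant to pitch
  lab2 <- rasterize(build_arrangement("s4"), c(121, 121), 0.5)
  p02 <- uniform_initial_pressure(lab2)
  expect_equal(sort(unique(as.numeric(p02$values))),
               sort(unique(as.numeric(p0$values))))

  med <- media_uniform()
  med <- med[med$name != "water", ]
  expect_error(uniform_initial_pressure(lab, media = med), "water")
})

test_that("absorption map is the elementwise mu_a * F product", {
  lab <- rasterize(build_arrangement("s2"), c(61, 61), 1)
  lev <- lab$levels
  f1 <- field_map(matrix(1, 61, 61), 1, quantity = "fluence")
  A <- absorption_map(f1, lab, media_mc())
  expect_equal(A$values[lab$values == match("blood", lev)], 2.38)

  f0 <- field_map(matrix(0, 61, 61), 1, quantity = "fluence")
  expect_true(all(absorption_map(f0, lab)$values == 0))

  set.seed(4)
  labs <- field_map(matrix(sample(1:5, 16, TRUE), 4, 4), 1,
                    quantity = "labels", levels = lev)
  fl <- field_map(matrix(runif(16), 4, 4), 1, quantity = "fluence")
  A2 <- absorption_map(fl, labs, media_mc())
  mu <- media_mc()$mu_a[match(lev, media_mc()$name)]
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- mu[labs$values[i, j]] * fl$values[i, j]
  expect_equal(A2$values, oracle)

  f_bad <- field_map(matrix(1, 5, 5), 1, quantity = "fluence")
  expect_error(absorption_map(f_bad, labs), "match")
})

test_that("Monte Carlo transmission through an absorbing slab is Beer-Lambert", {
  lev <- medium_levels()
  med <- media_mc()
  med$mu_a <- ifelse(med$name == "blood", 1, 0)  # 1/cm absorber
  med$mu_s <- 0; med$g <- 0; med$n <- 1
  lab <- matrix(match("background", lev), 40, 40)
  lab[15:24, ] <- match("blood", lev)           # 1 cm slab
  labfm <- field_map(lab, pitch = 1, quantity = "labels", levels = lev)
  beam <- beam_spec(waist_radius = 1, n_directions = 1, photon_count = 1e5,
                    seed = 7, standoff = 10)
  fl <- mc_fluence(labfm, med, beam)
  tot <- attr(fl, "totals")
  p <- exp(-1)
  sigma3 <- 3 * sqrt(p * (1 - p) / tot$launched)
  expect_lt(abs(tot$exited / tot$launched - p), sigma3 + 1e-12)

  # photon weight ledger closes
  expect_lt(abs(tot$launched - tot$absorbed - tot$exited -
                tot$roulette_balance) / tot$launched, 1e-6)
})

test_that("Monte Carlo is seed-deterministic and conserves weight in vacuum", {
  lab <- rasterize(build_arrangement("s4"), c(121, 121), 1)
  beam <- beam_spec(waist_radius = 10, photon_count = 2e4, seed = 42)
  f1 <- mc_fluence(lab, media_mc(), beam)
  f2 <- mc_fluence(lab, media_mc(), beam)
  expect_identical(f1$values, f2$values)
  f3 <- mc_fluence(lab, media_mc(), beam_spec(10, photon_count = 2e4, seed = 43))
  expect_false(identical(f1$values, f3$values))

  # zero-absorption zero-scattering medium: everything launched exits
  lev <- medium_levels()
  med0 <- media_mc()
  med0$mu_a <- 0; med0$mu_s <- 0; med0$n <- 1
  lab0 <- field_map(matrix(match("substrate", lev), 40, 40), 1,
                    quantity = "labels", levels = lev)
  t0 <- attr(mc_fluence(lab0, med0, beam_spec(5, photon_count = 1e4, seed = 1,
                                              standoff = 10)), "totals")
  expect_equal(t0$exited, t0$launched, tolerance = 1e-12)
  expect_equal(t0$absorbed, 0)
})

test_that("Gaussian launch profile has the configured waist", {
  b <- beam_spec(waist_radius = 8, n_directions = 1, photon_count = 1,
                 seed = 3, standoff = 0)
  n <- 2e4
  set.seed(3)
  L <- mc_launch(b, n, dim = 2)
  offs <- L$pos[, 1]  # transverse axis of a vertical beam at the origin
  target <- 8 / 2     # exp(-2 r^2 / w^2) has sd w/2 per axis
  se_sd <- target / sqrt(2 * n)
  expect_lt(abs(sd(offs) - target), 3 * se_sd)
  expect_equal(mean(L$dir[, 2]), -1)  # aimed downward at the phantom
})

test_that("central-slice projection picks the imaging plane", {
  vol <- voxelize(build_arrangement("s4"), c(61, 61, 21), 1, tube_length = 30)
  sl <- project_slice(vol)
  expect_equal(dim(sl$values), c(61L, 61L))
  expect_identical(sl$values, vol$values[, , 11])
})
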