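test_that("media tables carry the study's optical and acoustic constants", {
  mu <- media_uniform()
  expect_equal(mu$mu_a[mu$name == "blood"], 3)
  expect_equal(mu$mu_a[mu$name %in% c("air", "water", "substrate")], c(0, 0, 0))
  mc <- media_mc()
  blood <- mc[mc$name == "blood", ]
  expect_equal(unlist(blood[c("mu_a", "mu_s", "g", "n")]),
               c(mu_a = 2.38, mu_s = 522, g = 0.9, n = 1.4))
  air <- mc[mc$name == "air", ]
  expect_equal(unlist(air[c("mu_a", "mu_s", "g", "n")]),
               c(mu_a = 0.001, mu_s = 347, g = 0.001, n = 1.0))
  water <- mc[mc$name == "water", ]
  expect_equal(unlist(water[c("mu_a", "mu_s", "g", "n")]),
               c(mu_a = 0.06, mu_s = 1, g = 0.99, n = 1.3))
  expect_equal(mc$sound_speed[mc$name == "air"], 340)
  expect_equal(mc$density[mc$name == "air"], 1.2)
  expect_true(all(mc$sound_speed[mc$name != "air"] == 1500))
  expect_true(all(mc$density[mc$name != "air"] == 1000))
})

test_that("horizontal and single-medium arrangements place the right tubes", {
  s4 <- build_arrangement("s4", 0.5, 10)
  expect_equal(nrow(s4$inclusions), 3)
  expect_equal(s4$inclusions$medium, c("blood", "air", "water"))
  expect_equal(order(s4$inclusions$x), 1:3)  # left-to-right order

  s1 <- build_arrangement("s1", 0.5, 10)
  expect_equal(nrow(s1$inclusions), 1)

  expect_equal(nrow(build_arrangement("S2")$inclusions), 9)
  expect_true(all(build_arrangement("S2")$inclusions$medium == "blood"))
})

test_that("Latin squares are cyclic shifts with every medium once per row/column", {
  S5 <- build_arrangement("S5", 0.5, 10)
  inc <- S5$inclusions
  expect_equal(nrow(inc), 9)
  top <- inc[inc$y == max(inc$y), ]
  expect_equal(top$medium[order(top$x)], c("air", "blood", "water"))
  expect_true(is_latin_square(S5))
  for (id in c("S4", "S5", "S6"))
    expect_true(is_latin_square(build_arrangement(id)))
  expect_false(is_latin_square(build_arrangement("S1")))
  expect_false(is_latin_square(build_arrangement("s4")))
})

test_that("invalid arrangements and geometry are rejected", {
  expect_error(build_arrangement("s9"), "valid labels")
  expect_error(build_arrangement("s4", tube_radius = 0.5, spacing = 0.9),
               "spacing")
  expect_error(build_arrangement("s4", tube_radius = 0.5, spacing = 10,
                                 substrate_side = 15),
               "inside the substrate")
})

test_that("rasterization follows the centre-in-disk rule", {
  m <- build_arrangement("s2", tube_radius = 0.5)  # single blood disk
  lab <- rasterize(m, c(51, 51), pitch = 1)
  lev <- lab$levels
  blood <- which(lab$values == match("blood", lev), arr.ind = TRUE)
  expect_equal(nrow(blood), 1L)       # sub-pixel disk still marks its centre
  expect_equal(unname(blood[1, ]), c(26, 26))

  m0 <- m; m0$inclusions <- m0$inclusions[0, ]
  lab0 <- rasterize(m0, c(51, 51), pitch = 1)
  expect_true(all(lab0$values %in% match(c("substrate", "background"), lev)))
  expect_equal(sum(lab0$values == match("substrate", lev)), 51 * 51)

  # exhaustive per-pixel oracle for a resolvable disk
  m2 <- build_arrangement("s2", tube_radius = 2)
  lab2 <- rasterize(m2, c(51, 51), pitch = 1)
  co <- grid_coords(lab2)
  oracle <- 0
  for (r in 1:51) for (c2 in 1:51)
    if (co$x[c2]^2 + co$y[r]^2 <= 4) oracle <- oracle + 1
  expect_equal(sum(lab2$values == match("blood", lev)), oracle)
})

test_that("rasterization is deterministic and converges to disk area", {
  m <- build_arrangement("s2", tube_radius = 2)
  a <- rasterize(m, c(121, 121), 1)
  b <- rasterize(m, c(121, 121), 1)
  expect_identical(a$values, b$values)

  pitch <- 0.2  # radius / 10
  lab <- rasterize(m, c(253, 253), pitch)
  n_blood <- sum(lab$values == match("blood", lab$levels))
  expect_lt(abs(n_blood * pitch^2 - pi * 4) / (pi * 4), 0.05)

  expect_error(rasterize(m, c(31, 31), 1), "cover")
})

test_that("voxelization extrudes tubes along z with substrate past tube ends", {
  m <- build_arrangement("s4")
  vol <- voxelize(m, shape = c(61, 61, 61), pitch = 1, tube_length = 30)
  lev <- vol$levels
  mid <- vol$values[, , 31]
  expect_identical(mid, rasterize(m, c(61, 61), 1)$values)
  expect_false(any(vol$values[, , 3] != match("background", lev)))
  near_end <- vol$values[, , 31 + 20]  # past the tube half-length, inside the cube
  expect_false(any(near_end == match("blood", lev)))
})

test_that("phantom YAML specs round-trip", {
  m <- build_arrangement("S6", 0.45, 9)
  f <- tempfile(fileext = ".yaml")
  write_phantom_yaml(m, f)
  m2 <- read_phantom_yaml(f)
  expect_equal(m2$arrangement_id, "S6")
  expect_equal(m2$inclusions$medium, m$inclusions$medium)
  expect_equal(m2$inclusions$x, m$inclusions$x)
  expect_equal(unname(m2$substrate), unname(m$substrate))
})
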