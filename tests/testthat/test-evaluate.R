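test_that("metric suite matches closed forms and brute-force oracles", {
  set.seed(21)
  A <- matrix(runif(20 * 20), 20, 20)

  m_id <- image_metrics(A, A)
  expect_equal(m_id$mse, 0)
  expect_equal(m_id$nae, 0)
  expect_equal(m_id$ssim, 1)
  expect_identical(m_id$psnr, Inf)

  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  m_c <- image_metrics(ones, zeros)
  expect_equal(m_c$mse, 1)
  expect_equal(m_c$psnr, 0)
  expect_equal(m_c$nae, 1)

  B <- matrix(runif(400), 20, 20)
  m <- image_metrics(A, B)
  mse_loop <- 0
  for (i in 1:20) for (j in 1:20) mse_loop <- mse_loop + (A[i, j] - B[i, j])^2
  expect_equal(m$mse, mse_loop / 400, tolerance = 1e-14)
  expect_lt(abs(m$psnr - 10 * log10(1 / (mse_loop / 400))), 1e-9)
  expect_equal(m$nae, sum(abs(A - B)) / sum(A))
  expect_lt(abs(m$ssim - ssim_oracle(A, B)), 1e-6)

  expect_error(image_metrics(zeros, ones), "zero")
  expect_error(image_metrics(A, matrix(0, 3, 3)), "shape")
})

test_that("lift ratios follow the relative-change convention", {
  expect_equal(lift_ratio(10, 10), 0)
  expect_equal(lift_ratio(12, 10), 0.2)
  expect_equal(lift_ratio(0.25, 0.50), -0.5)   # error metric shrinking
  # scale consistency
  expect_equal(lift_ratio(3 * 12, 3 * 10), lift_ratio(12, 10))
  expect_warning(out <- lift_ratio(1, 1e-15), "epsilon")
  expect_true(is.na(out))
})

test_that("ideal images render absorbing disks only", {
  rs <- recon_spec(grid_shape = c(200, 200), pitch = 0.6)
  ga4 <- ideal_image(build_arrangement("s4"), rs)
  co <- grid_coords(ga4)
  on_blood <- ga4$values[abs(co$y) < 0.4, abs(co$x + 10) < 0.4]
  expect_true(all(on_blood == 1))
  expect_true(all(ga4$values[, abs(co$x) < 0.4] == 0))   # air column
  expect_true(all(ga4$values[, abs(co$x - 10) < 0.4] == 0))  # water column

  S5 <- build_arrangement("S5")
  gaS5 <- ideal_image(S5, rs)
  blood_pos <- S5$inclusions[S5$inclusions$medium == "blood", c("x", "y")]
  expect_equal(nrow(blood_pos), 3)
  for (i in 1:3) {
    r <- which.min(abs(co$y - blood_pos$y[i]))
    c2 <- which.min(abs(co$x - blood_pos$x[i]))
    expect_equal(gaS5$values[r, c2], 1)
  }
  # disk pixel area: three disks of radius 0.5 mm
  expect_equal(sum(gaS5$values > 0) / 3, sum(ga4$values > 0), tolerance = 0.4)

  expect_error(ideal_image(build_arrangement("s1"), rs), "absorbing")
})

test_that("artifact isolation is an exact linear subtraction", {
  set.seed(8)
  arr <- sensor_array(n_elements = 4)
  a <- sensor_data(matrix(rnorm(4 * 100), 4, 100), 1e-7, arr)
  b <- sensor_data(matrix(rnorm(4 * 100), 4, 100), 1e-7, arr)
  apb <- a; apb$traces <- a$traces + b$traces
  expect_equal(isolate_artifacts(apb, a)$traces, b$traces)
  expect_true(all(isolate_artifacts(a, a)$traces == 0))

  fa <- field_map(matrix(runif(25), 5, 5), 1)
  fb <- field_map(matrix(runif(25), 5, 5), 1)
  expect_true(all(isolate_artifacts(fa, fa)$values == 0))
  expect_error(isolate_artifacts(fa, a), "both")
  bad <- sensor_data(matrix(0, 4, 50), 1e-7, arr)
  expect_error(isolate_artifacts(a, bad), "match")
})

test_that("circle fitting recovers synthetic arcs", {
  rs <- recon_spec(grid_shape = c(240, 240), pitch = 0.5)
  blank <- matrix(0, 240, 240)
  paint <- function(img, cx, cy, r, th0, th1) {
    th <- seq(th0, th1, length.out = 720)
    xs <- cx + r * cos(th); ys <- cy + r * sin(th)
    cc <- round(xs / 0.5 + 120.5); rr <- round(120.5 - ys / 0.5)
    ok <- cc >= 1 & cc <= 240 & rr >= 1 & rr <= 240
    img[cbind(rr[ok], cc[ok])] <- 1
    img
  }
  half <- field_map(paint(blank, 0, 0, 20, pi, 2 * pi), 0.5)
  fit <- fit_semicircle(half, 0.5)
  expect_lt(sqrt(sum(fit$center_xy^2)), 1)
  expect_lt(abs(fit$radius - 20), 0.5)
  expect_lt(abs(fit$arc_span - 180), 25)

  full <- field_map(paint(blank, 3, -2, 15, 0, 2 * pi), 0.5)
  fit2 <- fit_semicircle(full, 0.5)
  expect_gt(fit2$arc_span, 350)
  expect_lt(abs(fit2$radius - 15), 0.5)
  expect_lt(sqrt(sum((fit2$center_xy - c(3, -2))^2)), 1)

  sparse <- blank; sparse[5, 5:9] <- 1
  expect_error(fit_semicircle(field_map(sparse, 0.5), 0.5), "10 pixels")
})

test_that("crossover detection interpolates sign changes of the smoothed ratio", {
  waists <- c(10, 12, 14, 16, 18, 20)
  # constructed trend crossing 1 between 16 and 18
  ratio <- c(0.70, 0.74, 0.80, 0.90, 1.10, 1.25)
  cx <- detect_crossover(waists, ratio, smooth_window = 1)
  expect_length(cx, 1)
  expect_gt(cx, 16); expect_lt(cx, 18)
  # smoothing keeps it inside the same bracket here
  cx3 <- detect_crossover(waists, ratio, smooth_window = 3)
  expect_true(all(cx3 > 14 & cx3 < 20))

  expect_length(detect_crossover(waists, rep(0.4, 6)), 0)
  expect_length(detect_crossover(waists, rep(1.7, 6)), 0)
})

test_that("a single-waist sweep emits one row per filter and metric", {
  g <- fast_grid()
  rs <- fast_recon()
  sw <- suppressWarnings(waist_sweep("s4", waists = 12, seed = 5, photons = 5e3,
                                     grid = g, rspec = rs))
  expect_equal(nrow(sw$table), 8)  # 2 filters x 4 metrics
  expect_setequal(unique(sw$table$filter), c("adf", "nlm"))
  expect_setequal(unique(sw$table$metric), c("psnr", "ssim", "mse", "nae"))
  expect_false(any(sw$table$unstable))
  expect_true(all(is.finite(sw$table$lift)))

  # determinism: identical seed reproduces the table
  sw2 <- suppressWarnings(waist_sweep("s4", waists = 12, seed = 5, photons = 5e3,
                                      grid = g, rspec = rs))
  expect_identical(sw$table, sw2$table)

  expect_error(waist_sweep("s4", waists = numeric(0)), "empty")
  expect_error(waist_sweep("s4", waists = c(5, 30)))
})
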