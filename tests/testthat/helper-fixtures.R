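# shared fixtures and independent oracles (no shared code with the package
# implementations they check)

# homogeneous substrate label map
substrate_labels <- function(n, pitch = 1) {
  lev <- medium_levels()
  field_map(matrix(match("substrate", lev), n, n), pitch = pitch,
            quantity = "labels", levels = lev)
}

# centred Gaussian initial-pressure blob
gaussian_p0 <- function(n, sigma_px = 2.5, pitch = 1) {
  x <- seq_len(n) - (n + 1) / 2
  v <- exp(-outer(x^2, x^2, "+") / (2 * sigma_px^2))
  field_map(v, pitch = pitch, quantity = "initial_pressure")
}

# fast study-geometry acoustic settings: same 121 x 121 grid and 55 mm ring,
# but a coarser time step (CFL 0.45) and just enough samples to cover the
# ring travel time -- keeps full-pipeline unit tests at ~1 s per forward run
fast_grid <- function(n_samples = 170) {
  acoustic_grid_spec(shape = c(121, 121), pitch = 1, dt = 0.3e-6,
                     n_samples = n_samples, pml_width = 10)
}
fast_recon <- function(...) {
  recon_spec(grid_shape = c(150, 150), pitch = 0.8, ...)
}

# brute-force per-pixel oracles ------------------------------------------

# non-local means by direct double loop over Eq-style definitions: search
# window clipped to the image, patch padding reflective
nlm_oracle <- function(img, h, pr, sr) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  patch <- function(i, j) {
    ii <- refl(i + (-pr:pr), nr)
    jj <- refl(j + (-pr:pr), nc)
    img[ii, jj, drop = FALSE]
  }
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vp <- patch(i, j)
    acc <- 0; wsum <- 0
    for (qi in max(1, i - sr):min(nr, i + sr))
      for (qj in max(1, j - sr):min(nc, j + sr)) {
        vq <- patch(qi, qj)
        w <- exp(-sum((vp - vq)^2) / h^2)
        acc <- acc + w * img[qi, qj]
        wsum <- wsum + w
      }
    out[i, j] <- acc / wsum
  }
  out
}

# SSIM by direct loops over valid window positions
ssim_oracle <- function(A, B, window = 11, sigma = 1.5, K1 = 0.01,
                        K2 = 0.03, L = 1) {
  r <- (window - 1) / 2
  k1d <- exp(-((-r:r)^2) / (2 * sigma^2)); k1d <- k1d / sum(k1d)
  W <- outer(k1d, k1d)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (1 + r):(nrow(A) - r)) for (j in (1 + r):(ncol(A) - r)) {
    a <- A[(i - r):(i + r), (j - r):(j + r)]
    b <- B[(i - r):(i + r), (j - r):(j + r)]
    mu1 <- sum(W * a); mu2 <- sum(W * b)
    s11 <- sum(W * a * a) - mu1^2
    s22 <- sum(W * b * b) - mu2^2
    s12 <- sum(W * a * b) - mu1 * mu2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
  }
  mean(vals)
}

# uniform-light pipeline for one arrangement (shared by evaluation tests)
run_uniform_pipeline <- function(arrangement_id, grid, rspec,
                                 normalize = "clip") {
  model <- build_arrangement(arrangement_id)
  labels <- rasterize(model, grid$shape, grid$pitch)
  p0 <- uniform_initial_pressure(labels)
  sd <- forward_simulate(p0, labels, grid = grid)
  go <- suppressWarnings(das_reconstruct(lowpass(sd, rspec$lowpass_cutoff),
                                         rspec, normalize = normalize))
  list(model = model, labels = labels, sd = sd, go = go,
       ga = ideal_image(model, rspec))
}

# cross-test cache so the acceptance file can reuse expensive stages
.pacavity_cache <- new.env(parent = emptyenv())
cache_get <- function(key, fun) {
  if (!exists(key, envir = .pacavity_cache)) {
    assign(key, fun(), envir = .pacavity_cache)
  }
  get(key, envir = .pacavity_cache)
}
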