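#' Image quality metrics
#'
#' Computes MSE, PSNR, NAE and SSIM between a reference image `ga` (the
#' anticipated/ideal image) and a test image `g`, both normalized to
#' `[0, 1]`:
#' * MSE = mean((ga - g)^2)
#' * PSNR = 10 log10(1 / MSE) (dB, data range 1; `Inf` for identical images)
#' * NAE = sum(|ga - g|) / sum(|ga|)
#' * SSIM with the standard constants K1 = 0.01, K2 = 0.03, data range 1 and
#'   an 11-pixel Gaussian window (sd 1.5), averaged over the valid region.
#'
#' @param ga reference image (`field_map` or matrix), in `[0, 1]`.
#' @param g test image, same shape.
#' @return Named list `psnr`, `ssim`, `mse`, `nae`.
#' @export
image_metrics <- function(ga, g) {
  A <- if (inherits(ga, "field_map")) ga$values else ga
  B <- if (inherits(g, "field_map")) g$values else g
  if (!identical(dim(A), dim(B))) stop("images must share a shape")
  if (all(A == 0)) stop("reference image is identically zero; NAE undefined")
  mse <- mean((A - B)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  nae <- sum(abs(A - B)) / sum(abs(A))
  list(psnr = psnr, ssim = ssim(A, B), mse = mse, nae = nae)
}

# separable 'valid' convolution with an odd kernel, via banded matrices
conv_valid <- function(m, kern) {
  n <- length(kern)
  band <- function(size) {
    out <- matrix(0, size - n + 1, size)
    for (i in seq_len(size - n + 1)) out[i, i:(i + n - 1)] <- kern
    out
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Structural similarity index
#'
#' @param A,B numeric matrices in `[0, data_range]`.
#' @param window Gaussian window size (odd).
#' @param sigma Gaussian window sd, pixels.
#' @param K1,K2 stability constants.
#' @param data_range intensity range of the images.
#' @return Mean SSIM over the valid (fully windowed) region.
#' @export
ssim <- function(A, B, window = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 data_range = 1) {
  stopifnot(identical(dim(A), dim(B)),
            nrow(A) >= window, ncol(A) >= window)
  r <- (window - 1) / 2
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mu1 <- conv_valid(A, kern); mu2 <- conv_valid(B, kern)
  s11 <- conv_valid(A * A, kern) - mu1^2
  s22 <- conv_valid(B * B, kern) - mu2^2
  s12 <- conv_valid(A * B, kern) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(map)
}

#' Lift ratio of an image-quality metric
#'
#' Relative change of metric X after filtering:
#' (X(Ga, Gf) - X(Ga, Go)) / X(Ga, Go). Negative for error metrics that
#' shrink, positive for quality metrics that grow.
#'
#' @param x_ga_gf metric between the ideal and the filtered image.
#' @param x_ga_go metric between the ideal and the unfiltered image.
#' @param eps guard on the baseline denominator.
#' @return The lift ratio (dimensionless), or `NA` with a warning when the
#'   baseline is below `eps`.
#' @export
lift_ratio <- function(x_ga_gf, x_ga_go, eps = 1e-12) {
  if (!is.finite(x_ga_go) || abs(x_ga_go) < eps) {
    warning("baseline metric below epsilon; lift ratio undefined")
    return(NA_real_)
  }
  (x_ga_gf - x_ga_go) / x_ga_go
}

#' Metric report for one original/filtered image pair
#'
#' @param ga ideal image, `go` unfiltered reconstruction, `gf` filtered image
#'   (all `[0, 1]`, same shape).
#' @param go,gf see above.
#' @param ids optional identifiers recorded with the report.
#' @return A `metric_report`: metrics for `go` and `gf` plus per-metric lift
#'   ratios.
#' @export
metric_report <- function(ga, go, gf, ids = NULL) {
  base <- image_metrics(ga, go)
  filt <- image_metrics(ga, gf)
  lifts <- mapply(lift_ratio, unlist(filt), unlist(base))
  structure(list(baseline = base, filtered = filt,
                 lift_ratios = as.list(lifts), ids = ids),
            class = "metric_report")
}

#' Ideal (anticipated) image of a phantom
#'
#' Renders the optically absorbing inclusions as disks at reconstruction
#' resolution with intensity proportional to their absorption coefficient,
#' normalized to `[0, 1]`; non-absorbing media and the substrate are 0.
#' This is the ground-truth reference `Ga` for the lift-ratio evaluation.
#'
#' @param model a `phantom_model`.
#' @param spec a [recon_spec()] (grid geometry).
#' @param media media table supplying `mu_a` (default [media_uniform()]).
#' @return An image `field_map`.
#' @export
ideal_image <- function(model, spec = recon_spec(), media = media_uniform()) {
  inc <- model$inclusions
  mu <- media_lookup(media, inc$medium, "mu_a")
  if (all(mu == 0))
    stop("arrangement has no absorbing inclusion; ideal image would be zero")
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * spec$pitch
  y <- ((nr + 1) / 2 - seq_len(nr)) * spec$pitch
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(inc))) {
    if (mu[i] == 0) next
    hit <- (X - inc$x[i])^2 + (Y - inc$y[i])^2 <= inc$radius[i]^2
    img[hit] <- pmax(img[hit], mu[i])
  }
  img <- img / max(img)
  field_map(img, pitch = spec$pitch, quantity = "image")
}

#' Isolate pure artifacts by paired subtraction
#'
#' Elementwise difference of a full simulation (all inclusions) and its
#' artifact-free pair (blood only). For sensor data the subtraction happens
#' on the raw traces; for images both inputs should carry the same
#' normalization state (use `normalize = "none"` reconstructions for a
#' strictly linear subtraction).
#'
#' @param full `sensor_data` or image `field_map` of the full phantom.
#' @param blood_only matching object from the blood-only phantom.
#' @return Object of the same type holding `full - blood_only`.
#' @export
isolate_artifacts <- function(full, blood_only) {
  if (inherits(full, "sensor_data") && inherits(blood_only, "sensor_data")) {
    if (!identical(dim(full$traces), dim(blood_only$traces)) ||
        !identical(full$dt, blood_only$dt))
      stop("sensor data acquisition specs do not match")
    full$traces <- full$traces - blood_only$traces
    return(full)
  }
  if (inherits(full, "field_map") && inherits(blood_only, "field_map")) {
    if (!identical(dim(full$values), dim(blood_only$values)) ||
        !identical(full$pitch, blood_only$pitch))
      stop("field maps do not share a grid")
    full$values <- full$values - blood_only$values
    return(full)
  }
  stop("inputs must both be sensor_data or both be field_map")
}

#' Fit a circle to a thresholded artifact image
#'
#' Pixels with |value| above `threshold` x the image |max| are fit with an
#' algebraic least-squares circle; the arc span is the angular extent
#' of those pixels around the fitted centre (360 minus the largest angular
#' gap).
#'
#' @param artifact an image `field_map`.
#' @param threshold fraction of the absolute maximum, in (0, 1).
#' @return An `artifact_profile`: `center_xy` (mm), `radius` (mm),
#'   `arc_span` (degrees), `n_pixels` used.
#' @export
fit_semicircle <- function(artifact, threshold = 0.5) {
  stopifnot(inherits(artifact, "field_map"))
  v <- abs(artifact$values)
  sel <- which(v >= threshold * max(v), arr.ind = TRUE)
  if (nrow(sel) < 10)
    stop("fewer than 10 pixels above threshold; cannot fit a circle")
  co <- grid_coords(artifact)
  px <- co$x[sel[, 2]]; py <- co$y[sel[, 1]]
  A <- cbind(2 * px, 2 * py, 1)
  b <- px^2 + py^2
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))
  ang <- sort(atan2(py - center[2], px - center[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  arc_span <- (2 * pi - max(gaps)) * 180 / pi
  structure(list(center_xy = as.numeric(center), radius = radius,
                 arc_span = arc_span, n_pixels = nrow(sel)),
            class = "artifact_profile")
}

#' Detect crossover radii of an improvement-rate ratio curve
#'
#' Smooths the ratio curve with a 3-point moving average and locates sign
#' changes of (ratio - 1) by linear interpolation.
#'
#' @param waists waist radii, mm (sorted).
#' @param ratio ADF/NLM improvement-rate ratios at those waists.
#' @param smooth_window moving-average window (odd; 1 disables smoothing).
#' @return Numeric vector of crossover radii (mm), possibly empty.
#' @export
detect_crossover <- function(waists, ratio, smooth_window = 3) {
  stopifnot(length(waists) == length(ratio), length(waists) >= 2)
  r <- ratio
  if (smooth_window > 1) {
    half <- (smooth_window - 1) / 2
    r <- vapply(seq_along(ratio), function(i) {
      j <- max(1, i - half):min(length(ratio), i + half)
      mean(ratio[j])
    }, numeric(1))
  }
  d <- r - 1
  out <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (is.na(d[i]) || is.na(d[i + 1])) next
    if (d[i] == 0) out <- c(out, waists[i])
    else if (d[i] * d[i + 1] < 0) {
      f <- d[i] / (d[i] - d[i + 1])
      out <- c(out, waists[i] + f * (waists[i + 1] - waists[i]))
    }
  }
  unique(out)
}

#' Tune filter hyperparameters on a held-out arrangement
#'
#' Grid-searches each filter's hyperparameters to maximize its PSNR lift on
#' the supplied ideal/original image pair (by design a *different*
#' arrangement from the ones later evaluated, preventing per-image tuning
#' bias).
#'
#' @param ga ideal image of the held-out arrangement.
#' @param go its unfiltered reconstruction, in `[0, 1]`.
#' @param adf_grid list of [adf_params()] candidates; `NULL` for a default
#'   grid over `k` and `n_iter`.
#' @param nlm_grid list of [nlm_params()] candidates; `NULL` for a default
#'   grid over `h`.
#' @return list with the winning `adf` and `nlm` parameter objects, each
#'   carrying its achieved PSNR lift as attribute `"psnr_lift"`.
#' @export
tune_filter_params <- function(ga, go, adf_grid = NULL, nlm_grid = NULL) {
  rng <- diff(range(if (inherits(go, "field_map")) go$values else go))
  # the grids cover each filter's intended operating regime: ADF stays
  # edge-preserving (k well below the dynamic range, moderate iteration
  # counts); NLM spans h up to where its lift saturates
  if (is.null(adf_grid))
    adf_grid <- unlist(lapply(c(0.05, 0.1, 0.2), function(kf)
      lapply(c(10, 20, 40), function(ni)
        adf_params(k = kf * rng, n_iter = ni))), recursive = FALSE)
  if (is.null(nlm_grid))
    nlm_grid <- lapply(c(0.5, 1, 2, 4), function(hf)
      nlm_params(h = hf * rng))
  base <- image_metrics(ga, go)
  best <- function(grid, filter_fun) {
    lifts <- vapply(grid, function(p) {
      gf <- filter_fun(go, p)
      lift_ratio(image_metrics(ga, gf)$psnr, base$psnr)
    }, numeric(1))
    win <- grid[[which.max(lifts)]]
    attr(win, "psnr_lift") <- max(lifts)
    win
  }
  list(adf = best(adf_grid, adf), nlm = best(nlm_grid, nlm))
}

#' Beam-waist uniformity sweep
#'
#' For each Gaussian waist radius: Monte Carlo fluence (fast in-plane mode) ->
#' absorption -> initial pressure -> acoustic forward simulation -> low-pass
#' + delay-and-sum reconstruction -> ADF and NLM filtering -> metrics and
#' lift ratios against the ideal image. Emits per-waist lift ratios, the
#' ADF/NLM improvement-rate ratio per metric, and any crossover radii of the
#' smoothed ratio curves. Waists below `unstable_below` mm are flagged
#' unstable (over-focused illumination makes the metrics unreliable there).
#'
#' @param arrangement_id phantom arrangement to sweep (e.g. `"s4"`).
#' @param waists waist radii in mm, within `[1, 20]`.
#' @param adf_par,nlm_par frozen filter hyperparameters.
#' @param seed base seed; waist i uses seed + i.
#' @param photons photon packets per waist.
#' @param grid acoustic grid spec.
#' @param array sensor array.
#' @param rspec reconstruction spec.
#' @param unstable_below waists strictly below this are flagged, mm.
#' @return list with `table` (long data.frame: waist, filter, metric, value,
#'   lift, unstable), `ratios` (data.frame waist x metric of ADF/NLM lift
#'   ratios), `crossovers` (named list per metric of crossover radii), and
#'   `params` (provenance).
#' @export
waist_sweep <- function(arrangement_id = "s4", waists = c(5, 10, 14, 17, 20),
                        adf_par = adf_params(), nlm_par = nlm_params(),
                        seed = 1L, photons = 1e5,
                        grid = acoustic_grid_spec(), array = sensor_array(),
                        rspec = recon_spec(), unstable_below = 8) {
  if (length(waists) < 1) stop("empty waist list")
  stopifnot(all(waists >= 1 & waists <= 20))
  model <- build_arrangement(arrangement_id)
  labels <- rasterize(model, grid_shape = grid$shape, pitch = grid$pitch)
  ga <- ideal_image(model, rspec)
  mcmedia <- media_mc()
  rows <- list(); ratios <- list()
  metrics_names <- c("psnr", "ssim", "mse", "nae")

  for (i in seq_along(waists)) {
    w <- waists[i]
    beam <- beam_spec(waist_radius = w, photon_count = photons,
                      seed = as.integer(seed + i))
    flu <- mc_fluence(labels, mcmedia, beam)
    A <- absorption_map(flu, labels, mcmedia)
    p0 <- field_map(A$values, pitch = A$pitch, quantity = "initial_pressure")
    sd <- forward_simulate(p0, labels, grid = grid, array = array)
    sd <- lowpass(sd, rspec$lowpass_cutoff)
    go <- das_reconstruct(sd, rspec)
    gf_adf <- adf(go, adf_par)
    gf_nlm <- nlm(go, nlm_par)
    rep_adf <- metric_report(ga, go, gf_adf)
    rep_nlm <- metric_report(ga, go, gf_nlm)
    for (m in metrics_names) {
      rows[[length(rows) + 1]] <- data.frame(
        waist = w,
        filter = c("adf", "nlm"),
        metric = m,
        value = c(rep_adf$filtered[[m]], rep_nlm$filtered[[m]]),
        baseline = rep_adf$baseline[[m]],
        lift = c(rep_adf$lift_ratios[[m]], rep_nlm$lift_ratios[[m]]),
        unstable = w < unstable_below)
    }
    ratios[[i]] <- vapply(metrics_names, function(m)
      rep_adf$lift_ratios[[m]] / rep_nlm$lift_ratios[[m]], numeric(1))
  }
  tab <- do.call(rbind, rows)
  rat <- as.data.frame(do.call(rbind, ratios))
  rat <- cbind(waist = waists, rat)
  stable <- !(waists < unstable_below)
  crossings <- lapply(metrics_names, function(m) {
    if (sum(stable) >= 2)
      detect_crossover(waists[stable], rat[[m]][stable])
    else numeric(0)
  })
  names(crossings) <- metrics_names
  list(table = tab, ratios = rat, crossovers = crossings,
       params = list(arrangement_id = arrangement_id, seed = seed,
                     photons = photons, adf = adf_par, nlm = nlm_par,
                     unstable_below = unstable_below,
                     smooth_window = 3, mc_mode = "2d"))
}
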