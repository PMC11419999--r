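#' Reconstruction specification
#'
#' Defaults are the desk-scale grid (300 x 300 at 0.4 mm); the full-scale
#' study grid (1200 x 1200 at 0.1 mm) is available by configuration. The
#' reconstruction sound speeds follow the delay model of the study: 1429 m/s
#' in water-like media and 430 m/s in air; the default `"uniform"` mode uses
#' straight rays at the water speed, the `"two_speed"` mode splits each
#' straight ray's travel time between air and non-air pixels.
#'
#' @param grid_shape integer pair (rows, cols).
#' @param pitch pixel size, mm.
#' @param sound_speed_water reconstruction speed in water, m/s.
#' @param sound_speed_air reconstruction speed in air, m/s.
#' @param lowpass_cutoff low-pass cutoff applied before beamforming, Hz.
#' @param speed_mode `"uniform"` or `"two_speed"`.
#' @return A `recon_spec`.
#' @export
recon_spec <- function(grid_shape = c(300, 300), pitch = 0.4,
                       sound_speed_water = 1429, sound_speed_air = 430,
                       lowpass_cutoff = 750e3,
                       speed_mode = c("uniform", "two_speed")) {
  stopifnot(pitch > 0, sound_speed_water > 0, sound_speed_air > 0,
            lowpass_cutoff > 0)
  structure(list(grid_shape = as.integer(grid_shape), pitch = pitch,
                 sound_speed_water = sound_speed_water,
                 sound_speed_air = sound_speed_air,
                 lowpass_cutoff = lowpass_cutoff,
                 speed_mode = match.arg(speed_mode)),
            class = "recon_spec")
}

#' Zero-phase low-pass filtering of sensor traces
#'
#' Forward-backward (zero-phase) Butterworth filtering, order 4 per pass,
#' applied trace by trace. Zero phase preserves the arrival times that
#' delay-and-sum depends on.
#'
#' @param traces a `sensor_data`.
#' @param cutoff cutoff frequency, Hz; must lie in (0, Nyquist).
#' @return The filtered `sensor_data`.
#' @export
lowpass <- function(traces, cutoff = 750e3) {
  stopifnot(inherits(traces, "sensor_data"))
  nyq <- 1 / (2 * traces$dt)
  if (cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, Nyquist = %.3g Hz)", nyq))
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  out <- t(apply(traces$traces, 1, function(tr)
    signal::filtfilt(bf, tr)))
  traces$traces <- out
  traces
}

#' Delay-and-sum image reconstruction
#'
#' For every image pixel the element traces are sampled at the straight-ray
#' time of flight from pixel to element and summed:
#' image(x) = sum_e trace_e(|x - x_e| / c). Delays beyond the recorded window
#' contribute zero (and are counted; a warning is raised if more than 10% of
#' pixel-element pairs fall outside). The summed image is signed; the default
#' normalization clips negative swings and scales the result onto `[0, 1]`.
#'
#' In `"two_speed"` mode the travel time of each ray is split between air
#' and non-air media: the straight ray is sampled at half-pixel steps on the
#' supplied label map and the air fraction of its length travels at the air
#' reconstruction speed. This is markedly slower and intended for small
#' grids.
#'
#' @param traces a (low-passed) `sensor_data`.
#' @param spec a [recon_spec()].
#' @param labels optional label `field_map` (required for
#'   `speed_mode = "two_speed"`).
#' @param normalize `"clip"` (default: negative swings zeroed, so a
#'   signal-free background maps to 0 as in the normalized study figures),
#'   `"minmax"`, or `"none"` (signed output).
#' @return An image `field_map` with attribute `"out_of_window"` (fraction of
#'   pixel-element delays beyond the recording).
#' @export
das_reconstruct <- function(traces, spec = recon_spec(), labels = NULL,
                            normalize = "clip") {
  stopifnot(inherits(traces, "sensor_data"), inherits(spec, "recon_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * spec$pitch
  y <- ((nr + 1) / 2 - seq_len(nr)) * spec$pitch
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  tr <- traces$traces
  nt <- ncol(tr)
  pos <- traces$array$element_positions
  img <- matrix(0, nr, nc)
  oow <- 0

  two_speed <- spec$speed_mode == "two_speed"
  if (two_speed && is.null(labels))
    stop("two_speed mode needs the label map")
  if (two_speed) {
    lev <- labels$levels
    air_code <- match("air", lev)
    lab <- labels$values
    lnr <- nrow(lab); lnc <- ncol(lab); lp <- labels$pitch
  }

  for (e in seq_len(nrow(pos))) {
    d_mm <- sqrt((X - pos[e, 1])^2 + (Y - pos[e, 2])^2)
    if (!two_speed) {
      tt <- d_mm * 1e-3 / spec$sound_speed_water
    } else {
      # air path length along the straight ray, sampled at half-pixel steps
      nstep <- 2 * ceiling(max(d_mm) / lp)
      frac_air <- matrix(0, nr, nc)
      for (s in seq_len(nstep)) {
        f <- (s - 0.5) / nstep
        sx <- pos[e, 1] + f * (X - pos[e, 1])
        sy <- pos[e, 2] + f * (Y - pos[e, 2])
        ci <- pmin(pmax(round(sx / lp + (lnc + 1) / 2), 1), lnc)
        ri <- pmin(pmax(round((lnr + 1) / 2 - sy / lp), 1), lnr)
        frac_air <- frac_air + (lab[cbind(c(ri), c(ci))] == air_code)
      }
      frac_air <- frac_air / nstep
      tt <- d_mm * 1e-3 * (frac_air / spec$sound_speed_air +
                           (1 - frac_air) / spec$sound_speed_water)
    }
    si <- tt / traces$dt + 1          # fractional sample index, t = 0 -> 1
    i0 <- floor(si)
    fr <- si - i0
    ok <- i0 >= 1 & i0 < nt
    oow <- oow + sum(!ok)
    v <- numeric(length(si))
    tre <- tr[e, ]
    v[ok] <- tre[i0[ok]] * (1 - fr[ok]) + tre[i0[ok] + 1] * fr[ok]
    img <- img + matrix(v, nr, nc)
  }
  frac_oow <- oow / (length(img) * nrow(pos))
  if (frac_oow > 0.10)
    warning(sprintf("%.1f%% of pixel-element delays fall outside the recorded window",
                    100 * frac_oow))
  out <- field_map(img, pitch = spec$pitch, quantity = "image")
  if (normalize %in% c("minmax", "clip")) out <- normalize_field(out, normalize)
  attr(out, "out_of_window") <- frac_oow
  attr(out, "speed_mode") <- spec$speed_mode
  out
}
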