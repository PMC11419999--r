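#' Grid-design formulas for heterogeneous acoustic simulation
#'
#' The slow sound speed in air dominates the design of a cavity-structure
#' simulation: the highest frequency a grid supports, the spatial step needed
#' for a target frequency, and the depth covered by a recording window all
#' scale with the sound speed of the limiting medium.
#'
#' * `max_supported_frequency(c, pitch)` = c / (2 * pitch), from the maximum
#'   resolvable wavenumber k_max = pi / dx.
#' * `max_spatial_step(c, f_max)` = c / (2 * f_max), the largest grid spacing
#'   that still resolves `f_max`.
#' * `max_depth(n_samples, c, f_max)` = n_samples * c / f_max, the depth to
#'   which wave phenomena are captured by a recording of `n_samples` points
#'   sampled to support `f_max`.
#'
#' @param c sound speed, m/s (> 0).
#' @param pitch grid spacing, m (> 0).
#' @param f_max maximum supported frequency, Hz (> 0).
#' @param n_samples number of recorded samples (>= 1).
#' @return frequency in Hz, step in m, or depth in m respectively.
#' @export
max_supported_frequency <- function(c, pitch) {
  stopifnot(is.numeric(c), c > 0, is.numeric(pitch), pitch > 0)
  c / (2 * pitch)
}

#' @rdname max_supported_frequency
#' @export
max_spatial_step <- function(c, f_max) {
  stopifnot(is.numeric(c), c > 0, is.numeric(f_max), f_max > 0)
  c / (2 * f_max)
}

#' @rdname max_supported_frequency
#' @export
max_depth <- function(n_samples, c, f_max) {
  stopifnot(is.numeric(n_samples), n_samples >= 1,
            is.numeric(c), c > 0, is.numeric(f_max), f_max > 0)
  n_samples * c / f_max
}

#' Acoustic propagation grid specification
#'
#' Defaults follow the study conditions: a 121 x 121 grid at 1 mm pitch,
#' 4096 samples at 12.5 ns temporal resolution, with a 10-pixel perfectly
#' matched layer outside the physical grid. Construction checks a CFL-type
#' stability bound for the fastest medium.
#'
#' @param shape integer pair (rows, cols) of the physical grid.
#' @param pitch grid spacing, mm.
#' @param dt time step, s.
#' @param n_samples recorded samples per sensor element.
#' @param pml_width absorbing layer width, pixels.
#' @param c_max fastest sound speed present, m/s (stability check).
#' @param cfl_limit maximum allowed Courant number c_max * dt / pitch.
#' @return An `acoustic_grid_spec`.
#' @export
acoustic_grid_spec <- function(shape = c(121, 121), pitch = 1, dt = 12.5e-9,
                               n_samples = 4096, pml_width = 10,
                               c_max = 1500, cfl_limit = 0.5) {
  stopifnot(pitch > 0, dt > 0, n_samples >= 1, pml_width >= 0)
  cfl <- c_max * dt / (pitch * 1e-3)
  if (cfl > cfl_limit)
    stop(sprintf("stability bound violated: CFL = %.3f exceeds %.3f (reduce dt below %.3g s)",
                 cfl, cfl_limit, cfl_limit * pitch * 1e-3 / c_max))
  structure(list(shape = as.integer(shape), pitch = pitch, dt = dt,
                 n_samples = as.integer(n_samples),
                 pml_width = as.integer(pml_width), cfl = cfl),
            class = "acoustic_grid_spec")
}

#' Half-ring sensor array
#'
#' 128 elements evenly distributed along a half ring of radius 55 mm,
#' by default arched over the phantom (positive y). Element angles are the
#' midpoints of equal arcs so the elements are evenly spaced.
#'
#' @param n_elements number of elements.
#' @param ring_radius ring radius, mm.
#' @param arc angular coverage, degrees (180 = half ring).
#' @param center arc centre, mm.
#' @param rotation rotation of the whole arc, degrees (0 puts the arc
#'   symmetric about +y).
#' @return A `sensor_array` with an `element_positions` matrix (mm).
#' @export
sensor_array <- function(n_elements = 128, ring_radius = 55, arc = 180,
                         center = c(0, 0), rotation = 0) {
  stopifnot(n_elements >= 1, ring_radius > 0, arc > 0, arc <= 360)
  th <- (seq_len(n_elements) - 0.5) / n_elements * arc
  th <- (90 - arc / 2 + th + rotation) * pi / 180
  pos <- cbind(x = center[1] + ring_radius * cos(th),
               y = center[2] + ring_radius * sin(th))
  structure(list(n_elements = as.integer(n_elements),
                 ring_radius = ring_radius, arc = arc, center = center,
                 element_positions = pos),
            class = "sensor_array")
}

#' Sensor data container
#'
#' @param traces matrix n_elements x n_samples of dimensionless pressure;
#'   the first sample is at t = 0.
#' @param dt sampling interval, s.
#' @param array the `sensor_array` that recorded the traces.
#' @param grid the `acoustic_grid_spec` used (optional provenance).
#' @return A `sensor_data` object.
#' @export
sensor_data <- function(traces, dt, array, grid = NULL) {
  stopifnot(is.matrix(traces), all(is.finite(traces)), dt > 0,
            inherits(array, "sensor_array"),
            nrow(traces) == array$n_elements)
  structure(list(traces = traces, dt = dt, array = array, grid = grid),
            class = "sensor_data")
}

#' @export
print.sensor_data <- function(x, ...) {
  cat(sprintf("<sensor_data: %d elements x %d samples, dt = %.3g ns>\n",
              nrow(x$traces), ncol(x$traces), x$dt * 1e9))
  invisible(x)
}

# bilinear interpolation indices/weights for positions (mm) on an
# nr x nc grid with given pitch, origin at grid centre. Returns 4 x n linear
# (column-major) indices and weights.
bilinear_weights <- function(pos, nr, nc, pitch) {
  cx <- pos[, 1] / pitch + (nc + 1) / 2   # fractional column
  ry <- (nr + 1) / 2 - pos[, 2] / pitch   # fractional row
  if (any(cx < 1 | cx > nc | ry < 1 | ry > nr))
    stop("sensor element outside the computational grid")
  c0 <- pmin(floor(cx), nc - 1); r0 <- pmin(floor(ry), nr - 1)
  fx <- cx - c0; fy <- ry - r0
  idx <- rbind(r0 + (c0 - 1) * nr,
               r0 + 1 + (c0 - 1) * nr,
               r0 + c0 * nr,
               r0 + 1 + c0 * nr)
  w <- rbind((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  list(idx = idx, w = w)
}

# expand the physical grid by the PML and pad to an FFT-friendly size;
# returns padded c/rho/p0 matrices and the offset of the physical grid
pad_acoustic_maps <- function(p0m, cm, rhom, pml_width) {
  nr <- nrow(p0m); nc <- ncol(p0m)
  NR <- good_fft_size(nr + 2 * pml_width)
  NC <- good_fft_size(nc + 2 * pml_width)
  ro <- floor((NR - nr) / 2); co <- floor((NC - nc) / 2)
  pad <- function(m, fill_edge) {
    out <- matrix(0, NR, NC)
    out[ro + seq_len(nr), co + seq_len(nc)] <- m
    if (fill_edge) {
      if (ro > 0) out[seq_len(ro), ] <- matrix(out[ro + 1, ], ro, NC, byrow = TRUE)
      nb <- NR - ro - nr
      if (nb > 0) out[ro + nr + seq_len(nb), ] <- matrix(out[ro + nr, ], nb, NC, byrow = TRUE)
      if (co > 0) out[, seq_len(co)] <- out[, co + 1]
      nrgt <- NC - co - nc
      if (nrgt > 0) out[, co + nc + seq_len(nrgt)] <- out[, co + nc]
    }
    out
  }
  list(p0 = pad(p0m, FALSE), c = pad(cm, TRUE), rho = pad(rhom, TRUE),
       row_off = ro, col_off = co, NR = NR, NC = NC)
}

# k-Wave style PML absorption profile (1/s) along one axis of length n,
# nonzero over the `width` points at each end, quartic ramp
pml_profile <- function(n, width, pitch_m, c_ref, alpha = 2) {
  sig <- numeric(n)
  if (width > 0) {
    ramp <- alpha * c_ref / pitch_m * ((seq_len(width)) / width)^4
    sig[width:1] <- ramp               # left edge, growing outward
    sig[(n - width + 1):n] <- ramp
  }
  sig
}

# Blackman smoothing of the initial pressure in k-space (suppresses the
# ringing a sharp source excites in a spectral solver)
smooth_source <- function(p0m) {
  nr <- nrow(p0m); nc <- ncol(p0m)
  bl <- function(n) {
    k <- seq(0, n - 1)
    w <- 0.42 - 0.5 * cos(2 * pi * k / n) + 0.08 * cos(4 * pi * k / n)
    # centre the window on wavenumber 0 (fftshifted)
    w[(c(seq(ceiling(n / 2) + 1, n), seq_len(ceiling(n / 2))))]
  }
  W <- outer(bl(nr), bl(nc))
  Re(fft(fft(p0m) * W, inverse = TRUE)) / (nr * nc)
}

#' Forward acoustic simulation (k-space pseudospectral)
#'
#' Propagates an initial pressure distribution through the acoustically
#' heterogeneous medium defined by the label map (air: 340 m/s, 1.2 kg/m^3;
#' all other media: 1500 m/s, 1000 kg/m^3) and records pressure time series
#' at the sensor elements by bilinear interpolation. The solver integrates
#' the first-order linear acoustic equations with FFT-based spatial
#' derivatives on staggered grids, the exact k-space correction for the
#' reference sound speed, and a split-field perfectly matched layer outside
#' the physical grid. Acoustic attenuation is not modelled.
#'
#' @param p0 initial-pressure `field_map` on the propagation grid.
#' @param labels label `field_map` on the same grid.
#' @param media media table (see [media_uniform()]); only `sound_speed` and
#'   `density` are used.
#' @param grid an `acoustic_grid_spec`.
#' @param array a `sensor_array`.
#' @param smooth_p0 apply Blackman source smoothing (default TRUE).
#' @param pml_alpha PML absorption strength (0 disables the PML; the FFT grid
#'   is then effectively periodic).
#' @param record_energy also return the total acoustic energy at each step
#'   (used for conservation checks).
#' @return A `sensor_data`; if `record_energy`, the energy trace is attached
#'   as attribute `"energy"`.
#' @export
forward_simulate <- function(p0, labels, media = media_uniform(),
                             grid = acoustic_grid_spec(), array = sensor_array(),
                             smooth_p0 = TRUE, pml_alpha = 2,
                             record_energy = FALSE) {
  stopifnot(inherits(p0, "field_map"), inherits(labels, "field_map"),
            identical(dim(p0$values), dim(labels$values)),
            identical(dim(p0$values), as.integer(grid$shape)))
  lev <- labels$levels
  cm <- matrix(media_lookup(media, lev[labels$values], "sound_speed"),
               nrow(labels$values))
  rhom <- matrix(media_lookup(media, lev[labels$values], "density"),
                 nrow(labels$values))
  cfl <- max(cm) * grid$dt / (grid$pitch * 1e-3)
  if (cfl > 0.5)
    stop(sprintf("stability bound violated: CFL = %.3f > 0.5", cfl))

  p0m <- p0$values
  if (smooth_p0) p0m <- smooth_source(p0m)
  pads <- pad_acoustic_maps(p0m, cm, rhom, grid$pml_width)
  pitch_m <- grid$pitch * 1e-3
  c_ref <- max(cm)
  sx <- pml_profile(pads$NC, grid$pml_width, pitch_m, c_ref, pml_alpha)
  sy <- pml_profile(pads$NR, grid$pml_width, pitch_m, c_ref, pml_alpha)
  if (grid$pml_width > 0 && pml_alpha > 0) {
    # the PML occupies the padding outside the physical grid; sources on the
    # outermost physical pixels radiate straight into it
    nr <- grid$shape[1]; nc <- grid$shape[2]
    edge <- abs(p0$values)
    edge[2:(nr - 1), 2:(nc - 1)] <- 0
    if (any(edge > 1e-9 * max(abs(p0$values))))
      warning("nonzero initial pressure at the PML boundary")
  }
  # sensor positions relative to the padded grid centre
  shift_x <- (pads$col_off + (grid$shape[2] + 1) / 2) - (pads$NC + 1) / 2
  shift_y <- -((pads$row_off + (grid$shape[1] + 1) / 2) - (pads$NR + 1) / 2)
  pos <- sweep(array$element_positions, 2,
               c(-shift_x * grid$pitch, -shift_y * grid$pitch))
  bw <- bilinear_weights(pos, pads$NR, pads$NC, grid$pitch)

  out <- kspace_forward_cpp(pads$p0, pads$c, pads$rho, pitch_m, grid$dt,
                            grid$n_samples, bw$idx, bw$w, sy, sx, c_ref,
                            record_energy)
  sd <- sensor_data(out$traces, grid$dt, array, grid)
  if (record_energy) attr(sd, "energy") <- as.numeric(out$energy)
  sd
}

#' Forward acoustic simulation (staggered-grid FDTD reference)
#'
#' An independent second-order finite-difference time-domain integration of
#' the same first-order acoustic system, used to cross-validate the spectral
#' solver on small grids. Pure R; intended for fixtures of order 64 x 64.
#'
#' @inheritParams forward_simulate
#' @return A `sensor_data`.
#' @export
fdtd_simulate <- function(p0, labels, media = media_uniform(),
                          grid = acoustic_grid_spec(), array = sensor_array(),
                          smooth_p0 = TRUE, pml_alpha = 2) {
  stopifnot(identical(dim(p0$values), dim(labels$values)))
  lev <- labels$levels
  cm <- matrix(media_lookup(media, lev[labels$values], "sound_speed"),
               nrow(labels$values))
  rhom <- matrix(media_lookup(media, lev[labels$values], "density"),
                 nrow(labels$values))
  pitch_m <- grid$pitch * 1e-3
  cfl <- max(cm) * grid$dt / pitch_m
  if (cfl > 1 / sqrt(2))
    stop(sprintf("FDTD stability bound violated: CFL = %.3f > %.3f",
                 cfl, 1 / sqrt(2)))
  p0m <- p0$values
  if (smooth_p0) p0m <- smooth_source(p0m)
  pads <- pad_acoustic_maps(p0m, cm, rhom, grid$pml_width)
  NR <- pads$NR; NC <- pads$NC
  c_ref <- max(cm)
  sx <- pml_profile(NC, grid$pml_width, pitch_m, c_ref, pml_alpha)
  sy <- pml_profile(NR, grid$pml_width, pitch_m, c_ref, pml_alpha)
  ax <- matrix(exp(-sx * grid$dt / 2), NR, NC, byrow = TRUE)
  ay <- matrix(exp(-sy * grid$dt / 2), NR, NC)

  shift_x <- (pads$col_off + (grid$shape[2] + 1) / 2) - (NC + 1) / 2
  shift_y <- -((pads$row_off + (grid$shape[1] + 1) / 2) - (NR + 1) / 2)
  pos <- sweep(array$element_positions, 2,
               c(-shift_x * grid$pitch, -shift_y * grid$pitch))
  bw <- bilinear_weights(pos, NR, NC, grid$pitch)

  rho <- pads$rho; c2 <- pads$c^2
  # staggered densities: ux lives at (i, j+1/2), uy at (i+1/2, j) going down
  rho_sgx <- (rho + cbind(rho[, -1], rho[, NC])) / 2
  rho_sgy <- (rho + rbind(rho[-1, ], rho[NR, ])) / 2
  rhox <- pads$p0 / (2 * c2); rhoy <- rhox
  p <- pads$p0
  ux <- matrix(0, NR, NC); uy <- matrix(0, NR, NC)
  dt <- grid$dt; nt <- grid$n_samples
  traces <- matrix(0, nrow(pos), nt)
  traces[, 1] <- colSums(matrix(p[bw$idx], 4) * bw$w)
  for (t in seq_len(nt - 1)) {
    dte <- if (t == 1) dt / 2 else dt
    dpdx <- (cbind(p[, -1], p[, NC]) - p) / pitch_m     # at (i, j+1/2)
    dpdy <- (rbind(p[-1, ], p[NR, ]) - p) / pitch_m     # at (i+1/2, j)
    ux <- ax * (ax * ux - dte / rho_sgx * dpdx)
    uy <- ay * (ay * uy - dte / rho_sgy * dpdy)
    duxdx <- (ux - cbind(ux[, 1], ux[, -NC])) / pitch_m
    duydy <- (uy - rbind(uy[1, ], uy[-NR, ])) / pitch_m
    rhox <- ax * (ax * rhox - dt * rho * duxdx)
    rhoy <- ay * (ay * rhoy - dt * rho * duydy)
    p <- c2 * (rhox + rhoy)
    traces[, t + 1] <- colSums(matrix(p[bw$idx], 4) * bw$w)
  }
  sensor_data(traces, dt, array, grid)
}
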