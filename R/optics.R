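#' Gaussian beam / source specification
#'
#' The illumination is delivered from `n_directions` collimated line sources
#' evenly fanned `angular_spacing` degrees apart, aimed at the phantom centre
#' from a stand-off radius. Each beam has the Gaussian intensity profile
#' exp(-2 r^2 / w^2) with waist radius `w`: transverse launch offsets are
#' sampled with standard deviation w / 2 per axis. The waist radius is the
#' study's proxy for light-source uniformity (1 mm = focused, 20 mm = near
#' uniform over the tube region).
#'
#' @param waist_radius Gaussian waist radius, mm (in `[1, 20]` in the study).
#' @param n_directions number of source directions.
#' @param angular_spacing fan spacing between adjacent sources, degrees.
#' @param source_length emitting line length, mm (offsets uniform along the
#'   tube axis in 3-D).
#' @param beam_width emitting aperture width, mm (recorded, the Gaussian
#'   profile dominates the launch distribution).
#' @param photon_count photon packets to launch (>= 1).
#' @param seed RNG seed recorded with every output.
#' @param standoff distance of the source centres from the phantom centre, mm.
#' @return A `beam_spec`.
#' @export
beam_spec <- function(waist_radius, n_directions = 5, angular_spacing = 39,
                      source_length = 10, beam_width = 1,
                      photon_count = 1e6, seed = 1L, standoff = 58) {
  stopifnot(is.numeric(waist_radius), waist_radius > 0,
            n_directions >= 1, angular_spacing > 0, photon_count >= 1)
  structure(list(waist_radius = waist_radius, n_directions = n_directions,
                 angular_spacing = angular_spacing,
                 source_length = source_length, beam_width = beam_width,
                 photon_count = as.double(photon_count),
                 seed = as.integer(seed), standoff = standoff),
            class = "beam_spec")
}

#' Sample photon launch positions and directions for a beam
#'
#' Source centres sit on a circle of radius `standoff` in the imaging plane at
#' angles 90 +/- k * angular_spacing degrees (fanned about the vertical, the
#' illuminated side), each aimed at the origin. Photons pick a source
#' uniformly; transverse offsets are Gaussian with sd = waist_radius / 2
#' (the exp(-2 r^2 / w^2) intensity profile), plus, in 3-D, a uniform offset
#' along the source line (the tube axis, z).
#'
#' @param beam a `beam_spec`.
#' @param n number of photons to sample.
#' @param dim 2 (in-plane transport) or 3.
#' @return list of matrices `pos` and `dir` (n x 3, mm / unit vectors).
#' @export
mc_launch <- function(beam, n, dim = 3) {
  stopifnot(dim %in% c(2, 3))
  k <- seq_len(beam$n_directions) - (beam$n_directions + 1) / 2
  th <- (90 + k * beam$angular_spacing) * pi / 180
  centers <- cbind(beam$standoff * cos(th), beam$standoff * sin(th))
  axes <- -cbind(cos(th), sin(th))            # aimed at the origin
  pick <- sample.int(beam$n_directions, n, replace = TRUE)
  sdw <- beam$waist_radius / 2
  g1 <- rnorm(n, sd = sdw)                    # in-plane transverse offset
  perp <- cbind(-axes[pick, 2], axes[pick, 1])
  pos <- centers[pick, , drop = FALSE] + perp * g1
  if (dim == 3) {
    z <- rnorm(n, sd = sdw) + runif(n, -beam$source_length / 2,
                                    beam$source_length / 2)
    pos <- cbind(pos, z)
    dir <- cbind(axes[pick, , drop = FALSE], 0)
  } else {
    pos <- cbind(pos, 0)
    dir <- cbind(axes[pick, , drop = FALSE], 0)
  }
  list(pos = pos, dir = dir)
}

#' Monte Carlo fluence in a voxelized phantom
#'
#' Transports photon packets through the labelled volume using the optical
#' properties in `media` (absorption and scattering in 1/cm, converted to
#' 1/mm internally, Henyey-Greenstein anisotropy `g`, refractive index `n`).
#' Free paths are sampled against the scattering coefficient with continuous
#' exponential absorption along every segment; Fresnel reflection/refraction
#' is applied at voxel faces where the refractive index changes; packets are
#' terminated by Russian roulette. Fluence is the track-length estimator per
#' voxel, normalized per launched photon and unit voxel volume. Media with
#' zero interaction coefficients are traversed ballistically.
#'
#' A 2-D label map runs the fast in-plane mode (used by the waist sweep):
#' scattering is confined to the imaging plane with the 2-D
#' Henyey-Greenstein phase function.
#'
#' @param labels 2-D or 3-D label `field_map` (see [voxelize()]).
#' @param media optical property table, typically [media_mc()].
#' @param beam a `beam_spec`; `beam$seed` seeds the run, `beam$photon_count`
#'   sets the packet count.
#' @param w_min roulette weight threshold.
#' @param roulette_m roulette survival multiplier.
#' @return A fluence `field_map` with attributes `totals` (launched /
#'   absorbed / exited / roulette_balance weight ledger), `seed`, `photons`
#'   and `mode` ("2d" or "3d").
#' @export
mc_fluence <- function(labels, media = media_mc(), beam,
                       w_min = 1e-4, roulette_m = 10) {
  stopifnot(inherits(labels, "field_map"), labels$quantity == "labels",
            inherits(beam, "beam_spec"))
  if (beam$photon_count < 1) stop("photon_count must be >= 1")
  dims <- dim(labels$values)
  dim_mode <- if (length(dims) == 2L || dims[3] == 1L) 2 else 3
  lev <- labels$levels
  mu_a <- media_lookup(media, lev, "mu_a") / 10  # 1/cm -> 1/mm
  mu_s <- media_lookup(media, lev, "mu_s") / 10
  gg <- media_lookup(media, lev, "g")
  nn <- media_lookup(media, lev, "n")

  if (!is.null(beam$seed)) set.seed(beam$seed)
  n <- as.integer(beam$photon_count)
  launch <- mc_launch(beam, n, dim = dim_mode)
  lab <- labels$values
  if (length(dims) == 2L) dim(lab) <- c(dims, 1L)
  # array axis 1 runs down the matrix rows (-y), axis 2 along columns (+x)
  pos <- cbind(-launch$pos[, 2], launch$pos[, 1], launch$pos[, 3])
  dir <- cbind(-launch$dir[, 2], launch$dir[, 1], launch$dir[, 3])
  res <- mc_transport_cpp(lab, dim(lab), labels$pitch, mu_a, mu_s, gg, nn,
                          pos, dir, w_min, as.integer(roulette_m))
  flu <- array(res$fluence, dim = dim(lab)) /
    (n * labels$pitch^dim_mode)
  if (length(dims) == 2L) dim(flu) <- dims
  out <- field_map(flu, pitch = labels$pitch, quantity = "fluence",
                   origin = labels$origin[1:2])
  attr(out, "totals") <- list(launched = res$launched,
                              absorbed = res$absorbed,
                              exited = res$exited,
                              roulette_balance = res$roulette_balance)
  attr(out, "absorbed_map") <- array(res$absorbed_map, dim = dim(lab)) /
    (n * labels$pitch^dim_mode)
  attr(out, "seed") <- beam$seed
  attr(out, "photons") <- n
  attr(out, "mode") <- if (dim_mode == 2) "2d" else "3d"
  out
}

#' Initial pressure under uniform illumination
#'
#' Applies the photoacoustic relation P0 = gamma * eta * mu_a * F pointwise
#' with a spatially constant fluence. With the default unit constants and
#' unit fluence, P0 numerically equals the absorption coefficient map.
#'
#' @param labels label `field_map`.
#' @param media media table supplying `mu_a` (1/cm), typically
#'   [media_uniform()].
#' @param constants a [pa_constants()].
#' @param fluence_value the constant fluence (dimensionless).
#' @return An initial-pressure `field_map`.
#' @export
uniform_initial_pressure <- function(labels, media = media_uniform(),
                                     constants = pa_constants(),
                                     fluence_value = 1) {
  stopifnot(inherits(labels, "field_map"), labels$quantity == "labels")
  lev <- labels$levels
  mu_a <- media_lookup(media, lev, "mu_a")
  p0 <- constants$gamma * constants$eta * fluence_value *
    array(mu_a[labels$values], dim = dim(labels$values))
  field_map(p0, pitch = labels$pitch, quantity = "initial_pressure",
            origin = labels$origin)
}

#' Optical absorption from a fluence map
#'
#' A = mu_a(label) * F per voxel (the local form of the photoacoustic
#' relation with unit conversion efficiencies).
#'
#' @param fluence fluence `field_map`.
#' @param labels label `field_map` on the same grid.
#' @param media media table supplying `mu_a`.
#' @return An absorption `field_map`.
#' @export
absorption_map <- function(fluence, labels, media = media_mc()) {
  stopifnot(inherits(fluence, "field_map"), inherits(labels, "field_map"))
  if (!identical(dim(fluence$values), dim(labels$values)))
    stop("fluence and label grids do not match")
  mu_a <- media_lookup(media, labels$levels, "mu_a")
  A <- array(mu_a[labels$values], dim = dim(labels$values)) * fluence$values
  field_map(A, pitch = fluence$pitch, quantity = "absorption",
            origin = fluence$origin)
}

#' Central imaging-plane slice of a 3-D field
#'
#' Tubes are extruded along z, so the central slice through the tube axes is
#' the representative 2-D section handed to the acoustic stage.
#'
#' @param fm 3-D `field_map`.
#' @return 2-D `field_map` (the middle z slice).
#' @export
project_slice <- function(fm) {
  d <- dim(fm$values)
  if (length(d) == 2L) return(fm)
  mid <- ceiling(d[3] / 2)
  field_map(fm$values[, , mid], pitch = fm$pitch, quantity = fm$quantity,
            origin = fm$origin[1:2], levels = fm$levels)
}
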