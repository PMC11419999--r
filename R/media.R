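#' Media property tables for the cavity-structure phantom
#'
#' Five media occur in the phantoms: the agarose `substrate`, `blood`, `air`
#' and `water` tube fillings, and the surrounding `background` (the water bath
#' / free space outside the substrate). Two optical configurations are
#' provided:
#'
#' * `media_uniform()` -- the uniform-illumination working point: absorption
#'   coefficients rounded for simulation (blood 3 cm^-1, everything else 0),
#'   used to derive initial pressure directly from the label map.
#' * `media_mc()` -- the full 800 nm optical property set used by the Monte
#'   Carlo photon transport (absorption, scattering, Henyey-Greenstein
#'   anisotropy, refractive index). The agarose substrate carries the
#'   background optics (near-transparent gel).
#'
#' Both tables carry the acoustic forward-simulation properties: air
#' propagates at 340 m/s with density 1.2 kg/m^3; water, blood and the
#' substrate all take the water values (1500 m/s, 1000 kg/m^3), as does the
#' surrounding bath.
#'
#' @return A data.frame with one row per medium and columns `name`, `mu_a`
#'   (1/cm), `mu_s` (1/cm), `g`, `n`, `sound_speed` (m/s), `density`
#'   (kg/m^3).
#' @export
media_uniform <- function() {
  m <- media_base()
  m$mu_a <- c(background = 0, substrate = 0, blood = 3, air = 0, water = 0)[m$name]
  m$mu_s <- 0
  m$g <- 0
  m$n <- 1
  m
}

#' @rdname media_uniform
#' @export
media_mc <- function() {
  m <- media_base()
  opt <- list( # mu_a, mu_s (1/cm), g, n at 800 nm
    background = c(0.0001, 0.1, 1.0, 1.0),
    substrate  = c(0.0001, 0.1, 1.0, 1.0),
    water      = c(0.06, 1, 0.99, 1.3),
    blood      = c(2.38, 522, 0.9, 1.4),
    air        = c(0.001, 347, 0.001, 1.0))
  for (i in seq_len(nrow(m))) {
    v <- opt[[m$name[i]]]
    m$mu_a[i] <- v[1]; m$mu_s[i] <- v[2]; m$g[i] <- v[3]; m$n[i] <- v[4]
  }
  m
}

media_base <- function() {
  data.frame(
    name = c("background", "substrate", "blood", "air", "water"),
    mu_a = NA_real_, mu_s = NA_real_, g = NA_real_, n = NA_real_,
    sound_speed = c(1500, 1500, 1500, 340, 1500),
    density = c(1000, 1000, 1000, 1.2, 1000),
    stringsAsFactors = FALSE)
}

#' Label codes used by rasterized phantoms
#' @return Character vector; integer label maps index into it.
#' @export
medium_levels <- function() c("background", "substrate", "blood", "air", "water")

# look up one property column by label name, erroring on missing media
media_lookup <- function(media, labels_chr, column) {
  idx <- match(labels_chr, media$name)
  if (anyNA(idx)) {
    missing <- unique(labels_chr[is.na(idx)])
    stop(sprintf("no %s entry for medium: %s", column,
                 paste(missing, collapse = ", ")))
  }
  media[[column]][idx]
}

#' Photoacoustic conversion constants
#'
#' The Grueneisen conversion efficiency `gamma` and heat transfer efficiency
#' `eta` entering the initial-pressure relation P0 = gamma * eta * mu_a * F.
#' Both default to 1, i.e. initial pressure numerically equals absorbed
#' energy density.
#'
#' @param gamma,eta dimensionless efficiencies (> 0).
#' @export
pa_constants <- function(gamma = 1, eta = 1) {
  stopifnot(is.numeric(gamma), gamma > 0, is.numeric(eta), eta > 0)
  structure(list(gamma = gamma, eta = eta), class = "pa_constants")
}
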