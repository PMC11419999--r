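#' Scalar field on a physical grid
#'
#' A `field_map` couples a 2-D matrix (or 3-D array) of values to its physical
#' geometry: grid spacing (`pitch`, mm) and the position of the grid centre
#' (`origin`, mm). Row 1 is the top of the image, x increases to the right and
#' y upward; the physical origin sits at the grid centre by default.
#'
#' @param values numeric matrix or 3-D array; for label maps an integer
#'   matrix/array of codes into `levels`.
#' @param pitch grid spacing in mm (> 0).
#' @param quantity one of `"labels"`, `"fluence"`, `"absorption"`,
#'   `"initial_pressure"`, `"image"`.
#' @param origin physical coordinates (mm) of the grid centre.
#' @param levels for label maps, the character vector the integer codes index.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, pitch, quantity = "image", origin = c(0, 0),
                      levels = NULL) {
  stopifnot(is.numeric(values) || is.integer(values),
            length(dim(values)) %in% c(2L, 3L))
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("`pitch` must be a single positive number (mm)")
  quantity <- match.arg(quantity,
                        c("labels", "fluence", "absorption",
                          "initial_pressure", "image"))
  if (quantity == "labels") {
    if (is.null(levels)) stop("label maps need `levels`")
    storage.mode(values) <- "integer"
  } else if (any(!is.finite(values))) {
    stop("field values must all be finite")
  }
  structure(list(values = values, pitch = pitch, origin = origin,
                 quantity = quantity, levels = levels),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_map: %s, %s px at %.3g mm pitch>\n",
              x$quantity, paste(d, collapse = "x"), x$pitch))
  invisible(x)
}

#' @export
dim.field_map <- function(x) dim(x$values)

#' Physical pixel-centre coordinates of a field map
#'
#' @param fm a `field_map` (2-D).
#' @return list with vectors `x` (per column) and `y` (per row), mm.
#' @export
grid_coords <- function(fm) {
  d <- dim(fm$values)
  nr <- d[1]; nc <- d[2]
  list(x = (seq_len(nc) - (nc + 1) / 2) * fm$pitch + fm$origin[1],
       y = ((nr + 1) / 2 - seq_len(nr)) * fm$pitch + fm$origin[2])
}

#' Rescale a field linearly onto the unit interval
#'
#' Two conventions are supported. `"minmax"` (default) maps the field minimum
#' to 0 and maximum to 1, keeping the bipolar structure of delay-and-sum
#' output visible. `"clip"` zeroes negative values first and divides by the
#' maximum, so a signal-free background stays at 0.
#'
#' @param fm a `field_map`.
#' @param mode `"minmax"` or `"clip"`.
#' @return the normalized `field_map`.
#' @export
normalize_field <- function(fm, mode = c("minmax", "clip")) {
  mode <- match.arg(mode)
  v <- fm$values
  if (mode == "clip") v[v < 0] <- 0
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  fm$values <- v
  fm
}

#' Write / read a field map as float TIFF with a JSON sidecar
#'
#' The TIFF stores raw 32-bit float values; the sidecar records pitch, origin,
#' quantity and any extra metadata so the geometry survives the round trip.
#'
#' @param fm a 2-D `field_map`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(fm, path, meta = list()) {
  stopifnot(inherits(fm, "field_map"), length(dim(fm$values)) == 2L)
  v <- fm$values
  storage.mode(v) <- "double"
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(pitch = fm$pitch, origin = fm$origin,
                 quantity = fm$quantity, levels = fm$levels), meta)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(side$quantity, "labels")) storage.mode(v) <- "integer"
  field_map(v, pitch = side$pitch, quantity = side$quantity,
            origin = side$origin, levels = side$levels)
}

# smallest 2^a * 3^b >= n (FFT-friendly size)
good_fft_size <- function(n) {
  m <- n
  repeat {
    k <- m
    while (k %% 2 == 0) k <- k / 2
    while (k %% 3 == 0) k <- k / 3
    if (k == 1) return(m)
    m <- m + 1
  }
}
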