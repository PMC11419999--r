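#' Build a cavity-structure phantom arrangement
#'
#' Constructs the tube layouts studied in the cavity-structure experiments:
#' a 5 cm square agarose substrate containing 1 mm diameter tubes of blood,
#' air or water, seen in cross-section (disks) in the imaging plane.
#'
#' Available arrangements:
#' * `s1`--`s3`: a single centred tube of air, blood, water (controls);
#' * `s4`--`s6`: three tubes in a horizontal row -- `s4` blood-air-water,
#'   `s5` air-blood-water, `s6` air-water-blood (left to right);
#' * `S1`--`S3`: 3 x 3 matrix of a single medium (air, blood, water);
#' * `S4`--`S6`: 3 x 3 Latin squares whose first rows match `s4`--`s6` and
#'   whose second and third rows are cyclic left shifts, so every medium
#'   appears exactly once per row and column.
#'
#' @param arrangement_id one of `"s1"`..`"s6"`, `"S1"`..`"S6"`.
#' @param tube_radius tube radius in mm (default 0.5, i.e. 1 mm diameter).
#' @param spacing centre-to-centre tube spacing in mm (must exceed one tube
#'   diameter); the paper does not state it, so it is a reported parameter.
#' @param substrate_side side length of the square substrate cross-section, mm.
#' @return A `phantom_model`: list with `arrangement_id`, `tube_radius`,
#'   `spacing`, `substrate` (xmin, xmax, ymin, ymax in mm) and `inclusions`
#'   (data.frame x, y, radius, medium).
#' @export
build_arrangement <- function(arrangement_id, tube_radius = 0.5, spacing = 10,
                              substrate_side = 50) {
  valid <- c(paste0("s", 1:6), paste0("S", 1:6))
  if (!is.character(arrangement_id) || length(arrangement_id) != 1L ||
      !(arrangement_id %in% valid))
    stop("unknown arrangement_id; valid labels are: ",
         paste(valid, collapse = ", "))
  stopifnot(tube_radius > 0, substrate_side > 0)
  if (spacing <= 2 * tube_radius)
    stop("`spacing` must exceed the tube diameter (2 * tube_radius)")

  singles <- c(s1 = "air", s2 = "blood", s3 = "water")
  rows3 <- list(s4 = c("blood", "air", "water"),
                s5 = c("air", "blood", "water"),
                s6 = c("air", "water", "blood"))
  xs <- c(-spacing, 0, spacing)

  inc <- if (arrangement_id %in% names(singles)) {
    data.frame(x = 0, y = 0, medium = singles[[arrangement_id]])
  } else if (arrangement_id %in% names(rows3)) {
    data.frame(x = xs, y = 0, medium = rows3[[arrangement_id]])
  } else if (arrangement_id %in% c("S1", "S2", "S3")) {
    med <- c(S1 = "air", S2 = "blood", S3 = "water")[[arrangement_id]]
    expand_grid_xy(xs, medium = rep(med, 9))
  } else { # Latin squares S4-S6: rows are cyclic left shifts of the first row
    first <- rows3[[tolower(arrangement_id)]]
    med <- unlist(lapply(0:2, function(s) first[(seq(0, 2) + s) %% 3 + 1]))
    expand_grid_xy(xs, medium = med)
  }
  inc$radius <- tube_radius
  inc <- inc[, c("x", "y", "radius", "medium")]
  rownames(inc) <- NULL

  model <- structure(list(arrangement_id = arrangement_id,
                          tube_radius = tube_radius, spacing = spacing,
                          substrate = c(xmin = -substrate_side / 2,
                                        xmax = substrate_side / 2,
                                        ymin = -substrate_side / 2,
                                        ymax = substrate_side / 2),
                          inclusions = inc),
                     class = "phantom_model")
  validate_phantom(model)
  model
}

# 3x3 grid positions row-major from the top row (y = +spacing) down
expand_grid_xy <- function(xs, medium) {
  data.frame(x = rep(xs, times = 3),
             y = rep(c(xs[3], 0, xs[1]), each = 3),
             medium = medium)
}

validate_phantom <- function(model) {
  inc <- model$inclusions
  s <- model$substrate
  inside <- inc$x - inc$radius >= s["xmin"] & inc$x + inc$radius <= s["xmax"] &
            inc$y - inc$radius >= s["ymin"] & inc$y + inc$radius <= s["ymax"]
  if (!all(inside)) stop("inclusion disks must lie inside the substrate")
  if (nrow(inc) > 1) {
    d <- as.matrix(stats::dist(inc[, c("x", "y")]))
    rr <- outer(inc$radius, inc$radius, "+")
    diag(d) <- Inf
    if (any(d <= rr)) stop("inclusions overlap")
  }
  invisible(model)
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model %s: %d inclusion(s), tube radius %.2f mm, spacing %.1f mm>\n",
              x$arrangement_id, nrow(x$inclusions), x$tube_radius, x$spacing))
  invisible(x)
}

#' Check the Latin-square balance of a matrix arrangement
#'
#' @param model a `phantom_model` with 9 inclusions on a 3 x 3 grid.
#' @return `TRUE` if each medium appears exactly once per row and column.
#' @export
is_latin_square <- function(model) {
  inc <- model$inclusions
  if (nrow(inc) != 9) return(FALSE)
  rows <- factor(-inc$y); cols <- factor(inc$x)
  if (nlevels(rows) != 3 || nlevels(cols) != 3) return(FALSE)
  m <- matrix(inc$medium[order(rows, cols)], 3, 3, byrow = TRUE)
  ok <- function(v) length(unique(v)) == 3
  all(apply(m, 1, ok)) && all(apply(m, 2, ok))
}

#' Rasterize a phantom onto a pixel grid
#'
#' Each pixel is labelled by the medium whose region contains the pixel
#' centre: inclusion disks take precedence over the substrate, pixels outside
#' the substrate rectangle are background. Membership is a strict
#' centre-in-disk test (no area weighting).
#'
#' @param model a `phantom_model`.
#' @param grid_shape integer pair (rows, cols).
#' @param pitch pixel spacing, mm.
#' @return A label `field_map` (integer codes into [medium_levels()]).
#' @export
rasterize <- function(model, grid_shape = c(121, 121), pitch = 1) {
  stopifnot(inherits(model, "phantom_model"), pitch > 0,
            length(grid_shape) == 2L, all(grid_shape >= 1))
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  x <- (seq_len(nc) - (nc + 1) / 2) * pitch
  y <- ((nr + 1) / 2 - seq_len(nr)) * pitch
  s <- model$substrate
  if (min(x) > s["xmin"] || max(x) < s["xmax"] ||
      min(y) > s["ymin"] || max(y) < s["ymax"])
    stop("grid does not cover the substrate; enlarge grid_shape or pitch")

  lev <- medium_levels()
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  lab <- matrix(match("background", lev), nr, nc)
  in_sub <- X >= s["xmin"] & X <= s["xmax"] & Y >= s["ymin"] & Y <= s["ymax"]
  lab[in_sub] <- match("substrate", lev)
  inc <- model$inclusions
  for (i in seq_len(nrow(inc))) {
    hit <- (X - inc$x[i])^2 + (Y - inc$y[i])^2 <= inc$radius[i]^2
    lab[hit] <- match(inc$medium[i], lev)
  }
  field_map(lab, pitch = pitch, quantity = "labels", levels = lev)
}

#' Voxelize a phantom into a 3-D volume by extrusion along the tube axis
#'
#' Tubes run perpendicular to the imaging plane (along z). The substrate
#' becomes a cube of the same side length; tubes span `tube_length` centred
#' on the plane. Used by the 3-D Monte Carlo optics.
#'
#' @param model a `phantom_model`.
#' @param shape integer triple (nx rows, ny cols, nz slices).
#' @param pitch voxel spacing, mm.
#' @param tube_length tube length along z, mm.
#' @return A 3-D label `field_map`; slice `[,, (nz+1)/2]` is the imaging plane.
#' @export
voxelize <- function(model, shape = c(120, 120, 120), pitch = 1,
                     tube_length = 50) {
  stopifnot(length(shape) == 3L)
  plane <- rasterize(model, grid_shape = shape[1:2], pitch = pitch)
  nz <- as.integer(shape[3])
  z <- (seq_len(nz) - (nz + 1) / 2) * pitch
  lev <- medium_levels()
  lab2 <- plane$values
  sub_code <- match("substrate", lev); bg <- match("background", lev)
  s <- model$substrate
  half_h <- (s["xmax"] - s["xmin"]) / 2
  vol <- array(bg, dim = c(dim(lab2), nz))
  for (k in seq_len(nz)) {
    sl <- lab2
    if (abs(z[k]) > half_h) {
      sl[] <- bg                     # outside the substrate cube
    } else if (abs(z[k]) > tube_length / 2) {
      sl[sl != bg] <- sub_code       # past the tube ends: substrate only
    }
    vol[, , k] <- sl
  }
  field_map(vol, pitch = pitch, quantity = "labels", levels = lev)
}

#' Phantom specification YAML round trip
#'
#' @param model a `phantom_model`.
#' @param path YAML file path.
#' @return `read_phantom_yaml` returns the reconstructed `phantom_model`.
#' @export
write_phantom_yaml <- function(model, path) {
  yaml::write_yaml(list(
    arrangement_id = model$arrangement_id,
    tube_radius = model$tube_radius,
    spacing = model$spacing,
    substrate = as.list(model$substrate),
    inclusions = lapply(seq_len(nrow(model$inclusions)), function(i)
      as.list(model$inclusions[i, ]))), path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  sp <- yaml::read_yaml(path)
  inc <- do.call(rbind, lapply(sp$inclusions, as.data.frame))
  structure(list(arrangement_id = sp$arrangement_id,
                 tube_radius = sp$tube_radius, spacing = sp$spacing,
                 substrate = unlist(sp$substrate),
                 inclusions = inc[, c("x", "y", "radius", "medium")]),
            class = "phantom_model")
}
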