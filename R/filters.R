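#' Anisotropic diffusion filter parameters
#'
#' @param k edge-magnitude parameter in image-intensity units (> 0); gradients
#'   well above `k` stop diffusing (edges kept), well below `k` diffuse
#'   isotropically. `NULL` defaults to 0.1 x the image dynamic range at
#'   filter time.
#' @param dt time step of the explicit update, in (0, 0.25] for 4-neighbour
#'   stability.
#' @param n_iter number of iterations (>= 1).
#' @param coefficient diffusion coefficient form: `"exponential"`
#'   exp(-(x/k)^2), `"rational"` 1/(1+(x/k)^2), or `"rational_printed"`
#'   1/(1+(x/2)^2) (kept selectable for audit).
#' @param eta_mode `"interior"` divides every update by the interior
#'   neighbour count (4), which makes the scheme conservative; `"local"`
#'   divides by the actual neighbour count at borders (3 at edges, 2 at
#'   corners).
#' @return An `adf_params`.
#' @export
adf_params <- function(k = NULL, dt = 0.2, n_iter = 20,
                       coefficient = c("exponential", "rational",
                                       "rational_printed"),
                       eta_mode = c("interior", "local")) {
  coefficient <- match.arg(coefficient)
  eta_mode <- match.arg(eta_mode)
  if (!is.null(k) && k <= 0) stop("k must be positive")
  if (dt <= 0 || dt > 0.25)
    stop("dt outside the (0, 0.25] stability range for 4-neighbour diffusion")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(k = k, dt = dt, n_iter = as.integer(n_iter),
                 coefficient = coefficient, eta_mode = eta_mode),
            class = "adf_params")
}

#' Non-local means filter parameters
#'
#' @param h decay parameter of the patch-similarity weight
#'   exp(-||v_p - v_q||^2 / h^2), in image-intensity units (> 0); applied to
#'   the raw squared Euclidean patch distance. `NULL` defaults to 0.1 x the
#'   image dynamic range at filter time.
#' @param patch_radius patch half-width in pixels (>= 0); patch vectors are
#'   (2r+1)^2 long.
#' @param search_radius search window half-width in pixels
#'   (>= patch_radius).
#' @return An `nlm_params`.
#' @export
nlm_params <- function(h = NULL, patch_radius = 2, search_radius = 7) {
  if (!is.null(h) && h <= 0) stop("h must be positive (h = 0 degenerates the weights)")
  if (patch_radius < 0) stop("patch_radius must be >= 0")
  if (search_radius < patch_radius)
    stop("search_radius must be >= patch_radius")
  structure(list(h = h, patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius)),
            class = "nlm_params")
}

diffusion_coefficient <- function(x, k, form) {
  switch(form,
         exponential = exp(-(x / k)^2),
         rational = 1 / (1 + (x / k)^2),
         rational_printed = 1 / (1 + (x / 2)^2))
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit iterations of the nonlinear diffusion update over the
#' 4-neighbourhood: each pixel moves by `dt / 4` times the sum of
#' c(|dI|) * dI over its neighbours, where dI is the neighbour-minus-centre
#' difference and c() the selected diffusion coefficient. Fluxes across the
#' image border are zero, so the image mean is conserved; with
#' `eta_mode = "local"` the update is instead divided by the local neighbour
#' count (the literal boundary-shrunk neighbourhood), which trades exact
#' conservation for the textbook form.
#'
#' @param image a `field_map` image or a plain numeric matrix.
#' @param params an [adf_params()].
#' @return The filtered image, same type as the input.
#' @export
adf <- function(image, params = adf_params()) {
  fm <- inherits(image, "field_map")
  I <- if (fm) image$values else image
  stopifnot(is.matrix(I), all(is.finite(I)))
  k <- params$k
  if (is.null(k)) k <- 0.1 * max(diff(range(I)), .Machine$double.eps)
  nr <- nrow(I); nc <- ncol(I)
  denom <- if (params$eta_mode == "interior") {
    # interior neighbour count of the domain (2 per axis with extent > 1)
    matrix(2 * (nr > 1) + 2 * (nc > 1), nr, nc)
  } else {
    matrix(2, nr, nc) +
      (row(I) > 1) + (row(I) < nr) + (col(I) > 1) + (col(I) < nc) - 2
  }
  for (it in seq_len(params$n_iter)) {
    dN <- rbind(rep(0, nc), I[-nr, , drop = FALSE]) - I; dN[1, ] <- 0
    dS <- rbind(I[-1, , drop = FALSE], rep(0, nc)) - I; dS[nr, ] <- 0
    dW <- cbind(rep(0, nr), I[, -nc, drop = FALSE]) - I; dW[, 1] <- 0
    dE <- cbind(I[, -1, drop = FALSE], rep(0, nr)) - I; dE[, nc] <- 0
    flux <- diffusion_coefficient(abs(dN), k, params$coefficient) * dN +
            diffusion_coefficient(abs(dS), k, params$coefficient) * dS +
            diffusion_coefficient(abs(dW), k, params$coefficient) * dW +
            diffusion_coefficient(abs(dE), k, params$coefficient) * dE
    I <- I + params$dt / denom * flux
  }
  if (fm) { image$values <- I; image } else I
}

#' Non-local means filter
#'
#' Each output pixel is the similarity-weighted average of all pixels in its
#' search window (clipped to the image at borders); weights decay with the
#' squared Euclidean distance between the surrounding patches,
#' exp(-||v_p - v_q||^2 / h^2), normalized to sum to one. Patches at borders
#' use reflective padding. The output is a convex combination of input
#' values, hence bounded by the input range.
#'
#' @param image a `field_map` image or a plain numeric matrix.
#' @param params an [nlm_params()].
#' @return The filtered image, same type as the input.
#' @export
nlm <- function(image, params = nlm_params()) {
  fm <- inherits(image, "field_map")
  I <- if (fm) image$values else image
  stopifnot(is.matrix(I), all(is.finite(I)))
  h <- params$h
  if (is.null(h)) h <- 0.1 * max(diff(range(I)), .Machine$double.eps)
  if (h <= 0) stop("h must be positive")
  out <- nlm_cpp(I, h, params$patch_radius, params$search_radius)
  if (fm) { image$values <- out; image } else out
}
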