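#' Synthesize a TEM-like image of a ground-truth structure
#'
#' Renders the emitter structure as electron-dense (dark) ridges on a
#' bright background in a transformed coordinate system, providing a
#' registration fixture with an exactly known SMLM-nm to EM-px transform.
#' The structure is splatted with a Gaussian ridge kernel, normalized, and
#' subtracted from the bright background; optional Gaussian pixel noise is
#' added.
#'
#' @param emitters An `emitter_set` (positions in nm).
#' @param trans A `transform2d` mapping SMLM nm to EM px (must be
#'   invertible, which `transform2d` enforces).
#' @param size Output image size `c(rows, cols)` in px.
#' @param ridge_sigma_px Gaussian ridge half-width in EM px.
#' @param contrast Ridge depth relative to the background level (0-1).
#' @param noise_level Gaussian noise sd in gray levels (0 = deterministic).
#' @param seed Integer seed (used only when `noise_level > 0`).
#' @return An `em_image` list: `image` (matrix in `[0, 1]`, bright
#'   background, dark structure) and `transform` (the true `transform2d`).
#' @export
synthesize_em_image <- function(emitters, trans, size = c(256, 256),
                                ridge_sigma_px = 2, contrast = 0.6,
                                noise_level = 0.02, seed = 1) {
  stopifnot(inherits(trans, "transform2d"), length(size) == 2, all(size >= 1))
  em_xy <- transform_xy(cbind(emitters$x_nm, emitters$y_nm), trans)
  ridge <- splat_gaussians(size, em_xy[, 1], em_xy[, 2], ridge_sigma_px,
                           pixel_nm = 1)
  mx <- max(ridge)
  if (mx > 0) ridge <- ridge / mx
  img <- 0.9 - contrast * ridge
  if (noise_level > 0) {
    img <- run_with_seed(seed, img + rnorm(length(img), 0, noise_level))
  }
  img <- matrix(pmin(pmax(img, 0), 1), size[1], size[2])
  structure(list(image = img, transform = trans), class = "em_image")
}

#' @export
print.em_image <- function(x, ...) {
  cat(sprintf("<em_image> %d x %d px, true transform kind %s\n",
              nrow(x$image), ncol(x$image), x$transform$kind))
  invisible(x)
}
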