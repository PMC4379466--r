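#' Super-resolution rendering settings
#'
#' @param out_pixel_nm Output pixel size in nm (default 5).
#' @param kernel_floor_nm Minimum rendering kernel sd in nm.
#' @param colormap Name of a [grDevices::hcl.colors()] palette for density
#'   color-coding.
#' @param density_range Optional `c(min, max)` density (points/um^2) mapped
#'   to the colormap ends; defaults to the data range.
#' @return A settings list for [render_sr_image()].
#' @export
render_settings <- function(out_pixel_nm = 5, kernel_floor_nm = 2,
                            colormap = "viridis", density_range = NULL) {
  stopifnot(out_pixel_nm > 0, kernel_floor_nm >= 0)
  if (!is.null(density_range)) stopifnot(density_range[1] < density_range[2])
  list(out_pixel_nm = out_pixel_nm, kernel_floor_nm = kernel_floor_nm,
       colormap = colormap, density_range = density_range)
}

#' Render a density-coded super-resolution image
#'
#' Each localization is drawn as a unit-mass integrated Gaussian whose sd
#' adapts to the local sampling: `sd_i = max(sigma_loc, nyquist_i / 2.35,
#' kernel_floor)`. Where the structure is densely sampled the kernel is the
#' localization accuracy; where sampling is sparse it widens to the local
#' Nyquist-equivalent sd so the image never suggests more resolution than
#' the data carry. A color raster codes the per-pixel mass-weighted mean
#' local density through the colormap (the dual density/Nyquist legend
#' convention).
#'
#' @param table A [loc_table()].
#' @param densres The matching `density_resolution` from
#'   [estimate_resolution()] (same record count and order).
#' @param settings A [render_settings()] list.
#' @param field_of_view FOV in nm (defaults to the table attribute or the
#'   bounding box).
#' @return An `sr_image` list: `intensity` (matrix, mass-preserving),
#'   `density` (per-pixel weighted mean density, NA where empty), `rgb`
#'   (H x W x 3 array in `[0,1]`), `legend` (tibble mapping density and
#'   Nyquist resolution to colors), with `pixel_nm` attributes on the
#'   rasters.
#' @export
render_sr_image <- function(table, densres, settings = render_settings(),
                            field_of_view = attr(table, "field_of_view")) {
  if (nrow(table) != nrow(densres)) {
    stop_smlm("render_sr_image: table and density result are misaligned (row counts differ)")
  }
  sigma_loc <- attr(densres, "sigma_loc")
  sd_i <- pmax(sigma_loc, densres$nyquist_nm / 2.35, settings$kernel_floor_nm)
  sd_i[is.na(sd_i)] <- max(sigma_loc, settings$kernel_floor_nm)
  rst <- render_points(table$x_nm, table$y_nm, sd_i, settings$out_pixel_nm,
                       field_of_view, weight2 = densres$rho_um2)
  dens <- rst$weighted / ifelse(rst$intensity > 0, rst$intensity, NA)
  rng <- settings$density_range
  if (is.null(rng)) {
    rng <- range(dens, na.rm = TRUE)
    if (!all(is.finite(rng)) || rng[1] >= rng[2]) rng <- c(0, 1)
  }
  pal <- grDevices::hcl.colors(256, settings$colormap)
  idx <- pmin(pmax(round((dens - rng[1]) / (rng[2] - rng[1]) * 255) + 1, 1), 256)
  scale01 <- rst$intensity / max(max(rst$intensity), .Machine$double.eps)
  rgbv <- grDevices::col2rgb(pal[ifelse(is.na(idx), 1, idx)]) / 255
  H <- nrow(rst$intensity); W <- ncol(rst$intensity)
  rgb_arr <- array(0, c(H, W, 3))
  for (ch in 1:3) rgb_arr[, , ch] <- matrix(rgbv[ch, ], H, W) * scale01
  legend_d <- seq(rng[1], rng[2], length.out = 7)
  legend <- tibble(rho_um2 = legend_d,
                   nyquist_nm = ifelse(legend_d > 0, nyquist_resolution(pmax(legend_d, 1e-9)), NA),
                   color = pal[pmin(pmax(round((legend_d - rng[1]) / (rng[2] - rng[1]) * 255) + 1, 1), 256)])
  out <- list(intensity = rst$intensity, density = dens, rgb = rgb_arr,
              legend = legend)
  attr(out$intensity, "pixel_nm") <- settings$out_pixel_nm
  attr(out$rgb, "pixel_nm") <- settings$out_pixel_nm
  attr(out, "pixel_nm") <- settings$out_pixel_nm
  class(out) <- "sr_image"
  out
}

render_points <- function(x, y, sd_nm, out_pixel_nm, field_of_view,
                          weight2 = NULL) {
  if (is.null(field_of_view)) {
    field_of_view <- c(max(x, 0) + 4 * max(sd_nm, 10), max(y, 0) + 4 * max(sd_nm, 10))
  }
  W <- as.integer(ceiling(field_of_view[1] / out_pixel_nm))
  H <- as.integer(ceiling(field_of_view[2] / out_pixel_nm))
  intensity <- splat_gaussians(c(H, W), x, y, sd_nm, out_pixel_nm)
  weighted <- if (!is.null(weight2)) {
    w2 <- ifelse(is.na(weight2), 0, weight2)
    splat_gaussians(c(H, W), x, y, sd_nm, out_pixel_nm, weight = w2)
  } else NULL
  list(intensity = intensity, weighted = weighted)
}

#' Render the diffraction-limited wide-field reference image
#'
#' Convolves the localizations with a Gaussian of the given FWHM (default
#' 250 nm), emulating the conventional wide-field fluorescence image of the
#' same field for resolution comparisons.
#'
#' @param table A [loc_table()] (or empty).
#' @param widefield_fwhm_nm FWHM of the diffraction-limited PSF, nm.
#' @param out_pixel_nm Output pixel size, nm.
#' @param field_of_view FOV in nm.
#' @return Intensity matrix (unit mass per localization) with a `pixel_nm`
#'   attribute.
#' @export
render_widefield_reference <- function(table, widefield_fwhm_nm = 250,
                                       out_pixel_nm = 5,
                                       field_of_view = attr(table, "field_of_view")) {
  stopifnot(widefield_fwhm_nm > 0)
  sd_nm <- widefield_fwhm_nm / 2.35
  if (nrow(table) == 0) {
    if (is.null(field_of_view)) field_of_view <- c(1000, 1000)
    W <- as.integer(ceiling(field_of_view[1] / out_pixel_nm))
    H <- as.integer(ceiling(field_of_view[2] / out_pixel_nm))
    out <- matrix(0, H, W)
  } else {
    out <- render_points(table$x_nm, table$y_nm, sd_nm, out_pixel_nm,
                         field_of_view)$intensity
  }
  attr(out, "pixel_nm") <- out_pixel_nm
  out
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("<sr_image> %d x %d px at %g nm/px, total mass %.1f\n",
              nrow(x$intensity), ncol(x$intensity), attr(x, "pixel_nm"),
              sum(x$intensity)))
  invisible(x)
}

#' @export
autoplot.sr_image <- function(object, ...) {
  px <- attr(object, "pixel_nm")
  df <- expand.grid(row = seq_len(nrow(object$intensity)),
                    col = seq_len(ncol(object$intensity)))
  df$r <- as.vector(object$rgb[, , 1])
  df$g <- as.vector(object$rgb[, , 2])
  df$b <- as.vector(object$rgb[, , 3])
  df$fill <- grDevices::rgb(df$r, df$g, df$b)
  ggplot(df, aes(x = .data$col * px, y = .data$row * px)) +
    geom_raster(aes(fill = .data$fill)) +
    scale_fill_identity() +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)") +
    theme_minimal()
}

#' Write rendered rasters to disk
#'
#' The intensity raster goes to 16-bit grayscale TIFF (scaled to the
#' maximum), the color-coded raster to 8-bit RGB PNG, and the legend to a
#' JSON sidecar.
#'
#' @param sr An `sr_image`.
#' @param path_base Output path without extension.
#' @return Invisibly, the written paths.
#' @export
write_sr_image <- function(sr, path_base) {
  mx <- max(max(sr$intensity), .Machine$double.eps)
  tif <- paste0(path_base, ".tif")
  tiff::writeTIFF(sr$intensity / mx, tif, bits.per.sample = 16)
  png_path <- paste0(path_base, ".png")
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(sr$rgb, png_path)
  } else {
    png_path <- NULL
  }
  legend_path <- paste0(path_base, "_legend.json")
  jsonlite::write_json(list(pixel_nm = attr(sr, "pixel_nm"),
                            intensity_scale = mx,
                            legend = sr$legend),
                       legend_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, png_path, legend_path))
}
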