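# Shared numeric helpers. Coordinate convention used throughout: continuous
# nm coordinates, x rightward (raster columns), y downward (raster rows);
# pixel (row r, col c) of a raster with pixel size p covers
# x in [(c-1)p, cp), y in [(r-1)p, rp), so the pixel center is at
# ((c-0.5)p, (r-0.5)p).

run_with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Mass of a unit 2D Gaussian integrated over the pixels of a raster window.
# Returns a matrix (rows = y pixels, cols = x pixels) for pixel index ranges
# rows, cols (1-based), center (cx, cy) in nm, isotropic sd in nm.
gauss_pixel_mass <- function(rows, cols, cx, cy, sd, pixel_nm) {
  fx <- pnorm(cols * pixel_nm, cx, sd) - pnorm((cols - 1) * pixel_nm, cx, sd)
  fy <- pnorm(rows * pixel_nm, cy, sd) - pnorm((rows - 1) * pixel_nm, cy, sd)
  outer(fy, fx)
}

# Add unit-mass Gaussian kernels at (x, y) nm with per-point sd and weight
# onto a raster of dimension dim (rows, cols). Truncated at +/- 4 sd.
splat_gaussians <- function(dim, x, y, sd, pixel_nm, weight = 1) {
  img <- matrix(0, dim[1], dim[2])
  n <- length(x)
  if (n == 0) return(img)
  sd <- rep_len(sd, n)
  weight <- rep_len(weight, n)
  for (i in seq_len(n)) {
    r <- ceiling(4 * sd[i] / pixel_nm)
    c0 <- max(1L, floor(x[i] / pixel_nm) + 1L - r)
    c1 <- min(dim[2], floor(x[i] / pixel_nm) + 1L + r)
    r0 <- max(1L, floor(y[i] / pixel_nm) + 1L - r)
    r1 <- min(dim[1], floor(y[i] / pixel_nm) + 1L + r)
    if (c0 > c1 || r0 > r1) next
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      weight[i] * gauss_pixel_mass(r0:r1, c0:c1, x[i], y[i], sd[i], pixel_nm)
  }
  img
}

# Bilinear sampling of a matrix at continuous index-space positions: cell
# (i, j) sits at position (i, j), so a pixel-center coordinate y (centers at
# y = r - 0.5) converts to index space as y + 0.5. Exact centers return the
# cell value.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  i0 <- floor(r); j0 <- floor(c)
  fr <- r - i0; fc <- c - j0
  val <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out <- rep(fill, length(i))
    out[ok] <- img[cbind(i[ok], j[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(i0, j0) +
    (1 - fr) * fc * val(i0, j0 + 1) +
    fr * (1 - fc) * val(i0 + 1, j0) +
    fr * fc * val(i0 + 1, j0 + 1)
}

stop_smlm <- function(msg, class = "smlmpipe_error", ...) {
  abort(msg, class = class, ...)
}
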