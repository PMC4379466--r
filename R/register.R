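#' 2D similarity / affine transforms between SMLM and EM coordinates
#'
#' A `transform2d` maps source coordinates (typically SMLM positions in nm)
#' to target coordinates (typically EM pixels) as `p' = A p + b`. For
#' `kind = "similarity"` (the "linear conformal" map: rotation, uniform
#' scale, translation, optionally reflection) the 2x2 block `A` is a scaled
#' rotation; `kind = "affine"` allows shear and anisotropic scale.
#'
#' @param A 2x2 linear part.
#' @param b Length-2 translation.
#' @param kind `"similarity"` or `"affine"`.
#' @param residual_rms Root-mean-square control-point misfit in target units
#'   (`NA` for a transform not estimated from points).
#' @param n_points Number of control points used.
#' @return A `transform2d` object.
#' @export
transform2d <- function(A, b, kind = c("similarity", "affine"),
                        residual_rms = NA_real_, n_points = NA_integer_) {
  kind <- match.arg(kind)
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  stopifnot(length(b) == 2)
  if (abs(det(A)) < 1e-12) stop_smlm("transform2d: singular linear part")
  structure(list(kind = kind, A = A, b = b, residual_rms = residual_rms,
                 n_points = n_points),
            class = "transform2d")
}

#' Build a similarity transform from scale, rotation and translation
#'
#' @param scale Uniform scale factor.
#' @param angle_deg Rotation angle, degrees, counter-clockwise in the
#'   x-right / y-down convention.
#' @param translation Length-2 translation in target units.
#' @param reflection Include a reflection about the x axis before rotating.
#' @return A `transform2d` of kind `"similarity"`.
#' @export
similarity_transform <- function(scale = 1, angle_deg = 0, translation = c(0, 0),
                                 reflection = FALSE) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (reflection) R <- R %*% diag(c(1, -1))
  transform2d(scale * R, translation, kind = "similarity")
}

#' Estimate a transform from paired control points
#'
#' Least-squares estimation of the SMLM-to-EM mapping from matched feature
#' positions: orthogonal Procrustes with isotropic scale for
#' `kind = "similarity"` (the "linear conformal" transform, sufficient when
#' the section does not shrink anisotropically during EM acquisition), or
#' the normal-equation solution for a full affine map (which can absorb
#' shrinkage/shear). The function never auto-selects between the two; fit
#' both and compare `residual_rms` if in doubt.
#'
#' @param points A data frame of control points with columns `smlm_x_nm`,
#'   `smlm_y_nm`, `em_x_px`, `em_y_px` (see [read_control_points()]), or a
#'   list with matrices `src` and `dst`.
#' @param kind `"similarity"` (>= 2 distinct pairs) or `"affine"` (>= 3
#'   non-collinear pairs).
#' @param allow_reflection Permit an orientation-reversing similarity.
#' @return A `transform2d` with `residual_rms` (target units) filled in.
#' @export
#' @examples
#' cp <- tibble::tibble(smlm_x_nm = c(0, 1000, 0), smlm_y_nm = c(0, 0, 1000),
#'                      em_x_px = c(10, 110, 10), em_y_px = c(20, 20, 120))
#' estimate_transform(cp, "similarity")
estimate_transform <- function(points, kind = c("similarity", "affine"),
                               allow_reflection = FALSE) {
  kind <- match.arg(kind)
  cp <- as_control_points(points)
  src <- cp$src; dst <- cp$dst
  n <- nrow(src)
  if (kind == "similarity" && n < 2) {
    stop_smlm("estimate_transform: similarity needs at least 2 control-point pairs")
  }
  if (kind == "affine" && n < 3) {
    stop_smlm("estimate_transform: affine needs at least 3 control-point pairs")
  }
  if (collinear_points(src) && (kind == "affine" || n > 2)) {
    if (kind == "affine") stop_smlm("estimate_transform: control points are collinear")
  }
  if (kind == "similarity") {
    mu_s <- colMeans(src); mu_d <- colMeans(dst)
    S <- sweep(src, 2, mu_s); D <- sweep(dst, 2, mu_d)
    var_s <- sum(S^2) / n
    if (var_s == 0) stop_smlm("estimate_transform: control points are coincident")
    # Umeyama: R = U diag(1,...,d) V', scale = tr(D S' R) implicit
    M <- crossprod(D, S) / n            # 2x2 covariance dst~src
    sv <- svd(M)
    d_sign <- sign(det(sv$u %*% t(sv$v)))
    if (d_sign == 0) d_sign <- 1
    Dg <- diag(c(1, if (allow_reflection) 1 else d_sign))
    R <- sv$u %*% Dg %*% t(sv$v)
    scale <- sum(sv$d * diag(Dg)) / var_s
    A <- scale * R
    b <- mu_d - A %*% mu_s
  } else {
    X <- cbind(src, 1)
    beta <- qr.solve(X, dst)            # 3x2
    A <- t(beta[1:2, ])
    b <- as.numeric(beta[3, ])
  }
  fit <- sweep(src %*% t(A), 2, as.numeric(b), `+`)
  rms <- sqrt(mean(rowSums((fit - dst)^2)))
  transform2d(A, b, kind = kind, residual_rms = rms, n_points = n)
}

as_control_points <- function(points) {
  if (is.list(points) && !is.data.frame(points) &&
      all(c("src", "dst") %in% names(points))) {
    src <- as.matrix(points$src); dst <- as.matrix(points$dst)
  } else {
    points <- as.data.frame(points)
    need <- c("smlm_x_nm", "smlm_y_nm", "em_x_px", "em_y_px")
    miss <- setdiff(need, names(points))
    if (length(miss) > 0) {
      stop_smlm(sprintf("control points: missing column %s", miss[1]))
    }
    src <- as.matrix(points[, c("smlm_x_nm", "smlm_y_nm")])
    dst <- as.matrix(points[, c("em_x_px", "em_y_px")])
  }
  if (nrow(src) != nrow(dst)) stop_smlm("control points: src/dst length mismatch")
  list(src = unname(src), dst = unname(dst))
}

collinear_points <- function(p, tol = 1e-9) {
  if (nrow(p) < 3) return(FALSE)
  S <- sweep(p, 2, colMeans(p))
  sv <- svd(S)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Apply a transform to points or a raster
#'
#' Points (a data frame with `x`/`y` or `x_nm`/`y_nm` columns, or a 2-column
#' matrix) are mapped forward. A raster (matrix) is resampled by inverse
#' mapping with bilinear interpolation: output pixel centers are pulled back
#' through the inverse transform and sampled in the source image (both
#' rasters addressed in pixel units, x = column, y = row).
#'
#' @param target Points or a numeric matrix raster.
#' @param trans A `transform2d`.
#' @param out_dim Output raster dimension `c(rows, cols)` (rasters only);
#'   defaults to the input dimension.
#' @param fill Fill value for out-of-field samples (rasters only).
#' @return Transformed points (same shape as input) or the resampled raster.
#' @export
apply_transform <- function(target, trans, out_dim = NULL, fill = 0) {
  stopifnot(inherits(trans, "transform2d"))
  if (is.matrix(target) && !is.data.frame(target)) {
    # a 2-column matrix with no requested output size is a point list;
    # anything else is a raster resampled by inverse mapping
    if (ncol(target) == 2 && is.null(out_dim)) {
      return(transform_xy(target, trans))
    }
    return(warp_raster(target, trans, out_dim, fill))
  }
  if (is.data.frame(target)) {
    nx <- intersect(c("x_nm", "x"), names(target))[1]
    ny <- intersect(c("y_nm", "y"), names(target))[1]
    if (is.na(nx) || is.na(ny)) {
      stop_smlm("apply_transform: data frame needs x/y or x_nm/y_nm columns")
    }
    xy <- transform_xy(cbind(target[[nx]], target[[ny]]), trans)
    target[[nx]] <- xy[, 1]
    target[[ny]] <- xy[, 2]
    return(target)
  }
  stop_smlm("apply_transform: unsupported target type")
}

transform_xy <- function(xy, trans) {
  if (nrow(xy) == 0) return(xy)
  sweep(xy %*% t(trans$A), 2, trans$b, `+`)
}

#' Invert a transform
#' @param trans A `transform2d`.
#' @return The inverse `transform2d`.
#' @export
invert_transform <- function(trans) {
  Ai <- solve(trans$A)
  transform2d(Ai, -Ai %*% trans$b, kind = trans$kind)
}

warp_raster <- function(img, trans, out_dim = NULL, fill = 0) {
  if (is.null(out_dim)) out_dim <- dim(img)
  inv <- invert_transform(trans)
  # output pixel centers in (x, y) = (col - 0.5, row - 0.5)
  cc <- rep(seq_len(out_dim[2]), each = out_dim[1]) - 0.5
  rr <- rep(seq_len(out_dim[1]), out_dim[2]) - 0.5
  src <- transform_xy(cbind(cc, rr), inv)
  v <- bilinear_sample(img, r = src[, 2] + 0.5, c = src[, 1] + 0.5, fill = fill)
  matrix(v, out_dim[1], out_dim[2])
}

#' Composite a super-resolution rendering over an EM image
#'
#' Resamples the SMLM rendering into the EM pixel frame through `trans`
#' (SMLM nm to EM px) and alpha-blends it over the EM grayscale. Regions
#' outside the SMLM field show the EM image alone.
#'
#' @param sr Super-resolution raster: a matrix (grayscale) or `H x W x 3`
#'   RGB array, addressed in nm via its `pixel_nm`/`origin_nm` attributes
#'   (as produced by [render_sr_image()]) or via the `sr_pixel_nm` argument.
#' @param em EM grayscale matrix (any range; rescaled to `[0, 1]`).
#' @param trans `transform2d` mapping SMLM nm to EM px.
#' @param alpha Blend weight of the SR layer in `[0, 1]`.
#' @param sr_pixel_nm SR raster pixel size in nm (default from attribute).
#' @return An `H x W x 3` RGB array in `[0, 1]` in the EM frame.
#' @export
make_overlay <- function(sr, em, trans, alpha = 0.5, sr_pixel_nm = NULL) {
  stopifnot(inherits(trans, "transform2d"), alpha >= 0, alpha <= 1,
            length(dim(em)) == 2, all(dim(em) > 0))
  if (is.null(sr_pixel_nm)) sr_pixel_nm <- attr(sr, "pixel_nm")
  if (is.null(sr_pixel_nm)) stop_smlm("make_overlay: sr raster pixel size unknown; pass sr_pixel_nm")
  rng <- range(em)
  em01 <- if (diff(rng) > 0) (em - rng[1]) / diff(rng) else em * 0
  # EM px -> SMLM nm -> SR px
  inv <- invert_transform(trans)
  cc <- rep(seq_len(ncol(em)), each = nrow(em)) - 0.5
  rr <- rep(seq_len(nrow(em)), ncol(em)) - 0.5
  nm <- transform_xy(cbind(cc, rr), inv)
  sr_r <- nm[, 2] / sr_pixel_nm + 0.5
  sr_c <- nm[, 1] / sr_pixel_nm + 0.5
  sr3 <- if (length(dim(sr)) == 3) sr else {
    m <- sr / max(max(sr), .Machine$double.eps)
    array(rep(m, 3), c(dim(sr), 3))
  }
  nr_s <- dim(sr3)[1]; nc_s <- dim(sr3)[2]
  inside <- sr_r >= 0 & sr_r <= nr_s + 1 & sr_c >= 0 & sr_c <= nc_s + 1
  out <- array(0, c(nrow(em), ncol(em), 3))
  for (ch in 1:3) {
    lay <- bilinear_sample(sr3[, , ch], sr_r, sr_c, fill = 0)
    a <- ifelse(inside, alpha, 0)
    out[, , ch] <- matrix((1 - a) * em01 + a * lay, nrow(em), ncol(em))
  }
  out
}

#' Extract an averaged line profile from an image
#'
#' Samples mean intensity across `width` perpendicular offsets at `n`
#' evenly spaced positions along the segment `p0`-`p1` (pixel coordinates,
#' x = column, y = row). With `invert = TRUE` values become
#' `max(image) - value`, the convention used to compare electron-dense
#' (dark) membranes in TEM with bright fluorescence ridges.
#'
#' @param image Numeric matrix.
#' @param p0,p1 Length-2 endpoints `c(x, y)` in pixel units, inside the image.
#' @param width Number of perpendicular samples averaged per position
#'   (spacing 1 px, centered on the segment).
#' @param n Number of positions along the segment (default: ~1 px spacing).
#' @param invert Invert pixel values.
#' @param scale_nm Physical length of one pixel, used for the `position_nm`
#'   column (default 1, i.e. positions in px).
#' @return A `line_profile` tibble with columns `position_nm`, `intensity`.
#' @export
line_profile <- function(image, p0, p1, width = 1, n = NULL, invert = FALSE,
                         scale_nm = 1) {
  stopifnot(is.matrix(image), length(p0) == 2, length(p1) == 2, width >= 1)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop_smlm("line_profile: endpoints must be distinct")
  inside <- function(p) p[1] >= 0 && p[1] <= ncol(image) && p[2] >= 0 && p[2] <= nrow(image)
  if (!inside(p0) || !inside(p1)) stop_smlm("line_profile: endpoints outside the image")
  if (is.null(n)) n <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n)
  u <- (p1 - p0) / len
  v <- c(-u[2], u[1])
  offs <- seq_len(width) - (width + 1) / 2
  acc <- matrix(0, n, length(offs))
  for (k in seq_along(offs)) {
    px <- p0[1] + t * len * u[1] + offs[k] * v[1]
    py <- p0[2] + t * len * u[2] + offs[k] * v[2]
    acc[, k] <- bilinear_sample(image, r = py + 0.5, c = px + 0.5)
  }
  val <- rowMeans(acc)
  if (invert) val <- max(image) - val
  out <- tibble(position_nm = t * len * scale_nm, intensity = val)
  attr(out, "invert") <- invert
  class(out) <- c("line_profile", class(out))
  out
}

#' Count resolved peaks in a line profile
#'
#' Counts the local maxima of a profile that are separated from every
#' higher peak by a sufficiently deep valley. A maximum counts as a
#' distinct peak only if the saddle toward the nearest higher (or equal)
#' peak drops to at most `1 - min_prominence` of its height. The default
#' 0.35 is slightly stricter than the Rayleigh criterion (the Airy-pattern
#' dip at the Rayleigh separation is ~26%), so two structures are counted
#' only once their profiles are separated beyond the classical limit —
#' a 300 nm membrane pair is two-peaked in a super-resolution profile but
#' single-peaked under a 250 nm-FWHM diffraction-limited profile, whose
#' residual dip is ~27%.
#'
#' @param profile A [line_profile()] tibble or numeric vector.
#' @param min_prominence Required relative dip in `(0, 1)`.
#' @param min_height Ignore maxima below this fraction of the global
#'   maximum.
#' @return Integer peak count.
#' @export
count_profile_peaks <- function(profile, min_prominence = 0.35, min_height = 0.2) {
  y <- if (is.data.frame(profile)) profile$intensity else as.numeric(profile)
  n <- length(y)
  if (n < 3 || max(y) <= 0) return(0L)
  is_max <- which(vapply(2:(n - 1), function(i) {
    y[i] > y[i - 1] && y[i] >= y[i + 1]
  }, logical(1))) + 1L
  is_max <- is_max[y[is_max] >= min_height * max(y)]
  if (length(is_max) == 0) return(0L)
  ord <- is_max[order(-y[is_max])]
  accepted <- ord[1]
  for (p in ord[-1]) {
    h <- y[p]
    ok <- TRUE
    for (a in accepted) {
      seg <- y[min(p, a):max(p, a)]
      saddle <- min(seg)
      if (saddle > (1 - min_prominence) * min(h, y[a])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, p)
  }
  length(accepted)
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> kind %s, residual RMS %s (n = %s)\n", x$kind,
              format(x$residual_rms, digits = 4), x$n_points))
  cat("A =\n"); print(x$A)
  cat("b =", x$b, "\n")
  invisible(x)
}

#' @export
tidy.transform2d <- function(x, ...) {
  tibble(term = c("a11", "a12", "a21", "a22", "tx", "ty"),
         estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b))
}

#' @export
glance.transform2d <- function(x, ...) {
  sc <- sqrt(abs(det(x$A)))
  tibble(kind = x$kind, scale = sc,
         rotation_deg = atan2(x$A[2, 1], x$A[1, 1]) * 180 / pi,
         residual_rms = x$residual_rms, n_points = x$n_points)
}

#' Serialize / deserialize a transform as JSON
#' @param trans A `transform2d`.
#' @param path JSON file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the `transform2d`.
#' @export
write_transform <- function(trans, path) {
  jsonlite::write_json(
    list(kind = trans$kind,
         coefficients = c(trans$A[1, 1], trans$A[1, 2], trans$b[1],
                          trans$A[2, 1], trans$A[2, 2], trans$b[2]),
         residual_rms = trans$residual_rms, n_points = trans$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- j$coefficients
  transform2d(matrix(c(co[1], co[4], co[2], co[5]), 2, 2), c(co[3], co[6]),
              kind = j$kind,
              residual_rms = if (is.null(j$residual_rms)) NA_real_ else j$residual_rms,
              n_points = if (is.null(j$n_points)) NA_integer_ else as.integer(j$n_points))
}

#' Read / write a 4-column control-point CSV
#'
#' Columns: `smlm_x_nm`, `smlm_y_nm`, `em_x_px`, `em_y_px`.
#' @param path CSV path.
#' @param points Control-point data frame.
#' @return A tibble of control points / `path` invisibly.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  as_control_points(df)   # validates columns
  as_tibble(df)
}

#' @rdname read_control_points
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
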