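#' Movie stack container
#'
#' A camera movie is stored as an `H x W x frames` array of nonnegative
#' counts with the [camera_model()] attached. Row index is y (downward),
#' column index is x (rightward).
#'
#' @param data Numeric array, `H x W x n_frames` (a matrix is treated as a
#'   single frame).
#' @param camera A [camera_model()].
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(data, camera) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, inherits(camera, "camera_model"))
  if (any(data < 0)) stop_smlm("movie_stack: counts must be nonnegative")
  structure(list(data = data, camera = camera), class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames of %d x %d px (%g nm/px)\n",
              d[3], d[1], d[2], x$camera$pixel_size_nm))
  invisible(x)
}

#' Number of frames in a movie stack
#' @param movie A `movie_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' Render a camera movie from a switching schedule
#'
#' Forward model of the acquisition: each emitter active in a frame
#' contributes an integrated 2D Gaussian spot carrying its detected-photon
#' count; a constant `background` (photons per pixel per frame) is added;
#' then EMCCD noise is applied as Poisson shot noise on the expected
#' photons, multiplied by `em_gain`, plus Gaussian read noise and the
#' camera `offset` (counts clamped at zero). With `noise = FALSE` the stack
#' is the deterministic expectation `gain * (signal + background) + offset`.
#'
#' A dense, continuously fluorescing population (molecules that do not
#' photo-switch) can be added at mean-field level via `background_image`
#' (expected photons per pixel per frame at time zero, e.g. from
#' [nonswitching_background_image()]) decaying exponentially with
#' `background_decay_rate` as the population photo-bleaches; per-frame
#' Poisson pixel noise still applies, only the discreteness of individual
#' bleaching events is averaged out. Sparse non-switching emitters can
#' instead be simulated explicitly through the schedule
#' (`nonswitching_fraction` in [switching_params()]).
#'
#' @param schedule A `switching_schedule` from [simulate_switching()].
#' @param psf A [psf_model()].
#' @param camera A [camera_model()].
#' @param background Expected background photons per pixel per frame (>= 0).
#' @param background_image Optional `H x W` matrix of additional expected
#'   background photons per pixel per frame at acquisition start.
#' @param background_decay_rate Bleaching rate (1/s) applied to
#'   `background_image` over the acquisition.
#' @param noise Apply the stochastic camera model (default `TRUE`).
#' @param seed Integer seed (used only when `noise = TRUE`).
#' @param field_of_view FOV in nm; defaults to the schedule's.
#' @param n_frames_out Number of frames; defaults to the schedule's.
#' @return A [movie_stack()].
#' @export
render_movie <- function(schedule, psf, camera, background = 2,
                         background_image = NULL, background_decay_rate = 0,
                         noise = TRUE, seed = 1,
                         field_of_view = attr(schedule, "field_of_view"),
                         n_frames_out = attr(schedule, "n_frames")) {
  stopifnot(inherits(psf, "psf_model"), inherits(camera, "camera_model"),
            background_decay_rate >= 0)
  if (background < 0) stop_smlm("render_movie: background must be >= 0")
  if (is.null(field_of_view) || is.null(n_frames_out)) {
    stop_smlm("render_movie: schedule lacks field_of_view / n_frames metadata")
  }
  px <- camera$pixel_size_nm
  W <- as.integer(ceiling(field_of_view[1] / px))
  H <- as.integer(ceiling(field_of_view[2] / px))
  outside <- schedule$x_nm < -4 * psf$sigma_nm | schedule$x_nm > W * px + 4 * psf$sigma_nm |
    schedule$y_nm < -4 * psf$sigma_nm | schedule$y_nm > H * px + 4 * psf$sigma_nm
  if (any(outside)) {
    warn(sprintf("render_movie: %d emitter-frames fall outside the field of view; contributions clipped",
                 sum(outside)))
  }
  expect <- array(background, c(H, W, n_frames_out))
  if (!is.null(background_image)) {
    stopifnot(all(dim(background_image) == c(H, W)), all(background_image >= 0))
    for (f in seq_len(n_frames_out)) {
      decay <- exp(-background_decay_rate * (f - 0.5) / camera$fps)
      expect[, , f] <- expect[, , f] + background_image * decay
    }
  }
  if (nrow(schedule) > 0) {
    by_frame <- split(seq_len(nrow(schedule)), schedule$frame)
    for (fr in names(by_frame)) {
      f <- as.integer(fr)
      if (f < 1 || f > n_frames_out) next
      idx <- by_frame[[fr]]
      expect[, , f] <- expect[, , f] +
        splat_gaussians(c(H, W), schedule$x_nm[idx], schedule$y_nm[idx],
                        psf$sigma_nm, px, weight = schedule$photons[idx])
    }
  }
  data <- if (noise) {
    run_with_seed(seed, {
      counts <- camera$em_gain * rpois(length(expect), expect) +
        rnorm(length(expect), 0, camera$read_noise) + camera$offset
      array(pmax(counts, 0), dim(expect))
    })
  } else {
    camera$em_gain * expect + camera$offset
  }
  movie_stack(data, camera)
}

#' Expected background image of a dense non-switching population
#'
#' Molecules that never enter the dark state fluoresce in every frame; at
#' the densities where this matters (tens of molecules per square micron,
#' many per diffraction-limited area) their images overlap into a
#' structured, quasi-continuous background glow rather than fittable
#' single-molecule spots. This helper builds that glow as the expected
#' photons per pixel per frame: each non-switching molecule contributes its
#' mean per-frame photon emission through the PSF. Feed the result to
#' [render_movie()]'s `background_image` with `background_decay_rate` set
#' to the population's bleaching rate.
#'
#' @param emitters An `emitter_set` holding the non-switching molecule
#'   positions.
#' @param photons_per_frame Expected detected photons per molecule per
#'   frame (a continuously emissive fluorophore delivers roughly a burst's
#'   worth of photons every frame).
#' @param psf A [psf_model()].
#' @param camera A [camera_model()].
#' @param field_of_view FOV in nm; defaults to the emitter set's.
#' @return `H x W` matrix of expected photons per pixel per frame.
#' @export
nonswitching_background_image <- function(emitters, photons_per_frame = 300,
                                          psf = psf_model(), camera = camera_model(),
                                          field_of_view = attr(emitters, "field_of_view")) {
  stopifnot(photons_per_frame >= 0)
  px <- camera$pixel_size_nm
  W <- as.integer(ceiling(field_of_view[1] / px))
  H <- as.integer(ceiling(field_of_view[2] / px))
  splat_gaussians(c(H, W), emitters$x_nm, emitters$y_nm, psf$sigma_nm, px,
                  weight = photons_per_frame)
}

#' Write / read a movie as multi-page TIFF with a metadata sidecar
#'
#' Frames are stored as 16-bit grayscale pages (counts clamped to
#' `[0, 65535]`); acquisition metadata (`pixel_size_nm`, `integration_ms`,
#' `fps`, and the remaining camera fields) goes to a YAML sidecar at
#' `<path>.yaml`.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @return `write_movie` returns `path` invisibly; `read_movie` returns a
#'   [movie_stack()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  pages <- lapply(seq_len(n_frames(movie)), function(f) {
    pmin(pmax(round(movie$data[, , f]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  cam <- movie$camera
  yaml::write_yaml(list(pixel_size_nm = cam$pixel_size_nm,
                        integration_ms = cam$integration_ms, fps = cam$fps,
                        em_gain = cam$em_gain, read_noise = cam$read_noise,
                        offset = cam$offset, qe = cam$qe),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    stop_smlm(sprintf("read_movie: metadata sidecar '%s' not found", meta_path))
  }
  m <- yaml::read_yaml(meta_path)
  cam <- camera_model(pixel_size_nm = m$pixel_size_nm, integration_ms = m$integration_ms,
                      fps = m$fps, em_gain = m$em_gain, read_noise = m$read_noise,
                      offset = m$offset, qe = m$qe)
  data <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    data[, , f] <- pg * 65535
  }
  movie_stack(data, cam)
}
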