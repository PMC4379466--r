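#' Simulate photo-switching schedules for an emitter set
#'
#' Runs the continuous-time switching model for every emitter over the
#' acquisition and bins emission into camera integration windows. Switching
#' emitters wait an exponential time (rate `recovery_rate`) in the dark
#' state, turn on for an exponential on-time (mean `mean_on_time_ms`), emit
#' a uniform draw from `photon_range` photons spread over the frames the
#' burst overlaps (proportionally to the in-frame on-time), then bleach with
#' probability `bleach_prob` or return to the dark state. Non-switching
#' emitters fluoresce in every frame until an exponential bleaching time
#' with rate `nonswitching_bleach_rate`.
#'
#' Frame `f` exposes during `[(f-1)/fps, (f-1)/fps + integration]`; photons
#' emitted in the dead time between exposures are lost.
#'
#' @param emitters An `emitter_set` from [generate_structure()].
#' @param params A [switching_params()] object.
#' @param n_frames Number of frames to simulate (>= 1).
#' @param camera A [camera_model()]; supplies frame rate and integration.
#' @param seed Integer seed.
#' @return A `switching_schedule` tibble with columns `frame`, `emitter_id`,
#'   `x_nm`, `y_nm`, `photons` (detected in that frame), `burst_id`
#'   (per-emitter burst counter; 0 for non-switching emitters),
#'   `burst_photons` (the full per-burst draw) and `switching` (logical).
#' @export
simulate_switching <- function(emitters, params, n_frames, camera, seed) {
  stopifnot(inherits(params, "switching_params"), inherits(camera, "camera_model"))
  if (!is.numeric(n_frames) || n_frames < 1) {
    stop_smlm("simulate_switching: n_frames must be >= 1")
  }
  n_frames <- as.integer(n_frames)
  period_s <- 1 / camera$fps
  expo_s <- camera$integration_ms / 1000
  t_total <- n_frames * period_s

  frame_overlap <- function(t0, t1) {
    # frames whose exposure window intersects [t0, t1], with overlap seconds
    f0 <- max(1L, as.integer(floor(t0 / period_s)) + 1L)
    f1 <- min(n_frames, as.integer(floor(t1 / period_s)) + 1L)
    if (f0 > f1) return(NULL)
    f <- f0:f1
    lo <- (f - 1) * period_s
    ov <- pmin(t1, lo + expo_s) - pmax(t0, lo)
    keep <- ov > 0
    if (!any(keep)) return(NULL)
    list(frame = f[keep], overlap = ov[keep])
  }

  run_with_seed(seed, {
    n <- nrow(emitters)
    if (n == 0) return(empty_schedule(emitters, camera, n_frames, params))
    is_ns <- runif(n) < params$nonswitching_fraction
    rows <- list(); nrow_used <- 0L
    push <- function(df) {
      nrow_used <<- nrow_used + 1L
      rows[[nrow_used]] <<- df
    }
    for (i in seq_len(n)) {
      xi <- emitters$x_nm[i]; yi <- emitters$y_nm[i]
      if (is_ns[i]) {
        t_bleach <- if (params$nonswitching_bleach_rate > 0) {
          rexp(1, params$nonswitching_bleach_rate)
        } else Inf
        ov <- frame_overlap(0, min(t_bleach, t_total))
        if (!is.null(ov)) {
          ph <- runif(length(ov$frame), params$photon_range[1], params$photon_range[2]) *
            ov$overlap / expo_s
          push(tibble(frame = ov$frame, emitter_id = emitters$emitter_id[i],
                      x_nm = xi, y_nm = yi, photons = ph, burst_id = 0L,
                      burst_photons = NA_real_, switching = FALSE))
        }
      } else {
        if (params$recovery_rate <= 0) next
        t <- 0; burst <- 0L
        repeat {
          t_on <- t + rexp(1, params$recovery_rate)
          if (t_on >= t_total) break
          on_dur <- rexp(1, 1000 / params$mean_on_time_ms)
          burst <- burst + 1L
          n_phot <- runif(1, params$photon_range[1], params$photon_range[2])
          ov <- frame_overlap(t_on, min(t_on + on_dur, t_total))
          if (!is.null(ov)) {
            push(tibble(frame = ov$frame, emitter_id = emitters$emitter_id[i],
                        x_nm = xi, y_nm = yi,
                        photons = n_phot * pmin(ov$overlap / on_dur, 1),
                        burst_id = burst, burst_photons = n_phot,
                        switching = TRUE))
          }
          t <- t_on + on_dur
          if (runif(1) < params$bleach_prob) break
        }
      }
    }
    if (nrow_used == 0L) return(empty_schedule(emitters, camera, n_frames, params))
    out <- bind_rows(rows[seq_len(nrow_used)]) %>% arrange(.data$frame, .data$emitter_id)
    schedule_attrs(out, emitters, camera, n_frames, params)
  })
}

empty_schedule <- function(emitters, camera, n_frames, params) {
  out <- tibble(frame = integer(), emitter_id = integer(), x_nm = numeric(),
                y_nm = numeric(), photons = numeric(), burst_id = integer(),
                burst_photons = numeric(), switching = logical())
  schedule_attrs(out, emitters, camera, n_frames, params)
}

schedule_attrs <- function(out, emitters, camera, n_frames, params) {
  attr(out, "field_of_view") <- attr(emitters, "field_of_view")
  attr(out, "camera") <- camera
  attr(out, "n_frames") <- n_frames
  attr(out, "switching_params") <- params
  class(out) <- c("switching_schedule", class(out))
  out
}

#' @export
print.switching_schedule <- function(x, ...) {
  cat(sprintf("<switching_schedule> %d emitter-frames over %d frames\n",
              nrow(x), attr(x, "n_frames")))
  NextMethod()
}
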