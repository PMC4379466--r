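#' Localization settings
#'
#' @param half_window Background median half-window, frames.
#' @param threshold Detection threshold in robust-sigma units.
#' @param roi_size Fit ROI side, odd pixels.
#' @param merge_radius_nm Radius for merging consecutive-frame detections of
#'   the same burst (0 disables merging).
#' @param min_photons Photon filter applied after fitting.
#' @param max_fit_sigma_factor Keep fits with sigma at most this multiple of
#'   the nominal PSF sigma.
#' @return A list of settings for [localize_movie()].
#' @export
localize_settings <- function(half_window = 10, threshold = 4, roi_size = 7,
                              merge_radius_nm = 50, min_photons = 100,
                              max_fit_sigma_factor = 2) {
  stopifnot(half_window >= 1, threshold > 0, roi_size %% 2 == 1,
            merge_radius_nm >= 0, min_photons >= 0)
  list(half_window = half_window, threshold = threshold, roi_size = roi_size,
       merge_radius_nm = merge_radius_nm, min_photons = min_photons,
       max_fit_sigma_factor = max_fit_sigma_factor)
}

#' Localize single molecules in a movie
#'
#' The full detection chain: sliding-window temporal-median background
#' subtraction, per-frame candidate detection on the clamped residual,
#' Poisson maximum-likelihood Gaussian fitting of each candidate on the
#' gain-corrected raw counts (background is a free fit parameter), removal
#' of failed or out-of-bounds fits, and merging of detections of the same
#' burst appearing in consecutive frames within `merge_radius_nm` into a
#' single record at the photon-weighted mean position.
#'
#' @param movie A [movie_stack()].
#' @param psf A [psf_model()].
#' @param settings A [localize_settings()] list.
#' @return A [loc_table()] with one row per (merged) burst detection.
#' @export
localize_movie <- function(movie, psf = psf_model(), settings = localize_settings()) {
  stopifnot(inherits(movie, "movie_stack"))
  cam <- movie$camera
  px <- cam$pixel_size_nm
  half <- settings$roi_size %/% 2
  res <- subtract_background(movie, settings$half_window)
  d <- dim(movie$data)
  # per-pixel noise maps in temporal blocks, so the detection threshold
  # tracks both spatial background structure and slow bleaching decay
  block <- 150L
  block_id <- ceiling(seq_len(d[3]) / block)
  noise_maps <- lapply(split(seq_len(d[3]), block_id),
                       function(fr) residual_noise_map(res, frames = fr))
  fits <- list(); nf <- 0L
  n_failed <- 0L
  for (f in seq_len(d[3])) {
    cands <- detect_candidates(res$data[, , f], settings$threshold,
                               noise = noise_maps[[block_id[f]]])
    if (nrow(cands) == 0) next
    for (i in seq_len(nrow(cands))) {
      r <- cands$row[i]; c <- cands$col[i]
      if (r - half < 1 || r + half > d[1] || c - half < 1 || c + half > d[2]) next
      # cheap gate: the residual photon mass in the ROI must plausibly reach
      # the photon filter, otherwise skip the expensive MLE
      roi_res <- res$data[(r - half):(r + half), (c - half):(c + half), f]
      if (sum(pmax(roi_res, 0)) / cam$em_gain < settings$min_photons / 3) next
      roi_counts <- movie$data[(r - half):(r + half), (c - half):(c + half), f]
      roi <- pmax((roi_counts - cam$offset) / cam$em_gain, 0)
      fit <- fit_spot_mle(roi, psf, cam)
      if (!fit$converged || is.na(fit$photons)) { n_failed <- n_failed + 1L; next }
      # reject fits that ran to the ROI edge or pinned sigma at a bound
      # (boundary optima are degenerate, typically noise clusters)
      s_px <- fit$fit_sigma_nm / px
      s_psf <- psf$sigma_nm / px
      if (fit$x_px < 0.5 || fit$x_px > settings$roi_size - 0.5 ||
          fit$y_px < 0.5 || fit$y_px > settings$roi_size - 0.5 ||
          s_px <= 0.5 * s_psf + 1e-6 || s_px >= 2 * s_psf - 1e-6) {
        n_failed <- n_failed + 1L; next
      }
      nf <- nf + 1L
      fits[[nf]] <- tibble(
        frame = f,
        x_nm = (c - 1 - half) * px + fit$x_nm,
        y_nm = (r - 1 - half) * px + fit$y_nm,
        photons = fit$photons, background = fit$background,
        fit_sigma_nm = fit$fit_sigma_nm,
        log_likelihood = fit$log_likelihood, n_merged = 1L)
    }
  }
  tab <- if (nf == 0) {
    tibble(frame = integer(), x_nm = numeric(), y_nm = numeric(),
           photons = numeric(), background = numeric(),
           fit_sigma_nm = numeric(), log_likelihood = numeric(),
           n_merged = integer())
  } else bind_rows(fits)
  tab <- tab[tab$photons >= settings$min_photons &
               tab$fit_sigma_nm <= settings$max_fit_sigma_factor * psf$sigma_nm, ,
             drop = FALSE]
  tab_raw <- tab
  if (settings$merge_radius_nm > 0 && nrow(tab) > 1) {
    tab <- merge_consecutive(tab, settings$merge_radius_nm)
  }
  message(sprintf("localize_movie: %d accepted fits, %d rejected, %d records after filtering/merging",
                  nf, n_failed, nrow(tab)))
  out <- loc_table(tab, pixel_size_nm = px, frame_time_ms = 1000 / cam$fps,
                   source = "localize_movie")
  attr(out, "field_of_view") <- c(d[2] * px, d[1] * px)
  if (settings$merge_radius_nm > 0) {
    # keep the per-frame records: adjacent-frame accuracy estimation (NeNA)
    # needs the two localizations of a burst that merging collapses
    raw <- loc_table(tab_raw, pixel_size_nm = px, frame_time_ms = 1000 / cam$fps,
                     source = "localize_movie_unmerged")
    attr(raw, "field_of_view") <- attr(out, "field_of_view")
    attr(out, "unmerged") <- raw
  }
  out
}

#' Merge consecutive-frame detections of the same burst
#'
#' Localizations in frame `t + 1` lying within `radius_nm` of an open chain
#' ending in frame `t` are merged into it; a closed chain becomes one record
#' at the photon-weighted mean position with summed photons and `n_merged`
#' set to the chain length. Total photons are conserved and the record
#' count never increases.
#'
#' @param tab Localization data frame (columns `frame`, `x_nm`, `y_nm`,
#'   `photons`, plus optional fit columns).
#' @param radius_nm Merge radius in nm.
#' @return Merged tibble.
#' @export
merge_consecutive <- function(tab, radius_nm = 50) {
  tab <- arrange(as_tibble(tab), .data$frame)
  if (is.null(tab[["background"]])) tab$background <- 0
  if (is.null(tab[["fit_sigma_nm"]])) tab$fit_sigma_nm <- NA_real_
  if (is.null(tab[["n_merged"]])) tab$n_merged <- 1L
  n <- nrow(tab)
  if (n == 0) return(tab)
  chain <- seq_len(n)        # chain id per record
  frames <- sort(unique(tab$frame))
  idx_by_frame <- split(seq_len(n), tab$frame)
  for (fi in seq_along(frames)[-1]) {
    if (frames[fi] - frames[fi - 1] != 1) next
    prev <- idx_by_frame[[as.character(frames[fi - 1])]]
    cur <- idx_by_frame[[as.character(frames[fi])]]
    if (length(prev) == 0 || length(cur) == 0) next
    taken <- rep(FALSE, length(prev))
    for (j in cur) {
      d2 <- (tab$x_nm[prev] - tab$x_nm[j])^2 + (tab$y_nm[prev] - tab$y_nm[j])^2
      d2[taken] <- Inf
      k <- which.min(d2)
      if (length(k) && d2[k] <= radius_nm^2) {
        chain[j] <- chain[prev[k]]
        taken[k] <- TRUE
      }
    }
  }
  tab$.chain <- chain
  has_ll <- "log_likelihood" %in% names(tab)
  out <- tab %>%
    group_by(.data$.chain) %>%
    summarise(
      frame = min(.data$frame),
      x_nm = sum(.data$x_nm * .data$photons) / sum(.data$photons),
      y_nm = sum(.data$y_nm * .data$photons) / sum(.data$photons),
      photons = sum(.data$photons),
      background = mean(.data$background),
      fit_sigma_nm = mean(.data$fit_sigma_nm),
      log_likelihood = if (has_ll) sum(.data$log_likelihood) else NA_real_,
      n_merged = sum(.data$n_merged),
      .groups = "drop") %>%
    arrange(.data$frame)
  out$.chain <- NULL
  out
}
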