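#' Localization table
#'
#' The pipeline's central exchange format: one row per detected
#' single-molecule signal with columns `frame`, `x_nm`, `y_nm`, `photons`,
#' `background` (photons per pixel), `fit_sigma_nm`, `n_merged` (number of
#' consecutive-frame detections merged into the record) and optionally
#' `log_likelihood`, `emitter_id` or any extra columns. Acquisition
#' metadata (`pixel_size_nm`, `frame_time_ms`, `source`) rides along as
#' attributes.
#'
#' @param records A data frame with at least `frame`, `x_nm`, `y_nm`,
#'   `photons`; missing `background`, `fit_sigma_nm`, `n_merged` columns are
#'   filled with defaults (0, NA, 1).
#' @param pixel_size_nm Camera pixel size, nm.
#' @param frame_time_ms Frame period, ms.
#' @param source Free-text provenance label.
#' @return A `loc_table` tibble sorted by frame.
#' @export
loc_table <- function(records, pixel_size_nm = NA_real_, frame_time_ms = NA_real_,
                      source = "unknown") {
  records <- as_tibble(records)
  need <- c("frame", "x_nm", "y_nm", "photons")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop_smlm(sprintf("loc_table: missing column %s", miss[1]))
  }
  if (is.null(records[["background"]])) records$background <- 0
  if (is.null(records[["fit_sigma_nm"]])) records$fit_sigma_nm <- NA_real_
  if (is.null(records[["n_merged"]])) records$n_merged <- 1L
  records <- arrange(records, .data$frame)
  attr(records, "pixel_size_nm") <- pixel_size_nm
  attr(records, "frame_time_ms") <- frame_time_ms
  attr(records, "source") <- source
  class(records) <- unique(c("loc_table", class(records)))
  records
}

loc_meta <- function(table) {
  list(pixel_size_nm = attr(table, "pixel_size_nm"),
       frame_time_ms = attr(table, "frame_time_ms"),
       source = attr(table, "source"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations over frames %s-%s (%g nm/px, %g ms/frame)\n",
              nrow(x), if (nrow(x)) min(x$frame) else NA, if (nrow(x)) max(x$frame) else NA,
              attr(x, "pixel_size_nm"), attr(x, "frame_time_ms")))
  NextMethod()
}

#' Filter a localization table on fit-quality thresholds
#'
#' Keeps records with `photons >= min_photons`, fitted PSF width at most
#' `max_fit_sigma_nm`, and position at least `margin_nm` from the field
#' border (when a field of view is known). Order is preserved; the number
#' of removed records is reported as a message and stored in the
#' `n_removed` attribute.
#'
#' @param table A `loc_table`.
#' @param min_photons Minimum photon count (default 100, the lower end of
#'   the detected single-molecule photon range).
#' @param max_fit_sigma_nm Maximum fitted sigma in nm (`Inf` to disable).
#' @param margin_nm Border margin (0 to disable); requires a
#'   `field_of_view` attribute on the table.
#' @return The filtered `loc_table`.
#' @export
filter_localizations <- function(table, min_photons = 100,
                                 max_fit_sigma_nm = Inf, margin_nm = 0) {
  stopifnot(min_photons >= 0, max_fit_sigma_nm >= 0, margin_nm >= 0)
  keep <- table$photons >= min_photons
  if (is.finite(max_fit_sigma_nm)) {
    keep <- keep & (is.na(table$fit_sigma_nm) | table$fit_sigma_nm <= max_fit_sigma_nm)
  }
  fov <- attr(table, "field_of_view")
  if (margin_nm > 0 && !is.null(fov)) {
    keep <- keep & table$x_nm >= margin_nm & table$x_nm <= fov[1] - margin_nm &
      table$y_nm >= margin_nm & table$y_nm <= fov[2] - margin_nm
  }
  out <- table[keep, , drop = FALSE]
  attrs <- attributes(table)
  for (a in setdiff(names(attrs), c("row.names", "names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "n_removed") <- sum(!keep)
  message(sprintf("filter_localizations: removed %d of %d records", sum(!keep), length(keep)))
  out
}
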