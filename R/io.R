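#' Read and write localization tables as CSV
#'
#' The on-disk format is a plain CSV with the header `frame, x_nm, y_nm,
#' photons, background, fit_sigma_nm, n_merged` (plus any extra columns,
#' e.g. `emitter_id` for simulated ground truth), preceded by `#`-prefixed
#' metadata lines carrying `pixel_size_nm`, `frame_time_ms` and `source`.
#' Numbers are written with 10 significant digits so a write/read round
#' trip preserves records bit-exactly at any 6-significant-digit
#' representation.
#'
#' @param table A [loc_table()].
#' @param path File path.
#' @return `write_localizations` returns `path` invisibly;
#'   `read_localizations` returns a [loc_table()].
#' @export
write_localizations <- function(table, path) {
  meta <- loc_meta(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_nm: %.10g", as.numeric(meta$pixel_size_nm)),
               sprintf("# frame_time_ms: %.10g", as.numeric(meta$frame_time_ms)),
               sprintf("# source: %s", meta$source)), con)
  df <- as.data.frame(table)
  lead <- intersect(c("frame", "x_nm", "y_nm", "photons", "background",
                      "fit_sigma_nm", "n_merged"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  meta <- list()
  if (n_meta > 0) {
    for (l in lines[seq_len(n_meta)]) {
      kv <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
      if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
    }
  }
  body <- lines[!is_meta]
  if (length(body) < 1) stop_smlm("read_localizations: no header line found")
  df <- utils::read.csv(text = body, colClasses = "character",
                        check.names = TRUE)
  mandatory <- c("frame", "x_nm", "y_nm", "photons", "background",
                 "fit_sigma_nm", "n_merged")
  miss <- setdiff(mandatory, names(df))
  if (length(miss) > 0) {
    stop_smlm(sprintf("read_localizations: missing column %s", miss[1]))
  }
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & !(df[[col]] %in% c("NA", "", "NaN")))
    if (col %in% mandatory && length(bad) > 0) {
      stop_smlm(sprintf("read_localizations: malformed value '%s' in column %s at line %d",
                        df[[col]][bad[1]], col, n_meta + 1L + bad[1]))
    }
    if (length(bad) == 0) df[[col]] <- v    # numeric column
  }
  df$frame <- as.integer(df$frame)
  df$n_merged <- as.integer(df$n_merged)
  loc_table(df,
            pixel_size_nm = as.numeric(meta$pixel_size_nm %||% NA),
            frame_time_ms = as.numeric(meta$frame_time_ms %||% NA),
            source = meta$source %||% "file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ground-truth schedule as a localization CSV
#'
#' Aggregates a [simulate_switching()] schedule per burst (photon-weighted
#' frame assignment) and writes it in the standard localization-table
#' schema with an extra `emitter_id` column.
#'
#' @param schedule A `switching_schedule`.
#' @param camera The [camera_model()] used.
#' @param path File path.
#' @return The [loc_table()] written, invisibly.
#' @export
write_ground_truth <- function(schedule, camera, path) {
  gt <- schedule %>%
    group_by(.data$emitter_id, .data$burst_id) %>%
    summarise(frame = .data$frame[which.max(.data$photons)],
              x_nm = .data$x_nm[1], y_nm = .data$y_nm[1],
              photons = sum(.data$photons), .groups = "drop") %>%
    mutate(background = 0, fit_sigma_nm = NA_real_, n_merged = 1L)
  tab <- loc_table(gt, pixel_size_nm = camera$pixel_size_nm,
                   frame_time_ms = 1000 / camera$fps, source = "ground_truth")
  write_localizations(tab, path)
  invisible(tab)
}
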