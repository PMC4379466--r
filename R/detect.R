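#' Detect candidate single-molecule peaks in a residual frame
#'
#' Finds local maxima of the (zero-clamped) residual frame exceeding
#' `threshold_factor` times a robust noise estimate (1.4826 x median
#' absolute deviation of the frame). Peaks closer than 2 px are suppressed
#' greedily, keeping the brighter one; ties break toward smaller row, then
#' smaller column.
#'
#' When the background is spatially structured (e.g. a dense non-switching
#' population), the shot noise varies across the field; passing a per-pixel
#' `noise` map (such as the temporal MAD of the residual stack, see
#' [residual_noise_map()]) makes the threshold locally adaptive instead of
#' frame-global.
#'
#' @param residual_frame Numeric matrix (one frame of signed residuals).
#' @param threshold_factor Threshold in robust-sigma units (> 0, default 4).
#' @param noise Robust noise sigma: a scalar or a matrix matching the
#'   frame; default is the frame-global `1.4826 * MAD`.
#' @return A tibble with columns `row`, `col` (1-based pixel indices) and
#'   `value`, ordered by decreasing value.
#' @export
detect_candidates <- function(residual_frame, threshold_factor = 4, noise = NULL) {
  stopifnot(is.matrix(residual_frame), threshold_factor > 0)
  f <- pmax(residual_frame, 0)
  if (is.null(noise)) noise <- mad(residual_frame)   # 1.4826 * MAD
  thr <- threshold_factor * noise
  thr[!is.finite(thr) | thr <= 0] <- .Machine$double.eps
  nr <- nrow(f); nc <- ncol(f)
  cand <- which(f > thr)
  if (length(cand) == 0) {
    return(tibble(row = integer(), col = integer(), value = numeric()))
  }
  rr <- ((cand - 1) %% nr) + 1
  cc <- ((cand - 1) %/% nr) + 1
  # 3x3 local maximum test (strict against earlier neighbors breaks ties
  # toward smaller row/col)
  is_max <- vapply(seq_along(cand), function(i) {
    r <- rr[i]; c <- cc[i]; v <- f[r, c]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- f[r2, c2]
      if (w > v) return(FALSE)
      if (w == v && (dr < 0 || (dr == 0 && dc < 0))) return(FALSE)
    }
    TRUE
  }, logical(1))
  rr <- rr[is_max]; cc <- cc[is_max]
  vv <- f[cbind(rr, cc)]
  ord <- order(-vv, rr, cc)
  rr <- rr[ord]; cc <- cc[ord]; vv <- vv[ord]
  # greedy minimum-separation suppression (2 px)
  keep <- logical(length(rr))
  for (i in seq_along(rr)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (rr[keep] - rr[i])^2 + (cc[keep] - cc[i])^2
    if (all(d2 >= 4)) keep[i] <- TRUE
  }
  tibble(row = rr[keep], col = cc[keep], value = vv[keep])
}
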