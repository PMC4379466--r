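# Integrated-Gaussian Poisson spot model. All positions in ROI pixel
# units: pixel (row r, col c) covers x in [c-1, c), y in [r-1, r).

# per-axis pixel-integrated Gaussian and its partials
axis_mass <- function(edges, mu, sigma) {
  hi <- (edges - mu) / sigma
  lo <- (edges - 1 - mu) / sigma
  list(g = pnorm(hi) - pnorm(lo),
       dmu = -(dnorm(hi) - dnorm(lo)) / sigma,
       dsigma = -(hi * dnorm(hi) - lo * dnorm(lo)) / sigma)
}

# expected ROI image and its partials wrt (x0, y0, N, b, sigma)
spot_model <- function(theta, nr, nc) {
  x0 <- theta[1]; y0 <- theta[2]; N <- theta[3]; b <- theta[4]; s <- theta[5]
  ax <- axis_mass(seq_len(nc), x0, s)
  ay <- axis_mass(seq_len(nr), y0, s)
  g <- outer(ay$g, ax$g)
  list(mu = N * g + b,
       dx = N * outer(ay$g, ax$dmu),
       dy = N * outer(ay$dmu, ax$g),
       dN = g,
       db = matrix(1, nr, nc),
       ds = N * (outer(ay$dsigma, ax$g) + outer(ay$g, ax$dsigma)))
}

#' Maximum-likelihood Gaussian fit of a single-molecule spot
#'
#' Maximizes the Poisson likelihood of the model
#' `mu_i = N * G_i(x0, y0, sigma) + b` over the ROI, where `G_i` is a 2D
#' Gaussian integrated over pixel `i`. All five parameters (position,
#' photon count, background per pixel, PSF width) are free; `sigma` is
#' bounded to `[0.5, 2]` times the nominal PSF sigma, since section-induced
#' aberrations of unknown size can broaden the spot. Optimization uses
#' L-BFGS-B with analytic gradients from moment-based starting values.
#'
#' @param roi Odd-sized square matrix of nonnegative counts in photon
#'   units (convert camera counts first: `(counts - offset) / em_gain`).
#' @param psf A [psf_model()].
#' @param camera A [camera_model()] (supplies the pixel size).
#' @return A one-row tibble: `x_px`, `y_px` (ROI coordinates), `x_nm`,
#'   `y_nm`, `photons`, `background`, `fit_sigma_nm`, `log_likelihood`,
#'   `converged`. A degenerate ROI (all counts equal) is returned with
#'   `converged = FALSE` rather than an error.
#' @export
fit_spot_mle <- function(roi, psf, camera) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi), nrow(roi) %% 2 == 1)
  if (any(roi < 0)) stop_smlm("fit_spot_mle: ROI counts must be nonnegative")
  nr <- nrow(roi); nc <- ncol(roi)
  px <- camera$pixel_size_nm
  s_psf <- psf$sigma_nm / px
  fail <- function() tibble(x_px = NA_real_, y_px = NA_real_, x_nm = NA_real_,
                            y_nm = NA_real_, photons = NA_real_,
                            background = NA_real_, fit_sigma_nm = NA_real_,
                            log_likelihood = NA_real_, converged = FALSE)
  if (diff(range(roi)) == 0) return(fail())

  border <- c(roi[1, ], roi[nr, ], roi[, 1], roi[, nc])
  b0 <- max(median(border), 1e-3)
  n0 <- max(sum(roi) - b0 * nr * nc, 10)
  w <- pmax(roi - b0, 0)
  if (sum(w) <= 0) w <- roi
  x0 <- sum(w * matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)) / sum(w)
  y0 <- sum(w * matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)) / sum(w)
  theta0 <- c(x0, y0, n0, b0, s_psf)
  lower <- c(0, 0, 1e-2, 0, 0.5 * s_psf)
  upper <- c(nc, nr, Inf, Inf, 2 * s_psf)

  nll <- function(theta) {
    mu <- pmax(spot_model(theta, nr, nc)$mu, 1e-9)
    sum(mu - roi * log(mu))
  }
  gr <- function(theta) {
    m <- spot_model(theta, nr, nc)
    mu <- pmax(m$mu, 1e-9)
    wgt <- 1 - roi / mu
    c(sum(wgt * m$dx), sum(wgt * m$dy), sum(wgt * m$dN),
      sum(wgt * m$db), sum(wgt * m$ds))
  }
  opt <- tryCatch(
    optim(theta0, nll, gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 400, factr = 1e4, pgtol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(opt) || !all(is.finite(opt$par))) return(fail())
  th <- opt$par
  tibble(x_px = th[1], y_px = th[2], x_nm = th[1] * px, y_nm = th[2] * px,
         photons = th[3], background = th[4], fit_sigma_nm = th[5] * px,
         log_likelihood = -opt$value, converged = opt$convergence == 0)
}

#' Cramér-Rao lower bound for the spot model
#'
#' Numerically evaluates the Fisher information of the five-parameter
#' integrated-Gaussian Poisson model and returns the per-axis position
#' bound, the best-case standard deviation any unbiased localization
#' estimator can reach for a given photon count, background and PSF width.
#'
#' @param photons Expected photons in the spot.
#' @param background Expected background photons per pixel.
#' @param sigma_px PSF sigma in pixel units.
#' @param roi_size Odd ROI side length in pixels.
#' @return Lower-bound standard deviation of the x (or y) position
#'   estimate, in pixel units.
#' @export
crlb_sigma_px <- function(photons, background, sigma_px, roi_size = 7) {
  stopifnot(roi_size %% 2 == 1)
  c0 <- roi_size / 2
  m <- spot_model(c(c0, c0, photons, background, sigma_px), roi_size, roi_size)
  mu <- pmax(m$mu, 1e-12)
  J <- list(m$dx, m$dy, m$dN, m$db, m$ds)
  FI <- matrix(0, 5, 5)
  for (a in 1:5) for (b in a:5) {
    FI[a, b] <- FI[b, a] <- sum(J[[a]] * J[[b]] / mu)
  }
  sqrt(solve(FI)[1, 1])
}
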