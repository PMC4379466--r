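# Fixtures shared across test files. Everything is generated in code; the
# sizes are kept small enough for a default test run.

fix_psf <- psf_model()
fix_cam <- camera_model()
fix_sigma_px <- fix_psf$sigma_nm / fix_cam$pixel_size_nm

# Noiseless expected ROI from the internal forward model.
noiseless_roi <- function(x0, y0, N, b, sigma_px = fix_sigma_px, size = 7) {
  smlmpipe:::spot_model(c(x0, y0, N, b, sigma_px), size, size)$mu
}

# Uniform Poisson point field on [0, L]^2 nm at rho points/um^2.
poisson_field <- function(rho_um2, L_nm, seed) {
  set.seed(seed)
  n <- rpois(1, rho_um2 * (L_nm / 1000)^2)
  cbind(runif(n, 0, L_nm), runif(n, 0, L_nm))
}

# Edge-corrected interior mask: points whose K-th neighbor is closer than
# the field border.
interior_mask <- function(xy, K, L_nm) {
  kth <- RANN::nn2(xy, xy, k = K + 1)$nn.dists[, K + 1]
  bd <- pmin(xy[, 1], L_nm - xy[, 1], xy[, 2], L_nm - xy[, 2])
  kth <= bd
}

# A small localization table for IO / NeNA tests.
toy_loc_table <- function(n = 3) {
  loc_table(tibble::tibble(
    frame = seq_len(n), x_nm = 100 * seq_len(n) + 0.123456,
    y_nm = 50 * seq_len(n), photons = 500 + seq_len(n),
    background = 2.5, fit_sigma_nm = 120.25, n_merged = 1L
  ), pixel_size_nm = 80, frame_time_ms = 58.8235, source = "toy")
}

# Localization table of n_pairs adjacent-frame repeats jittered with
# per-axis sd sigma, plus optional extra isolated points per frame pair.
jittered_pair_table <- function(n_pairs, sigma, seed, spread_nm = 50000) {
  set.seed(seed)
  x <- runif(n_pairs, 0, spread_nm)
  y <- runif(n_pairs, 0, spread_nm)
  frames <- rep(seq_len(n_pairs), each = 2) * 2 - rep(c(1, 0), n_pairs)
  loc_table(tibble::tibble(
    frame = frames,
    x_nm = rep(x, each = 2) + rnorm(2 * n_pairs, 0, sigma),
    y_nm = rep(y, each = 2) + rnorm(2 * n_pairs, 0, sigma),
    photons = runif(2 * n_pairs, 100, 1000)
  ), pixel_size_nm = 80, frame_time_ms = 58.8, source = "pairs")
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
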