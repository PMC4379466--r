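test_that("knn_mean_distance matches hand-computable geometries", {
  # square grid, spacing a: the 4 nearest neighbors of an interior point
  # are all at distance a
  a <- 25
  g <- expand.grid(x = a * (0:6), y = a * (0:6))
  xy <- as.matrix(g)
  md <- knn_mean_distance(xy, 4)
  interior <- g$x > 0 & g$x < 6 * a & g$y > 0 & g$y < 6 * a
  expect_equal(md[interior], rep(a, sum(interior)))

  # three collinear points at 0, 10, 30 nm, K = 1
  xy3 <- cbind(c(0, 10, 30), 0)
  expect_equal(knn_mean_distance(xy3, 1), c(10, 10, 20))

  expect_error(knn_mean_distance(xy3, 5), "more than K")
})

test_that("knn_mean_distance equals the O(n^2) all-pairs oracle", {
  xy <- poisson_field(2000, 1500, seed = 301)
  expect_gt(nrow(xy), 21)
  md <- knn_mean_distance(xy, 20)
  # oracle: full distance matrix, sort each row, mean of the 20 smallest
  D <- as.matrix(dist(xy))
  oracle <- vapply(seq_len(nrow(xy)), function(i) {
    mean(sort(D[i, -i])[1:20])
  }, numeric(1))
  expect_equal(md, oracle, tolerance = 1e-12)
})

test_that("circular-symmetry normalization factor has its analytic values", {
  expect_equal(knn_norm_factor(1), 0.5)
  # strictly increasing in K
  cs <- vapply(1:30, knn_norm_factor, numeric(1))
  expect_true(all(diff(cs) > 0))
  # K = 20 against Monte-Carlo Poisson calibration, ~10^6 aggregate points
  set.seed(302)
  tot <- 0; cnt <- 0
  for (rep in 1:20) {
    L <- 5000; rho_nm <- 2000 / 1e6
    n <- rpois(1, rho_nm * L^2)
    xy <- cbind(runif(n, 0, L), runif(n, 0, L))
    ok <- interior_mask(xy, 20, L)
    tot <- tot + sum(knn_mean_distance(xy, 20)[ok] * sqrt(rho_nm))
    cnt <- cnt + sum(ok)
  }
  expect_gt(cnt, 5e5)
  expect_rel_error(tot / cnt, knn_norm_factor(20), 0.01)
})

test_that("local density recovers uniform Poisson fields within 5% (edge-corrected)", {
  for (rho in c(1000, 10000, 40000)) {
    xy <- poisson_field(rho, 3000, seed = 300 + rho)
    ok <- interior_mask(xy, 20, 3000)
    md <- knn_mean_distance(xy, 20)
    expect_rel_error(field_density(md[ok], 20), rho, 0.05)
  }
})

test_that("local density scales as expected and flags duplicates", {
  xy <- poisson_field(22000, 2000, seed = 310)
  md <- knn_mean_distance(xy, 20)
  rho1 <- local_density(md, 20)
  # doubling all coordinates dilutes density 4x
  rho2 <- local_density(knn_mean_distance(xy * 2, 20), 20)
  expect_equal(mean(rho2, na.rm = TRUE), mean(rho1, na.rm = TRUE) / 4,
               tolerance = 1e-10)
  # mean_dist equal to c_K nm means 1 point per nm^2
  expect_equal(local_density(knn_norm_factor(20), 20), 1e6 * 1)
  expect_warning(local_density(c(10, 0), 20), "duplicate")
})

test_that("Nyquist resolution follows the sampling-theorem arithmetic", {
  expect_equal(nyquist_resolution(10000), 20)
  expect_equal(nyquist_resolution(1600), 50)
  expect_equal(nyquist_resolution(22000), 2 / sqrt(0.022))
})

test_that("structural resolution combines accuracy and sampling in quadrature", {
  rn <- nyquist_resolution(22000)
  r <- structural_resolution(17, rn)
  expect_equal(r, sqrt((2.35 * 17)^2 + rn^2))
  expect_gt(r, 40); expect_lt(r, 50)
  # limits
  expect_equal(structural_resolution(0, rn), rn)
  expect_equal(structural_resolution(17, 0), 2.35 * 17)
  # monotone non-decreasing in both arguments
  s <- seq(0, 30, by = 5); ny <- seq(0, 60, by = 10)
  expect_true(all(diff(structural_resolution(s, 20)) >= 0))
  expect_true(all(diff(structural_resolution(15, ny)) >= 0))
})

test_that("molecules per diffraction-limited area reproduce the printed counts", {
  expect_gt(molecules_per_dl_area(22000), 1000)
  expect_equal(molecules_per_dl_area(22000), 22000 * pi * 0.125^2)
  expect_equal(round(molecules_per_dl_area(40000)), 1963)
  expect_equal(molecules_per_dl_area(0), 0)
})

test_that("estimate_resolution produces an aligned per-point table with border flags", {
  xy <- poisson_field(5000, 2500, seed = 320)
  tab <- loc_table(tibble::tibble(frame = seq_len(nrow(xy)), x_nm = xy[, 1],
                                  y_nm = xy[, 2], photons = 500))
  attr(tab, "field_of_view") <- c(2500, 2500)
  res <- estimate_resolution(tab, sigma_loc = 15, K = 20)
  expect_equal(nrow(res), nrow(tab))
  expect_true(all(res$structural_nm >= res$nyquist_nm, na.rm = TRUE))
  expect_true(all(res$structural_nm >= 2.35 * 15 - 1e-9, na.rm = TRUE))
  expect_true(any(res$border))          # corners must be flagged
  g <- glance(res)
  expect_rel_error(g$field_rho_um2, 5000, 0.1)
  expect_equal(g$mean_structural_nm,
               mean(res$structural_nm[!res$border & !is.na(res$rho_um2)]))
})

test_that("end-to-end structural resolution on a known field matches closed form", {
  # emitters at rho, localizations jittered with sd sigma: summary
  # structural resolution should match sqrt((2.35 sigma)^2 + (2/sqrt(rho))^2)
  sigma <- 15; rho <- 8000
  xy <- poisson_field(rho, 3000, seed = 330)
  set.seed(331)
  obs <- xy + rnorm(length(xy), 0, sigma)
  tab <- loc_table(tibble::tibble(frame = seq_len(nrow(obs)), x_nm = obs[, 1],
                                  y_nm = obs[, 2], photons = 500))
  attr(tab, "field_of_view") <- c(3000, 3000)
  res <- estimate_resolution(tab, sigma_loc = sigma, K = 20)
  g <- glance(res)
  closed <- structural_resolution(sigma, nyquist_resolution(rho))
  expect_rel_error(g$mean_structural_nm, closed, 0.1)
})
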