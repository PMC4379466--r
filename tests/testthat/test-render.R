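make_table <- function(xy, fov) {
  tab <- loc_table(tibble::tibble(frame = seq_len(nrow(xy)), x_nm = xy[, 1],
                                  y_nm = xy[, 2], photons = 500))
  attr(tab, "field_of_view") <- fov
  tab
}

membrane_table <- function(seed = 701, spacing = 300, fov = c(4000, 2000)) {
  em <- generate_structure("membrane_pair",
                           list(spacing_nm = spacing, linear_density_um = 400,
                                length_nm = 3200),
                           fov, seed = seed)
  set.seed(seed + 1)
  xy <- cbind(em$x_nm, em$y_nm) + rnorm(2 * nrow(em), 0, 15)
  make_table(xy, fov)
}

test_that("each localization carries unit mass in the rendering", {
  tab <- make_table(cbind(500, 400), c(1000, 800))
  res <- estimate_resolution(make_table(poisson_field(5000, 1000, 702), c(1000, 1000)),
                             sigma_loc = 15)[1, ]
  # single-point rendering needs a matching one-row density result
  res$nyquist_nm <- 20
  sr <- render_sr_image(tab, res, render_settings(out_pixel_nm = 5))
  expect_lt(abs(sum(sr$intensity) - 1), 1e-3)
  pk <- which(sr$intensity == max(sr$intensity), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(80, 100))   # y = 400 nm -> row 80, x = 500 -> col 100
})

test_that("total rendered mass equals the record count", {
  xy <- poisson_field(3000, 1500, seed = 703) + 200
  tab <- make_table(xy, c(2000, 2000))
  dres <- estimate_resolution(tab, sigma_loc = 15)
  sr <- render_sr_image(tab, dres, render_settings(out_pixel_nm = 10))
  expect_rel_error(sum(sr$intensity), nrow(tab), 0.01)
  wf <- render_widefield_reference(tab, out_pixel_nm = 10,
                                   field_of_view = c(3000, 3000))
  expect_rel_error(sum(wf), nrow(tab), 0.01)
  expect_error(render_sr_image(tab[-1, ], dres), "misaligned")
})

test_that("a 300 nm membrane pair resolves in SR but not in wide field", {
  tab <- membrane_table()
  dres <- estimate_resolution(tab, sigma_loc = 15)
  sr <- render_sr_image(tab, dres, render_settings(out_pixel_nm = 10))
  wf <- render_widefield_reference(tab, widefield_fwhm_nm = 250, out_pixel_nm = 10)
  # profile across the membranes at mid-length
  profile_peaks <- function(img) {
    col <- round(ncol(img) / 2)
    count_profile_peaks(rowMeans(img[, (col - 10):(col + 10)]))
  }
  expect_equal(profile_peaks(sr$intensity), 2)
  expect_equal(profile_peaks(wf), 1)
})

test_that("an infinite kernel floor degrades SR to the wide-field image", {
  tab <- membrane_table(seed = 704)
  dres <- estimate_resolution(tab, sigma_loc = 15)
  fwhm <- 250
  sr <- render_sr_image(tab, dres,
                        render_settings(out_pixel_nm = 10, kernel_floor_nm = fwhm / 2.35))
  wf <- render_widefield_reference(tab, widefield_fwhm_nm = fwhm, out_pixel_nm = 10)
  expect_lt(max(abs(sr$intensity - wf)), 1e-6 * max(wf))
})

test_that("density color mapping is monotone and the legend carries both scales", {
  tab <- membrane_table(seed = 705)
  dres <- estimate_resolution(tab, sigma_loc = 15)
  sr <- render_sr_image(tab, dres, render_settings(out_pixel_nm = 10))
  expect_equal(nrow(sr$legend), 7)
  expect_true(all(diff(sr$legend$rho_um2) > 0))
  expect_true(all(diff(sr$legend$nyquist_nm) < 0))   # denser -> finer resolution
  expect_equal(dim(sr$rgb)[3], 3)
  expect_true(all(sr$rgb >= 0 & sr$rgb <= 1))
})

test_that("empty tables render to a zero wide-field raster", {
  tab <- loc_table(tibble::tibble(frame = integer(), x_nm = numeric(),
                                  y_nm = numeric(), photons = numeric()))
  wf <- render_widefield_reference(tab, field_of_view = c(500, 500))
  expect_true(all(wf == 0))
})

test_that("rendered artifacts write to TIFF/PNG/JSON", {
  tab <- membrane_table(seed = 706)
  dres <- estimate_resolution(tab, sigma_loc = 15)
  sr <- render_sr_image(tab, dres, render_settings(out_pixel_nm = 20))
  base <- tempfile()
  paths <- write_sr_image(sr, base)
  expect_true(file.exists(paste0(base, ".tif")))
  expect_true(file.exists(paste0(base, "_legend.json")))
  leg <- jsonlite::read_json(paste0(base, "_legend.json"), simplifyVector = TRUE)
  expect_equal(leg$pixel_nm, 20)
})
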