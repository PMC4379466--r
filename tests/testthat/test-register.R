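set.seed(401)
ref_points <- matrix(runif(16, 0, 4000), 8, 2)

test_that("identical point sets give the identity transform with zero residual", {
  tr <- estimate_transform(list(src = ref_points, dst = ref_points), "similarity")
  expect_equal(tr$A, diag(2), tolerance = 1e-12)
  expect_equal(tr$b, c(0, 0), tolerance = 1e-9)
  expect_equal(tr$residual_rms, 0, tolerance = 1e-9)
})

test_that("a known similarity (scale 1.6, rotation 30 deg, translation (100, -50)) is recovered", {
  truth <- similarity_transform(1.6, 30, c(100, -50))
  dst <- apply_transform(ref_points, truth)
  for (kind in c("similarity", "affine")) {
    est <- estimate_transform(list(src = ref_points, dst = dst), kind)
    expect_lt(max(abs(est$A - truth$A)) / 1.6, 1e-6)
    expect_lt(max(abs(est$b - truth$b)) / 100, 1e-6)
    expect_lt(est$residual_rms, 1e-6)
  }
  g <- glance(estimate_transform(list(src = ref_points, dst = dst), "similarity"))
  expect_equal(g$scale, 1.6, tolerance = 1e-9)
  expect_equal(g$rotation_deg, 30, tolerance = 1e-9)
})

test_that("anisotropic scaling is affine-exact but leaves similarity residual", {
  A <- diag(c(1.5, 1.0))
  dst <- ref_points %*% t(A)
  aff <- estimate_transform(list(src = ref_points, dst = dst), "affine")
  sim <- estimate_transform(list(src = ref_points, dst = dst), "similarity")
  expect_lt(aff$residual_rms, 1e-9)
  expect_gt(sim$residual_rms, 1)
})

test_that("affine residual never exceeds similarity residual (nested models)", {
  set.seed(402)
  for (i in 1:10) {
    src <- matrix(runif(12, 0, 1000), 6, 2)
    dst <- src %*% matrix(c(1.2, 0.1, -0.05, 0.9), 2, 2) + matrix(rnorm(12, 0, 5), 6, 2)
    aff <- estimate_transform(list(src = src, dst = dst), "affine")
    sim <- estimate_transform(list(src = src, dst = dst), "similarity")
    expect_lte(aff$residual_rms, sim$residual_rms + 1e-12)
  }
})

test_that("similarity estimation is invariant to a global rotation of both point sets", {
  truth <- similarity_transform(2, 45, c(10, 20))
  dst <- apply_transform(ref_points, truth)
  rot <- similarity_transform(1, 77)
  est1 <- estimate_transform(list(src = ref_points, dst = dst), "similarity")
  est2 <- estimate_transform(list(src = apply_transform(ref_points, rot),
                                  dst = apply_transform(dst, rot)), "similarity")
  expect_equal(sqrt(det(est2$A)), sqrt(det(est1$A)), tolerance = 1e-9)
  expect_equal(est2$residual_rms, est1$residual_rms, tolerance = 1e-9)
})

test_that("preconditions are enforced", {
  expect_error(estimate_transform(list(src = ref_points[1, , drop = FALSE],
                                       dst = ref_points[1, , drop = FALSE]),
                                  "similarity"), "at least 2")
  expect_error(estimate_transform(list(src = ref_points[1:2, ], dst = ref_points[1:2, ]),
                                  "affine"), "at least 3")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_transform(list(src = line, dst = line), "affine"), "collinear")
  expect_error(transform2d(matrix(c(1, 2, 2, 4), 2, 2), c(0, 0)), "singular")
})

test_that("point transforms form a group: forward-then-inverse is the identity", {
  tr <- similarity_transform(1.6, 30, c(100, -50))
  back <- apply_transform(apply_transform(ref_points, tr), invert_transform(tr))
  expect_lt(max(abs(back - ref_points)), 1e-9)
  # identity on points is bit-exact up to arithmetic
  id <- transform2d(diag(2), c(0, 0))
  expect_equal(apply_transform(ref_points, id), ref_points)
})

test_that("raster warping matches an exact roll for integer translations", {
  set.seed(403)
  img <- matrix(runif(400), 20, 20)
  tr <- transform2d(diag(2), c(3, 2))   # +3 px in x (cols), +2 px in y (rows)
  warped <- apply_transform(img, tr, out_dim = dim(img))
  expect_equal(warped[3:20, 4:20], img[1:18, 1:17], tolerance = 1e-12)
  # identity warp reproduces the raster
  id <- transform2d(diag(2), c(0, 0))
  expect_equal(apply_transform(img, id, out_dim = dim(img)), img, tolerance = 1e-12)
})

test_that("transform JSON serialization round-trips", {
  tr <- estimate_transform(list(src = ref_points,
                                dst = apply_transform(ref_points,
                                                      similarity_transform(1.3, -20, c(5, 7)))),
                           "affine")
  path <- tempfile(fileext = ".json")
  write_transform(tr, path)
  tr2 <- read_transform(path)
  expect_equal(tr2$A, tr$A, tolerance = 1e-12)
  expect_equal(tr2$b, tr$b, tolerance = 1e-12)
  expect_equal(tr2$kind, tr$kind)
})

test_that("overlay limits: alpha 0 keeps the EM image, alpha 1 shows the SR layer", {
  em <- matrix(seq(0, 1, length.out = 900), 30, 30)
  sr <- matrix(0, 40, 40); sr[15:25, 15:25] <- 1
  attr(sr, "pixel_nm") <- 10
  tr <- similarity_transform(0.1, 0, c(0, 0))   # nm -> px
  ov0 <- make_overlay(sr, em, tr, alpha = 0)
  rng <- range(em)
  expect_equal(ov0[, , 1], (em - rng[1]) / diff(rng), tolerance = 1e-12)
  ov1 <- make_overlay(sr, em, tr, alpha = 1)
  # center of the SR support maps to EM px around (20, 20)
  expect_equal(ov1[20, 20, 1], 1, tolerance = 1e-6)
})

test_that("line profiles: constants, inversion and endpoint validation", {
  img <- matrix(3.5, 15, 15)
  lp <- line_profile(img, c(2, 2), c(12, 12), width = 3)
  expect_true(all(abs(lp$intensity - 3.5) < 1e-12))
  expect_true(all(diff(lp$position_nm) > 0))
  lp_inv <- line_profile(img, c(2, 2), c(12, 12), width = 3, invert = TRUE)
  expect_true(all(abs(lp_inv$intensity) < 1e-12))
  expect_error(line_profile(img, c(2, 2), c(2, 2)), "distinct")
  expect_error(line_profile(img, c(-5, 2), c(12, 12)), "outside")
})
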