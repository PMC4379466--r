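test_that("temporal-median background subtraction removes constant backgrounds", {
  cam <- camera_model()
  stack <- array(37.5, c(8, 8, 30))
  res <- subtract_background(movie_stack(stack, cam), half_window = 5)
  expect_true(all(res$data == 0))
  # idempotence: a second pass leaves the residual unchanged
  res2 <- subtract_background(movie_stack(res$data - min(res$data), cam), 5)
  expect_true(all(res2$data == 0))
  expect_error(subtract_background(movie_stack(stack, cam), 20), "window larger")
})

test_that("a short burst survives the median window", {
  cam <- camera_model()
  stack <- array(10, c(6, 6, 41))
  stack[3, 3, 20:22] <- 10 + 250   # 3-frame burst, half_window 10 (21-frame window)
  res <- subtract_background(movie_stack(stack, cam), half_window = 10)
  expect_rel_error(res$data[3, 3, 21], 250, 0.05)
  # pixels away from the burst stay flat
  expect_true(all(abs(res$data[1, 1, ]) < 1e-9))
})

test_that("a linear temporal ramp leaves bounded residuals", {
  cam <- camera_model()
  s <- 2.5; T <- 60; h <- 10
  stack <- array(rep(100 + s * seq_len(T), each = 16), c(4, 4, T))
  res <- subtract_background(movie_stack(stack, cam), half_window = h)
  expect_lte(max(abs(res$data)), s * h + 1e-9)
})

test_that("candidate detection finds isolated peaks and respects separation", {
  expect_equal(nrow(detect_candidates(matrix(0, 15, 15))), 0)
  frame <- matrix(0, 21, 21)
  spot <- noiseless_roi(3.5, 3.5, 300, 0)
  frame[8:14, 8:14] <- spot
  cands <- detect_candidates(frame, 4)
  expect_equal(nrow(cands), 1)
  expect_equal(c(cands$row, cands$col), c(11, 11))
  # two spots 10 px apart resolve into two peaks
  frame2 <- matrix(0, 25, 25)
  frame2[6:12, 6:12] <- spot
  frame2[16:22, 6:12] <- spot
  expect_equal(nrow(detect_candidates(frame2, 4)), 2)
  # 1 px apart collapses to one peak
  frame3 <- matrix(0, 25, 25)
  frame3[6:12, 6:12] <- spot
  frame3[7:13, 6:12] <- frame3[7:13, 6:12] + spot
  expect_equal(nrow(detect_candidates(frame3, 4)), 1)
})

test_that("the MLE fit recovers noiseless spots and matches a grid-search oracle", {
  cam <- camera_model(); psf <- psf_model()
  # centered spot: symmetry pins the position
  roi_c <- noiseless_roi(3.5, 3.5, 500, 5)
  fit_c <- fit_spot_mle(roi_c, psf, cam)
  expect_lt(abs(fit_c$x_px - 3.5), 1e-3)
  expect_lt(abs(fit_c$y_px - 3.5), 1e-3)
  # off-center spots against an exhaustive 0.02 px likelihood grid with the
  # generating N, b, sigma (independent pnorm-based model)
  grid_loglik <- function(roi, x0, y0, N, b, s) {
    gx <- pnorm((1:7 - x0) / s) - pnorm((0:6 - x0) / s)
    gy <- pnorm((1:7 - y0) / s) - pnorm((0:6 - y0) / s)
    mu <- N * outer(gy, gx) + b
    sum(roi * log(mu) - mu)
  }
  for (truth in list(c(3.2, 3.8), c(3.9, 3.1), c(3.45, 3.55))) {
    roi <- noiseless_roi(truth[1], truth[2], 420, 7)
    fit <- fit_spot_mle(roi, psf, cam)
    gxs <- seq(truth[1] - 0.5, truth[1] + 0.5, by = 0.02)
    gys <- seq(truth[2] - 0.5, truth[2] + 0.5, by = 0.02)
    ll <- outer(gys, gxs, Vectorize(function(y, x)
      grid_loglik(roi, x, y, 420, 7, fix_sigma_px)))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    expect_lt(abs(fit$x_px - gxs[best[2]]), 0.02 + 1e-9)
    expect_lt(abs(fit$y_px - gys[best[1]]), 0.02 + 1e-9)
  }
  # degenerate flat ROI is flagged, not thrown
  flat <- matrix(5, 7, 7)
  expect_false(fit_spot_mle(flat, psf, cam)$converged)
})

test_that("repeated noisy fits reach the Cramer-Rao bound within 15%", {
  cam <- camera_model(); psf <- psf_model(sigma_nm = 130)
  s_px <- 130 / cam$pixel_size_nm
  mu <- smlmpipe:::spot_model(c(3.5, 3.5, 500, 10, s_px), 7, 7)$mu
  set.seed(601)
  err <- replicate(500, {
    f <- fit_spot_mle(matrix(rpois(49, mu), 7, 7), psf, cam)
    c(f$x_px - 3.5, f$y_px - 3.5)
  })
  emp_sd <- sd(as.numeric(err))
  # independent numerical CRLB: finite-difference Fisher information
  num_crlb <- {
    theta <- c(3.5, 3.5, 500, 10, s_px)
    model <- function(th) {
      gx <- pnorm((1:7 - th[1]) / th[5]) - pnorm((0:7 - th[1])[1:7] / th[5])
      gy <- pnorm((1:7 - th[2]) / th[5]) - pnorm((0:7 - th[2])[1:7] / th[5])
      th[3] * outer(gy, gx) + th[4]
    }
    eps <- 1e-5
    J <- sapply(1:5, function(a) {
      tp <- theta; tp[a] <- tp[a] + eps
      tm <- theta; tm[a] <- tm[a] - eps
      as.numeric(model(tp) - model(tm)) / (2 * eps)
    })
    FI <- t(J) %*% (J / as.numeric(model(theta)))
    sqrt(solve(FI)[1, 1])
  }
  expect_rel_error(emp_sd, num_crlb, 0.15)
  # the analytic-gradient helper agrees with the numerical bound
  expect_rel_error(crlb_sigma_px(500, 10, s_px), num_crlb, 0.01)
})

test_that("localize_movie recovers simulated emitters with high recall and precision", {
  fov <- c(7680, 7680)
  cam <- camera_model(); psf <- psf_model()
  em <- generate_structure("uniform", list(density_um2 = 300 / 58.98), fov, seed = 611)
  sch <- simulate_switching(em, switching_params(recovery_rate = 0.25, bleach_prob = 0.3),
                            120, cam, seed = 612)
  mv <- render_movie(sch, psf, cam, background = 2, noise = TRUE, seed = 613)
  locs <- suppressWarnings(suppressMessages(localize_movie(mv, psf)))
  gt <- sch %>%
    dplyr::group_by(.data$emitter_id, .data$burst_id) %>%
    dplyr::summarise(frame = .data$frame[which.max(.data$photons)],
                     x = .data$x_nm[1], y = .data$y_nm[1],
                     pmax = max(.data$photons), .groups = "drop")
  # precision: every localization near a truly active emitter (100 nm, +/-2
  # frames; merged records carry their first frame)
  prec <- vapply(seq_len(nrow(locs)), function(i) {
    sel <- abs(gt$frame - locs$frame[i]) <= 2
    any((gt$x[sel] - locs$x_nm[i])^2 + (gt$y[sel] - locs$y_nm[i])^2 <= 100^2)
  }, logical(1))
  expect_gte(mean(prec), 0.95)
  # recall on clearly detectable bursts (>= 150 photons in their best frame)
  # whose ROI fits inside the field
  m <- 4 * cam$pixel_size_nm
  gt_big <- gt[gt$pmax >= 150 & gt$x > m & gt$x < fov[1] - m &
                 gt$y > m & gt$y < fov[2] - m, ]
  rec <- vapply(seq_len(nrow(gt_big)), function(i) {
    sel <- abs(locs$frame - gt_big$frame[i]) <= 2
    any(sel & (locs$x_nm - gt_big$x[i])^2 + (locs$y_nm - gt_big$y[i])^2 <= 100^2)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("a zero-emitter movie yields at most one false localization per 100 frames", {
  cam <- camera_model(); psf <- psf_model()
  em0 <- generate_structure("uniform", list(density_um2 = 0), c(7680, 7680), seed = 614)
  sch0 <- simulate_switching(em0, switching_params(recovery_rate = 0), 100, cam, seed = 614)
  mv0 <- render_movie(sch0, psf, cam, background = 2, noise = TRUE, seed = 615)
  locs0 <- suppressWarnings(suppressMessages(localize_movie(mv0, psf)))
  expect_lte(nrow(locs0), 1)
})

test_that("merging fuses consecutive-frame bursts and conserves photons", {
  tab <- tibble::tibble(
    frame = c(1L, 2L, 2L, 5L),
    x_nm = c(1000, 1010, 4000, 1000),
    y_nm = c(1000, 995, 4000, 1000),
    photons = c(300, 200, 400, 150))
  merged <- merge_consecutive(tab, radius_nm = 50)
  expect_equal(nrow(merged), 3)
  expect_equal(sum(merged$photons), sum(tab$photons))
  rec <- merged[merged$n_merged == 2, ]
  expect_equal(rec$x_nm, (1000 * 300 + 1010 * 200) / 500)
  expect_equal(rec$frame, 1L)
  # merging never increases the record count
  expect_lte(nrow(merge_consecutive(tab, radius_nm = 1e6)), nrow(tab))
})
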