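# Continuous-time oracle for burst discretization, independent of the
# simulator: draw an activation phase uniform over the frame period and an
# exponential on-time, and count the integration windows the burst overlaps.
oracle_burst_frames <- function(n, mean_on_ms, period_ms, expo_ms, seed) {
  set.seed(seed)
  t0 <- runif(n, 0, period_ms)
  dur <- rexp(n, 1 / mean_on_ms)
  t1 <- t0 + dur
  vapply(seq_len(n), function(i) {
    f <- floor(t0[i] / period_ms):floor(t1[i] / period_ms)
    lo <- f * period_ms
    sum(pmin(t1[i], lo + expo_ms) - pmax(t0[i], lo) > 0)
  }, numeric(1))
}

burst_lengths <- function(schedule) {
  sw <- schedule[schedule$switching, ]
  as.numeric(table(paste(sw$emitter_id, sw$burst_id)))
}

test_that("no recovery and no non-switching population means an empty schedule", {
  em <- generate_structure("uniform", list(density_um2 = 50), c(2000, 2000), seed = 1)
  sch <- simulate_switching(em, switching_params(recovery_rate = 0), 50,
                            camera_model(), seed = 1)
  expect_equal(nrow(sch), 0)
})

test_that("burst frame counts match the continuous-time oracle", {
  em <- generate_structure("uniform", list(density_um2 = 2000 / 25), c(5000, 5000), seed = 10)
  cam <- camera_model(integration_ms = 50, fps = 17)
  sch <- simulate_switching(em, switching_params(recovery_rate = 1, bleach_prob = 0,
                                                 mean_on_time_ms = 60),
                            100, cam, seed = 11)
  obs <- burst_lengths(sch)
  expect_gt(length(obs), 1e4)
  ora <- oracle_burst_frames(5e4, 60, 1000 / 17, 50, seed = 12)
  ora <- ora[ora >= 1]   # unobservable dead-time bursts never enter a schedule
  # mean frames per burst within 2%
  expect_rel_error(mean(obs), mean(ora), 0.02)
  # Kolmogorov-Smirnov distance of the two length distributions
  xs <- 0:max(obs, ora)
  ks <- max(abs(ecdf(obs)(xs) - ecdf(ora)(xs)))
  expect_lt(ks, 0.02)
})

test_that("per-burst photon draws respect the detected-photon range", {
  em <- generate_structure("uniform", list(density_um2 = 20), c(5000, 5000), seed = 13)
  sch <- simulate_switching(em, switching_params(recovery_rate = 0.5),
                            200, camera_model(), seed = 14)
  expect_true(all(sch$burst_photons[sch$switching] >= 100))
  expect_true(all(sch$burst_photons[sch$switching] <= 1000))
  # per-frame photons never exceed the burst draw
  expect_true(all(sch$photons[sch$switching] <= sch$burst_photons[sch$switching] + 1e-9))
})

test_that("the non-switching population bleaches exponentially", {
  em <- generate_structure("uniform", list(density_um2 = 3000 / 25), c(5000, 5000), seed = 15)
  rate <- 0.3
  cam <- camera_model()
  sch <- simulate_switching(em, switching_params(nonswitching_fraction = 1,
                                                 nonswitching_bleach_rate = rate),
                            150, cam, seed = 16)
  per_frame <- tapply(sch$photons, factor(sch$frame, levels = 1:150), sum)
  per_frame[is.na(per_frame)] <- 0
  t_s <- (seq_len(150) - 0.5) / cam$fps
  keep <- per_frame > 0 & t_s < 10
  fit <- lm(log(per_frame[keep]) ~ t_s[keep])
  expect_rel_error(-coef(fit)[2], rate, 0.10)
})

test_that("identical seeds give bit-identical schedules and movies", {
  em <- generate_structure("line", list(linear_density_um = 60), c(3000, 3000), seed = 17)
  sw <- switching_params(recovery_rate = 0.5)
  cam <- camera_model(); psf <- psf_model()
  s1 <- simulate_switching(em, sw, 40, cam, seed = 18)
  s2 <- simulate_switching(em, sw, 40, cam, seed = 18)
  expect_identical(s1$photons, s2$photons)
  m1 <- render_movie(s1, psf, cam, background = 2, noise = TRUE, seed = 19)
  m2 <- render_movie(s2, psf, cam, background = 2, noise = TRUE, seed = 19)
  expect_identical(m1$data, m2$data)
})
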