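test_that("displacement is measured from each track's first sample", {
  d <- displacement_series(stationary_track())
  expect_true(all(d$L_um == 0))

  d <- displacement_series(straight_track(10, dt = 0.25, n = 9))  # 2 hr at 10 um/hr
  expect_equal(d$L_um[nrow(d)], 20)
  expect_equal(d$L2_um2[nrow(d)], 400)

  d <- displacement_series(track_from_xy(c(0, 3), c(0, 4)))
  expect_equal(d$L_um[2], 5)
})

test_that("ensemble MSD averages squared displacements over live tracks", {
  m <- ensemble_msd(bind_tracks(list(stationary_track())), t_max = 2)
  expect_true(all(m$mean_sq_um2 == 0))
  expect_equal(m$mean_sq_um2[1], 0)

  # L^2 = 100 t and 200 t -> mean 150 t
  tt <- seq(0, 2, 0.25)
  e <- bind_tracks(list(track_from_xy(sqrt(100 * tt), 0 * tt, id = "a"),
                        track_from_xy(sqrt(200 * tt), 0 * tt, id = "b")))
  m <- ensemble_msd(e, t_max = 2)
  expect_equal(m$mean_sq_um2, 150 * m$t_hr, tolerance = 1e-9)
  expect_true(all(m$n_live == 2))

  expect_error(ensemble_msd(e, t_max = -1), "positive",
               class = "stemwalk_argument_error")
})

test_that("the zero-intercept fit recovers exact diffusive series", {
  tt <- seq(0, 7, 0.25)
  fit <- fit_diffusivity(tibble::tibble(t_hr = tt, mean_sq_um2 = 159.6 * tt))
  expect_equal(fit$D, 79.8, tolerance = 1e-12)
  expect_equal(fit$slope, 159.6, tolerance = 1e-12)
  expect_equal(fit$D_ci95, 0, tolerance = 1e-9)

  fit <- fit_diffusivity(tibble::tibble(t_hr = tt, mean_sq_um2 = 98.2 * tt))
  expect_equal(fit$D, 49.1, tolerance = 1e-12)

  fit <- fit_diffusivity(tibble::tibble(t_hr = tt, mean_sq_um2 = 0 * tt))
  expect_equal(fit$D, 0)

  expect_error(fit_diffusivity(tibble::tibble(t_hr = c(0, 1), mean_sq_um2 = c(0, 1))),
               "fewer than 3", class = "stemwalk_fit_error")
  expect_warning(fit_diffusivity(tibble::tibble(t_hr = tt, mean_sq_um2 = -2 * tt)),
                 "negative")
})

test_that("the closed-form slope agrees with brute-force 1-D minimization", {
  for (seed in 1:20) {
    msd <- withr::with_seed(seed, {
      tt <- seq(0, 7, 0.25)
      tibble::tibble(t_hr = tt,
                     mean_sq_um2 = stats::runif(1, 10, 300) * tt +
                       stats::rnorm(length(tt), 0, 30))
    })
    fit <- fit_diffusivity(msd)
    oracle <- stats::optimize(
      function(s) sum((msd$mean_sq_um2 - s * msd$t_hr)^2),
      interval = c(-1000, 1000), tol = 1e-12)$minimum
    expect_equal(fit$slope, oracle, tolerance = 1e-7)
  }
})

test_that("step lengths report per-axis medians, correlation and identity conventions", {
  # every step (3, 3): equal medians, identical samples -> p = 1
  e <- bind_tracks(list(track_from_xy(cumsum(rep(3, 8)), cumsum(rep(3, 8)))))
  st <- step_lengths(e)
  expect_equal(st$summary$median_um, c(3, 3))
  expect_equal(st$ks_p, 1)
  expect_equal(st$mwu_p, 1)

  # alternating (5,0), (0,5): equal medians, perfectly anticorrelated
  dx <- rep(c(5, 0), 10); dy <- rep(c(0, 5), 10)
  e <- bind_tracks(list(track_from_xy(c(0, cumsum(dx)), c(0, cumsum(dy)))))
  st <- step_lengths(e)
  expect_equal(st$summary$median_um[1], st$summary$median_um[2])
  expect_equal(st$pearson_r, -1)

  expect_error(step_lengths(two_track_ensemble()[0, ]),
               class = "stemwalk_argument_error")
})

test_that("steps pooled over many walks pass the isotropy tests", {
  tau <- 0.6
  w <- walk_params(v = 16.25, tau = tau, dt = 4 * tau, duration = 4 * tau * 110)
  e <- bind_tracks(lapply(1:100, function(i)
    simulate_walk(w, seed = 3000 + i, track_id = sprintf("w%03d", i))))
  st <- step_lengths(e)
  expect_gte(nrow(st$steps), 1e4)
  expect_lt(abs(st$pearson_r), 0.1)
  expect_gt(st$ks_p, 0.01)
  expect_gt(st$mwu_p, 0.01)
})

test_that("instantaneous speeds pool per-frame displacements over cells", {
  e <- bind_tracks(list(straight_track(12, n = 9)))
  expect_equal(instantaneous_speeds(e)$median, 12)

  e <- bind_tracks(list(stationary_track(), stationary_track(id = "2", at = c(9, 9))))
  expect_equal(instantaneous_speeds(e)$median, 0)

  # unstained preset: pooled median within 15% of the path speed
  p <- preset_params("unstained")
  w <- walk_params(v = p$walk$v, tau = p$walk$tau, dt = 0.25, duration = 7)
  e <- bind_tracks(lapply(1:60, function(i)
    simulate_walk(w, seed = 500 + i, track_id = sprintf("w%02d", i))))
  sp <- instantaneous_speeds(e)
  expect_lt(abs(sp$median - 16.25) / 16.25, 0.15)
  expect_equal(nrow(sp$per_cell), 60)
})

test_that("correlation time is the monotone map tau = 2D/v^2 of the speed distribution", {
  expect_equal(round(correlation_time(79.8, 16.25)$tau_median_hr, 1), 0.6)
  expect_equal(round(correlation_time(49.1, 11.51)$tau_median_hr, 1), 0.7)
  expect_equal(correlation_time(0, c(1, 2, 3))$tau_median_hr, 0)

  v <- withr::with_seed(1, stats::rlnorm(500, log(16), 0.4))
  ct <- correlation_time(80, v)
  expect_equal(ct$tau_median_hr, 2 * 80 / median(v)^2, tolerance = 1e-12)
  # quartiles map from the opposite speed quartiles
  expect_equal(ct$tau_q25_hr, 2 * 80 / quantile(v, 0.75)^2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(ct$tau_q25_hr <= ct$tau_median_hr &&
              ct$tau_median_hr <= ct$tau_q75_hr)

  expect_error(correlation_time(80, c(0, 0, 0)), class = "stemwalk_argument_error")
})

test_that("directionality is 1 for straight paths, 0 on return, in [0,1] and decays", {
  d <- directionality(straight_track(10, n = 9))
  expect_equal(d$directionality, rep(1, nrow(d)))

  # out and back: zero at the return time
  out_back <- track_from_xy(c(0, 5, 10, 5, 0), rep(0, 5))
  d <- directionality(out_back)
  expect_equal(d$directionality[d$elapsed_hr == 1], 0)
  expect_true(all(d$directionality >= 0 & d$directionality <= 1))

  # ensemble mean decays with time for diffusive walks
  w <- walk_params(v = 16.25, tau = 0.6, dt = 0.25, duration = 7)
  e <- bind_tracks(lapply(1:300, function(i)
    simulate_walk(w, seed = 4000 + i, track_id = sprintf("w%03d", i))))
  ed <- ensemble_directionality(e, t_max = 7)
  d1 <- ed$mean_directionality[ed$t_hr == 1]
  d4 <- ed$mean_directionality[ed$t_hr == 4]
  d7 <- ed$mean_directionality[ed$t_hr == 7]
  expect_true(d1 > d4 && d4 > d7)
})

test_that("the kinematics summary reports death fractions at the 10 and 20 hr checkpoints", {
  tracks <- lapply(1:26, function(i)
    straight_track(5, angle = i, id = as.character(i), n = 81))  # 20 hr
  tracks[[3]] <- straight_track(5, angle = 3, id = "3", n = 61, fate = "died")  # dies at 15 hr
  s <- summarize_kinematics(bind_tracks(tracks), window = c(0, 7))
  expect_equal(s$n_cells, 26)
  expect_equal(s$death_fraction_10hr, 0)
  expect_equal(s$death_fraction_20hr, 1 / 26)

  s <- summarize_kinematics(bind_tracks(tracks[-3]), window = c(0, 7))
  expect_equal(s$death_fraction_10hr, 0)
  expect_equal(s$death_fraction_20hr, 0)
})

test_that("stained preset deaths accumulate to the observed fraction by 10-20 hr", {
  p <- preset_params("stained")
  fr10 <- vapply(1:30, function(s) {
    summarize_kinematics(
      simulate_population(p$walk, p$fate, n_cells = 22, seed = 600 + s),
      window = c(0, 7))$death_fraction_20hr
  }, numeric(1))
  # near the reported 23% (constant hazard spreads deaths across 0-20 hr)
  expect_gt(mean(fr10), 0.10)
  expect_lt(mean(fr10), 0.30)
})

test_that("speed comparisons detect the staining slowdown", {
  x <- withr::with_seed(1, stats::rlnorm(1000, log(16), 0.3))
  cmp <- speed_comparison(x, x)
  expect_equal(cmp$relative_difference, 0)
  expect_equal(cmp$mwu_p, 1)

  cmp <- speed_comparison(x, x - 5)
  expect_lt(cmp$mwu_p, 0.01)

  cmp <- speed_comparison(c(16.25, 16.25, 16.25), c(11.51, 11.51, 11.51))
  expect_equal(round(100 * cmp$relative_difference, 1), 29.2)
})

test_that("tidiers expose fits and summaries as tibbles", {
  tt <- seq(0, 7, 0.25)
  fit <- fit_diffusivity(tibble::tibble(t_hr = tt, mean_sq_um2 = 159.6 * tt))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "D"], 79.8, tolerance = 1e-9)
  expect_equal(glance(fit)$D_um2_hr, 79.8, tolerance = 1e-9)

  p <- preset_params("unstained")
  e <- simulate_population(p$walk, p$fate, n_cells = 12, seed = 8)
  td <- tidy(summarize_kinematics(e))
  expect_true(all(c("speed_um_hr", "D_um2_hr", "tau_hr") %in% td$parameter))
})
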