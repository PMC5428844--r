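test_that("pair velocities decompose into centroid and relative components", {
  # identical velocities: vr = 0, vpc = common speed
  a <- straight_track(8, angle = 0, id = "a", n = 9)
  b <- straight_track(8, angle = 0, id = "b", n = 9)
  b$y_um <- b$y_um + 16
  pk <- pair_kinematics(a, b)
  expect_equal(pk$data$vr_um_hr[-1], rep(0, 8), tolerance = 1e-12)
  expect_equal(pk$data$vpc_um_hr[-1], rep(8, 8), tolerance = 1e-12)

  # opposite velocities: vpc = 0, vr = 16
  b2 <- straight_track(8, angle = pi, id = "b", n = 9)
  b2$y_um <- b2$y_um + 16
  pk <- pair_kinematics(a, b2)
  expect_equal(pk$data$vpc_um_hr[-1], rep(0, 8), tolerance = 1e-12)
  expect_equal(pk$data$vr_um_hr[-1], rep(16, 8), tolerance = 1e-12)

  # cells at (0,0) and (16,0) drifting apart at 2 um/hr each for 5 hr
  tt <- seq(0, 5, 0.25)
  left <- track_from_xy(-2 * tt, 0 * tt, id = "L")
  right <- track_from_xy(16 + 2 * tt, 0 * tt, id = "R")
  pk <- pair_kinematics(left, right)
  expect_equal(pk$s0, 16)
  expect_equal(pk$s_f, 36)
  expect_equal(pk$s_max, 36)
  expect_equal(pk$t_max_hr, 5)

  expect_error(pair_kinematics(a[1, ], b[1, ]), class = "stemwalk_argument_error")
})

test_that("centroid +/- half the relative vector reconstructs the tracks", {
  p <- preset_params("pair_B")
  tr <- simulate_pair(p$pair, p$walk, seed = 5)
  pk <- pair_kinematics(tr$track1, tr$track2)
  expect_equal(pk$data$cx_um + pk$data$rx_um / 2, tr$track1$x_um, tolerance = 1e-9)
  expect_equal(pk$data$cy_um + pk$data$ry_um / 2, tr$track1$y_um, tolerance = 1e-9)
  expect_equal(pk$data$cx_um - pk$data$rx_um / 2, tr$track2$x_um, tolerance = 1e-9)
  # triangle inequality of the decomposition, frame-wise
  d <- pk$data[-1, ]
  expect_true(all(d$v1_um_hr <= d$vpc_um_hr + d$vr_um_hr / 2 + 1e-9))
  expect_true(all(d$v2_um_hr <= d$vpc_um_hr + d$vr_um_hr / 2 + 1e-9))
  # summary invariants
  expect_gte(pk$s_max, max(pk$s0, pk$s_f))
  expect_true(pk$t_max_hr >= 0 && pk$t_max_hr <= pk$tracking_hr)
})

test_that("pairs are classified by the final-to-maximum separation ratio", {
  tt <- seq(0, 10, 0.25)
  mono <- pair_kinematics(track_from_xy(-tt, 0 * tt, id = "a"),
                          track_from_xy(16 + tt, 0 * tt, id = "b"))
  cls <- classify_pair(mono)
  expect_equal(cls$label, "A")
  expect_equal(cls$ratio, 1)

  # rising to 98 then falling to 34 (the observed Type B medians): ratio 0.35 -> B
  s_up <- seq(17, 98, length.out = 21)
  s_down <- seq(98, 34, length.out = 21)[-1]
  s <- c(s_up, s_down)
  rise_fall <- pair_kinematics(
    track_from_xy(rep(0, length(s)), rep(0, length(s)), id = "a"),
    track_from_xy(s, rep(0, length(s)), id = "b"))
  cls <- classify_pair(rise_fall)
  expect_equal(cls$label, "B")
  expect_equal(round(cls$ratio, 2), 0.35)

  # rising to 95, ending at 91 (Type A medians): ratio 0.96 -> A
  s <- c(seq(16, 95, length.out = 30), seq(95, 91, length.out = 11)[-1])
  ease_off <- pair_kinematics(
    track_from_xy(rep(0, length(s)), rep(0, length(s)), id = "a"),
    track_from_xy(s, rep(0, length(s)), id = "b"))
  cls <- classify_pair(ease_off)
  expect_equal(cls$label, "A")
  expect_equal(round(cls$ratio, 2), 0.96)
})

test_that("generated pair types are recovered at the default threshold", {
  recover <- function(scenario, n = 60) {
    p <- preset_params(scenario)
    cls <- classify_pairs(lapply(1:n, function(i) {
      tr <- simulate_pair(p$pair, p$walk, seed = i)
      pair_kinematics(tr$track1, tr$track2, pair_id = as.character(i))
    }))
    mean(cls$label == sub("pair_", "", scenario))
  }
  expect_gte(recover("pair_A"), 0.9)
  expect_gte(recover("pair_B"), 0.9)
})

test_that("sibling pairs come from lineage links and share a time window", {
  p <- preset_params("unstained")
  e <- simulate_population(p$walk, p$fate, n_cells = 12, seed = 21)
  prs <- sibling_pairs(e)
  lin <- build_lineage(e)
  expect_equal(length(prs), sum(lin$fate == "divided"))
  for (pk in prs) {
    expect_gte(nrow(pk$data), 2)
    expect_equal(pk$s0, 16, tolerance = 1e-9)  # daughters start s0 apart
  }
})

test_that("pair-centroid diffusivity matches exact and stationary series", {
  tt <- seq(0, 7, 0.25)
  still <- pair_kinematics(track_from_xy(rep(0, 29), rep(0, 29), id = "a"),
                           track_from_xy(rep(10, 29), rep(0, 29), id = "b"))
  expect_equal(pair_centroid_diffusivity(still)$D, 0)

  # centroid MSD = 117 t exactly -> D = 58.5
  drift <- pair_kinematics(
    track_from_xy(sqrt(117 * tt) - 5, 0 * tt, id = "a"),
    track_from_xy(sqrt(117 * tt) + 5, 0 * tt, id = "b"))
  expect_equal(pair_centroid_diffusivity(drift)$D, 58.5, tolerance = 1e-9)

  # parameter recovery at the preset centroid diffusivity; the ensemble
  # standard error comes from the spread of per-pair fits (the pooled fit on a
  # shared grid equals their mean)
  p <- preset_params("pair_A")
  prs <- lapply(1:100, function(i) {
    tr <- simulate_pair(p$pair, p$walk, seed = 700 + i)
    pair_kinematics(tr$track1, tr$track2, pair_id = as.character(i))
  })
  fit <- pair_centroid_diffusivity(prs, window = c(0, 7))
  per_pair <- vapply(prs, function(pk)
    pair_centroid_diffusivity(pk, window = c(0, 7))$D, numeric(1))
  se <- stats::sd(per_pair) / sqrt(length(per_pair))
  expect_equal(fit$D, mean(per_pair), tolerance = 1e-9)
  expect_lt(abs(fit$D - 58.5), 3 * se)
})

test_that("pair summaries report per-class medians and quartiles", {
  tt <- seq(0, 5, 0.25)
  mk <- function(s0, id) pair_kinematics(
    track_from_xy(-tt, 0 * tt, id = paste0(id, "a")),
    track_from_xy(s0 + tt, 0 * tt, id = paste0(id, "b")), pair_id = id)
  one <- pair_summary(list(mk(16, "p1")))
  expect_equal(one$median[one$statistic == "s0_um"], 16)
  expect_equal(one$q25[one$statistic == "s0_um"],
               one$q75[one$statistic == "s0_um"])  # degenerate quartiles

  multi <- pair_summary(list(mk(16, "p1"), mk(17, "p2"), mk(16, "p3")))
  expect_equal(multi$median[multi$statistic == "s0_um"], 16)

  # simulated types: B reaches maximum separation earlier than A
  prs <- list(); labs <- list()
  for (scenario in c("pair_A", "pair_B")) {
    p <- preset_params(scenario)
    for (i in 1:20) {
      tr <- simulate_pair(p$pair, p$walk, seed = 900 + i)
      id <- paste0(scenario, i)
      prs[[id]] <- pair_kinematics(tr$track1, tr$track2, pair_id = id)
      labs[[id]] <- sub("pair_", "", scenario)
    }
  }
  labels <- tibble::tibble(pair_id = names(labs), label = unlist(labs))
  s <- pair_summary(prs, labels)
  tmax_a <- s$median[s$label == "A" & s$statistic == "tmax_hr"]
  tmax_b <- s$median[s$label == "B" & s$statistic == "tmax_hr"]
  expect_lt(tmax_b, tmax_a)

  # a class with no member pairs is omitted with a warning
  stray <- dplyr::bind_rows(labels,
                            tibble::tibble(pair_id = "ghost", label = "C"))
  expect_warning(pair_summary(prs, stray), "'C'")
})

test_that("relative-speed distributions separate Type A from Type B", {
  x <- withr::with_seed(2, stats::rlnorm(500, log(30), 0.4))
  cmp <- compare_relative_speeds(x, x)
  expect_equal(cmp$ks_p, 1)
  expect_equal(cmp$mwu_p, 1)

  cmp <- compare_relative_speeds(x, x - 5)
  expect_lt(cmp$mwu_p, 0.01)

  # presets at the reported median split (31.1 vs 27.7 um/hr)
  pool <- function(scenario, n) {
    p <- preset_params(scenario)
    unlist(lapply(1:n, function(i) {
      tr <- simulate_pair(p$pair, p$walk, seed = 50 + i)
      pair_kinematics(tr$track1, tr$track2)$data$vr_um_hr
    }))
  }
  cmp <- compare_relative_speeds(pool("pair_A", 12), pool("pair_B", 12))
  expect_lt(cmp$mwu_p, 0.01)
})
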