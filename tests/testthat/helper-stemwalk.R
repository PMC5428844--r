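# fixture builders (all fixtures are generated in code)

track_from_xy <- function(x, y, dt = 0.25, id = "1", parent = NA_character_,
                          fate = "censored", t0 = 0) {
  n <- length(x)
  tibble::tibble(track_id = id, parent_id = parent,
                 frame = as.integer(round((t0 + (seq_len(n) - 1) * dt) / dt)),
                 t_hr = t0 + (seq_len(n) - 1) * dt,
                 x_um = x, y_um = y, fate = fate)
}

straight_track <- function(speed, angle = 0, dt = 0.25, n = 9, id = "1", ...) {
  tt <- (seq_len(n) - 1) * dt
  track_from_xy(speed * tt * cos(angle), speed * tt * sin(angle),
                dt = dt, id = id, ...)
}

stationary_track <- function(n = 9, dt = 0.25, id = "1", at = c(0, 0), ...) {
  track_from_xy(rep(at[1], n), rep(at[2], n), dt = dt, id = id, ...)
}

two_track_ensemble <- function(dt = 0.25, n = 3) {
  bind_tracks(list(straight_track(10, 0, dt, n, id = "a"),
                   straight_track(10, pi / 2, dt, n, id = "b")))
}

# ensemble with random but valid geometry, for round-trip property tests
random_valid_ensemble <- function(seed, n_tracks = 4, n = 6, dt = 0.25) {
  withr::with_seed(seed, {
    tracks <- lapply(seq_len(n_tracks), function(i) {
      track_from_xy(cumsum(stats::rnorm(n, 0, 3)), cumsum(stats::rnorm(n, 0, 3)),
                    dt = dt, id = sprintf("t%02d", i),
                    fate = sample(c("censored", "divided", "died", "lost"), 1))
    })
    # make fates lineage-consistent: no divisions without children recorded
    tracks <- lapply(tracks, function(tr) { tr$fate <- sub("divided", "censored", tr$fate); tr })
    bind_tracks(tracks, dt = dt)
  })
}

expect_ensembles_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
  expect_equal(ensemble_dt(a), ensemble_dt(b))
}
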