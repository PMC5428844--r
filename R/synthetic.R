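#' Random-walk parameters
#'
#' Parameters of the fixed-leg isotropic walk used to emulate single-cell
#' migration: the cell moves in a straight line at path speed `v` for legs of
#' duration `tau` (the correlation time), picking a new direction uniformly on
#' \[0, 2pi) at each leg boundary. Positions are reported on the `dt` sampling
#' grid. With this construction the diffusivity of the walk is exactly
#' D = tau * v^2 / 2 (in the mean-square-displacement = 2Dt convention).
#'
#' @param v Path speed in um/hr (>= 0).
#' @param tau Correlation time in hours (> 0): the straight-leg duration.
#' @param dt Sampling interval in hours (> 0); 0.25 hr mirrors 15-minute
#'   time-lapse imaging.
#' @param duration Total tracked duration in hours (>= dt).
#' @param pixel_size Optional pixel size in um; when set, reported positions
#'   are quantized to multiples of it (emulating imaging). Off by default.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(v, tau, dt = 0.25, duration = 7, pixel_size = NULL) {
  stopifnot(v >= 0, tau > 0, dt > 0, duration >= dt)
  structure(list(v = v, tau = tau, dt = dt, duration = duration,
                 pixel_size = pixel_size),
            class = "walk_params")
}

#' Division and death parameters
#'
#' Division times are lognormal (median `division_time_median`, log-sd
#' `division_time_logsd`), matching the positive, right-skewed division-time
#' distributions seen in tracked colonies; death is a constant hazard acting
#' until division. On division the mother track ends and two daughters start
#' at the mother's last position, offset symmetrically by half the daughter
#' separation along a uniformly random axis.
#'
#' @param division_time_median Median time to division, hours.
#' @param division_time_logsd Lognormal sd on the log scale (dimensionless).
#' @param death_hazard Constant death hazard, per hour.
#' @param max_events Maximum number of division generations to simulate;
#'   cells at the cap are censored instead of dividing.
#' @param daughter_separation_um Initial separation of the two daughters, um.
#' @return A list of class `fate_params`.
#' @export
fate_params <- function(division_time_median, division_time_logsd,
                        death_hazard, max_events = 2L,
                        daughter_separation_um = 16) {
  stopifnot(division_time_median >= 0, division_time_logsd >= 0,
            death_hazard >= 0, max_events >= 0, daughter_separation_um >= 0)
  structure(list(division_time_median = division_time_median,
                 division_time_logsd = division_time_logsd,
                 death_hazard = death_hazard,
                 max_events = as.integer(max_events),
                 daughter_separation_um = daughter_separation_um),
            class = "fate_params")
}

#' Cell-pair dynamics parameters
#'
#' Phenomenological model of a post-division sibling pair: the pair centroid
#' performs an isotropic walk with diffusivity `centroid_diffusivity`, while
#' the relative vector between the cells carries a radial drift
#' (`outward_speed` until `switch_time`, then `-inward_speed`) plus isotropic
#' relative noise (a fixed-leg walk at `rel_noise_speed`). A missing
#' `switch_time` gives repel-only (Type A) dynamics; a finite one gives
#' repel-then-attract (Type B).
#'
#' With a finite `rel_noise_relax` the noise component is mean-reverting
#' (bounded jitter) rather than freely diffusing: the cells jostle at the
#' observed relative speed while the separation stays drift-dominated, which
#' is what the narrow interquartile ranges of observed final separations
#' imply. `rel_noise_relax = Inf` recovers a pure random-walk noise.
#'
#' @param s0 Initial separation, um (> 0).
#' @param outward_speed Radial separation growth rate, um/hr (>= 0).
#' @param switch_time Time at which the drift reverses, hours; `NA` for
#'   repel-only behaviour.
#' @param inward_speed Radial approach rate after `switch_time`, um/hr.
#' @param centroid_diffusivity Pair-centroid diffusivity, um^2/hr.
#' @param centroid_tau Pair-centroid correlation time, hours.
#' @param rel_noise_speed Speed of the isotropic relative-noise walk, um/hr.
#' @param rel_noise_tau Correlation time of the relative noise, hours.
#' @param rel_noise_relax Relaxation time of the relative-noise jitter,
#'   hours; `Inf` (default) leaves the noise a free random walk.
#' @return A list of class `pair_params`.
#' @export
pair_params <- function(s0, outward_speed, switch_time = NA_real_,
                        inward_speed = 0, centroid_diffusivity = 58.5,
                        centroid_tau = 0.5, rel_noise_speed = 0,
                        rel_noise_tau = 0.25, rel_noise_relax = Inf) {
  stopifnot(s0 > 0, outward_speed >= 0, inward_speed >= 0,
            centroid_diffusivity >= 0, centroid_tau > 0,
            rel_noise_speed >= 0, rel_noise_tau > 0, rel_noise_relax > 0)
  if (!is.na(switch_time)) stopifnot(switch_time > 0)
  structure(list(s0 = s0, outward_speed = outward_speed,
                 switch_time = switch_time, inward_speed = inward_speed,
                 centroid_diffusivity = centroid_diffusivity,
                 centroid_tau = centroid_tau,
                 rel_noise_speed = rel_noise_speed,
                 rel_noise_tau = rel_noise_tau,
                 rel_noise_relax = rel_noise_relax),
            class = "pair_params")
}

#' Preset parameter bundles for the study scenarios
#'
#' Returns the generator parameters calibrated to the tracked hESC data:
#' `unstained` (26 cells, v = 16.25 um/hr, tau = 0.6 hr, median division
#' 4.9 hr), `stained` (22 Cell-Tracer-treated cells, v = 11.51 um/hr,
#' tau = 0.7 hr, median division 9.3 hr), and the pair scenarios `pair_A`
#' (repel-only), `pair_B` (repel-then-attract) and `pair_stained`.
#'
#' @param scenario One of `"unstained"`, `"stained"`, `"pair_A"`, `"pair_B"`,
#'   `"pair_stained"`.
#' @return A list with elements `walk` ([walk_params()]), `fate`
#'   ([fate_params()]), `pair` ([pair_params()] or `NULL`) and `n_cells`
#'   (the tracked sample size of the scenario).
#' @export
preset_params <- function(scenario) {
  presets <- list(
    unstained = list(
      walk = walk_params(v = 16.25, tau = 0.6, dt = 0.25, duration = 20),
      fate = fate_params(4.9, 0.82, death_hazard = 0.013),
      pair = NULL, n_cells = 26L
    ),
    stained = list(
      walk = walk_params(v = 11.51, tau = 0.7, dt = 0.25, duration = 20),
      fate = fate_params(9.3, 0.56, death_hazard = 0.026),
      pair = NULL, n_cells = 22L
    ),
    pair_A = list(
      walk = walk_params(v = 20.0, tau = 0.6, dt = 0.25, duration = 23),
      fate = fate_params(4.9, 0.82, death_hazard = 0.013),
      pair = pair_params(s0 = 16, outward_speed = 3.3, switch_time = NA,
                         inward_speed = 0, centroid_diffusivity = 58.5,
                         centroid_tau = 0.5, rel_noise_speed = 31,
                         rel_noise_tau = 0.25, rel_noise_relax = 2),
      n_cells = 10L
    ),
    pair_B = list(
      walk = walk_params(v = 20.5, tau = 0.6, dt = 0.25, duration = 24.25),
      fate = fate_params(4.9, 0.82, death_hazard = 0.013),
      pair = pair_params(s0 = 17, outward_speed = 10, switch_time = 8,
                         inward_speed = 3.9, centroid_diffusivity = 58.5,
                         centroid_tau = 0.5, rel_noise_speed = 27.5,
                         rel_noise_tau = 0.25, rel_noise_relax = 2),
      n_cells = 12L
    ),
    pair_stained = list(
      walk = walk_params(v = 15.4, tau = 0.7, dt = 0.25, duration = 31.5),
      fate = fate_params(9.3, 0.56, death_hazard = 0.026),
      pair = pair_params(s0 = 16, outward_speed = 2.5, switch_time = 4,
                         inward_speed = 0.3, centroid_diffusivity = 34,
                         centroid_tau = 0.5, rel_noise_speed = 16,
                         rel_noise_tau = 0.25, rel_noise_relax = 2),
      n_cells = 17L
    )
  )
  if (!scenario %in% names(presets)) {
    abort(sprintf("unknown scenario '%s'; valid scenarios: %s",
                  scenario, paste(names(presets), collapse = ", ")),
          class = "stemwalk_argument_error")
  }
  presets[[scenario]]
}

# core walk sampler: positions of a fixed-leg isotropic walk on the dt grid.
# Leg boundaries sit at exact multiples of tau from the track start, so that
# at those instants E[L^2] = v^2 * tau * t exactly (D = tau v^2 / 2).
sample_fixed_leg_walk <- function(v, tau, dt, duration, start = c(0, 0)) {
  tt <- seq(0, duration, by = dt)
  n_legs <- ceiling(duration / tau) + 1L
  theta <- runif(n_legs, 0, 2 * pi)
  boundaries <- seq(0, by = tau, length.out = n_legs + 1L)
  px <- c(0, cumsum(v * tau * cos(theta)))
  py <- c(0, cumsum(v * tau * sin(theta)))
  leg <- pmin(findInterval(tt, boundaries), n_legs)
  frac <- tt - boundaries[leg]
  cbind(t = tt,
        x = start[1] + px[leg] + v * frac * cos(theta[leg]),
        y = start[2] + py[leg] + v * frac * sin(theta[leg]))
}

make_track <- function(pos, track_id, parent_id = NA_character_,
                       fate = "censored", t0 = 0, dt = NULL, pixel_size = NULL) {
  x <- pos[, "x"]
  y <- pos[, "y"]
  if (!is.null(pixel_size)) {
    x <- round(x / pixel_size) * pixel_size
    y <- round(y / pixel_size) * pixel_size
  }
  t_abs <- t0 + pos[, "t"]
  tibble(track_id = track_id, parent_id = parent_id,
         frame = as.integer(round(t_abs / dt)),
         t_hr = t_abs, x_um = x, y_um = y, fate = fate)
}

#' Simulate one fixed-leg isotropic random walk
#'
#' @param params A [walk_params()] object.
#' @param start Starting position `c(x, y)` in um.
#' @param seed Integer seed; the same (params, seed) always yields the same
#'   track.
#' @param track_id Identifier for the returned track.
#' @return A track tibble (tracks-CSV columns) with fate `"censored"`.
#' @examples
#' w <- simulate_walk(walk_params(v = 16.25, tau = 0.6, duration = 7), seed = 1)
#' head(w)
#' @export
simulate_walk <- function(params, start = c(0, 0), seed, track_id = "1") {
  stopifnot(inherits(params, "walk_params"))
  pos <- withr::with_seed(seed,
    sample_fixed_leg_walk(params$v, params$tau, params$dt, params$duration, start))
  make_track(pos, track_id, dt = params$dt, pixel_size = params$pixel_size)
}

# one cell's life: walk until division/death/duration end; recurse on division
simulate_cell <- function(walk, fate, track_id, parent_id, start, t0,
                          t_end_global, generation) {
  remaining <- t_end_global - t0
  if (remaining < 2 * walk$dt) return(list())
  t_div <- if (fate$division_time_median > 0 && generation < fate$max_events) {
    rlnorm(1, log(fate$division_time_median), fate$division_time_logsd)
  } else {
    Inf
  }
  t_death <- if (fate$death_hazard > 0) rexp(1, fate$death_hazard) else Inf
  t_event <- min(t_div, t_death, remaining)
  # track ends on the sampling grid, never with fewer than 2 samples
  t_track <- max(floor(t_event / walk$dt + 1e-9) * walk$dt, walk$dt)
  t_track <- min(t_track, floor(remaining / walk$dt + 1e-9) * walk$dt)
  cell_fate <- if (t_event == remaining || t_track >= remaining) "censored"
    else if (t_death <= t_div) "died" else "divided"
  pos <- sample_fixed_leg_walk(walk$v, walk$tau, walk$dt, t_track, start)
  track <- make_track(pos, track_id, parent_id, cell_fate, t0 = t0,
                      dt = walk$dt, pixel_size = walk$pixel_size)
  out <- list(track)
  if (cell_fate == "divided") {
    last <- c(track$x_um[nrow(track)], track$y_um[nrow(track)])
    phi <- runif(1, 0, 2 * pi)
    half <- fate$daughter_separation_um / 2 * c(cos(phi), sin(phi))
    t_birth <- t0 + t_track
    for (k in 1:2) {
      child <- simulate_cell(walk, fate,
                             track_id = paste0(track_id, ".", k),
                             parent_id = track_id,
                             start = last + (if (k == 1) half else -half),
                             t0 = t_birth, t_end_global = t_end_global,
                             generation = generation + 1L)
      out <- c(out, child)
    }
    # too little time left to track either daughter: record the mother as
    # censored instead, keeping the lineage invariant (divided => 2 children)
    if (length(out) == 1) out[[1]]$fate <- "censored"
  }
  out
}

#' Simulate a population of dividing, dying, migrating cells
#'
#' Founders are placed uniformly in a square whose area matches a plating
#' density of 1500 cells/cm^2 and migrate as fixed-leg isotropic walks.
#' Division times are lognormal, death is a constant hazard acting until
#' division; on division the mother track ends and two daughter tracks begin
#' at the mother's last position, offset by half the daughter separation
#' along a random axis. Lineage links are recorded in `parent_id`.
#'
#' @param walk A [walk_params()] object.
#' @param fate A [fate_params()] object.
#' @param n_cells Number of founder cells (>= 1).
#' @param seed Integer seed; output is deterministic given
#'   (walk, fate, n_cells, seed).
#' @param label Scenario tag for the returned ensemble.
#' @return An [as_ensemble()] object.
#' @examples
#' p <- preset_params("unstained")
#' e <- simulate_population(p$walk, p$fate, n_cells = 26, seed = 1)
#' @export
simulate_population <- function(walk, fate, n_cells, seed, label = "") {
  stopifnot(inherits(walk, "walk_params"), inherits(fate, "fate_params"),
            n_cells >= 1)
  side_um <- sqrt(n_cells / 1500) * 1e4  # plating density 1500 cells/cm^2
  tracks <- withr::with_seed(seed, {
    founders <- lapply(seq_len(n_cells), function(i) {
      start <- runif(2, 0, side_um)
      simulate_cell(walk, fate, track_id = as.character(i),
                    parent_id = NA_character_, start = start, t0 = 0,
                    t_end_global = walk$duration, generation = 0L)
    })
    unlist(founders, recursive = FALSE)
  })
  bind_tracks(tracks, dt = walk$dt, pixel_size = walk$pixel_size, label = label)
}

#' Simulate a post-division cell pair
#'
#' The centroid performs a fixed-leg isotropic walk at the pair-centroid
#' diffusivity; the relative vector carries a radial drift (outward until
#' `switch_time`, inward after) plus isotropic fixed-leg relative noise. The
#' two tracks are reconstructed as centroid +/- half the relative vector.
#' Separation is floored at 1 um (cells cannot interpenetrate fully).
#'
#' @param params A [pair_params()] object.
#' @param walk A [walk_params()] object supplying `dt` and `duration`.
#' @param seed Integer seed.
#' @param ids Track identifiers of the two cells.
#' @return A named list with track tibbles `track1`, `track2`.
#' @export
simulate_pair <- function(params, walk, seed, ids = c("1", "2")) {
  stopifnot(inherits(params, "pair_params"), inherits(walk, "walk_params"))
  dt <- walk$dt
  duration <- walk$duration
  withr::with_seed(seed, {
    vc <- sqrt(2 * params$centroid_diffusivity / params$centroid_tau)
    centroid <- sample_fixed_leg_walk(vc, params$centroid_tau, dt, duration)
    noise <- if (params$rel_noise_speed > 0) {
      sample_fixed_leg_walk(params$rel_noise_speed, params$rel_noise_tau, dt, duration)
    } else {
      cbind(t = seq(0, duration, by = dt), x = 0, y = 0)
    }
    tt <- centroid[, "t"]
    n <- length(tt)
    rx <- ry <- numeric(n)
    jx <- jy <- 0  # bounded jitter state (mean-reverting noise component)
    a <- exp(-dt / params$rel_noise_relax)
    phi0 <- runif(1, 0, 2 * pi)
    rx[1] <- params$s0 * cos(phi0)
    ry[1] <- params$s0 * sin(phi0)
    for (k in seq_len(n - 1)) {
      drift <- if (is.na(params$switch_time) || tt[k] < params$switch_time) {
        params$outward_speed
      } else {
        -params$inward_speed
      }
      s <- sqrt(rx[k]^2 + ry[k]^2)
      ux <- if (s > 0) rx[k] / s else cos(phi0)
      uy <- if (s > 0) ry[k] / s else sin(phi0)
      dnx <- (a - 1) * jx + (noise[k + 1, "x"] - noise[k, "x"])
      dny <- (a - 1) * jy + (noise[k + 1, "y"] - noise[k, "y"])
      jx <- jx + dnx
      jy <- jy + dny
      rx[k + 1] <- rx[k] + drift * dt * ux + dnx
      ry[k + 1] <- ry[k] + drift * dt * uy + dny
      s_new <- sqrt(rx[k + 1]^2 + ry[k + 1]^2)
      if (s_new < 1) {  # floor separation at one cell-contact distance
        scale <- if (s_new > 0) 1 / s_new else 1
        rx[k + 1] <- if (s_new > 0) rx[k + 1] * scale else ux
        ry[k + 1] <- if (s_new > 0) ry[k + 1] * scale else uy
      }
    }
    pos1 <- cbind(t = tt, x = centroid[, "x"] + rx / 2, y = centroid[, "y"] + ry / 2)
    pos2 <- cbind(t = tt, x = centroid[, "x"] - rx / 2, y = centroid[, "y"] - ry / 2)
    list(track1 = make_track(pos1, ids[1], dt = dt, pixel_size = walk$pixel_size),
         track2 = make_track(pos2, ids[2], dt = dt, pixel_size = walk$pixel_size))
  })
}
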