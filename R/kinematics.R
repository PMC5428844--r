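#' Displacement of a track from its own first sample
#'
#' The displacement at time t is the straight-line distance from the track's
#' first sampled position, L(t) = sqrt((x(t) - x0)^2 + (y(t) - y0)^2); it is 0
#' at the first sample by construction.
#'
#' @param track A single-track tibble (tracks-CSV columns).
#' @return A tibble with columns `t_hr` (absolute time), `elapsed_hr` (time
#'   since the track's first sample), `L_um` and `L2_um2`.
#' @export
displacement_series <- function(track) {
  track <- dplyr::arrange(as_tibble(track), .data$t_hr)
  L <- sqrt((track$x_um - track$x_um[1])^2 + (track$y_um - track$y_um[1])^2)
  tibble(t_hr = track$t_hr, elapsed_hr = track$t_hr - track$t_hr[1],
         L_um = L, L2_um2 = L^2)
}

#' Ensemble mean-squared displacement
#'
#' At each grid time (elapsed since each track's first sample) up to `t_max`,
#' the mean and median of the squared displacements over the tracks that have
#' a sample at that time. The number of contributing ("live") tracks is
#' reported per time and shrinks as tracks end in division, death or loss; no
#' imputation is performed.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param t_max Largest elapsed time to report, hours (> 0).
#' @param founders_only If `TRUE`, restrict to founder tracks (no parent),
#'   the convention for single-cell analyses of a dividing population.
#' @return A tibble of class `msd_series` with columns `t_hr`, `mean_sq_um2`,
#'   `median_sq_um2`, `q25_um2`, `q75_um2`, `n_live`.
#' @export
ensemble_msd <- function(ensemble, t_max = NULL, founders_only = FALSE) {
  dt <- ensemble_dt(ensemble)
  x <- as_tibble(ensemble)
  if (founders_only) x <- x[is.na(x$parent_id), ]
  if (nrow(x) == 0) abort("no tracks to average", class = "stemwalk_argument_error")
  if (is.null(t_max)) t_max <- max(x$t_hr) - min(x$t_hr)
  if (t_max <= 0) abort("t_max must be positive", class = "stemwalk_argument_error")
  disp <- dplyr::group_modify(dplyr::group_by(x, .data$track_id),
                              ~ displacement_series(.x))
  disp <- dplyr::ungroup(disp)
  disp <- disp[disp$elapsed_hr <= t_max + 1e-9, ]
  disp$elapsed_hr <- round(disp$elapsed_hr / dt) * dt
  out <- dplyr::summarise(
    dplyr::group_by(disp, t_hr = .data$elapsed_hr),
    mean_sq_um2 = mean(.data$L2_um2),
    median_sq_um2 = median(.data$L2_um2),
    q25_um2 = unname(quantile(.data$L2_um2, 0.25)),
    q75_um2 = unname(quantile(.data$L2_um2, 0.75)),
    n_live = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$t_hr)
  structure(out, dt = dt, class = c("msd_series", class(tibble())))
}

#' Fit a diffusivity to a mean-squared-displacement series
#'
#' Unweighted least squares of the mean squared displacement on time,
#' constrained to pass through the origin, over the stated window. Under the
#' isotropic random-walk description, mean L^2 = 2 D t, so the diffusivity is
#' half the fitted slope. The 95% confidence interval comes from the slope's
#' standard error (t distribution, n - 1 residual degrees of freedom).
#'
#' @param msd An [ensemble_msd()] result (or any data frame with `t_hr` and
#'   `mean_sq_um2`).
#' @param window Fit window `c(t_start, t_end)` in hours; default 0-7 hr, the
#'   interval over which tracked hESC migration is diffusive.
#' @return An object of class `diffusivity_fit` with elements `slope`
#'   (um^2/hr), `slope_se`, `slope_ci95`, `D` (= slope/2), `D_ci95`, `window`,
#'   `n_points` and `negative_slope` (flag). Supports [tidy()] and
#'   [glance()].
#' @examples
#' msd <- tibble::tibble(t_hr = seq(0, 7, 0.25), mean_sq_um2 = 159.6 * t_hr)
#' fit_diffusivity(msd)$D  # 79.8
#' @export
fit_diffusivity <- function(msd, window = c(0, 7)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- msd$t_hr >= window[1] - 1e-9 & msd$t_hr <= window[2] + 1e-9
  t <- msd$t_hr[keep]
  y <- msd$mean_sq_um2[keep]
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3) {
    abort("fewer than 3 time points in the fit window", class = "stemwalk_fit_error")
  }
  sxx <- sum(t^2)
  slope <- sum(t * y) / sxx
  resid <- y - slope * t
  n <- length(t)
  slope_se <- sqrt(sum(resid^2) / (n - 1) / sxx)
  ci <- qt(0.975, df = n - 1) * slope_se
  if (slope < 0) {
    warn("fitted slope is negative; the series is not diffusive on this window")
  }
  structure(list(slope = slope, slope_se = slope_se, slope_ci95 = ci,
                 D = slope / 2, D_ci95 = ci / 2,
                 window = window, n_points = n, negative_slope = slope < 0),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-intercept MSD fit over %g-%g hr (%d points)\n  slope = %.4g +/- %.4g um^2/hr (95%% CI)\n  D     = %.4g +/- %.4g um^2/hr\n",
    x$window[1], x$window[2], x$n_points, x$slope, x$slope_ci95, x$D, x$D_ci95))
  invisible(x)
}

per_frame_steps <- function(ensemble, founders_only = FALSE) {
  dt <- ensemble_dt(ensemble)
  x <- as_tibble(ensemble)
  if (founders_only) x <- x[is.na(x$parent_id), ]
  steps <- dplyr::reframe(
    dplyr::group_by(x, .data$track_id),
    t_hr = .data$t_hr[-1],
    dx_um = diff(.data$x_um),
    dy_um = diff(.data$y_um)
  )
  steps$dt_hr <- dt
  steps
}

#' Per-frame step lengths and isotropy checks
#'
#' Pools the absolute per-frame displacements along x and y across all tracks
#' and frames, and tests the isotropy of the migration: for an isotropic walk
#' the two step-length distributions coincide (two-sample Kolmogorov-Smirnov
#' and Mann-Whitney U tests) and are uncorrelated (Pearson r on the paired
#' absolute steps). Identical samples are reported with p = 1 by convention.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param founders_only Restrict to founder tracks.
#' @return An object of class `step_length_summary`: a list with `steps`
#'   (tibble of per-frame `|dx|`, `|dy|`), `summary` (medians and quartiles
#'   per axis), `pearson_r`, `ks_p`, `mwu_p`.
#' @export
step_lengths <- function(ensemble, founders_only = FALSE) {
  steps <- per_frame_steps(ensemble, founders_only)
  if (nrow(steps) == 0) abort("no steps in ensemble", class = "stemwalk_argument_error")
  lx <- abs(steps$dx_um)
  ly <- abs(steps$dy_um)
  qs <- function(v) c(q25 = unname(quantile(v, 0.25)), median = median(v),
                      q75 = unname(quantile(v, 0.75)))
  identical_samples <- isTRUE(all.equal(sort(lx), sort(ly)))
  if (identical_samples) {
    ks_p <- 1
    mwu_p <- 1
  } else {
    ks_p <- suppressWarnings(stats::ks.test(lx, ly)$p.value)
    mwu_p <- suppressWarnings(stats::wilcox.test(lx, ly)$p.value)
  }
  pearson_r <- if (stats::sd(lx) == 0 || stats::sd(ly) == 0) NA_real_ else cor(lx, ly)
  structure(list(
    steps = tibble(track_id = steps$track_id, t_hr = steps$t_hr,
                   lx_um = lx, ly_um = ly),
    summary = tibble(axis = c("x", "y"),
                     q25_um = unname(c(qs(lx)["q25"], qs(ly)["q25"])),
                     median_um = unname(c(qs(lx)["median"], qs(ly)["median"])),
                     q75_um = unname(c(qs(lx)["q75"], qs(ly)["q75"]))),
    pearson_r = pearson_r, ks_p = ks_p, mwu_p = mwu_p
  ), class = "step_length_summary")
}

#' Instantaneous migration speeds
#'
#' Per-frame displacement divided by the sampling interval, pooled over all
#' cells and frames (the convention used for reported migration speeds), with
#' per-cell medians also returned.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param founders_only Restrict to founder tracks.
#' @return An object of class `speed_summary`: a list with `speeds` (tibble
#'   `track_id`, `t_hr`, `speed_um_hr`), pooled `median`, `q25`, `q75`
#'   (um/hr) and `per_cell` (tibble of per-cell medians and quartiles).
#' @export
instantaneous_speeds <- function(ensemble, founders_only = FALSE) {
  steps <- per_frame_steps(ensemble, founders_only)
  if (nrow(steps) == 0) abort("no steps in ensemble", class = "stemwalk_argument_error")
  sp <- sqrt(steps$dx_um^2 + steps$dy_um^2) / steps$dt_hr
  speeds <- tibble(track_id = steps$track_id, t_hr = steps$t_hr, speed_um_hr = sp)
  per_cell <- dplyr::summarise(
    dplyr::group_by(speeds, .data$track_id),
    n_steps = dplyr::n(),
    q25_um_hr = unname(quantile(.data$speed_um_hr, 0.25)),
    median_um_hr = median(.data$speed_um_hr),
    q75_um_hr = unname(quantile(.data$speed_um_hr, 0.75)),
    .groups = "drop"
  )
  structure(list(speeds = speeds,
                 median = median(sp),
                 q25 = unname(quantile(sp, 0.25)),
                 q75 = unname(quantile(sp, 0.75)),
                 per_cell = per_cell),
            class = "speed_summary")
}

#' Correlation time from diffusivity and instantaneous speeds
#'
#' Applies tau = 2 D / v^2 to the instantaneous-speed distribution. Because
#' the map is a decreasing monotone transform, the median of tau equals
#' 2 D / median(v)^2 exactly, and the tau quartiles map from the opposite
#' speed quartiles.
#'
#' @param D Diffusivity, um^2/hr (>= 0).
#' @param speeds An [instantaneous_speeds()] result or a numeric vector of
#'   speeds in um/hr.
#' @return A one-row tibble with `tau_median_hr`, `tau_q25_hr`, `tau_q75_hr`.
#' @examples
#' correlation_time(79.8, 16.25)$tau_median_hr  # 0.604 -> 0.6 at 1 d.p.
#' @export
correlation_time <- function(D, speeds) {
  stopifnot(D >= 0)
  if (inherits(speeds, "speed_summary")) {
    v <- c(q25 = speeds$q25, median = speeds$median, q75 = speeds$q75)
  } else {
    v <- c(q25 = unname(quantile(speeds, 0.25)), median = median(speeds),
           q75 = unname(quantile(speeds, 0.75)))
  }
  if (D > 0 && any(v == 0)) {
    abort("correlation time undefined: a speed quantile is zero",
          class = "stemwalk_argument_error")
  }
  tau <- function(s) if (D == 0) 0 else 2 * D / s^2
  tibble(tau_median_hr = tau(v[["median"]]),
         tau_q25_hr = tau(v[["q75"]]),   # opposite quartiles: tau decreasing in v
         tau_q75_hr = tau(v[["q25"]]))
}

#' Directionality of a track
#'
#' Directionality at time t is the net displacement divided by the integrated
#' path length up to t: 1 for straight, monotone motion, approaching 0 for a
#' long random walk. Times with zero path length (including the first sample)
#' are excluded as undefined.
#'
#' @param track A single-track tibble.
#' @return A tibble with `t_hr`, `elapsed_hr` and `directionality` in
#'   \[0, 1\].
#' @export
directionality <- function(track) {
  track <- dplyr::arrange(as_tibble(track), .data$t_hr)
  disp <- displacement_series(track)
  path <- c(0, cumsum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)))
  keep <- path > 1e-9
  tibble(t_hr = disp$t_hr[keep], elapsed_hr = disp$elapsed_hr[keep],
         directionality = pmin(disp$L_um[keep] / path[keep], 1))
}

#' Ensemble mean directionality over time
#'
#' @param ensemble An [as_ensemble()] object.
#' @param t_max Largest elapsed time to report, hours.
#' @param founders_only Restrict to founder tracks.
#' @return A tibble with `t_hr` (elapsed), `mean_directionality`, `n_live`.
#' @export
ensemble_directionality <- function(ensemble, t_max = NULL, founders_only = FALSE) {
  dt <- ensemble_dt(ensemble)
  x <- as_tibble(ensemble)
  if (founders_only) x <- x[is.na(x$parent_id), ]
  d <- dplyr::group_modify(dplyr::group_by(x, .data$track_id),
                           ~ directionality(.x))
  d <- dplyr::ungroup(d)
  if (!is.null(t_max)) d <- d[d$elapsed_hr <= t_max + 1e-9, ]
  d$elapsed_hr <- round(d$elapsed_hr / dt) * dt
  out <- dplyr::summarise(
    dplyr::group_by(d, t_hr = .data$elapsed_hr),
    mean_directionality = mean(.data$directionality),
    n_live = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$t_hr)
}

#' Summarize the single-cell kinematics of an ensemble
#'
#' Assembles the standard single-cell migration report: sample size, pooled
#' migration speed (median and quartiles), step lengths per axis with
#' isotropy checks, diffusivity with its 95% CI from the zero-intercept MSD
#' fit, correlation time via tau = 2 D / v^2, founder time to first division
#' (median and quartiles) and founder death fractions at the 10 hr and 20 hr
#' checkpoints (events at a boundary count as occurred). Medians with
#' quartiles throughout; the MSD itself uses means, following its definition
#' as a mean-square quantity.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param window MSD fit window in hours, default 0-7 hr.
#' @param founders_only Use only founder tracks for speeds, steps and MSD
#'   (default `TRUE`, the single-cell convention).
#' @return An object of class `kinematics_summary` (list); supports [tidy()].
#' @export
summarize_kinematics <- function(ensemble, window = c(0, 7), founders_only = TRUE) {
  lineage <- build_lineage(ensemble)
  founders <- founder_events(lineage)
  msd <- ensemble_msd(ensemble, t_max = window[2], founders_only = founders_only)
  fit <- fit_diffusivity(msd, window = window)
  sp <- instantaneous_speeds(ensemble, founders_only = founders_only)
  st <- step_lengths(ensemble, founders_only = founders_only)
  tau <- correlation_time(fit$D, sp)
  div_times <- founders$event_hr[founders$fate == "divided"]
  death_frac <- function(t_check) {
    died <- founders$fate == "died" & !is.na(founders$event_hr) &
      founders$event_hr <= t_check + 1e-9
    sum(died) / nrow(founders)
  }
  structure(list(
    n_cells = nrow(founders),
    speed = tibble(median_um_hr = sp$median, q25_um_hr = sp$q25, q75_um_hr = sp$q75),
    step_lengths = st$summary,
    isotropy = tibble(pearson_r = st$pearson_r, ks_p = st$ks_p, mwu_p = st$mwu_p),
    tau = tau,
    fit = fit,
    t_div = tibble(
      n_divided = length(div_times),
      median_hr = if (length(div_times)) median(div_times) else NA_real_,
      q25_hr = if (length(div_times)) unname(quantile(div_times, 0.25)) else NA_real_,
      q75_hr = if (length(div_times)) unname(quantile(div_times, 0.75)) else NA_real_),
    death_fraction_10hr = death_frac(10),
    death_fraction_20hr = death_frac(20),
    window = window
  ), class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("Single-cell kinematics summary (N = %d)\n", x$n_cells))
  cat(sprintf("  speed  : %.2f (%.2f-%.2f) um/hr\n",
              x$speed$median_um_hr, x$speed$q25_um_hr, x$speed$q75_um_hr))
  cat(sprintf("  l_x/l_y: %.2f / %.2f um (medians); Pearson r = %.2f\n",
              x$step_lengths$median_um[1], x$step_lengths$median_um[2],
              x$isotropy$pearson_r))
  cat(sprintf("  D      : %.1f +/- %.1f um^2/hr (fit %g-%g hr)\n",
              x$fit$D, x$fit$D_ci95, x$window[1], x$window[2]))
  cat(sprintf("  tau    : %.1f (%.1f-%.1f) hr\n",
              x$tau$tau_median_hr, x$tau$tau_q25_hr, x$tau$tau_q75_hr))
  if (!is.na(x$t_div$median_hr)) {
    cat(sprintf("  t_div  : %.1f (%.1f-%.1f) hr, %d divided\n",
                x$t_div$median_hr, x$t_div$q25_hr, x$t_div$q75_hr, x$t_div$n_divided))
  }
  cat(sprintf("  deaths : %.0f%% by 10 hr, %.0f%% by 20 hr\n",
              100 * x$death_fraction_10hr, 100 * x$death_fraction_20hr))
  invisible(x)
}

#' Compare migration speeds between two groups
#'
#' Mann-Whitney U test on the pooled instantaneous speeds plus the relative
#' median difference (a - b) / a. Identical samples are reported with p = 1.
#'
#' @param a,b [instantaneous_speeds()] results or numeric speed vectors, in
#'   um/hr.
#' @return A one-row tibble with `median_a`, `median_b`,
#'   `relative_difference` and `mwu_p`.
#' @export
speed_comparison <- function(a, b) {
  va <- if (inherits(a, "speed_summary")) a$speeds$speed_um_hr else as.numeric(a)
  vb <- if (inherits(b, "speed_summary")) b$speeds$speed_um_hr else as.numeric(b)
  stopifnot(length(va) > 0, length(vb) > 0)
  p <- if (isTRUE(all.equal(sort(va), sort(vb)))) 1 else
    suppressWarnings(stats::wilcox.test(va, vb)$p.value)
  tibble(median_a = median(va), median_b = median(vb),
         relative_difference = (median(va) - median(vb)) / median(va),
         mwu_p = p)
}
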