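#' Tidy a diffusivity fit
#'
#' @param x A [fit_diffusivity()] object.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`slope`, `D`), with
#'   `estimate`, `std_error`, `conf_low`, `conf_high` (95%).
#' @export
tidy.diffusivity_fit <- function(x, ...) {
  tibble(term = c("slope", "D"),
         estimate = c(x$slope, x$D),
         std_error = c(x$slope_se, x$slope_se / 2),
         conf_low = c(x$slope - x$slope_ci95, x$D - x$D_ci95),
         conf_high = c(x$slope + x$slope_ci95, x$D + x$D_ci95))
}

#' Glance at a diffusivity fit
#'
#' @inheritParams tidy.diffusivity_fit
#' @return A one-row tibble: `D_um2_hr`, `D_ci95`, `slope_um2_hr`,
#'   `slope_ci95`, `window_start_hr`, `window_end_hr`, `n_points`,
#'   `negative_slope`.
#' @export
glance.diffusivity_fit <- function(x, ...) {
  tibble(D_um2_hr = x$D, D_ci95 = x$D_ci95,
         slope_um2_hr = x$slope, slope_ci95 = x$slope_ci95,
         window_start_hr = x$window[1], window_end_hr = x$window[2],
         n_points = x$n_points, negative_slope = x$negative_slope)
}

#' Tidy a kinematics summary into a long table
#'
#' @param x A [summarize_kinematics()] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `q25`, `q75` - one row
#'   per reported quantity, quartiles where applicable (the diffusivity row
#'   carries its 95% CI half-width in `ci95` instead).
#' @export
tidy.kinematics_summary <- function(x, ...) {
  tibble(
    parameter = c("n_cells", "speed_um_hr", "step_x_um", "step_y_um",
                  "tau_hr", "D_um2_hr", "t_div_hr",
                  "death_fraction_10hr", "death_fraction_20hr",
                  "pearson_r", "ks_p", "mwu_p"),
    value = c(x$n_cells, x$speed$median_um_hr,
              x$step_lengths$median_um[1], x$step_lengths$median_um[2],
              x$tau$tau_median_hr, x$fit$D, x$t_div$median_hr,
              x$death_fraction_10hr, x$death_fraction_20hr,
              x$isotropy$pearson_r, x$isotropy$ks_p, x$isotropy$mwu_p),
    q25 = c(NA, x$speed$q25_um_hr,
            x$step_lengths$q25_um[1], x$step_lengths$q25_um[2],
            x$tau$tau_q25_hr, NA, x$t_div$q25_hr, NA, NA, NA, NA, NA),
    q75 = c(NA, x$speed$q75_um_hr,
            x$step_lengths$q75_um[1], x$step_lengths$q75_um[2],
            x$tau$tau_q75_hr, NA, x$t_div$q75_hr, NA, NA, NA, NA, NA),
    ci95 = c(NA, NA, NA, NA, NA, x$fit$D_ci95, NA, NA, NA, NA, NA, NA)
  )
}

#' Tidy a seeding model
#'
#' @param x A [seeding_model()] object.
#' @param ... Unused.
#' @return A long tibble of the model's inputs and derived prognostics.
#' @export
tidy.seeding_model <- function(x, ...) {
  tibble(
    parameter = c("n0_cm2", "D_um2_hr", "dc_um", "alpha",
                  "d0_um", "t0_hr", "theta_rad", "P", "P_squared", "n0_max_cm2"),
    value = c(x$n0_cm2, x$D_um2_hr, x$dc_um, x$alpha,
              x$d0_um, x$t0_hr, x$theta_rad, x$P, x$P_squared, x$n0_max_cm2),
    role = c(rep("input", 4), rep("derived", 6))
  )
}

#' Glance at a seeding model
#'
#' @inheritParams tidy.seeding_model
#' @return A one-row tibble of the derived prognostics.
#' @export
glance.seeding_model <- function(x, ...) {
  tibble(d0_um = x$d0_um, t0_hr = x$t0_hr, theta_rad = x$theta_rad,
         P = x$P, P_squared = x$P_squared, n0_max_cm2 = x$n0_max_cm2)
}

#' Tidy a diffusivity-vs-cell-number extrapolation
#'
#' @param x An [extrapolate_diffusivity()] object.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` rows for the slope, the
#'   intercept and the zero-diffusivity cell count.
#' @export
tidy.diffusivity_extrapolation <- function(x, ...) {
  tibble(term = c("intercept", "slope", "n_zero"),
         estimate = c(x$intercept, x$slope, x$n_zero))
}
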