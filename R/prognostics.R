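# 1 cm^2 = 1e8 um^2
CM2_PER_UM2 <- 1e8

#' Mean inter-cell distance at a seeding density
#'
#' For cells plated at density n0 the mean inter-cell distance is
#' d0 = 1/sqrt(n0).
#'
#' @param n0_cm2 Seeding density in cells/cm^2 (> 0).
#' @return d0 in um.
#' @export
mean_separation <- function(n0_cm2) {
  stopifnot(n0_cm2 > 0)
  1 / sqrt(n0_cm2 / CM2_PER_UM2)
}

#' Encounter timescale of neighbouring cells
#'
#' Two neighbouring cells plated d0 apart, each diffusing with diffusivity D,
#' have typical displacement L = sqrt(2 D t); their displacement circles
#' first touch when L ~ d0/2, i.e. at t0 = d0^2 / (8 D) = 1 / (8 D n0).
#'
#' @param n0_cm2 Seeding density in cells/cm^2 (> 0).
#' @param D Diffusivity in um^2/hr (> 0).
#' @return t0 in hours.
#' @examples
#' encounter_time(1500, 80)    # 104.2 hr
#' encounter_time(1500, 58.5)  # 142.5 hr
#' @export
encounter_time <- function(n0_cm2, D) {
  if (!(n0_cm2 > 0) || !(D > 0)) {
    abort("n0 and D must be positive", class = "stemwalk_domain_error")
  }
  1 / (8 * D * n0_cm2 / CM2_PER_UM2)
}

#' Probability that two neighbouring cells form a pair
#'
#' At the encounter time each cell sits uniformly on a circle of radius d0/2
#' around its plating position. The cells interact when they come within the
#' critical distance dc, which subtends an angle theta = 2 arccos(dc/d0) at
#' each circle; the probability that one cell falls in that arc is
#' P = theta/(2 pi), and, the two walks being independent, the pair forms
#' with probability P^2 = arccos^2(dc/d0) / pi^2 (at most 1/4, in the limit
#' dc/d0 -> 0).
#'
#' @param dc Critical interaction distance in um (0 < dc <= d0).
#' @param d0 Mean inter-cell distance in um.
#' @return A one-row tibble with `theta_rad`, `P`, `P_squared`.
#' @export
pair_formation_probability <- function(dc, d0) {
  if (!(dc > 0)) abort("dc must be positive", class = "stemwalk_domain_error")
  if (dc > d0) {
    abort("dc must not exceed d0: arccos(dc/d0) undefined",
          class = "stemwalk_domain_error")
  }
  theta <- 2 * acos(dc / d0)
  tibble(theta_rad = theta, P = theta / (2 * pi), P_squared = acos(dc / d0)^2 / pi^2)
}

#' Maximal seeding density for clonal colonies
#'
#' Keeping the pair-formation probability below a tolerance alpha requires
#' n0 < cos^2(pi sqrt(alpha)) / dc^2. Valid for 0 < alpha < 1/4, the branch
#' on which the cosine stays positive.
#'
#' @param alpha Tolerated pair-formation probability, in (0, 0.25).
#' @param dc Critical interaction distance in um (> 0).
#' @return The density bound in cells/cm^2.
#' @examples
#' max_seeding_density(0.1, 150)  # ~1324, i.e. 1300 at 2 s.f.
#' @export
max_seeding_density <- function(alpha, dc) {
  if (!(alpha > 0) || !(alpha < 0.25)) {
    abort("alpha must lie in (0, 0.25)", class = "stemwalk_domain_error")
  }
  if (!(dc > 0)) abort("dc must be positive", class = "stemwalk_domain_error")
  cos(pi * sqrt(alpha))^2 / dc^2 * CM2_PER_UM2
}

#' Seeding-density prognostic model
#'
#' Bundles the analytic prognostics for clonal colony formation at a given
#' seeding density: the mean inter-cell distance d0, the encounter timescale
#' t0, the pair-formation geometry (theta, P, P^2) at the critical distance
#' dc, and the maximal density keeping the pair probability below alpha.
#'
#' @param n0_cm2 Seeding density in cells/cm^2.
#' @param D Diffusivity in um^2/hr.
#' @param dc Critical interaction distance in um (default 150, the radius
#'   below which tracked hESCs interact).
#' @param alpha Tolerated pair-formation probability (default 0.1).
#' @return An object of class `seeding_model`; supports [tidy()] and
#'   [glance()].
#' @examples
#' m <- seeding_model(1500, 80)
#' glance(m)
#' @export
seeding_model <- function(n0_cm2, D, dc = 150, alpha = 0.1) {
  d0 <- mean_separation(n0_cm2)
  prob <- pair_formation_probability(dc, d0)
  structure(list(
    n0_cm2 = n0_cm2, D_um2_hr = D, dc_um = dc, alpha = alpha,
    d0_um = d0, t0_hr = encounter_time(n0_cm2, D),
    theta_rad = prob$theta_rad, P = prob$P, P_squared = prob$P_squared,
    n0_max_cm2 = max_seeding_density(alpha, dc)
  ), class = "seeding_model")
}

#' @export
print.seeding_model <- function(x, ...) {
  cat("Seeding-density prognostic model\n")
  cat(sprintf("  inputs : n0 = %g cells/cm^2, D = %g um^2/hr, dc = %g um, alpha = %g\n",
              x$n0_cm2, x$D_um2_hr, x$dc_um, x$alpha))
  cat(sprintf("  d0     = %.1f um (mean inter-cell distance)\n", x$d0_um))
  cat(sprintf("  t0     = %.0f hr (encounter timescale)\n", x$t0_hr))
  cat(sprintf("  P^2    = %.4f (pair-formation probability at t ~ t0)\n", x$P_squared))
  cat(sprintf("  n0_max = %.0f cells/cm^2 (about %g at 2 s.f.) for P^2 < %g\n",
              x$n0_max_cm2, signif(x$n0_max_cm2, 2), x$alpha))
  invisible(x)
}

#' Extrapolate diffusivity versus cell number
#'
#' Straight-line fit of diffusivity against the number of cells in an
#' aggregate (1 = single cells, 2 = pairs, ...), extrapolated to the cell
#' count at which the diffusivity reaches zero - an estimate of the smallest
#' aggregate that no longer migrates and can settle into a colony.
#'
#' @param points A data frame with columns `n_cells` and `D_um2_hr` (at
#'   least 2 distinct cell counts).
#' @return An object of class `diffusivity_extrapolation` with `slope`,
#'   `intercept`, `n_zero` (fractional) and `n_zero_rounded`; supports
#'   [tidy()].
#' @examples
#' extrapolate_diffusivity(data.frame(n_cells = c(1, 2), D_um2_hr = c(79.8, 58.5)))
#' @export
extrapolate_diffusivity <- function(points) {
  stopifnot(all(c("n_cells", "D_um2_hr") %in% names(points)))
  if (length(unique(points$n_cells)) < 2) {
    abort("need at least 2 distinct cell counts", class = "stemwalk_argument_error")
  }
  fit <- lm(D_um2_hr ~ n_cells, data = points)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    abort("diffusivity does not decrease with cell number: no zero crossing",
          class = "stemwalk_fit_error")
  }
  n_zero <- -intercept / slope
  structure(list(points = as_tibble(points), slope = slope,
                 intercept = intercept, n_zero = n_zero,
                 n_zero_rounded = round(n_zero)),
            class = "diffusivity_extrapolation")
}

#' @export
print.diffusivity_extrapolation <- function(x, ...) {
  cat(sprintf(
    "Diffusivity extrapolation: D = %.3g %+.3g * N; D = 0 at N = %.3g (about %d cells)\n",
    x$intercept, x$slope, x$n_zero, x$n_zero_rounded))
  invisible(x)
}

#' Monte-Carlo first-contact simulation for two diffusing cells
#'
#' Simulates pairs of independent fixed-leg walks started a distance d0 apart
#' and records the first time their separation falls to dc or below (censored
#' at the walk duration). Provided for qualitative checks of the analytic
#' encounter model - e.g. the diffusive scaling of contact times with d0^2 -
#' not as an estimator of the pair-formation probability.
#'
#' @param d0 Initial separation in um (> dc).
#' @param dc Contact distance in um (> 0).
#' @param walk A [walk_params()] object (speed, correlation time, sampling).
#' @param n_rep Number of replicate pair simulations (>= 1).
#' @param seed Integer seed.
#' @return An object of class `encounter_sim`: a list with
#'   `first_contact_hr` (length `n_rep`, NA when censored),
#'   `contact_fraction` (tibble `t_hr`, `fraction` of pairs in contact by t),
#'   `median_contact_hr` (NA when fewer than half made contact),
#'   `contacted_fraction` and `n_rep`.
#' @export
simulate_encounter <- function(d0, dc, walk, n_rep, seed) {
  stopifnot(d0 > 0, dc > 0, n_rep >= 1, inherits(walk, "walk_params"))
  first_contact <- withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      if (dc >= d0) return(0)
      a <- sample_fixed_leg_walk(walk$v, walk$tau, walk$dt, walk$duration, c(0, 0))
      b <- sample_fixed_leg_walk(walk$v, walk$tau, walk$dt, walk$duration, c(d0, 0))
      s <- sqrt((a[, "x"] - b[, "x"])^2 + (a[, "y"] - b[, "y"])^2)
      hit <- which(s <= dc)
      if (length(hit) == 0) NA_real_ else a[hit[1], "t"]
    }, numeric(1))
  })
  tt <- seq(0, walk$duration, by = walk$dt)
  frac <- vapply(tt, function(t) mean(!is.na(first_contact) & first_contact <= t),
                 numeric(1))
  contacted <- mean(!is.na(first_contact))
  structure(list(
    first_contact_hr = first_contact,
    contact_fraction = tibble(t_hr = tt, fraction = frac),
    median_contact_hr = if (contacted >= 0.5) {
      unname(quantile(ifelse(is.na(first_contact), Inf, first_contact), 0.5))
    } else {
      NA_real_
    },
    contacted_fraction = contacted,
    n_rep = n_rep
  ), class = "encounter_sim")
}
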