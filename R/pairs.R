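#' Kinematics of a cell pair
#'
#' Restricts two tracks to their common sampling times and computes the pair
#' centroid (midpoint), the relative vector, the separation s(t), and the
#' per-frame pair-centroid and relative speeds. The pair centroid velocity is
#' the vector average of the two cell velocities, v_pc = (v1 + v2)/2, and the
#' relative velocity their difference, v_r = v1 - v2; the reported speeds are
#' the vector magnitudes. Velocities are finite differences over one frame
#' and are attached to the frame's end time (NA at the first common time).
#'
#' @param t1,t2 Single-track tibbles sharing at least 2 common grid times.
#' @param pair_id Optional identifier for the pair.
#' @return An object of class `pair_series`: a list with `data` (tibble
#'   `t_hr`, `elapsed_hr`, `cx_um`, `cy_um`, `rx_um`, `ry_um`, `s_um`,
#'   `v1_um_hr`, `v2_um_hr`, `vpc_um_hr`, `vr_um_hr`), summary scalars `s0`,
#'   `s_f`, `s_max` (um), `t_max_hr` (earliest time of maximum separation,
#'   elapsed) and `tracking_hr`, plus `pair_id` and `dt`.
#' @export
pair_kinematics <- function(t1, t2, pair_id = NULL) {
  a <- dplyr::arrange(as_tibble(t1), .data$t_hr)
  b <- dplyr::arrange(as_tibble(t2), .data$t_hr)
  key_a <- round(a$t_hr, 9)
  key_b <- round(b$t_hr, 9)
  common <- intersect(key_a, key_b)
  if (length(common) < 2) {
    abort("tracks share fewer than 2 common sample times",
          class = "stemwalk_argument_error")
  }
  a <- a[match(sort(common), key_a), ]
  b <- b[match(sort(common), key_b), ]
  tt <- a$t_hr
  dt <- min(diff(tt))
  cx <- (a$x_um + b$x_um) / 2
  cy <- (a$y_um + b$y_um) / 2
  rx <- a$x_um - b$x_um
  ry <- a$y_um - b$y_um
  s <- sqrt(rx^2 + ry^2)
  dtv <- diff(tt)
  v1x <- diff(a$x_um) / dtv; v1y <- diff(a$y_um) / dtv
  v2x <- diff(b$x_um) / dtv; v2y <- diff(b$y_um) / dtv
  v1 <- c(NA, sqrt(v1x^2 + v1y^2))
  v2 <- c(NA, sqrt(v2x^2 + v2y^2))
  vpc <- c(NA, sqrt(((v1x + v2x) / 2)^2 + ((v1y + v2y) / 2)^2))
  vr <- c(NA, sqrt((v1x - v2x)^2 + (v1y - v2y)^2))
  i_max <- which.max(s)  # which.max returns the earliest maximum
  structure(list(
    data = tibble(t_hr = tt, elapsed_hr = tt - tt[1],
                  cx_um = cx, cy_um = cy, rx_um = rx, ry_um = ry, s_um = s,
                  v1_um_hr = v1, v2_um_hr = v2,
                  vpc_um_hr = vpc, vr_um_hr = vr),
    s0 = s[1], s_f = s[length(s)], s_max = s[i_max],
    t_max_hr = tt[i_max] - tt[1],
    tracking_hr = tt[length(tt)] - tt[1],
    pair_id = pair_id %||% paste(a$track_id[1], b$track_id[1], sep = "+"),
    dt = dt
  ), class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat(sprintf(
    "<pair_series> %s: %.4g hr tracked, s0 = %.3g, s_f = %.3g, s_max = %.3g um (at %.3g hr)\n",
    x$pair_id, x$tracking_hr, x$s0, x$s_f, x$s_max, x$t_max_hr))
  invisible(x)
}

#' Extract sibling pairs from a lineage-resolved ensemble
#'
#' Pairs are formed from tracks sharing a parent (the two daughters of each
#' division) and restricted to their common time window.
#'
#' @param ensemble An [as_ensemble()] object.
#' @return A list of [pair_kinematics()] objects, named by the parent track;
#'   pairs with fewer than 2 common sample times are dropped with a warning.
#' @export
sibling_pairs <- function(ensemble) {
  x <- as_tibble(ensemble)
  kids <- unique(x[!is.na(x$parent_id), c("track_id", "parent_id")])
  parents <- names(which(table(kids$parent_id) == 2))
  out <- list()
  for (p in parents) {
    ids <- kids$track_id[kids$parent_id == p]
    res <- tryCatch(
      pair_kinematics(x[x$track_id == ids[1], ], x[x$track_id == ids[2], ],
                      pair_id = p),
      stemwalk_argument_error = function(e) NULL)
    if (is.null(res)) {
      warn(sprintf("pair from parent '%s' has fewer than 2 common times; dropped", p))
    } else {
      out[[p]] <- res
    }
  }
  out
}

#' Classify a pair as repel-only (A) or repel-then-attract (B)
#'
#' The observed distinction between the two behaviours is whether the
#' separation keeps (close to) its maximum until the end of tracking. The
#' classifier uses the ratio of final to maximum separation: label B when
#' s_f / s_max falls below the threshold, else A. The default threshold 0.6
#' separates the reported class medians (0.96 for A, 0.35 for B) with a wide
#' margin; the ratio and threshold used are always recorded.
#'
#' @param series A [pair_kinematics()] object.
#' @param ratio_threshold Classification threshold on s_f / s_max.
#' @return A one-row tibble with `pair_id`, `label` ("A" or "B"), `ratio`,
#'   `threshold`.
#' @export
classify_pair <- function(series, ratio_threshold = 0.6) {
  stopifnot(inherits(series, "pair_series"))
  if (series$s_max <= 0) {
    abort("cannot classify: maximum separation is zero", class = "stemwalk_argument_error")
  }
  ratio <- series$s_f / series$s_max
  tibble(pair_id = series$pair_id,
         label = if (ratio < ratio_threshold) "B" else "A",
         ratio = ratio, threshold = ratio_threshold)
}

#' Classify a list of pairs
#'
#' @param pairs A list of [pair_kinematics()] objects.
#' @inheritParams classify_pair
#' @return A tibble with one row per pair ([classify_pair()] columns).
#' @export
classify_pairs <- function(pairs, ratio_threshold = 0.6) {
  dplyr::bind_rows(lapply(pairs, classify_pair, ratio_threshold = ratio_threshold))
}

#' Pair-centroid diffusivity
#'
#' Mean-squared displacement of the pair centroid from the pair's first
#' common position, averaged over pairs at each elapsed time, fitted with the
#' same zero-intercept least squares as single cells.
#'
#' @param pairs A list of [pair_kinematics()] objects (or a single one).
#' @param window Fit window in hours.
#' @return A [fit_diffusivity()] object.
#' @export
pair_centroid_diffusivity <- function(pairs, window = c(0, 7)) {
  if (inherits(pairs, "pair_series")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1)
  dt <- min(vapply(pairs, `[[`, numeric(1), "dt"))
  disp <- dplyr::bind_rows(lapply(pairs, function(p) {
    d <- p$data
    tibble(elapsed_hr = round(d$elapsed_hr / dt) * dt,
           L2_um2 = (d$cx_um - d$cx_um[1])^2 + (d$cy_um - d$cy_um[1])^2)
  }))
  msd <- dplyr::summarise(
    dplyr::group_by(disp, t_hr = .data$elapsed_hr),
    mean_sq_um2 = mean(.data$L2_um2),
    median_sq_um2 = median(.data$L2_um2),
    n_live = dplyr::n(), .groups = "drop")
  msd <- dplyr::arrange(msd, .data$t_hr)
  if (sum(msd$t_hr >= window[1] & msd$t_hr <= window[2]) < 3) {
    abort("fewer than 3 centroid MSD points in the fit window",
          class = "stemwalk_fit_error")
  }
  fit_diffusivity(msd, window = window)
}

#' Summary statistics of a collection of pairs, per class
#'
#' Medians and quartiles of the standard pair quantities (initial, final and
#' maximum separation, time to maximum separation, individual-cell speed,
#' pair-centroid speed and relative speed, tracking time), per class label.
#' Speeds pool per-frame values across pairs; per-pair medians are available
#' through each pair's `data`.
#'
#' @param pairs A list of [pair_kinematics()] objects.
#' @param labels Optional [classify_pairs()] tibble; when omitted all pairs
#'   are summarized as one class `"all"`.
#' @return A tibble with one row per (class, statistic): columns `label`,
#'   `statistic`, `q25`, `median`, `q75`, `n_pairs`.
#' @export
pair_summary <- function(pairs, labels = NULL) {
  stopifnot(length(pairs) >= 1)
  if (is.null(labels)) {
    lab <- stats::setNames(rep("all", length(pairs)),
                           vapply(pairs, `[[`, character(1), "pair_id"))
  } else {
    lab <- stats::setNames(labels$label, labels$pair_id)
  }
  rows <- list()
  for (cls in unique(lab)) {
    sel <- pairs[vapply(pairs, function(p) identical(lab[[p$pair_id]], cls), logical(1))]
    if (length(sel) == 0) {
      warn(sprintf("class '%s' has no pairs; omitted", cls))
      next
    }
    scalar <- function(f) vapply(sel, `[[`, numeric(1), f)
    pooled <- function(col) {
      v <- unlist(lapply(sel, function(p) p$data[[col]]))
      v[is.finite(v)]
    }
    stat_row <- function(name, v) {
      tibble(label = cls, statistic = name,
             q25 = unname(quantile(v, 0.25)), median = median(v),
             q75 = unname(quantile(v, 0.75)), n_pairs = length(sel))
    }
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      stat_row("tracking_hr", scalar("tracking_hr")),
      stat_row("s0_um", scalar("s0")),
      stat_row("sf_um", scalar("s_f")),
      stat_row("smax_um", scalar("s_max")),
      stat_row("tmax_hr", scalar("t_max_hr")),
      stat_row("v_um_hr", c(pooled("v1_um_hr"), pooled("v2_um_hr"))),
      stat_row("vpc_um_hr", pooled("vpc_um_hr")),
      stat_row("vr_um_hr", pooled("vr_um_hr"))
    )
  }
  dplyr::bind_rows(rows)
}

#' Compare relative speeds between two groups of pairs
#'
#' Kolmogorov-Smirnov and Mann-Whitney U tests on the pooled per-frame
#' relative speeds of two groups (e.g. Type A vs Type B). Identical samples
#' are reported with p = 1 by convention.
#'
#' @param a,b Lists of [pair_kinematics()] objects, or numeric vectors of
#'   per-frame relative speeds in um/hr.
#' @return A one-row tibble with `median_a`, `median_b`, `ks_p`, `mwu_p`.
#' @export
compare_relative_speeds <- function(a, b) {
  pool <- function(x) {
    if (is.numeric(x)) return(x[is.finite(x)])
    if (inherits(x, "pair_series")) x <- list(x)
    v <- unlist(lapply(x, function(p) p$data$vr_um_hr))
    v[is.finite(v)]
  }
  va <- pool(a); vb <- pool(b)
  stopifnot(length(va) > 0, length(vb) > 0)
  if (isTRUE(all.equal(sort(va), sort(vb)))) {
    ks_p <- 1; mwu_p <- 1
  } else {
    ks_p <- suppressWarnings(stats::ks.test(va, vb)$p.value)
    mwu_p <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
  }
  tibble(median_a = median(va), median_b = median(vb), ks_p = ks_p, mwu_p = mwu_p)
}
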