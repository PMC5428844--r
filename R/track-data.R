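#' Build a trajectory ensemble from a data frame
#'
#' An *ensemble* is the unit of analysis: a set of cell tracks sharing one
#' sampling grid. It is stored as a tibble in long format with one row per
#' (track, frame) and columns `track_id`, `parent_id`, `frame`, `t_hr`,
#' `x_um`, `y_um`, `fate`, carrying the sampling interval `dt` (hours), an
#' optional `pixel_size` (um/pixel) and a free-text `label` as attributes.
#'
#' Positions are continuous 2D coordinates in micrometres; no pixel grid is
#' imposed on stored data. Frames are 0-based; the time column is
#' authoritative and the frame index is kept as a consistency check.
#'
#' @param x A data frame with the tracks-CSV columns (see [read_tracks()]).
#' @param dt Sampling interval in hours. When `NULL`, inferred as the modal
#'   inter-sample spacing across tracks.
#' @param pixel_size Optional pixel size in um/pixel (metadata only).
#' @param label Free-text scenario tag.
#' @param validate If `TRUE` (default), invariant violations raise an error;
#'   use [validate_ensemble()] for a non-raising report.
#' @return A tibble of class `ensemble`.
#' @seealso [read_tracks()], [write_tracks()], [validate_ensemble()]
#' @export
as_ensemble <- function(x, dt = NULL, pixel_size = NULL, label = "", validate = TRUE) {
  missing_cols <- setdiff(tracks_columns(), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "stemwalk_format_error")
  }
  x <- as_tibble(x)[tracks_columns()]
  x$track_id <- as.character(x$track_id)
  x$parent_id <- as.character(x$parent_id)
  x$parent_id[!is.na(x$parent_id) & x$parent_id == ""] <- NA_character_
  x$frame <- as.integer(x$frame)
  x <- dplyr::arrange(x, .data$track_id, .data$frame)
  if (is.null(dt)) dt <- infer_dt(x)
  e <- new_ensemble(x, dt = dt, pixel_size = pixel_size, label = label)
  if (validate) {
    report <- validate_ensemble(e)
    if (nrow(report) > 0) {
      abort(paste0("invalid ensemble:\n",
                   paste("-", report$message, collapse = "\n")),
            class = "stemwalk_validation_error")
    }
  }
  e
}

new_ensemble <- function(x, dt, pixel_size = NULL, label = "") {
  structure(x,
            dt = dt, pixel_size = pixel_size, label = label,
            class = c("ensemble", class(tibble())))
}

infer_dt <- function(x) {
  gaps <- unlist(lapply(split(x$t_hr, x$track_id), diff), use.names = FALSE)
  gaps <- gaps[is.finite(gaps) & gaps > 0]
  if (length(gaps) == 0) {
    abort("cannot infer sampling interval: no positive inter-sample gaps",
          class = "stemwalk_validation_error")
  }
  gaps <- round(gaps, 9)
  as.numeric(names(sort(table(gaps), decreasing = TRUE))[1])
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d tracks, dt = %g hr%s\n",
              length(unique(x$track_id)), attr(x, "dt"),
              if (nzchar(attr(x, "label") %||% "")) paste0(", label: ", attr(x, "label")) else ""))
  NextMethod()
}

#' Sampling interval of an ensemble
#' @param ensemble An [as_ensemble()] object.
#' @return The sampling interval in hours.
#' @export
ensemble_dt <- function(ensemble) {
  attr(ensemble, "dt") %||% infer_dt(ensemble)
}

#' Validate an ensemble against the track invariants
#'
#' Checks every stored invariant without raising: at least 2 samples per
#' track, strictly increasing times and frame indices, uniform sampling at
#' the ensemble interval (to 1e-9 hr), unique (track, frame) rows, resolvable
#' parent links, known fate labels and a positive `dt`. Never mutates input.
#'
#' @param ensemble A data frame with tracks-CSV columns (typically an
#'   [as_ensemble()] result).
#' @return A tibble with columns `rule`, `track_id`, `message`; zero rows
#'   when the ensemble is valid.
#' @export
validate_ensemble <- function(ensemble) {
  v <- list()
  add <- function(rule, track_id, message) {
    v[[length(v) + 1]] <<- tibble(rule = rule, track_id = track_id, message = message)
  }
  dt <- attr(ensemble, "dt")
  if (!is.null(dt) && (!is.finite(dt) || dt <= 0)) {
    add("dt_positive", NA_character_, sprintf("sampling interval dt = %g is not positive", dt))
    dt <- NULL
  }
  bad_fate <- unique(ensemble$fate[!is.na(ensemble$fate) & !(ensemble$fate %in% track_fates())])
  for (f in bad_fate) {
    add("fate_known", NA_character_,
        sprintf("unknown fate label '%s' (valid: %s)", f, paste(track_fates(), collapse = ", ")))
  }
  by_track <- split(seq_len(nrow(ensemble)), ensemble$track_id)
  for (id in names(by_track)) {
    rows <- ensemble[by_track[[id]], ]
    rows <- rows[order(rows$frame), ]
    if (nrow(rows) < 2) {
      add("min_samples", id, sprintf("track '%s' has fewer than 2 samples", id))
      next
    }
    if (anyDuplicated(rows$frame)) {
      add("unique_frames", id, sprintf("track '%s' has duplicate frame indices", id))
    }
    if (any(diff(rows$frame) <= 0)) {
      add("frames_increasing", id, sprintf("track '%s' has non-increasing frame indices", id))
    }
    if (any(diff(rows$t_hr) <= 0)) {
      add("times_increasing", id, sprintf("track '%s' has non-monotonic sample times", id))
      next
    }
    if (!is.null(dt) && any(abs(diff(rows$t_hr) - dt) > 1e-9)) {
      add("uniform_spacing", id,
          sprintf("track '%s' sample spacing deviates from dt = %g hr", id, dt))
    }
  }
  ids <- unique(ensemble$track_id)
  parents <- unique(ensemble[!is.na(ensemble$parent_id), c("track_id", "parent_id")])
  dangling <- parents[!(parents$parent_id %in% ids), ]
  for (i in seq_len(nrow(dangling))) {
    add("parent_resolves", dangling$track_id[i],
        sprintf("track '%s' lists parent '%s' absent from the ensemble",
                dangling$track_id[i], dangling$parent_id[i]))
  }
  mixed_parent <- names(which(vapply(
    split(ensemble$parent_id, ensemble$track_id),
    function(p) length(unique(p)) > 1, logical(1))))
  for (id in mixed_parent) {
    add("consistent_parent", id, sprintf("track '%s' has inconsistent parent_id rows", id))
  }
  mixed_fate <- names(which(vapply(
    split(ensemble$fate, ensemble$track_id),
    function(p) length(unique(p)) > 1, logical(1))))
  for (id in mixed_fate) {
    add("consistent_fate", id, sprintf("track '%s' has inconsistent fate rows", id))
  }
  if (length(v) == 0) {
    tibble(rule = character(), track_id = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Read tracked cell trajectories from a tracks-CSV file
#'
#' The tracks-CSV dialect is UTF-8, comma-separated, with header exactly
#' `track_id,parent_id,frame,t_hr,x_um,y_um,fate`, one row per (track, frame),
#' decimal points, rows sorted by (track_id, frame), and a missing parent
#' serialized as an empty field.
#'
#' @param path Path to a tracks-CSV file.
#' @param label Optional scenario tag attached to the ensemble.
#' @return An [as_ensemble()] tibble; `dt` is inferred as the modal
#'   inter-sample spacing.
#' @export
read_tracks <- function(path, label = "") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "stemwalk_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(tracks_columns(), header)
  extra_cols <- setdiff(header, tracks_columns())
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    parts <- c(
      if (length(missing_cols) > 0) paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      if (length(extra_cols) > 0) paste0("unexpected column(s): ", paste(extra_cols, collapse = ", "))
    )
    abort(paste0("not a tracks-CSV file: ", paste(parts, collapse = "; ")),
          class = "stemwalk_format_error")
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      track_id = readr::col_character(),
      parent_id = readr::col_character(),
      frame = readr::col_integer(),
      t_hr = readr::col_double(),
      x_um = readr::col_double(),
      y_um = readr::col_double(),
      fate = readr::col_character()
    ),
    na = "", progress = FALSE
  )
  as_ensemble(x, label = label)
}

#' Write an ensemble to a tracks-CSV file
#'
#' Serializes with full double precision so that `read_tracks(write_tracks(e))`
#' reproduces the ensemble exactly; a missing parent becomes an empty field.
#' An empty ensemble yields a header-only file.
#'
#' @param ensemble An [as_ensemble()] object (or data frame with its columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ensemble, path) {
  x <- as_tibble(ensemble)[tracks_columns()]
  x <- dplyr::arrange(x, .data$track_id, .data$frame)
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Build the lineage tree of an ensemble
#'
#' One row per track with its parent, founder, generation, first/last sample
#' time and event time (the last sample time when the track ended in division
#' or death). Founders are ordered by time to their first division or death,
#' the convention used for lineage-tree displays of tracked colonies.
#'
#' @param ensemble An [as_ensemble()] object.
#' @return A tibble of class `lineage_tree` with columns `track_id`,
#'   `parent_id`, `founder_id`, `generation`, `fate`, `t_start_hr`,
#'   `t_end_hr`, `event_hr`, `n_children`, ordered founders-first by event
#'   time.
#' @export
build_lineage <- function(ensemble) {
  per_track <- dplyr::summarise(
    dplyr::group_by(as_tibble(ensemble), .data$track_id),
    parent_id = .data$parent_id[1],
    fate = .data$fate[1],
    t_start_hr = min(.data$t_hr),
    t_end_hr = max(.data$t_hr),
    .groups = "drop"
  )
  kids <- table(per_track$parent_id[!is.na(per_track$parent_id)])
  per_track$n_children <- as.integer(kids[per_track$track_id])
  per_track$n_children[is.na(per_track$n_children)] <- 0L
  bad <- per_track$fate == "divided" & per_track$n_children != 2L
  if (any(bad)) {
    abort(sprintf("track(s) marked 'divided' without exactly 2 children: %s",
                  paste(per_track$track_id[bad], collapse = ", ")),
          class = "stemwalk_validation_error")
  }
  parent_of <- stats::setNames(per_track$parent_id, per_track$track_id)
  end_of <- stats::setNames(per_track$t_end_hr, per_track$track_id)
  start_of <- stats::setNames(per_track$t_start_hr, per_track$track_id)
  late <- !is.na(per_track$parent_id) &
    start_of[per_track$track_id] < end_of[per_track$parent_id] - 1e-9
  if (any(late, na.rm = TRUE)) {
    abort(sprintf("child track(s) starting before their parent ends: %s",
                  paste(per_track$track_id[which(late)], collapse = ", ")),
          class = "stemwalk_validation_error")
  }
  root_gen <- function(id) {
    gen <- 0L
    seen <- character()
    while (!is.na(parent_of[[id]])) {
      if (id %in% seen) {
        abort("lineage contains a cycle", class = "stemwalk_validation_error")
      }
      seen <- c(seen, id)
      id <- parent_of[[id]]
      gen <- gen + 1L
    }
    list(founder = id, generation = gen)
  }
  rg <- lapply(per_track$track_id, root_gen)
  per_track$founder_id <- vapply(rg, `[[`, character(1), "founder")
  per_track$generation <- vapply(rg, `[[`, integer(1), "generation")
  per_track$event_hr <- ifelse(per_track$fate %in% c("divided", "died"),
                               per_track$t_end_hr, NA_real_)
  founder_event <- stats::setNames(per_track$event_hr, per_track$track_id)
  founders <- per_track[per_track$generation == 0L, ]
  founder_rank <- rank(ifelse(is.na(founders$event_hr), Inf, founders$event_hr),
                       ties.method = "first")
  rank_of <- stats::setNames(founder_rank, founders$track_id)
  out <- dplyr::arrange(per_track, rank_of[.data$founder_id], .data$generation,
                        .data$t_start_hr, .data$track_id)
  out <- out[, c("track_id", "parent_id", "founder_id", "generation", "fate",
                 "t_start_hr", "t_end_hr", "event_hr", "n_children")]
  structure(out, class = c("lineage_tree", class(tibble())))
}

#' Founder time-to-first-event summary of a lineage
#'
#' @param lineage A [build_lineage()] result.
#' @return A tibble with one row per founder: `track_id`, `fate`, `event_hr`.
#' @export
founder_events <- function(lineage) {
  founders <- lineage[lineage$generation == 0L, ]
  tibble(track_id = founders$track_id, fate = founders$fate,
         event_hr = founders$event_hr)
}

# bind a list of per-track tibbles into one ensemble
#' Combine individual tracks into an ensemble
#'
#' @param tracks A list of track tibbles (tracks-CSV columns).
#' @inheritParams as_ensemble
#' @return An [as_ensemble()] object.
#' @export
bind_tracks <- function(tracks, dt = NULL, pixel_size = NULL, label = "") {
  as_ensemble(dplyr::bind_rows(tracks), dt = dt, pixel_size = pixel_size, label = label)
}
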