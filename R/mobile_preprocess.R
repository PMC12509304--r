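# Preprocessing of raw 1 Hz mobile readings into per-segment aggregates.
#
# The pipeline order is fixed: plausibility filter -> campaign-wide
# winsorization (per pollutant) -> reference-site temporal correction ->
# snapping to segments -> drive-pass construction -> mean-of-means
# aggregation. Winsorization is applied campaign-wide because the trimming
# targets instrument artifacts of the whole raw series, not day-level
# extremes.

#' Remove improbable measurement values
#'
#' Drops readings outside the plausible concentration range for the pollutant
#' and reports how many were removed.
#'
#' @param readings tibble with a `concentration` column.
#' @param plausible_range numeric length 2, `c(low, high)`, `low < high`.
#' @param quiet suppress the removal message.
#' @return the filtered tibble; the number of removed rows is available as
#'   attribute `"n_removed"`.
#' @export
filter_improbable <- function(readings, plausible_range, quiet = FALSE) {
  if (length(plausible_range) != 2 || plausible_range[1] >= plausible_range[2]) {
    stop_invalid("`plausible_range` must be c(low, high) with low < high.")
  }
  assert_columns(readings, "concentration", "`readings`")
  keep <- readings$concentration >= plausible_range[1] &
    readings$concentration <= plausible_range[2] &
    is.finite(readings$concentration)
  out <- readings[keep, ]
  n_removed <- sum(!keep)
  if (!quiet && n_removed > 0) {
    inform(sprintf("filter_improbable: removed %d of %d readings.",
                   n_removed, nrow(readings)))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Winsorize a vector of concentrations
#'
#' Values below the lower percentile are set to it, values above the upper
#' percentile likewise; order and length are preserved. Percentiles use the
#' linear-interpolation rule (`stats::quantile` type 7).
#'
#' @param values numeric vector, non-empty.
#' @param lower_pct,upper_pct percentile bounds in \[0, 100\],
#'   `lower_pct < upper_pct`.
#' @return the winsorized vector.
#' @export
#' @examples
#' winsorize(c(1, 2, 3, 100), 0, 75)
winsorize <- function(values, lower_pct = 2.5, upper_pct = 97.5) {
  if (length(values) == 0) stop_invalid("`values` must be non-empty.")
  if (lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    stop_invalid("Require 0 <= lower_pct < upper_pct <= 100.")
  }
  q <- quantile(values, probs = c(lower_pct, upper_pct) / 100,
                names = FALSE, type = 7)
  pmin(pmax(values, q[1]), q[2])
}

#' Reference-site temporal correction
#'
#' Removes campaign-wide background fluctuation: each reading is corrected by
#' the deviation of the reference site's hourly value from the reference's
#' campaign mean, `corrected = raw - (ref(hour) - mean(ref))`. An alternative
#' ratio correction, `raw * mean(ref) / ref(hour)`, is available behind
#' `method = "ratio"`. Missing reference hours are an error listing the gaps;
#' nothing is imputed silently.
#'
#' @param readings tibble with `timestamp` and `concentration`.
#' @param reference tibble with hourly `timestamp` and `concentration`.
#' @param method `"additive"` (default) or `"ratio"`.
#' @return `readings` with corrected `concentration`.
#' @export
temporal_correct <- function(readings, reference, method = c("additive", "ratio")) {
  method <- match.arg(method)
  assert_columns(readings, c("timestamp", "concentration"), "`readings`")
  assert_columns(reference, c("timestamp", "concentration"), "`reference`")
  if (nrow(readings) == 0) return(readings)
  rh <- trunc(as.numeric(readings$timestamp) / 3600)
  fh <- trunc(as.numeric(reference$timestamp) / 3600)
  idx <- match(rh, fh)
  if (anyNA(idx)) {
    gaps <- sort(unique(rh[is.na(idx)]))
    gap_times <- format(as.POSIXct(gaps * 3600, origin = "1970-01-01",
                                   tz = "UTC"), "%Y-%m-%d %H:00")
    abort(paste0("Reference series has no value for ",
                 length(gaps), " hour(s) needed by the readings: ",
                 paste(head(gap_times, 10), collapse = ", "),
                 if (length(gaps) > 10) ", ..."),
          class = "vlur_reference_gap")
  }
  ref_mean <- mean(reference$concentration)
  ref_at <- reference$concentration[idx]
  out <- readings
  out$concentration <- if (method == "additive") {
    readings$concentration - (ref_at - ref_mean)
  } else {
    readings$concentration * ref_mean / ref_at
  }
  out
}

#' Snap readings to the nearest road segment
#'
#' Each reading is assigned the segment minimising point-to-line-segment
#' distance; readings farther than `max_snap_distance` from every segment are
#' left unassigned (`segment_id` `NA`) and counted.
#'
#' @param readings tibble with `x`, `y`.
#' @param segments road-segment table with line geometry (`x0`,`y0`,`x1`,`y1`).
#' @param max_snap_distance meters; default 20, consistent with the pipeline's
#'   other 20 m matching buffers.
#' @param quiet suppress the unassigned-count message.
#' @return `readings` with `segment_id` and `snap_distance` columns added.
#' @export
snap_to_segments <- function(readings, segments, max_snap_distance = 20,
                             quiet = FALSE) {
  if (nrow(segments) == 0) stop_invalid("`segments` is empty.")
  assert_columns(readings, c("x", "y"), "`readings`")
  assert_columns(segments, c("segment_id", "x0", "y0", "x1", "y1"),
                 "`segments`")
  out <- readings
  if (nrow(readings) == 0) {
    out$segment_id <- character(0)
    out$snap_distance <- numeric(0)
    return(out)
  }
  nn <- nearest_segment(readings$x, readings$y, segments)
  too_far <- nn$distance > max_snap_distance
  nn$segment_id[too_far] <- NA_character_
  out$segment_id <- nn$segment_id
  out$snap_distance <- nn$distance
  if (!quiet && any(too_far)) {
    inform(sprintf("snap_to_segments: %d reading(s) beyond %g m left unassigned.",
                   sum(too_far), max_snap_distance))
  }
  out
}

#' Split snapped readings into drive passes
#'
#' Within one car, one drive day, and one segment, consecutive readings whose
#' inter-timestamp gap is at most `gap_threshold` seconds form one pass; a
#' larger gap, or a different car/day/segment, starts a new pass. With 1 Hz
#' data and 50 m segments a pass lasts seconds, so any same-segment revisit
#' after a signal gap is a new traversal.
#'
#' @param readings snapped tibble with `timestamp`, `car_id`, `drive_day`,
#'   `segment_id` (unassigned rows are dropped).
#' @param gap_threshold seconds; default 10.
#' @return `readings` with a `pass_id` column (unique across the table).
#' @export
split_passes <- function(readings, gap_threshold = 10) {
  assert_columns(readings, c("timestamp", "car_id", "drive_day", "segment_id"),
                 "`readings`")
  out <- readings[!is.na(readings$segment_id), ]
  if (nrow(out) == 0) {
    out$pass_id <- character(0)
    return(out)
  }
  key <- paste(out$car_id, out$drive_day, out$segment_id, sep = "|")
  ord <- order(key, as.numeric(out$timestamp))
  out <- out[ord, ]
  key <- key[ord]
  t <- as.numeric(out$timestamp)
  new_group <- c(TRUE, key[-1] != key[-length(key)])
  gap_break <- c(TRUE, diff(t) > gap_threshold)
  pass_index <- cumsum(new_group | gap_break)
  out$pass_id <- sprintf("pass%06d", pass_index)
  out[order(out$car_id, as.numeric(out$timestamp)), ]
}

#' Mean-of-means segment aggregation
#'
#' The segment value is the mean over drive days of the mean over that day's
#' passes of the mean over each pass's readings. In seasonal mode passes are
#' partitioned by the warm/cold rule on the drive day before aggregating.
#' Segments with zero passes are absent from the output, never zero-filled.
#'
#' @param passes tibble from [split_passes()] (needs `segment_id`, `drive_day`,
#'   `pass_id`, `concentration`).
#' @param by_season also split by [season_of()] the drive day.
#' @return a tibble: `segment_id`, `season` (`"all"` or `"warm"`/`"cold"`),
#'   `value`, `n_passes`, `n_days`.
#' @export
aggregate_mean_of_means <- function(passes, by_season = FALSE) {
  assert_columns(passes, c("segment_id", "drive_day", "pass_id", "concentration"),
                 "`passes`")
  df <- passes
  df$season <- if (by_season) season_of(df$drive_day) else "all"
  pass_means <- df |>
    dplyr::group_by(.data$segment_id, .data$season, .data$drive_day,
                    .data$pass_id) |>
    dplyr::summarise(pass_mean = mean(.data$concentration), .groups = "drop")
  day_means <- pass_means |>
    dplyr::group_by(.data$segment_id, .data$season, .data$drive_day) |>
    dplyr::summarise(day_mean = mean(.data$pass_mean),
                     n_passes = dplyr::n(), .groups = "drop")
  day_means |>
    dplyr::group_by(.data$segment_id, .data$season) |>
    dplyr::summarise(value = mean(.data$day_mean),
                     n_passes = sum(.data$n_passes),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$segment_id, .data$season)
}

#' Run the full mobile preprocessing pipeline
#'
#' filter -> winsorize -> temporal correction -> snap -> passes -> aggregate,
#' in that order.
#'
#' @param measurements raw readings tibble.
#' @param reference reference-site series.
#' @param segments road-segment table.
#' @param plausible_range plausibility bounds for [filter_improbable()].
#' @param winsor_pct length-2 percentile bounds for [winsorize()]; use
#'   `c(0, 100)` to disable trimming.
#' @param correction `"additive"`, `"ratio"`, or `"none"`.
#' @param max_snap_distance meters.
#' @param gap_threshold seconds, for pass construction.
#' @param by_season aggregate per warm/cold season as well.
#' @param quiet suppress progress messages.
#' @return list with `aggregates` (and `aggregates_seasonal` if requested)
#'   and `passes`.
#' @export
preprocess_mobile <- function(measurements, reference, segments,
                              plausible_range = c(0, 200),
                              winsor_pct = c(2.5, 97.5),
                              correction = "additive",
                              max_snap_distance = 20,
                              gap_threshold = 10,
                              by_season = FALSE,
                              quiet = TRUE) {
  x <- filter_improbable(measurements, plausible_range, quiet = quiet)
  x$concentration <- winsorize(x$concentration, winsor_pct[1], winsor_pct[2])
  if (correction != "none") {
    x <- temporal_correct(x, reference, method = correction)
  }
  x <- snap_to_segments(x, segments, max_snap_distance, quiet = quiet)
  passes <- split_passes(x, gap_threshold)
  out <- list(aggregates = aggregate_mean_of_means(passes, by_season = FALSE),
              passes = passes)
  if (by_season) {
    out$aggregates_seasonal <- aggregate_mean_of_means(passes, by_season = TRUE)
  }
  out
}
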