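# Panorama-to-segment assignment and the three temporal selection strategies.
#
# A panorama already carries panorama-level features: object counts summed
# over its four directional images (counts are extensive) and segmentation
# fractions averaged over them (fractions are intensive). That aggregation
# convention is applied once, at the feature-extraction boundary, and the
# tables here simply carry it through.

#' Assign panoramas to their nearest road segment within a buffer
#'
#' Each panorama is mapped to the segment minimising point-to-line distance,
#' if that distance is within `buffer` meters; panoramas farther from every
#' segment are dropped and counted. A segment may receive many panoramas.
#'
#' @param panoramas tibble with `panorama_id`, `x`, `y`, `capture_date`.
#' @param segments road-segment table.
#' @param buffer meters, default 20.
#' @param quiet suppress the dropped-count message.
#' @return a tibble: `panorama_id`, `segment_id`, `distance`, `capture_date`.
#' @export
assign_panoramas <- function(panoramas, segments, buffer = 20, quiet = TRUE) {
  if (nrow(panoramas) == 0) {
    return(tibble::tibble(panorama_id = character(), segment_id = character(),
                          distance = numeric(),
                          capture_date = as.Date(character())))
  }
  assert_columns(panoramas, c("panorama_id", "x", "y", "capture_date"),
                 "`panoramas`")
  nn <- nearest_segment(panoramas$x, panoramas$y, segments)
  keep <- nn$distance <= buffer
  if (!quiet && any(!keep)) {
    inform(sprintf("assign_panoramas: %d panorama(s) beyond %g m dropped.",
                   sum(!keep), buffer))
  }
  tibble::tibble(
    panorama_id = panoramas$panorama_id[keep],
    segment_id = nn$segment_id[keep],
    distance = nn$distance[keep],
    capture_date = as.Date(panoramas$capture_date[keep])
  )
}

# Deterministic ranking used by every strategy; tie-breaks are fixed as
# distance, then capture date, then panorama id.
pick_first <- function(df, ...) {
  df |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::arrange(..., .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Specific-year selection
#'
#' At most one panorama per segment: among the segment's panoramas captured
#' inside the campaign window, the one at minimal distance (ties: earlier
#' capture date, then panorama id). Segments without an in-window panorama are
#' absent.
#'
#' @param assignments tibble from [assign_panoramas()].
#' @param campaign_window length-2 `Date` vector, inclusive.
#' @return one row per selected segment, same columns as `assignments`.
#' @export
select_specific_year <- function(assignments, campaign_window) {
  campaign_window <- as.Date(campaign_window)
  inwin <- assignments[assignments$capture_date >= campaign_window[1] &
                         assignments$capture_date <= campaign_window[2], ]
  pick_first(inwin, .data$distance, .data$capture_date, .data$panorama_id)
}

#' Most-nearby-year selection
#'
#' At most one panorama per segment from the nearest available year
#' (including the campaign year itself): panoramas are ranked by absolute
#' year gap to the campaign reference year, then by distance, then by later
#' capture date, then by panorama id. Every segment with at least one
#' assigned panorama is selected, so this strategy's training set always
#' contains the specific-year one.
#'
#' @param assignments tibble from [assign_panoramas()].
#' @param campaign_window length-2 `Date` vector; the reference year is the
#'   year containing most of the window unless overridden.
#' @param reference_year optional integer override.
#' @return one row per selected segment, with a `year_gap` column added.
#' @export
select_most_near_year <- function(assignments, campaign_window,
                                  reference_year = NULL) {
  campaign_window <- as.Date(campaign_window)
  if (is.null(reference_year)) {
    days <- seq(campaign_window[1], campaign_window[2], by = "day")
    yr <- as.integer(format(days, "%Y"))
    reference_year <- as.integer(names(which.max(table(yr))))
  }
  df <- assignments
  df$year_gap <- abs(as.integer(format(df$capture_date, "%Y")) - reference_year)
  pick_first(df, .data$year_gap, .data$distance,
             dplyr::desc(.data$capture_date), .data$panorama_id)
}

#' Season-weighted selection
#'
#' Restricts the assignments to panoramas captured in each season's months
#' (warm: May-October; cold: November-April, by calendar month from any
#' year), then applies the most-nearby-year rule within each subset. A
#' segment may appear in one, both, or neither seasonal selection.
#'
#' @inheritParams select_most_near_year
#' @return a named list, `warm` and `cold`, each as in
#'   [select_most_near_year()].
#' @export
select_season_weighted <- function(assignments, campaign_window,
                                   reference_year = NULL) {
  season <- season_of(assignments$capture_date)
  list(
    warm = select_most_near_year(assignments[season == "warm", ],
                                 campaign_window, reference_year),
    cold = select_most_near_year(assignments[season == "cold", ],
                                 campaign_window, reference_year)
  )
}

#' Build per-segment visual feature rows from a selection
#'
#' One row per selected segment with all `obj.*` (object counts) and `seg.*`
#' (segmentation fractions) columns of the selected panorama. Objects or
#' segmentation classes in the vocabulary but missing from the panorama table
#' get 0; segments absent from the selection get no row.
#'
#' @param selection tibble from a selection operator (`segment_id`,
#'   `panorama_id`).
#' @param panoramas wide panorama feature table (one row per panorama with
#'   `obj.*` / `seg.*` columns).
#' @param vocabulary optional character vector of required feature column
#'   names; missing ones are zero-filled.
#' @return tibble: `segment_id`, `panorama_id`, `capture_date`, features.
#' @export
build_visual_features <- function(selection, panoramas, vocabulary = NULL) {
  feat_cols <- grep("^(obj|seg)\\.", names(panoramas), value = TRUE)
  out <- dplyr::inner_join(
    selection[, c("segment_id", "panorama_id", "capture_date")],
    panoramas[, c("panorama_id", feat_cols)],
    by = "panorama_id"
  )
  if (!is.null(vocabulary)) {
    for (v in setdiff(vocabulary, names(out))) out[[v]] <- 0
    out <- out[, c("segment_id", "panorama_id", "capture_date", vocabulary)]
  }
  tibble::as_tibble(out)
}
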