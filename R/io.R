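# File interfaces: scenario YAML, segments GeoJSON, and documented CSV
# readers for the tabular inputs.

#' Write / read a scenario configuration as YAML
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `path` (writer) or a `vlur_scenario_config` (reader).
#' @export
write_scenario_yaml <- function(config, path) {
  x <- unclass(config)
  x$campaign_start <- as.character(x$campaign_start)
  x$campaign_end <- as.character(x$campaign_end)
  x$true_coefficients <- as.list(x$true_coefficients)
  x$seasonal_offsets <- as.list(x$seasonal_offsets)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$true_coefficients <- unlist(x$true_coefficients)
  x$seasonal_offsets <- unlist(x$seasonal_offsets)
  x$image_coverage <- unlist(x$image_coverage)
  do.call(scenario_config, x)
}

#' Write road segments as GeoJSON LineStrings
#'
#' One feature per segment; all non-geometry columns become properties.
#'
#' @param segments road-segment table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, path) {
  prop_cols <- setdiff(names(segments), c("x0", "y0", "x1", "y1"))
  features <- lapply(seq_len(nrow(segments)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(segments$x0[i], segments$y0[i]),
                           c(segments$x1[i], segments$y1[i]))
      ),
      properties = as.list(segments[i, prop_cols])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read road segments from GeoJSON LineStrings
#'
#' Inverse of [write_segments_geojson()].
#'
#' @param path GeoJSON file.
#' @return a road-segment tibble.
#' @export
read_segments_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates
    props <- tibble::as_tibble(f$properties)
    props$x0 <- cc[[1]][[1]]; props$y0 <- cc[[1]][[2]]
    props$x1 <- cc[[2]][[1]]; props$y1 <- cc[[2]][[2]]
    props
  })
  dplyr::bind_rows(rows)
}

#' CSV readers for the documented tabular schemas
#'
#' * measurements: `timestamp` (ISO 8601, UTC), `x`, `y`, `concentration`,
#'   `car_id`, `drive_day` (date)
#' * reference: `timestamp`, `concentration`
#' * panoramas: `panorama_id`, `x`, `y`, `capture_date`, wide `obj.*` /
#'   `seg.*` columns
#' * aggregates (writer): `segment_id`, `pollutant`, `season`, `value`,
#'   `n_passes`, `n_days`
#'
#' @param path CSV file.
#' @return a tibble with typed columns.
#' @export
read_measurements_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df$drive_day <- as.Date(df$drive_day)
  df
}

#' @rdname read_measurements_csv
#' @export
read_reference_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df
}

#' @rdname read_measurements_csv
#' @export
read_panoramas_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  df$capture_date <- as.Date(df$capture_date)
  df
}

#' @rdname read_measurements_csv
#' @param aggregates a segment-aggregate tibble.
#' @param pollutant pollutant label written into the file.
#' @export
write_aggregates_csv <- function(aggregates, path, pollutant = "NO2") {
  out <- aggregates
  out$pollutant <- pollutant
  utils::write.csv(
    out[, c("segment_id", "pollutant", "season", "value", "n_passes", "n_days")],
    path, row.names = FALSE)
  invisible(path)
}
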