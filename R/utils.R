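#' @importFrom rlang abort warn inform .data
#' @importFrom stats coef cor lm median pf predict pt quantile rbinom rgamma
#'   rlnorm rnorm rpois runif sd setNames var density complete.cases
#' @importFrom utils head
NULL

# All geometry is planar Cartesian in meters: at city scale the 20 m / 50 m
# thresholds the pipeline relies on are metric and geodesic corrections are
# far below the GPS error of a moving car.

#' Distance from points to a line segment
#'
#' Vectorised perpendicular (clamped) distance from one or more points to a
#' single segment given by its endpoints.
#'
#' @param px,py point coordinates (meters), vectors of equal length.
#' @param x0,y0,x1,y1 segment endpoints (scalars, meters).
#' @return numeric vector of distances in meters.
#' @keywords internal
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - x0)^2 + (py - y0)^2))
  }
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

#' Nearest road segment for a set of points
#'
#' For each point, the segment (line geometry) minimising point-to-segment
#' distance. Points are processed in chunks against the full segment table so
#' memory stays bounded for campaign-scale inputs.
#'
#' @param px,py point coordinates (meters).
#' @param segments a road-segment table as built by [generate_road_network()]
#'   (needs columns `segment_id`, `x0`, `y0`, `x1`, `y1`).
#' @return a tibble with columns `segment_id` and `distance`, one row per point
#'   in input order.
#' @keywords internal
nearest_segment <- function(px, py, segments) {
  n <- length(px)
  m <- nrow(segments)
  if (m == 0L) abort("`segments` is empty.", class = "vlur_invalid_argument")
  best_id <- rep(NA_character_, n)
  best_d <- rep(Inf, n)
  chunk <- max(1L, floor(2e6 / m))
  x0 <- segments$x0; y0 <- segments$y0; x1 <- segments$x1; y1 <- segments$y1
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1 # degenerate segment: t forced to 0 below via zero dx,dy
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    # outer products: rows = points in chunk, cols = segments
    tx <- outer(px[idx], x0, "-")
    ty <- outer(py[idx], y0, "-")
    t <- sweep(sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"), 2, len2, "/")
    t[t < 0] <- 0
    t[t > 1] <- 1
    ddx <- tx - sweep(t, 2, dx, "*")
    ddy <- ty - sweep(t, 2, dy, "*")
    d2 <- ddx * ddx + ddy * ddy
    j <- max.col(-d2, ties.method = "first")
    sel <- cbind(seq_along(idx), j)
    best_id[idx] <- segments$segment_id[j]
    best_d[idx] <- sqrt(d2[sel])
  }
  tibble::tibble(segment_id = best_id, distance = best_d)
}

#' Season of a calendar date
#'
#' The warm season runs May through October, the cold season November through
#' April, so that October 31 is the last warm day — the dividing-date
#' convention used for seasonal model stratification. The rule is applied by
#' calendar month to dates from any year.
#'
#' @param dates a `Date` vector.
#' @return character vector, `"warm"` or `"cold"`.
#' @export
#' @examples
#' season_of(as.Date(c("2019-07-15", "2019-11-02")))
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(m >= 5L & m <= 10L, "warm", "cold")
}

# Named substream seeds derived from one master seed, so each pipeline stage
# is independently reproducible. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 97651.0
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483629)
}

stop_invalid <- function(msg) abort(msg, class = "vlur_invalid_argument")

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_invalid(sprintf("%s is missing column(s): %s", what,
                         paste(miss, collapse = ", ")))
  }
  invisible(df)
}
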