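# Predictor-matrix assembly: classic buffer-based variables merged with
# visual features, each column annotated with a category and a direction
# prior for the supervised selection stage.

#' Default direction priors
#'
#' Expected coefficient signs for the classic predictor families: traffic,
#' industry, port, airport, transportation, residential and population
#' variables are expected positive; urban green and natural/forested areas
#' negative. Visual (`obj.*` / `seg.*`) features are unconstrained by
#' default — street-view features can carry counterintuitive positive signs
#' (grass along highway medians, walls of tunnels), so their direction is
#' left to the data.
#'
#' @param feature_names character vector of predictor column names.
#' @return named character vector over `feature_names` with values `"+"`,
#'   `"-"`, or `"0"` (unconstrained).
#' @export
default_priors <- function(feature_names) {
  prior <- setNames(rep("0", length(feature_names)), feature_names)
  pos <- grepl("traffic|industr|port|airport|transport|residential|population|pop_density|road_length|heavy",
               feature_names, ignore.case = TRUE)
  neg <- grepl("green|natural|forest", feature_names, ignore.case = TRUE)
  visual <- grepl("^(obj|seg)\\.", feature_names)
  prior[pos & !visual] <- "+"
  prior[neg & !visual] <- "-"
  prior
}

# Category of a predictor column, inferred from its name.
feature_category <- function(feature_names) {
  dplyr::case_when(
    grepl("^obj\\.", feature_names) ~ "visual-object",
    grepl("^seg\\.", feature_names) ~ "visual-segmentation",
    grepl("pop", feature_names, ignore.case = TRUE) ~ "population",
    grepl("traffic|road", feature_names, ignore.case = TRUE) ~ "traffic",
    TRUE ~ "land use"
  )
}

#' Buffer statistics of a spatial layer around segment centroids
#'
#' For each segment centroid and radius, a summary of the layer within
#' Euclidean distance `r`. Point layers support `count` (number of points)
#' and `sum` / `area` (sum of the `weight` column — polygon layers are
#' expected pre-gridded to weighted cell points, the usual treatment of
#' rasterised land-use data). Line layers (`x0`,`y0`,`x1`,`y1` rows) support
#' `length`: the exact chord length of each line piece inside the disc.
#'
#' @param segments road-segment table.
#' @param layer tibble: either points (`x`, `y`, optional `weight`) or lines
#'   (`x0`, `y0`, `x1`, `y1`).
#' @param radii positive numeric vector of buffer radii (meters).
#' @param statistic one of `"count"`, `"sum"`, `"area"`, `"length"`.
#' @return tibble: `segment_id` plus one column per radius named
#'   `<statistic>_<radius>`.
#' @export
buffer_features <- function(segments, layer, radii, statistic = "count") {
  if (!statistic %in% c("count", "sum", "area", "length")) {
    stop_invalid(sprintf("Unknown statistic '%s'.", statistic))
  }
  if (any(radii <= 0) && !all(radii >= 0)) stop_invalid("`radii` must be > 0.")
  out <- tibble::tibble(segment_id = segments$segment_id)
  for (r in radii) {
    col <- sprintf("%s_%g", statistic, r)
    if (statistic == "length") {
      assert_columns(layer, c("x0", "y0", "x1", "y1"), "`layer`")
      out[[col]] <- vapply(seq_len(nrow(segments)), function(i) {
        sum(chord_length(segments$x[i], segments$y[i], r,
                         layer$x0, layer$y0, layer$x1, layer$y1))
      }, numeric(1))
    } else {
      assert_columns(layer, c("x", "y"), "`layer`")
      w <- if (statistic == "count") rep(1, nrow(layer)) else layer$weight
      out[[col]] <- vapply(seq_len(nrow(segments)), function(i) {
        d2 <- (layer$x - segments$x[i])^2 + (layer$y - segments$y[i])^2
        sum(w[d2 <= r^2])
      }, numeric(1))
    }
  }
  out
}

# Length of each line piece (x0,y0)-(x1,y1) inside the disc of radius r
# centred at (cx, cy): clip the parametric line to the circle analytically.
chord_length <- function(cx, cy, r, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  fx <- x0 - cx
  fy <- y0 - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  len <- sqrt(a)
  out <- numeric(length(a))
  ok <- disc > 0 & a > 0
  sq <- sqrt(pmax(disc[ok], 0))
  t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
  t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
  out[ok] <- pmax(0, t2 - t1) * len[ok]
  out
}

#' Assemble the per-segment predictor matrix
#'
#' Inner-joins segment aggregates (the response), classic predictors, and —
#' for the visual variant — the visual feature rows, on `segment_id`. Only
#' segments present in every table survive, matching the strategy-dependent
#' training-set sizes that partial image coverage induces. Constant columns
#' are dropped with a warning (they carry no information and break selection);
#' duplicate segment rows are an error, never silently deduplicated.
#'
#' @param aggregates tibble with `segment_id` and `value` (the response).
#' @param classic_features tibble: `segment_id` + classic predictor columns.
#' @param visual_features optional tibble from [build_visual_features()];
#'   `NULL` for the classic-only variant.
#' @param priors optional named vector of direction priors (`"+"`, `"-"`,
#'   `"0"`); defaults to [default_priors()] over the assembled columns.
#' @return a list of class `vlur_feature_matrix`: `segment_id`, `response`,
#'   `x` (numeric predictor tibble), and `metadata` (tibble: `feature`,
#'   `category`, `prior`).
#' @export
assemble_matrix <- function(aggregates, classic_features,
                            visual_features = NULL, priors = NULL) {
  for (nm in c("aggregates", "classic_features", "visual_features")) {
    df <- get(nm)
    if (!is.null(df) && anyDuplicated(df$segment_id) > 0) {
      stop_invalid(sprintf("Duplicate segment rows in `%s`.", nm))
    }
  }
  m <- dplyr::inner_join(aggregates[, c("segment_id", "value")],
                         classic_features, by = "segment_id")
  if (!is.null(visual_features)) {
    vis_cols <- grep("^(obj|seg)\\.", names(visual_features), value = TRUE)
    m <- dplyr::inner_join(m,
                           visual_features[, c("segment_id", vis_cols)],
                           by = "segment_id")
  }
  feat_cols <- setdiff(names(m), c("segment_id", "value"))
  x <- m[, feat_cols]
  keep <- vapply(x, function(v) is.numeric(v) && length(unique(v)) > 1,
                 logical(1))
  if (any(!keep)) {
    warn(sprintf("Dropping constant or non-numeric column(s): %s",
                 paste(feat_cols[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  if (anyNA(x) || anyNA(m$value)) {
    stop_invalid("Assembled matrix contains missing values.")
  }
  feats <- names(x)
  if (is.null(priors)) {
    priors <- default_priors(feats)
  } else {
    full <- default_priors(feats)
    full[intersect(names(priors), feats)] <-
      priors[intersect(names(priors), feats)]
    priors <- full
  }
  structure(list(
    segment_id = m$segment_id,
    response = m$value,
    x = tibble::as_tibble(x),
    metadata = tibble::tibble(feature = feats,
                              category = feature_category(feats),
                              prior = unname(priors[feats]))
  ), class = "vlur_feature_matrix")
}

#' @export
print.vlur_feature_matrix <- function(x, ...) {
  cat(sprintf("<vlur_feature_matrix> %d segments x %d predictors\n",
              length(x$segment_id), ncol(x$x)))
  print(table(x$metadata$category))
  invisible(x)
}

# Restrict a feature matrix to a subset of rows (used by CV) or columns.
subset_matrix <- function(fm, rows = NULL, cols = NULL) {
  out <- fm
  if (!is.null(rows)) {
    out$segment_id <- fm$segment_id[rows]
    out$response <- fm$response[rows]
    out$x <- fm$x[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    out$x <- out$x[, cols, drop = FALSE]
    out$metadata <- out$metadata[out$metadata$feature %in% cols, ]
  }
  out
}
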