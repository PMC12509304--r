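# Synthetic scenario generator
#
# Every downstream stage (preprocessing, image selection, feature assembly,
# model fitting, evaluation) is validated against data produced here, where
# the ground-truth concentration surface is known by construction. The
# generator emulates a mobile monitoring campaign over a 50 m road-segment
# network: drive-pass-structured 1 Hz readings with instrument noise and a
# shared temporal background drift also seen at a reference site, multi-year
# street-view panorama feature tables with year-stable structure and
# season-varying greenery, classic buffer-style predictors, and long-term
# fixed validation sites.

#' Scenario configuration
#'
#' Bundles every knob of the synthetic study design into one validated list.
#' Defaults describe a desk-scale analogue of a 10-month urban campaign:
#' two cars, weekday drives, a handful of passes per segment, street-view
#' coverage over several years with warm-season capture oversampled, and an
#' NO2-like linear ground truth in which both classic traffic predictors and
#' visual features (traffic lights, wall/road/grass pixel fractions) carry
#' signal.
#'
#' @param n_segments number of 50 m road segments.
#' @param segment_length segment length in meters.
#' @param campaign_start,campaign_end campaign date range (`Date` or
#'   coercible).
#' @param n_drive_days number of distinct weekday drive days.
#' @param passes_per_segment_mean Poisson mean of drive passes per segment
#'   over the whole campaign.
#' @param noise_sd instrument noise standard deviation (concentration units).
#' @param drift_amplitude amplitude of the shared temporal background drift
#'   (concentration units); the drift is sinusoidal plus a linear trend,
#'   centred to zero mean over the campaign's hourly grid.
#' @param ref_noise_sd noise of the reference-site series.
#' @param outlier_fraction fraction of readings replaced by implausible
#'   values (negative spikes / extreme highs), flagged in hidden truth.
#' @param plausible_range length-2 numeric; readings outside it are
#'   "improbable" for the plausibility filter.
#' @param intercept intercept of the linear ground truth.
#' @param true_coefficients named numeric vector of generating coefficients;
#'   names must match segment feature columns.
#' @param seasonal_offsets named numeric `c(warm = , cold = )` additive
#'   season shifts of the true surface.
#' @param truth_floor lower clip for the true surface.
#' @param image_years integer vector of panorama capture years.
#' @param image_coverage per-year probability a segment has a panorama that
#'   year; length 1 (recycled) or `length(image_years)`; in \[0, 1\].
#' @param image_jitter_max maximum panorama offset from the segment centroid
#'   (meters).
#' @param warm_capture_prob probability a panorama is captured in a warm
#'   month (May-October); street-view collection is scheduled mostly in
#'   spring/summer, so the default oversamples warm months.
#' @param season_greenery_delta additive seasonal perturbation of the grass
#'   and tree segmentation fractions (+ in warm, - in cold months).
#' @param n_fixed_sites number of long-term fixed validation sites.
#' @param site_noise_sd noise of fixed-site long-term values.
#' @param site_far_fraction fraction of fixed sites placed beyond the 20 m
#'   matching threshold (exercises the matching filter).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a list of class `vlur_scenario_config`.
#' @export
scenario_config <- function(n_segments = 500,
                            segment_length = 50,
                            campaign_start = "2019-05-01",
                            campaign_end = "2020-02-28",
                            n_drive_days = 40,
                            passes_per_segment_mean = 4,
                            noise_sd = 3,
                            drift_amplitude = 0,
                            ref_noise_sd = 0,
                            outlier_fraction = 0,
                            plausible_range = c(0, 200),
                            intercept = 20,
                            true_coefficients = c(
                              traffic_intensity = 8e-4,
                              traffic_intensity_major = 3e-4,
                              pop_density = 5e-4,
                              urban_green_300 = -4,
                              obj.traffic_light = 0.17,
                              seg.wall = 35.6,
                              seg.road = 11.6,
                              seg.grass = 11.2
                            ),
                            seasonal_offsets = c(warm = -1.5, cold = 1.5),
                            truth_floor = 1,
                            image_years = 2015:2023,
                            image_coverage = 0.68,
                            image_jitter_max = 8,
                            warm_capture_prob = 0.75,
                            season_greenery_delta = 0.015,
                            n_fixed_sites = 60,
                            site_noise_sd = 1,
                            site_far_fraction = 0.2,
                            seed = 1L) {
  campaign_start <- as.Date(campaign_start)
  campaign_end <- as.Date(campaign_end)
  if (n_segments < 1) stop_invalid("`n_segments` must be >= 1.")
  if (campaign_start >= campaign_end) {
    stop_invalid("`campaign_start` must be before `campaign_end`.")
  }
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0.")
  if (any(image_coverage < 0 | image_coverage > 1)) {
    stop_invalid("`image_coverage` values must lie in [0, 1].")
  }
  if (length(image_coverage) == 1L) {
    image_coverage <- rep(image_coverage, length(image_years))
  }
  if (length(image_coverage) != length(image_years)) {
    stop_invalid("`image_coverage` must have length 1 or length(image_years).")
  }
  cfg <- list(
    n_segments = as.integer(n_segments), segment_length = segment_length,
    campaign_start = campaign_start, campaign_end = campaign_end,
    n_drive_days = as.integer(n_drive_days),
    passes_per_segment_mean = passes_per_segment_mean,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    ref_noise_sd = ref_noise_sd, outlier_fraction = outlier_fraction,
    plausible_range = plausible_range,
    intercept = intercept, true_coefficients = true_coefficients,
    seasonal_offsets = seasonal_offsets, truth_floor = truth_floor,
    image_years = as.integer(image_years), image_coverage = image_coverage,
    image_jitter_max = image_jitter_max,
    warm_capture_prob = warm_capture_prob,
    season_greenery_delta = season_greenery_delta,
    n_fixed_sites = as.integer(n_fixed_sites), site_noise_sd = site_noise_sd,
    site_far_fraction = site_far_fraction, seed = as.integer(seed)
  )
  structure(cfg, class = "vlur_scenario_config")
}

#' Generate a planar road-segment network with classic and latent visual
#' attributes
#'
#' Segments are laid out as horizontal 50 m pieces on a Cartesian grid (rows
#' 100 m apart, so snapping within 20 m is unambiguous). Each segment carries
#' classic land-use-regression predictors (traffic intensities, road length,
#' population density, land-use shares) and latent scene features: year-stable
#' object counts (`obj.*`, Poisson rates tied to road class so that traffic
#' lights co-vary with traffic intensity) and segmentation pixel fractions
#' (`seg.*`, summing below 1). The latent `obj.`/`seg.` columns are what the
#' street-view generator later observes, season-perturbed, as panoramas.
#'
#' @param n_segments number of segments (>= 1).
#' @param segment_length segment length, meters.
#' @param seed integer seed.
#' @return a tibble, one row per segment: `segment_id`, centroid `x`, `y`,
#'   endpoints `x0`, `y0`, `x1`, `y1`, `road_class`, classic predictors, and
#'   latent `obj.*` / `seg.*` columns.
#' @export
generate_road_network <- function(n_segments, segment_length = 50, seed = 1L) {
  if (length(n_segments) != 1 || is.na(n_segments) || n_segments < 1) {
    stop_invalid("`n_segments` must be a positive count.")
  }
  n <- as.integer(n_segments)
  set.seed(substream_seed(seed, "network"))
  ncol_grid <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  row <- idx %/% ncol_grid
  col <- idx %% ncol_grid
  x0 <- col * segment_length
  y0 <- row * 100
  major <- rbinom(n, 1, 0.2) == 1

  traffic <- rlnorm(n, meanlog = ifelse(major, 9.2, 6.8), sdlog = 0.5)
  traffic_major <- traffic * ifelse(major, 1, 0) +
    rlnorm(n, meanlog = 7.5, sdlog = 0.6)
  heavy <- traffic * runif(n, 0.03, 0.10)
  pop <- rgamma(n, shape = 2, scale = 2500)
  green <- pmin(0.9, rgamma(n, shape = 1.2, scale = 0.12))
  industry <- pmin(0.8, rgamma(n, shape = 0.6, scale = 0.1))
  residential <- pmin(0.95, pmax(0, 0.75 - green - industry +
    rnorm(n, 0, 0.05)))
  road_len <- segment_length * (2 + rpois(n, ifelse(major, 6, 3)))

  # objects: counts summed over the 4 directional views, year-stable
  obj_traffic_light <- rpois(n, ifelse(major, 2.5, 0.3))
  obj_chimney <- rpois(n, 0.4 + residential * 4)
  obj_shop <- rpois(n, 0.2 + pop / 8000)
  obj_tree <- rpois(n, 1 + green * 10)
  obj_car <- rpois(n, ifelse(major, 8, 4))
  obj_truck <- rpois(n, ifelse(major, 1.2, 0.2))
  obj_bus <- rpois(n, ifelse(major, 0.8, 0.1))
  obj_streetlamp <- rpois(n, 2)
  obj_window <- rpois(n, 6 + residential * 10)

  # segmentation fractions: drawn on a simplex-like scale, total <= 0.92 so
  # seasonal greenery perturbation can never push the sum past 1
  raw <- cbind(
    road = runif(n, 0.6, 1.4) * ifelse(major, 1.5, 1),
    wall = rgamma(n, 0.8, scale = ifelse(major, 0.25, 0.12)),
    grass = rgamma(n, 1.0, scale = 0.25) * (0.3 + green),
    sky = runif(n, 0.5, 1.2),
    fence = rgamma(n, 0.5, scale = 0.15),
    tree = rgamma(n, 1.0, scale = 0.2) * (0.3 + green),
    building = runif(n, 0.4, 1.2) * (0.3 + residential),
    other = runif(n, 0.3, 0.8)
  )
  segf <- raw / rowSums(raw) * 0.92

  tibble::tibble(
    segment_id = sprintf("S%05d", seq_len(n)),
    x = x0 + segment_length / 2, y = y0,
    x0 = x0, y0 = y0, x1 = x0 + segment_length, y1 = y0,
    road_class = ifelse(major, "major", "residential"),
    traffic_intensity = traffic,
    traffic_intensity_major = traffic_major,
    heavy_traffic = heavy,
    road_length_500 = road_len,
    pop_density = pop,
    urban_green_300 = green,
    industry_500 = industry,
    residential_300 = residential,
    obj.traffic_light = obj_traffic_light,
    obj.chimney = obj_chimney,
    obj.shop = obj_shop,
    obj.tree = obj_tree,
    obj.car = obj_car,
    obj.truck = obj_truck,
    obj.bus = obj_bus,
    obj.streetlamp = obj_streetlamp,
    obj.window = obj_window,
    seg.road = segf[, "road"],
    seg.wall = segf[, "wall"],
    seg.grass = segf[, "grass"],
    seg.sky = segf[, "sky"],
    seg.fence = segf[, "fence"],
    seg.tree = segf[, "tree"],
    seg.building = segf[, "building"],
    seg.other = segf[, "other"]
  )
}

#' Generate the true concentration surface
#'
#' The truth is linear in segment features: `intercept + sum(coef * feature)`,
#' with additive seasonal offsets. The long-term truth is defined as the mean
#' of the two (clipped) seasonal truths, so the long-term/seasonal consistency
#' invariant holds by construction even when clipping engages.
#'
#' @param segments road-segment table from [generate_road_network()].
#' @param true_coefficients named numeric vector; names must be segment
#'   feature columns.
#' @param seasonal_offsets named numeric `c(warm = , cold = )`.
#' @param intercept scalar intercept.
#' @param truth_floor seasonal truths below this are clipped up (with a
#'   warning) to keep concentrations positive.
#' @return a tibble: `segment_id`, `truth`, `truth_warm`, `truth_cold`, with
#'   the generating coefficients in attribute `"coefficients"`.
#' @export
generate_true_surface <- function(segments, true_coefficients,
                                  seasonal_offsets = c(warm = 0, cold = 0),
                                  intercept = 20, truth_floor = 1) {
  unknown <- setdiff(names(true_coefficients), names(segments))
  if (length(unknown) > 0) {
    stop_invalid(sprintf("Unknown feature name(s) in coefficients: %s",
                         paste(unknown, collapse = ", ")))
  }
  base <- rep(intercept, nrow(segments))
  for (nm in names(true_coefficients)) {
    base <- base + true_coefficients[[nm]] * segments[[nm]]
  }
  warm <- base + seasonal_offsets[["warm"]]
  cold <- base + seasonal_offsets[["cold"]]
  n_clip <- sum(warm < truth_floor) + sum(cold < truth_floor)
  if (n_clip > 0) {
    warn(sprintf("%d seasonal truth value(s) clipped to the floor %g.",
                 n_clip, truth_floor))
  }
  warm <- pmax(warm, truth_floor)
  cold <- pmax(cold, truth_floor)
  out <- tibble::tibble(
    segment_id = segments$segment_id,
    truth = (warm + cold) / 2,
    truth_warm = warm,
    truth_cold = cold
  )
  attr(out, "coefficients") <- c("(Intercept)" = intercept, true_coefficients)
  out
}

# Centred background drift on the campaign's hourly grid: a weekly sinusoid
# plus a linear trend, shifted to zero mean so reference correction is exactly
# invertible in the noiseless limit.
drift_series <- function(hours_grid, amplitude) {
  h <- as.numeric(hours_grid - hours_grid[1]) / 3600
  b <- amplitude * sin(2 * pi * h / 168) +
    0.5 * amplitude * (h / max(h, 1) - 0.5)
  b - mean(b)
}

#' Simulate a mobile monitoring campaign
#'
#' Emits 1 Hz readings organised as drive days, passes, and points. A reading
#' is its segment's seasonal truth plus the shared hourly background drift
#' plus i.i.d. instrument noise; a configurable fraction is replaced by
#' implausible outliers and flagged in hidden truth. The reference series
#' observes the same drift (plus its own noise) on the campaign's hourly grid.
#'
#' @param segments road-segment table.
#' @param truth true-surface table from [generate_true_surface()].
#' @param config a [scenario_config()].
#' @return a list with `measurements` (tibble: `timestamp`, `x`, `y`,
#'   `concentration`, `car_id`, `drive_day`, plus hidden-truth columns
#'   `true_segment_id`, `is_outlier`) and `reference` (tibble: `timestamp`,
#'   `concentration`).
#' @export
generate_mobile_campaign <- function(segments, truth, config) {
  if (!all(segments$segment_id %in% truth$segment_id)) {
    stop_invalid("`truth` must cover every segment.")
  }
  set.seed(substream_seed(config$seed, "campaign"))
  all_days <- seq(config$campaign_start, config$campaign_end, by = "day")
  weekdays_ok <- all_days[!format(all_days, "%u") %in% c("6", "7")]
  drive_days <- sort(sample(weekdays_ok,
                            min(config$n_drive_days, length(weekdays_ok))))

  n_seg <- nrow(segments)
  n_passes <- rpois(n_seg, config$passes_per_segment_mean)
  pass_seg <- rep(seq_len(n_seg), n_passes)
  total_passes <- length(pass_seg)
  if (total_passes == 0L) {
    return(list(
      measurements = tibble::tibble(
        timestamp = as.POSIXct(character(), tz = "UTC"), x = numeric(),
        y = numeric(), concentration = numeric(), car_id = character(),
        drive_day = as.Date(character()), true_segment_id = character(),
        is_outlier = logical()),
      reference = reference_for(drive_days, config)))
  }
  pass_day <- sample(drive_days, total_passes, replace = TRUE)
  pass_car <- sample(c("car1", "car2"), total_passes, replace = TRUE)
  pass_len <- sample(3:6, total_passes, replace = TRUE)

  # sequential start times per car-day keep timestamps strictly increasing
  slot <- stats::ave(seq_len(total_passes),
                     paste(pass_car, pass_day),
                     FUN = seq_along)
  start_s <- 9L * 3600L + (slot - 1L) * 60L
  pass_start <- as.POSIXct(pass_day, tz = "UTC") + start_s

  reading_pass <- rep(seq_len(total_passes), pass_len)
  within <- sequence(pass_len)
  seg_i <- pass_seg[reading_pass]
  ts <- pass_start[reading_pass] + (within - 1L)

  # points spaced along the segment's interior, small lateral jitter
  frac <- 0.1 + 0.8 * (within - 1L) / pmax(1L, pass_len[reading_pass] - 1L)
  px <- segments$x0[seg_i] +
    frac * (segments$x1[seg_i] - segments$x0[seg_i])
  py <- segments$y0[seg_i] +
    frac * (segments$y1[seg_i] - segments$y0[seg_i]) +
    runif(length(seg_i), -3, 3)

  hours_grid <- seq(as.POSIXct(config$campaign_start, tz = "UTC"),
                    as.POSIXct(config$campaign_end, tz = "UTC") + 86399,
                    by = "hour")
  b <- drift_series(hours_grid, config$drift_amplitude)
  hour_of <- function(t) as.integer(difftime(t, hours_grid[1], units = "hours"))
  drift_val <- b[hour_of(ts) + 1L]

  season <- season_of(pass_day[reading_pass])
  tr <- truth[match(segments$segment_id[seg_i], truth$segment_id), ]
  base_val <- ifelse(season == "warm", tr$truth_warm, tr$truth_cold)
  value <- base_val + drift_val + rnorm(length(seg_i), 0, config$noise_sd)

  is_outlier <- runif(length(value)) < config$outlier_fraction
  n_out <- sum(is_outlier)
  if (n_out > 0) {
    lo <- config$plausible_range[1]
    hi <- config$plausible_range[2]
    spike_low <- runif(n_out) < 0.5
    value[is_outlier] <- ifelse(spike_low,
                                lo - runif(n_out, 5, 30),
                                hi + runif(n_out, 20, 100))
  }

  meas <- tibble::tibble(
    timestamp = ts, x = px, y = py, concentration = value,
    car_id = pass_car[reading_pass], drive_day = pass_day[reading_pass],
    true_segment_id = segments$segment_id[seg_i], is_outlier = is_outlier
  )
  meas <- meas[order(meas$car_id, meas$timestamp), ]
  ref <- tibble::tibble(
    timestamp = hours_grid,
    concentration = 25 + b + rnorm(length(b), 0, config$ref_noise_sd)
  )
  list(measurements = meas, reference = ref)
}

reference_for <- function(drive_days, config) {
  hours_grid <- seq(as.POSIXct(config$campaign_start, tz = "UTC"),
                    as.POSIXct(config$campaign_end, tz = "UTC") + 86399,
                    by = "hour")
  b <- drift_series(hours_grid, config$drift_amplitude)
  tibble::tibble(timestamp = hours_grid,
                 concentration = 25 + b +
                   rnorm(length(b), 0, config$ref_noise_sd))
}

#' Generate multi-year street-view panorama feature tables
#'
#' For each segment and year, with the configured per-year coverage
#' probability, one panorama record is emitted at a jittered location near the
#' segment centroid. Object counts are the segment's year-stable latent
#' counts; segmentation fractions are the latent fractions with the grass and
#' tree classes shifted by a deterministic seasonal delta (+ in warm months,
#' - in cold months). Capture months oversample the warm season, emulating
#' street-view collection scheduling.
#'
#' @param segments road-segment table (with latent `obj.*`/`seg.*` columns).
#' @param image_years integer vector of capture years (non-empty).
#' @param config a [scenario_config()]; uses `image_coverage`,
#'   `image_jitter_max`, `warm_capture_prob`, `season_greenery_delta`, `seed`.
#' @return a tibble, one row per panorama: `panorama_id`, `x`, `y`,
#'   `capture_date`, hidden-truth `source_segment_id` and `capture_season`,
#'   and wide `obj.*` / `seg.*` feature columns.
#' @export
generate_streetview_features <- function(segments, image_years, config) {
  if (length(image_years) == 0) stop_invalid("`image_years` is empty.")
  set.seed(substream_seed(config$seed, "streetview"))
  coverage <- config$image_coverage
  if (length(coverage) == 1L) coverage <- rep(coverage, length(image_years))
  feat_cols <- grep("^(obj|seg)\\.", names(segments), value = TRUE)

  rows <- list()
  for (yi in seq_along(image_years)) {
    year <- image_years[yi]
    has <- runif(nrow(segments)) < coverage[yi]
    if (!any(has)) next
    sub <- segments[has, ]
    n <- nrow(sub)
    ang <- runif(n, 0, 2 * pi)
    rad <- runif(n, 0, config$image_jitter_max)
    warm <- runif(n) < config$warm_capture_prob
    month <- ifelse(warm, sample(5:10, n, replace = TRUE),
                    sample(c(1:4, 11:12), n, replace = TRUE))
    day <- sample(1:28, n, replace = TRUE)
    rec <- tibble::tibble(
      panorama_id = sprintf("P%d_%s", year, sub$segment_id),
      x = sub$x + rad * cos(ang),
      y = sub$y + rad * sin(ang),
      capture_date = as.Date(sprintf("%d-%02d-%02d", year, month, day)),
      source_segment_id = sub$segment_id,
      capture_season = ifelse(warm, "warm", "cold")
    )
    feats <- sub[, feat_cols]
    delta <- ifelse(warm, config$season_greenery_delta,
                    -config$season_greenery_delta)
    for (cl in intersect(c("seg.grass", "seg.tree"), feat_cols)) {
      feats[[cl]] <- pmax(0, feats[[cl]] + delta)
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(rec, feats)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(panorama_id = character()))
  }
  dplyr::bind_rows(rows)
}

#' Generate long-term fixed validation sites
#'
#' Each site sits perpendicular to a host segment's midpoint: most within the
#' 20 m matching threshold, a configured fraction deliberately beyond it, so
#' the site-matching filter can be exercised against construction flags. The
#' site value is the host segment's long-term truth plus site noise.
#'
#' @param segments road-segment table.
#' @param truth true-surface table.
#' @param n_sites number of sites (0 allowed: empty table).
#' @param far_fraction fraction of sites placed 25-40 m away (beyond 20 m).
#' @param site_noise_sd site value noise SD.
#' @param seed integer seed.
#' @return a tibble: `site_id`, `x`, `y`, `value`, and hidden-truth columns
#'   `host_segment_id`, `offset`, `is_far`.
#' @export
generate_fixed_sites <- function(segments, truth, n_sites,
                                 far_fraction = 0.2, site_noise_sd = 1,
                                 seed = 1L) {
  if (n_sites == 0) {
    return(tibble::tibble(site_id = character(), x = numeric(), y = numeric(),
                          value = numeric(), host_segment_id = character(),
                          offset = numeric(), is_far = logical()))
  }
  set.seed(substream_seed(seed, "sites"))
  host <- sample(nrow(segments), n_sites, replace = n_sites > nrow(segments))
  is_far <- runif(n_sites) < far_fraction
  offset <- ifelse(is_far, runif(n_sites, 25, 40), runif(n_sites, 1, 15))
  side <- sample(c(-1, 1), n_sites, replace = TRUE)
  tv <- truth$truth[match(segments$segment_id[host], truth$segment_id)]
  tibble::tibble(
    site_id = sprintf("F%03d", seq_len(n_sites)),
    x = segments$x[host],
    y = segments$y[host] + side * offset,
    value = tv + rnorm(n_sites, 0, site_noise_sd),
    host_segment_id = segments$segment_id[host],
    offset = offset,
    is_far = is_far
  )
}

#' Simulate a full scenario
#'
#' Runs every generator under one configuration and returns all pipeline
#' inputs plus ground truth.
#'
#' @param config a [scenario_config()].
#' @return a list: `config`, `segments`, `truth`, `measurements`, `reference`,
#'   `panoramas`, `fixed_sites`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "vlur_scenario_config"))
  segments <- generate_road_network(config$n_segments, config$segment_length,
                                    seed = config$seed)
  truth <- generate_true_surface(segments, config$true_coefficients,
                                 config$seasonal_offsets,
                                 intercept = config$intercept,
                                 truth_floor = config$truth_floor)
  campaign <- generate_mobile_campaign(segments, truth, config)
  panoramas <- generate_streetview_features(segments, config$image_years,
                                            config)
  sites <- generate_fixed_sites(segments, truth, config$n_fixed_sites,
                                far_fraction = config$site_far_fraction,
                                site_noise_sd = config$site_noise_sd,
                                seed = config$seed)
  list(config = config, segments = segments, truth = truth,
       measurements = campaign$measurements, reference = campaign$reference,
       panoramas = panoramas, fixed_sites = sites)
}
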