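test_that("plausibility filter removes exactly the out-of-range readings", {
  r <- tibble::tibble(concentration = c(5, 50, 100))
  expect_equal(filter_improbable(r, c(0, 150), quiet = TRUE), r,
               ignore_attr = TRUE)
  expect_equal(nrow(filter_improbable(r[0, ], c(0, 150), quiet = TRUE)), 0)
  expect_error(filter_improbable(r, c(10, 5)), class = "vlur_invalid_argument")

  cfg <- scenario_config(n_segments = 80, noise_sd = 1, outlier_fraction = 0.05,
                         plausible_range = c(0, 150), seed = 21)
  scn <- simulate_scenario(cfg)
  kept <- filter_improbable(scn$measurements, c(0, 150), quiet = TRUE)
  # generator's hidden flags are the oracle
  expect_equal(nrow(kept), sum(!scn$measurements$is_outlier))
  expect_false(any(kept$is_outlier))
})

test_that("winsorization matches a brute-force percentile oracle", {
  expect_equal(winsorize(rep(7, 20)), rep(7, 20))
  v <- as.numeric(1:1000)
  w <- winsorize(v)
  expect_equal(min(w), oracle_percentile(v, 2.5))
  expect_equal(max(w), oracle_percentile(v, 97.5))
  expect_equal(w[v > 26 & v < 975], v[v > 26 & v < 975])
  expect_equal(winsorize(v, 0, 100), v)
  expect_error(winsorize(numeric(0)), class = "vlur_invalid_argument")
  expect_error(winsorize(v, 50, 40), class = "vlur_invalid_argument")

  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(sample(10:200, 1), sd = sample(1:20, 1))
    lp <- runif(1, 0, 20)
    up <- runif(1, 80, 100)
    expect_equal(winsorize(x, lp, up), oracle_winsorize(x, lp, up))
  }
})

test_that("temporal correction is the additive hourly-deviation rule", {
  ts0 <- as.POSIXct("2019-06-03 09:00:00", tz = "UTC")
  readings <- tibble::tibble(timestamp = ts0 + c(0, 1800, 7200),
                             concentration = c(30, 32, 28))
  ref_const <- tibble::tibble(timestamp = ts0 + 3600 * (0:3),
                              concentration = rep(12, 4))
  expect_equal(temporal_correct(readings, ref_const), readings)

  # a reading in an hour missing from the reference is a gap error
  ref_gap <- ref_const[-3, ]
  expect_error(temporal_correct(readings, ref_gap),
               class = "vlur_reference_gap")

  # ratio variant: constant reference is also the identity
  expect_equal(temporal_correct(readings, ref_const, method = "ratio"),
               readings)
})

test_that("drift-corrected aggregates match the drift-free regeneration", {
  base <- list(n_segments = 60, noise_sd = 0, outlier_fraction = 0, seed = 31)
  cfg_d <- do.call(scenario_config, c(base, drift_amplitude = 8))
  cfg_0 <- do.call(scenario_config, c(base, drift_amplitude = 0))
  scn_d <- simulate_scenario(cfg_d)
  scn_0 <- simulate_scenario(cfg_0)
  agg_d <- preprocess_mobile(scn_d$measurements, scn_d$reference,
                             scn_d$segments, winsor_pct = c(0, 100))$aggregates
  agg_0 <- preprocess_mobile(scn_0$measurements, scn_0$reference,
                             scn_0$segments, winsor_pct = c(0, 100),
                             correction = "none")$aggregates
  expect_equal(agg_d$segment_id, agg_0$segment_id)
  expect_equal(agg_d$value, agg_0$value, tolerance = 1e-8)
})

test_that("snapping equals exhaustive nearest-segment search", {
  seg <- generate_road_network(40, seed = 41)
  r <- tibble::tibble(x = seg$x[5], y = seg$y[5])
  expect_equal(snap_to_segments(r, seg, quiet = TRUE)$segment_id,
               seg$segment_id[5])

  far <- tibble::tibble(x = -500, y = -500)
  expect_true(is.na(snap_to_segments(far, seg, quiet = TRUE)$segment_id))

  set.seed(42)
  pts <- tibble::tibble(x = runif(300, -50, 400), y = runif(300, -50, 400))
  got <- snap_to_segments(pts, seg, max_snap_distance = 25, quiet = TRUE)
  want <- oracle_nearest(pts$x, pts$y, seg, max_dist = 25)
  expect_equal(got$segment_id, want$segment_id)
  expect_equal(got$snap_distance, want$distance)
  expect_error(snap_to_segments(pts, seg[0, ]),
               class = "vlur_invalid_argument")
})

test_that("pass construction follows the gap rule", {
  ts0 <- as.POSIXct("2019-06-03 10:00:00", tz = "UTC")
  base <- tibble::tibble(
    timestamp = ts0 + 0:4, x = 0, y = 0, concentration = 1,
    car_id = "car1", drive_day = as.Date("2019-06-03"), segment_id = "S1")
  expect_equal(length(unique(split_passes(base)$pass_id)), 1L)

  revisit <- base
  revisit$timestamp <- ts0 + c(0, 1, 2, 300, 301)
  expect_equal(length(unique(split_passes(revisit)$pass_id)), 2L)

  for (s in 1:30) {
    r <- random_readings(80, seed = s)
    got <- split_passes(r, gap_threshold = 10)
    expect_equal(length(unique(got$pass_id)), oracle_pass_count(r, 10))
  }
})

test_that("mean-of-means aggregation nests pass means within day means", {
  ts0 <- as.POSIXct("2019-06-03 10:00:00", tz = "UTC")
  passes <- tibble::tibble(
    segment_id = "S1",
    drive_day = as.Date(c("2019-06-03", "2019-06-03", "2019-06-03",
                          "2019-06-04")),
    pass_id = c("p1", "p1", "p2", "p3"),
    concentration = c(10, 20, 30, 40))
  # day 1: pass means 15, 30 -> day mean 22.5; day 2: 40 -> value 31.25
  agg <- aggregate_mean_of_means(passes)
  expect_equal(agg$value, 31.25)
  expect_equal(agg$n_passes, 3L)
  expect_equal(agg$n_days, 2L)

  one <- passes[3, ]
  expect_equal(aggregate_mean_of_means(one)$value, 30)

  # duplicating every reading within each pass leaves pass means unchanged
  dup <- dplyr::bind_rows(passes, passes)
  expect_equal(aggregate_mean_of_means(dup)$value, 31.25)

  # permutation invariance
  shuffled <- passes[sample(nrow(passes)), ]
  expect_equal(aggregate_mean_of_means(shuffled), agg)
})

test_that("aggregation matches the looped oracle on random pass tables", {
  for (s in 1:20) {
    r <- random_readings(120, seed = 100 + s)
    passes <- split_passes(r)
    got <- aggregate_mean_of_means(passes)
    want <- oracle_mean_of_means(passes)
    expect_equal(got$value, unname(unlist(want[got$segment_id])))
  }
})

test_that("seasonal aggregation partitions passes by the warm/cold rule", {
  r <- random_readings(200, n_days = 6, seed = 77)
  r$drive_day <- as.Date("2019-10-25") + as.integer(factor(r$drive_day)) * 3
  r$timestamp <- as.POSIXct(r$drive_day, tz = "UTC") + 3600 * 10 +
    as.numeric(r$timestamp) %% 600
  passes <- split_passes(r)
  both <- aggregate_mean_of_means(passes, by_season = TRUE)
  expect_setequal(unique(both$season), c("warm", "cold"))
  manual <- aggregate_mean_of_means(passes[season_of(passes$drive_day) == "warm", ])
  warm <- both[both$season == "warm", ]
  expect_equal(warm$value, manual$value[match(warm$segment_id,
                                              manual$segment_id)])
})

test_that("noiseless pipeline recovers ground truth exactly end to end", {
  cfg <- scenario_config(n_segments = 50, noise_sd = 0, drift_amplitude = 0,
                         outlier_fraction = 0, seasonal_offsets = c(warm = 0,
                                                                    cold = 0),
                         seed = 51)
  scn <- simulate_scenario(cfg)
  prep <- preprocess_mobile(scn$measurements, scn$reference, scn$segments,
                            winsor_pct = c(0, 100))
  agg <- prep$aggregates
  truth <- scn$truth$truth[match(agg$segment_id, scn$truth$segment_id)]
  expect_equal(agg$value, truth, tolerance = 1e-12)
})
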