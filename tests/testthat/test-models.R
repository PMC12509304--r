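test_that("noiseless single-feature truth is recovered to machine precision", {
  d <- make_slr_dataset(100, 5, 1, beta_abs = 2, noise_sd = 0, seed = 1)
  m <- supervised_stepwise_select(d$X, d$y, d$priors)
  expect_equal(m$features, d$true_features)
  expect_equal(unname(m$coefficients[d$true_features]),
               unname(d$beta), tolerance = 1e-10)
  expect_equal(m$intercept, 10, tolerance = 1e-8)
})

test_that("selection matches the independent exhaustive-step oracle", {
  for (s in 1:15) {
    d <- make_slr_dataset(150, 6, 2, beta_abs = 1.5, noise_sd = 1,
                          seed = 400 + s)
    m <- supervised_stepwise_select(d$X, d$y, d$priors)
    want <- oracle_slr_select(d$X, d$y, d$priors)
    expect_setequal(m$features, want)
  }
})

test_that("a response opposing every prior yields an intercept-only model", {
  set.seed(5)
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(200 * 4), 200, 4)))
  names(X) <- paste0("f", 1:4)
  y <- -(2 * X$f1 + 2 * X$f2 + 2 * X$f3 + 2 * X$f4) + rnorm(200, 0, 0.1)
  priors <- setNames(rep("+", 4), names(X))
  expect_warning(m <- supervised_stepwise_select(X, y, priors),
                 "intercept-only")
  expect_length(m$features, 0)
  expect_equal(predict(m, X), rep(mean(y), 200))
})

test_that("adjusted R2 is non-decreasing along the selection trace", {
  for (s in 1:10) {
    d <- make_slr_dataset(300, 10, 4, beta_abs = 1, noise_sd = 2,
                          seed = 500 + s)
    m <- supervised_stepwise_select(d$X, d$y, d$priors)
    if (nrow(m$trace) > 1) {
      expect_true(all(diff(m$trace$adj_r2) > 0))
    }
  }
})

test_that("every constrained selected coefficient matches its prior", {
  for (s in 1:30) {
    d <- make_slr_dataset(120, 8, 3, beta_abs = runif(1, 0.5, 2),
                          noise_sd = runif(1, 0.5, 3), seed = 600 + s,
                          rho = runif(1, 0, 0.5))
    m <- suppressWarnings(supervised_stepwise_select(d$X, d$y, d$priors))
    if (length(m$features) == 0) next
    for (f in m$features) {
      pr <- d$priors[[f]]
      if (pr == "+") expect_gt(m$coefficients[[f]], 0)
      if (pr == "-") expect_lt(m$coefficients[[f]], 0)
    }
    expect_true(all(m$diagnostics$vif <= 3 + 1e-8))
  }
})

test_that("SLR precondition and schema errors are raised", {
  d <- make_slr_dataset(8, 3, 1, seed = 7)
  expect_error(supervised_stepwise_select(d$X, d$y, d$priors),
               class = "vlur_invalid_argument")
  d2 <- make_slr_dataset(50, 3, 1, seed = 8)
  m <- supervised_stepwise_select(d2$X, d2$y, d2$priors)
  expect_error(predict(m, d2$X[, setdiff(names(d2$X), m$features[1])]),
               class = "vlur_invalid_argument")
})

test_that("SLR prediction is the stated linear form", {
  m <- vlur:::new_slr(10, c(obj.traffic_light = 0.17),
                      tibble::tibble(), list(), 10,
                      feature_means = c(obj.traffic_light = 1))
  m$features <- "obj.traffic_light"
  got <- predict(m, tibble::tibble(obj.traffic_light = 2))
  expect_equal(got, 10 + 0.17 * 2) # 10.34, by hand
})

test_that("random grid search is seeded, exhaustive at full draws, and picks the CV optimum", {
  d <- make_slr_dataset(120, 5, 2, noise_sd = 1, seed = 9)
  one <- fit_rf(d$X, d$y, grid = list(num_trees = 50, max_depth = 3,
                                      min_node_size = 5),
                n_draws = 1, seed = 3)
  expect_equal(one$best, list(num_trees = 50, max_depth = 3,
                              min_node_size = 5))

  grid <- list(num_trees = c(30, 100), max_depth = c(2, 0),
               min_node_size = 5)
  a <- fit_rf(d$X, d$y, grid = grid, n_draws = 4, cv_folds = 3, seed = 11)
  b <- fit_rf(d$X, d$y, grid = grid, n_draws = 4, cv_folds = 3, seed = 11)
  expect_identical(a$best, b$best)
  expect_equal(nrow(a$tuning_log), 4) # full enumeration at n_draws = |grid|
  expect_equal(unlist(a$best),
               unlist(a$tuning_log[which.min(a$tuning_log$cv_rmse),
                                   names(grid)]))
  expect_error(fit_rf(d$X, d$y, grid = list(num_trees = numeric(0)),
                      n_draws = 2), class = "vlur_invalid_argument")
})

test_that("rf predictions respect the training schema", {
  d <- make_slr_dataset(80, 4, 2, seed = 12)
  m <- fit_rf(d$X, d$y, grid = list(num_trees = 50, max_depth = 0,
                                    min_node_size = 5), n_draws = 1)
  expect_length(predict(m, d$X), 80)
  expect_error(predict(m, d$X[, 1:2]), class = "vlur_invalid_argument")
})

test_that("season weighting averages the two seasonal predictions", {
  fm <- function(ids, vals) {
    structure(list(segment_id = ids,
                   response = vals,
                   x = tibble::tibble(f = vals),
                   metadata = tibble::tibble(feature = "f",
                                             category = "traffic",
                                             prior = "0")),
              class = "vlur_feature_matrix")
  }
  lin <- function(int, slope) {
    m <- vlur:::new_slr(int, c(f = slope), tibble::tibble(), list(), int,
                        feature_means = c(f = 0))
    m$features <- "f"
    m
  }
  warm <- fm(c("S1", "S2"), c(10, 10))
  cold <- fm(c("S1", "S3"), c(20, 20))
  pair <- list(warm = lin(0, 1), cold = lin(0, 1))
  got <- season_weighted_predict(pair, warm, cold)
  expect_equal(got$estimate[got$segment_id == "S1"], 15) # (10 + 20) / 2
  expect_equal(got$estimate[got$segment_id == "S2"], 10)
  expect_equal(got$estimate[got$segment_id == "S3"], 20)
  expect_equal(got$both_seasons, c(TRUE, FALSE, FALSE))

  # identical seasonal models and features collapse to the single model
  same <- fm(c("S1", "S2"), c(3, 7))
  pair2 <- list(warm = lin(2, 0.5), cold = lin(2, 0.5))
  sw <- season_weighted_predict(pair2, same, same)
  expect_equal(sw$estimate, predict(lin(2, 0.5), same))

  # randomized pairs equal an element-wise mean computed independently
  set.seed(13)
  v1 <- rnorm(20); v2 <- rnorm(20)
  ids <- sprintf("S%02d", 1:20)
  sw2 <- season_weighted_predict(pair2, fm(ids, v1), fm(ids, v2))
  expect_equal(sw2$estimate, (predict(lin(2, 0.5), fm(ids, v1)) +
                                predict(lin(2, 0.5), fm(ids, v2))) / 2)
})

test_that("SLR models serialise to readable JSON", {
  d <- make_slr_dataset(100, 4, 2, noise_sd = 0.5, seed = 14)
  m <- supervised_stepwise_select(d$X, d$y, d$priors)
  path <- withr::local_tempfile(fileext = ".json")
  write_slr_json(m, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$type, "slr")
  expect_equal(unlist(x$coefficients), m$coefficients, tolerance = 1e-12)
})
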