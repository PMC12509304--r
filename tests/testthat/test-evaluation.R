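test_that("score computes squared-Pearson R2, MAE, RMSE", {
  obs <- c(10, 20, 30, 25)
  s <- score(obs, obs)
  expect_equal(unlist(s), c(r2 = 1, mae = 0, rmse = 0))

  s2 <- score(-obs, obs)
  expect_equal(s2$r2, 1) # correlation sign squares away
  expect_equal(s2$mae, 2 * mean(abs(obs)))

  set.seed(15)
  pred <- rnorm(10); o <- rnorm(10)
  s3 <- score(pred, o)
  # textbook formulas, written out
  r <- sum((pred - mean(pred)) * (o - mean(o))) /
    sqrt(sum((pred - mean(pred))^2) * sum((o - mean(o))^2))
  expect_equal(s3$r2, r^2)
  expect_equal(s3$mae, sum(abs(pred - o)) / 10)
  expect_equal(s3$rmse, sqrt(sum((pred - o)^2) / 10))

  expect_warning(s4 <- score(pred, rep(5, 10)), "undefined")
  expect_true(is.na(s4$r2))
  expect_false(is.na(s4$mae) || is.na(s4$rmse))
  expect_error(score(1:3, 1:4), class = "vlur_invalid_argument")
})

make_fm <- function(X, y, ids = sprintf("S%03d", seq_along(y)),
                    priors = NULL) {
  agg <- tibble::tibble(segment_id = ids, value = y)
  classic <- dplyr::bind_cols(tibble::tibble(segment_id = ids), X)
  assemble_matrix(agg, classic, priors = priors)
}

test_that("k-fold CV partitions rows exactly once and supports LOO", {
  d <- make_slr_dataset(40, 4, 2, noise_sd = 1, seed = 16)
  names(d$X) <- paste0("traffic_", names(d$X)) # inherit + priors harmlessly
  fm <- make_fm(d$X, d$y, priors = setNames(rep("0", 4), names(d$X)))
  cv <- kfold_cv(fm, list(learner = "slr"), k = 40, seed = 1)
  expect_equal(sort(table(cv$oof$fold)), sort(table(1:40)), ignore_attr = TRUE)
  expect_false(anyNA(cv$oof$pred))

  cv5 <- kfold_cv(fm, list(learner = "slr"), k = 5, seed = 2)
  expect_equal(sort(unique(cv5$oof$fold)), 1:5)
  expect_equal(length(cv5$oof$pred), 40)
  expect_error(kfold_cv(fm, list(learner = "slr"), k = 41),
               class = "vlur_invalid_argument")
})

test_that("CV on noiseless linear truth is exact", {
  d <- make_slr_dataset(60, 5, 2, beta_abs = 2, noise_sd = 0, seed = 17)
  fm <- make_fm(d$X, d$y, priors = d$priors)
  cv <- kfold_cv(fm, list(learner = "slr"), k = 5, seed = 3)
  expect_equal(cv$metrics$r2, 1, tolerance = 1e-9)
  expect_lt(cv$metrics$mae, 1e-8)
})

test_that("selection runs inside each fold, not on the full data", {
  d <- make_slr_dataset(80, 10, 3, beta_abs = 0.6, noise_sd = 2.5, seed = 18)
  fm <- make_fm(d$X, d$y, priors = d$priors)
  cv <- kfold_cv(fm, list(learner = "slr"), k = 5, seed = 4)
  expect_length(cv$fold_features, 5)
  # leakage guard: freezing the full-data selection and only refitting
  # coefficients per fold must give different out-of-fold predictions
  full <- supervised_stepwise_select(fm)
  set.seed(vlur:::substream_seed(4, "cv_folds"))
  folds <- sample(rep(1:5, length.out = 80))
  oof_frozen <- rep(NA_real_, 80)
  for (i in 1:5) {
    dat <- as.data.frame(fm$x[folds != i, full$features, drop = FALSE])
    dat$.y <- fm$response[folds != i]
    fit <- lm(.y ~ ., data = dat)
    oof_frozen[folds == i] <-
      predict(fit, as.data.frame(fm$x[folds == i, , drop = FALSE]))
  }
  expect_false(isTRUE(all.equal(cv$oof$pred, oof_frozen)))
})

test_that("fixed-site matching keeps only sites within 20 m", {
  seg <- generate_road_network(30, seed = 19)
  sites <- tibble::tibble(
    site_id = c("near", "far"),
    x = c(seg$x[2], seg$x[2]),
    y = c(seg$y[2] + 5, seg$y[2] + 30),
    value = c(25, 30))
  got <- match_fixed_sites(sites, seg)
  expect_equal(got$site_id, "near")
  expect_equal(got$segment_id, seg$segment_id[2])

  tr <- generate_true_surface(seg, c(pop_density = 1e-4), intercept = 18)
  s <- generate_fixed_sites(seg, tr, 300, far_fraction = 0.2, seed = 20)
  m <- match_fixed_sites(s, seg)
  # construction flags are the oracle for the matched fraction
  expect_equal(nrow(m), sum(!s$is_far))

  # common-subset mode intersects strategy coverages
  ids_a <- seg$segment_id[1:15]
  ids_b <- seg$segment_id[10:30]
  mc <- match_fixed_sites(s, seg, common_segments = list(ids_a, ids_b))
  expect_true(all(mc$segment_id %in% intersect(ids_a, ids_b)))
})

test_that("linear Shapley decomposition matches coalition enumeration", {
  d <- make_slr_dataset(60, 3, 3, beta_abs = 1.5, noise_sd = 0.3, seed = 21)
  m <- supervised_stepwise_select(d$X, d$y, d$priors)
  x <- as.data.frame(d$X)[1:10, m$features, drop = FALSE]
  phi_lin <- shapley_linear(m, x)
  bg <- as.data.frame(d$X)[, m$features, drop = FALSE]
  # enumeration oracle with the training-mean baseline
  mu <- as.data.frame(as.list(m$feature_means))
  phi_oracle <- oracle_shapley(function(dd) predict(m, dd), x, mu)
  expect_equal(phi_lin, phi_oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("exact enumeration and permutation sampling agree with the oracle", {
  set.seed(22)
  X <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  f <- function(d) 2 * d$a - 3 * d$b + 0.5 * d$a * d$c
  bg <- X[1:8, ]
  x <- X[9:13, ]
  exact <- shapley_exact(f, x, bg)
  want <- oracle_shapley(f, x, bg)
  expect_equal(exact, want, tolerance = 1e-10)
  sampled <- shapley_sampled(f, x, bg, n_perm = 200, seed = 1)
  expect_equal(sampled, want, tolerance = 0.15)
})

test_that("street-view ratio is the visual share of total importance", {
  set.seed(23)
  n <- 80
  X <- tibble::tibble(traffic_intensity = rnorm(n),
                      pop_density = rnorm(n),
                      obj.chimney = rnorm(n),
                      seg.road = rnorm(n))
  y <- 2 * X$traffic_intensity + 1 * X$obj.chimney + rnorm(n, 0, 0.2)
  fm <- make_fm(X, y, priors = setNames(rep("0", 4), names(X)))
  m <- supervised_stepwise_select(fm)
  imp <- shapley_ratio(m, fm)
  expect_gt(imp$streetview_ratio, 0)
  expect_lt(imp$streetview_ratio, 1)
  vis <- grepl("^visual", imp$importance$category)
  expect_equal(imp$streetview_ratio,
               sum(imp$importance$mean_abs_shapley[vis]) /
                 sum(imp$importance$mean_abs_shapley))

  # classic-only model: ratio 0; visual-only model: ratio 1
  m0 <- supervised_stepwise_select(X[, 1:2], y)
  expect_equal(shapley_ratio(m0, X)$streetview_ratio, 0)
  y1 <- 3 * X$obj.chimney - 2 * X$seg.road + rnorm(n, 0, 0.1)
  m1 <- supervised_stepwise_select(X[, 3:4], y1)
  expect_equal(shapley_ratio(m1, X)$streetview_ratio, 1)
})

test_that("density export yields unit-mass summaries and handles degeneracy", {
  set.seed(24)
  v <- rnorm(500, 30, 5)
  d1 <- export_density_comparison(list(a = v, b = v))
  a <- d1[d1$series == "a", ]
  b <- d1[d1$series == "b", ]
  expect_equal(a$x, b$x)
  expect_equal(a$density, b$density)
  # trapezoid integration
  integral <- sum(diff(a$x) * (head(a$density, -1) + a$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 0.01)

  dd <- export_density_comparison(list(point = rep(7, 10)))
  expect_equal(nrow(dd), 1)
  expect_equal(dd$x, 7)
})
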