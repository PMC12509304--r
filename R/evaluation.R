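# Model evaluation: squared-Pearson R2 / MAE / RMSE, k-fold cross-validation
# with selection re-run inside each fold, external fixed-site validation with
# 20 m matching, Shapley-based street-view contribution ratios, and the
# density-comparison export.

#' Accuracy metrics
#'
#' R-squared is the squared Pearson correlation between predictions and
#' observations (not 1 - SS_res/SS_tot), so it measures association and can
#' mask calibration bias; MAE and RMSE, in concentration units, cover
#' calibration. With constant observations the correlation is undefined: R2
#' is returned as `NA` with a warning while MAE and RMSE are still computed.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @return a list: `r2`, `mae`, `rmse`.
#' @export
#' @examples
#' score(c(1, 2, 3), c(1.1, 1.9, 3.2))
score <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2) {
    stop_invalid("`pred` and `obs` must have equal length >= 2.")
  }
  mae <- mean(abs(pred - obs))
  rmse <- sqrt(mean((pred - obs)^2))
  if (sd(obs) == 0 || sd(pred) == 0) {
    warn("Constant predictions or observations: R2 undefined, returned as NA.")
    r2 <- NA_real_
  } else {
    r2 <- cor(pred, obs)^2
  }
  list(r2 = r2, mae = mae, rmse = rmse)
}

# Unified fit interface used by cross-validation and orchestration.
# spec: list(learner = "slr" | "rf", ...learner arguments)
fit_learner <- function(fm, spec, seed = 1L) {
  if (spec$learner == "slr") {
    supervised_stepwise_select(
      fm,
      gain_threshold = spec$gain_threshold %||% 0.01,
      p_remove = spec$p_remove %||% 0.1,
      vif_max = spec$vif_max %||% 3
    )
  } else if (spec$learner == "rf") {
    fit_rf(
      fm,
      grid = spec$grid %||% list(num_trees = spec$num_trees %||% 300,
                                 max_depth = spec$max_depth %||% 0,
                                 min_node_size = spec$min_node_size %||% 5),
      n_draws = spec$n_draws %||% 1,
      cv_folds = spec$tune_folds %||% 3,
      seed = seed
    )
  } else {
    stop_invalid(sprintf("Unknown learner '%s'.", spec$learner))
  }
}

#' k-fold cross-validation with in-fold model selection
#'
#' Rows are partitioned into `k` seeded folds covering every row exactly
#' once. The learner is refit per fold — for the SLR this re-runs the full
#' stepwise selection inside the fold, so no selection leakage inflates the
#' scores; the features each fold selected are recorded. Metrics are computed
#' on the pooled out-of-fold predictions.
#'
#' @param matrix a `vlur_feature_matrix`.
#' @param learner_spec list with `learner = "slr"` or `"rf"` plus learner
#'   arguments (see [fit_learner] internals / [fit_rf()]).
#' @param k number of folds (2..n).
#' @param seed integer seed for the fold assignment.
#' @return a list: `oof` (tibble `segment_id`, `fold`, `obs`, `pred`),
#'   `metrics` (from [score()]), `fold_features` (list of per-fold selected
#'   feature sets; SLR only).
#' @export
kfold_cv <- function(matrix, learner_spec, k = 5, seed = 1L) {
  n <- length(matrix$response)
  if (k < 2 || k > n) stop_invalid("`k` must be between 2 and the row count.")
  set.seed(substream_seed(seed, "cv_folds"))
  folds <- sample(rep(seq_len(k), length.out = n))
  oof <- rep(NA_real_, n)
  fold_features <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- subset_matrix(matrix, rows = which(folds != i))
    te <- subset_matrix(matrix, rows = which(folds == i))
    model <- fit_learner(tr, learner_spec, seed = seed + i)
    oof[folds == i] <- predict(model, te)
    if (inherits(model, "vlur_slr")) fold_features[[i]] <- model$features
  }
  list(
    oof = tibble::tibble(segment_id = matrix$segment_id, fold = folds,
                         obs = matrix$response, pred = oof),
    metrics = score(oof, matrix$response),
    fold_features = fold_features
  )
}

#' Match fixed validation sites to road segments
#'
#' Pairs each site with its nearest segment when within `max_distance`
#' meters; farther sites are dropped. `common_segments` restricts the result
#' to sites whose matched segment is present in every supplied segment-id
#' set — the device used to compare temporal strategies on one shared
#' validation subset.
#'
#' @param sites tibble with `site_id`, `x`, `y`, `value`.
#' @param segments road-segment table.
#' @param max_distance meters, default 20.
#' @param common_segments optional list of character vectors of segment ids;
#'   matched sites are kept only if their segment appears in all of them.
#' @return tibble: `site_id`, `segment_id`, `distance`, `value`.
#' @export
match_fixed_sites <- function(sites, segments, max_distance = 20,
                              common_segments = NULL) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(site_id = character(), segment_id = character(),
                          distance = numeric(), value = numeric()))
  }
  nn <- nearest_segment(sites$x, sites$y, segments)
  out <- tibble::tibble(site_id = sites$site_id, segment_id = nn$segment_id,
                        distance = nn$distance, value = sites$value)
  out <- out[out$distance <= max_distance, ]
  if (!is.null(common_segments)) {
    for (ids in common_segments) out <- out[out$segment_id %in% ids, ]
  }
  out
}

# ---- Shapley attribution ---------------------------------------------------

#' Exact Shapley values of a linear model
#'
#' For a linear model with interventional baseline at the feature means, the
#' Shapley value of feature j on row i is exactly
#' `coefficient_j * (x_ij - mean_j)`.
#'
#' @param model a `vlur_slr`.
#' @param x data frame of rows to explain.
#' @param baseline optional named means; defaults to the training means
#'   stored in the model.
#' @return numeric matrix, rows of `x` by selected features.
#' @export
shapley_linear <- function(model, x, baseline = NULL) {
  feats <- model$features
  if (length(feats) == 0) {
    return(matrix(numeric(0), nrow = nrow(as.data.frame(x)), ncol = 0))
  }
  xm <- as.matrix(extract_x(x, feats))
  mu <- baseline %||% model$feature_means
  sweep(xm, 2, mu[feats]) * rep(model$coefficients[feats],
                                each = nrow(xm))
}

#' Exact interventional Shapley values by coalition enumeration
#'
#' Enumerates all `2^p` feature coalitions; the value of a coalition for a
#' row is the mean model prediction over background rows with the coalition's
#' features taken from the explained row. Exact but exponential: refuse
#' above `max_p` features.
#'
#' @param predict_fun function(data.frame) -> numeric predictions.
#' @param x data frame of rows to explain.
#' @param background data frame of background rows (interventional baseline).
#' @param max_p refusal threshold on the number of features.
#' @return numeric matrix, rows of `x` by features.
#' @export
shapley_exact <- function(predict_fun, x, background, max_p = 12) {
  x <- as.data.frame(x)
  background <- as.data.frame(background)[, names(x), drop = FALSE]
  p <- ncol(x)
  if (p > max_p) {
    stop_invalid(sprintf("Exact enumeration refused for p = %d > %d.", p, max_p))
  }
  n <- nrow(x)
  nb <- nrow(background)
  n_coal <- 2^p
  # v[i, S]: mean prediction over background with coalition S from row i
  v <- matrix(NA_real_, n, n_coal)
  for (s in 0:(n_coal - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    big <- background[rep(seq_len(nb), times = n), , drop = FALSE]
    for (j in members) {
      big[[j]] <- rep(x[[j]], each = nb)
    }
    pr <- predict_fun(big)
    v[, s + 1L] <- colMeans(matrix(pr, nrow = nb))
  }
  w <- function(s_size) factorial(s_size) * factorial(p - s_size - 1) / factorial(p)
  phi <- matrix(0, n, p, dimnames = list(NULL, names(x)))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_coal - 1L)) {
      if (bitwAnd(s, bit) != 0L) next
      s_size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      phi[, j] <- phi[, j] + w(s_size) * (v[, s + bit + 1L] - v[, s + 1L])
    }
  }
  phi
}

#' Sampled interventional Shapley values (permutation method)
#'
#' Monte-Carlo estimate for models with too many features for enumeration:
#' features are inserted in random orders and the marginal prediction changes
#' averaged, with the interventional expectation taken over a background
#' sample. Predictions are batched into a single model call per permutation.
#'
#' @inheritParams shapley_exact
#' @param n_perm number of feature permutations.
#' @param seed integer seed.
#' @return numeric matrix, rows of `x` by features.
#' @export
shapley_sampled <- function(predict_fun, x, background, n_perm = 10,
                            seed = 1L) {
  xm <- as.matrix(as.data.frame(x))
  bm <- as.matrix(as.data.frame(background)[, colnames(xm), drop = FALSE])
  p <- ncol(xm)
  n <- nrow(xm)
  nb <- nrow(bm)
  set.seed(substream_seed(seed, "shapley_perm"))
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(xm)))
  base <- bm[rep(seq_len(nb), times = n), , drop = FALSE]
  x_rep <- xm[rep(seq_len(n), each = nb), , drop = FALSE]
  big <- matrix(0, nrow(base) * (p + 1L), p, dimnames = list(NULL, colnames(xm)))
  for (perm_i in seq_len(n_perm)) {
    ord <- sample(p)
    # cumulative coalitions: step 0 (empty) .. step p (all features)
    cur <- base
    big[seq_len(nrow(base)), ] <- cur
    for (step in seq_len(p)) {
      j <- ord[step]
      cur[, j] <- x_rep[, j]
      big[step * nrow(base) + seq_len(nrow(base)), ] <- cur
    }
    pr <- predict_fun(as.data.frame(big))
    vmean <- matrix(colMeans(matrix(pr, nrow = nb)), nrow = n) # n x (p+1)
    for (step in seq_len(p)) {
      j <- ord[step]
      phi[, j] <- phi[, j] + (vmean[, step + 1L] - vmean[, step])
    }
  }
  phi / n_perm
}

#' Street-view Shapley contribution ratio
#'
#' Per-feature importance is the mean absolute Shapley value over the
#' explained rows; the street-view ratio is the summed importance of visual
#' (`obj.*` / `seg.*`) features over the summed importance of all features,
#' so the street-view and classic shares add to one exactly. SLR models use
#' the exact linear decomposition; other models use exact coalition
#' enumeration up to `exact_max_p` features and seeded permutation sampling
#' beyond.
#'
#' @param model a fitted `vlur_slr` or `vlur_rf`.
#' @param matrix a `vlur_feature_matrix` (or data frame) of rows to explain.
#' @param category_map optional named vector mapping feature -> category;
#'   defaults to visual = `obj.*`/`seg.*` by name.
#' @param background optional background rows; defaults to `matrix`
#'   (subsampled to `n_background`).
#' @param n_background background sample size for interventional expectations.
#' @param n_explain maximum number of rows to explain (subsampled, seeded).
#' @param exact_max_p switch-over point between enumeration and sampling.
#' @param n_perm permutations for the sampled estimator.
#' @param seed integer seed.
#' @return a list of class `vlur_importance`: `importance` (tibble `feature`,
#'   `category`, `mean_abs_shapley`), `streetview_ratio`, `method`.
#' @export
shapley_ratio <- function(model, matrix, category_map = NULL,
                          background = NULL, n_background = 20,
                          n_explain = 100, exact_max_p = 8, n_perm = 5,
                          seed = 1L) {
  x <- if (inherits(matrix, "vlur_feature_matrix")) {
    as.data.frame(matrix$x)
  } else {
    as.data.frame(matrix)
  }
  feats <- if (inherits(model, "vlur_slr")) model$features else model$features
  x <- x[, intersect(names(x), feats), drop = FALSE]
  set.seed(substream_seed(seed, "shapley_rows"))
  if (nrow(x) > n_explain) x_ex <- x[sample(nrow(x), n_explain), ] else x_ex <- x
  if (inherits(model, "vlur_slr")) {
    phi <- shapley_linear(model, x_ex)
    method <- "linear-exact"
  } else {
    bg <- background %||% x
    if (nrow(bg) > n_background) bg <- bg[sample(nrow(bg), n_background), ]
    pf <- function(d) predict(model, d)
    if (ncol(x_ex) <= exact_max_p) {
      phi <- shapley_exact(pf, x_ex, bg)
      method <- "exact-enumeration"
    } else {
      phi <- shapley_sampled(pf, x_ex, bg, n_perm = n_perm, seed = seed)
      method <- "permutation-sampling"
    }
  }
  if (ncol(phi) == 0) {
    stop_invalid("Model has no features; importance undefined.")
  }
  imp <- colMeans(abs(phi))
  total <- sum(imp)
  if (total == 0) {
    abort("Total Shapley importance is zero; ratio undefined.",
          class = "vlur_undefined")
  }
  cats <- if (is.null(category_map)) {
    feature_category(names(imp))
  } else {
    unname(category_map[names(imp)])
  }
  visual <- grepl("^visual", cats)
  structure(list(
    importance = tibble::tibble(feature = names(imp), category = cats,
                                mean_abs_shapley = unname(imp)),
    streetview_ratio = sum(imp[visual]) / total,
    method = method
  ), class = "vlur_importance")
}

#' @export
print.vlur_importance <- function(x, ...) {
  cat(sprintf("<vlur_importance> street-view ratio %.3f (%s)\n",
              x$streetview_ratio, x$method))
  print(dplyr::arrange(x$importance, dplyr::desc(.data$mean_abs_shapley)))
  invisible(x)
}

#' Density comparison of training, prediction, and validation series
#'
#' Kernel-density summaries of each named series on its own support, as a
#' tidy table ready for plotting (the figure itself is left to the caller).
#' A series with a single distinct value degenerates to one histogram bin of
#' mass one (`density` `NA`).
#'
#' @param series named list of numeric vectors, e.g.
#'   `list(mobile = , slr_pred = , validation = )`.
#' @param n grid points per density.
#' @return tibble: `series`, `x`, `density`.
#' @export
export_density_comparison <- function(series, n = 256) {
  stopifnot(is.list(series), length(names(series)) == length(series))
  rows <- lapply(names(series), function(nm) {
    v <- series[[nm]]
    if (length(unique(v)) < 2) {
      return(tibble::tibble(series = nm, x = unique(v), density = NA_real_))
    }
    d <- density(v, n = n)
    tibble::tibble(series = nm, x = d$x, density = d$y)
  })
  dplyr::bind_rows(rows)
}
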