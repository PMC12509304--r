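# The two land-use-regression learners.
#
# The supervised stepwise linear regression (SLR) is implemented here in
# full: forward selection maximising adjusted R-squared under direction
# priors (a candidate is ineligible in a step if its own coefficient would
# violate its prior or if adding it would flip the sign of any
# already-selected constrained coefficient), a gain-threshold stop, then
# backward pruning by p-value and by variance inflation factor. The random
# forest stage wraps a standard ensemble learner (ranger) behind a seeded
# random grid search.

adj_r2 <- function(fit) summary(fit)$adj.r.squared

sign_ok <- function(coefs, priors) {
  all(vapply(names(coefs), function(nm) {
    p <- priors[[nm]]
    if (is.null(p) || p == "0") return(TRUE)
    if (p == "+") coefs[[nm]] > 0 else coefs[[nm]] < 0
  }, logical(1)))
}

vif_values <- function(x) {
  p <- ncol(x)
  if (p < 2) return(setNames(rep(1, p), colnames(x)))
  vapply(seq_len(p), function(j) {
    r2 <- summary(lm(x[[j]] ~ ., data = x[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1)) |> setNames(colnames(x))
}

#' Direction-constrained supervised stepwise linear regression
#'
#' Forward loop: at each step, among candidates whose entry (a) gives the
#' candidate a coefficient sign consistent with its prior and (b) does not
#' flip any already-selected constrained coefficient, add the one maximising
#' adjusted R-squared; stop when the best gain falls below `gain_threshold`.
#' Then prune backward: drop variables with p-value above `p_remove` (worst
#' first), then variables with VIF above `vif_max` (worst first), and finally
#' any variable whose constrained sign no longer matches its prior. If no
#' candidate is eligible at step one the result is an intercept-only model,
#' with a warning.
#'
#' @param matrix a `vlur_feature_matrix` from [assemble_matrix()], or a
#'   plain numeric tibble/data.frame of predictors.
#' @param response numeric response; taken from the matrix when omitted.
#' @param priors named direction priors (`"+"`, `"-"`, `"0"`); taken from the
#'   matrix metadata when omitted.
#' @param gain_threshold minimum adjusted-R-squared gain to keep stepping.
#' @param p_remove backward p-value threshold.
#' @param vif_max maximum tolerated variance inflation factor.
#' @return an object of class `vlur_slr`: intercept, named `coefficients`,
#'   selection `trace`, and a `diagnostics` table (coefficient, SE, p, VIF,
#'   prior).
#' @export
supervised_stepwise_select <- function(matrix, response = NULL, priors = NULL,
                                       gain_threshold = 0.01, p_remove = 0.1,
                                       vif_max = 3) {
  if (inherits(matrix, "vlur_feature_matrix")) {
    x <- as.data.frame(matrix$x)
    if (is.null(response)) response <- matrix$response
    if (is.null(priors)) {
      priors <- setNames(matrix$metadata$prior, matrix$metadata$feature)
    }
  } else {
    x <- as.data.frame(matrix)
  }
  if (is.null(priors)) priors <- setNames(rep("0", ncol(x)), names(x))
  if (nrow(x) < 10) stop_invalid("Need at least 10 rows to fit the SLR.")
  if (any(!is.finite(response))) stop_invalid("`response` must be finite.")
  y <- response

  selected <- character(0)
  candidates <- names(x)
  cur_adj <- 0
  trace <- list()
  repeat {
    best <- NULL
    for (cand in setdiff(candidates, selected)) {
      dat <- x[, c(selected, cand), drop = FALSE]
      fit <- lm(y ~ ., data = dat)
      cf <- coef(fit)[-1]
      if (anyNA(cf)) next # exact collinearity: ineligible
      if (!sign_ok(cf, priors)) next
      a <- adj_r2(fit)
      if (is.null(best) || a > best$adj) best <- list(feature = cand, adj = a)
    }
    if (is.null(best)) break
    gain <- best$adj - cur_adj
    if (gain < gain_threshold) break
    selected <- c(selected, best$feature)
    cur_adj <- best$adj
    trace[[length(trace) + 1L]] <-
      tibble::tibble(step = length(selected), feature = best$feature,
                     adj_r2 = cur_adj)
  }
  if (length(selected) == 0) {
    warn("No candidate entered the model (none direction-feasible or none above the gain threshold); intercept-only model.")
    return(new_slr(mean(y), numeric(0), tibble::tibble(), priors, y))
  }

  # backward prune on p-values, worst first
  repeat {
    fit <- lm(y ~ ., data = x[, selected, drop = FALSE])
    cf <- summary(fit)$coefficients
    pv <- setNames(cf[-1, 4], rownames(cf)[-1])
    if (all(pv <= p_remove) || length(selected) == 0) break
    selected <- setdiff(selected, names(which.max(pv)))
    if (length(selected) == 0) break
  }
  # VIF prune, worst first
  while (length(selected) >= 2) {
    v <- vif_values(x[, selected, drop = FALSE])
    if (max(v) <= vif_max) break
    selected <- setdiff(selected, names(which.max(v)))
  }
  # pruning can flip a constrained sign; drop offenders
  repeat {
    if (length(selected) == 0) break
    fit <- lm(y ~ ., data = x[, selected, drop = FALSE])
    cf <- coef(fit)[-1]
    bad <- names(cf)[vapply(names(cf), function(nm) {
      p <- priors[[nm]]
      !is.null(p) && p != "0" &&
        ((p == "+" && cf[[nm]] <= 0) || (p == "-" && cf[[nm]] >= 0))
    }, logical(1))]
    if (length(bad) == 0) break
    selected <- setdiff(selected, bad[1])
  }
  if (length(selected) == 0) {
    warn("All selected features pruned; intercept-only model.")
    return(new_slr(mean(y), numeric(0),
                   dplyr::bind_rows(trace), priors, y))
  }

  fit <- lm(y ~ ., data = x[, selected, drop = FALSE])
  sm <- summary(fit)$coefficients
  v <- vif_values(x[, selected, drop = FALSE])
  diag <- tibble::tibble(
    feature = selected,
    coefficient = unname(coef(fit)[selected]),
    se = unname(sm[selected, 2]),
    p_value = unname(sm[selected, 4]),
    vif = unname(v[selected]),
    prior = unname(vapply(selected,
                          function(f) priors[[f]] %||% "0", character(1)))
  )
  new_slr(unname(coef(fit)[1]), coef(fit)[selected],
          dplyr::bind_rows(trace), priors, y, diag,
          feature_means = colMeans(x[, selected, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_slr <- function(intercept, coefficients, trace, priors, y,
                    diagnostics = NULL, feature_means = NULL) {
  structure(list(
    intercept = intercept,
    coefficients = coefficients,
    features = names(coefficients),
    trace = trace,
    diagnostics = diagnostics,
    priors = priors,
    feature_means = feature_means,
    response_mean = mean(y)
  ), class = "vlur_slr")
}

#' @export
print.vlur_slr <- function(x, ...) {
  cat("<vlur_slr> intercept:", format(x$intercept, digits = 4), "\n")
  if (length(x$coefficients)) {
    print(tibble::tibble(feature = x$features,
                         coefficient = unname(x$coefficients)))
  } else {
    cat("(intercept-only)\n")
  }
  invisible(x)
}

extract_x <- function(newdata, features) {
  x <- if (inherits(newdata, "vlur_feature_matrix")) newdata$x else newdata
  miss <- setdiff(features, names(x))
  if (length(miss) > 0) {
    stop_invalid(sprintf("New data lacks training feature(s): %s",
                         paste(miss, collapse = ", ")))
  }
  as.data.frame(x)[, features, drop = FALSE]
}

#' Predict from a fitted SLR model
#'
#' @param object a `vlur_slr`.
#' @param newdata a `vlur_feature_matrix` or a data frame containing every
#'   selected feature (extra columns ignored; missing ones are an error).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.vlur_slr <- function(object, newdata, ...) {
  if (length(object$coefficients) == 0) {
    n <- if (inherits(newdata, "vlur_feature_matrix")) {
      length(newdata$segment_id)
    } else {
      nrow(newdata)
    }
    return(rep(object$intercept, n))
  }
  x <- extract_x(newdata, object$features)
  drop(object$intercept + as.matrix(x) %*% object$coefficients)
}

#' Random-forest LUR with seeded random grid search
#'
#' Samples `n_draws` hyperparameter combinations from the grid (without
#' replacement when the grid is small), scores each by `cv_folds`-fold
#' cross-validated RMSE, and refits the best on all rows. The tuned
#' hyperparameters are the number of trees, the maximum tree depth, and the
#' minimum node size (the ensemble backend controls leaf granularity through
#' node size rather than a leaf-count cap).
#'
#' @param matrix a `vlur_feature_matrix` or predictor data frame.
#' @param response numeric response; taken from the matrix when omitted.
#' @param grid named list with `num_trees`, `max_depth` (0 = unlimited), and
#'   `min_node_size`, each a vector of values to search.
#' @param n_draws number of random grid draws to score.
#' @param cv_folds folds of the tuning cross-validation.
#' @param seed integer seed governing draws, fold assignment, and forests.
#' @return an object of class `vlur_rf`: the fitted ensemble, `best`
#'   hyperparameters, and the `tuning_log`.
#' @export
fit_rf <- function(matrix, response = NULL,
                   grid = list(num_trees = c(100, 300, 500, 1000),
                               max_depth = c(5, 10, 20, 0),
                               min_node_size = c(1, 5, 10, 20)),
                   n_draws = 20, cv_folds = 5, seed = 1L) {
  if (inherits(matrix, "vlur_feature_matrix")) {
    x <- as.data.frame(matrix$x)
    if (is.null(response)) response <- matrix$response
  } else {
    x <- as.data.frame(matrix)
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) == 0) stop_invalid("Empty hyperparameter grid.")
  set.seed(substream_seed(seed, "rf_tuning"))
  draw <- sample(nrow(combos), min(n_draws, nrow(combos)))
  combos <- combos[draw, , drop = FALSE]
  n <- nrow(x)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  dat <- cbind(x, .y = response)

  score_one <- function(hp) {
    errs <- vapply(seq_len(cv_folds), function(k) {
      tr <- dat[folds != k, , drop = FALSE]
      te <- dat[folds == k, , drop = FALSE]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = tr,
        num.trees = hp$num_trees, max.depth = hp$max_depth,
        min.node.size = hp$min_node_size,
        seed = substream_seed(seed, "rf_fit"), num.threads = 1
      )
      pred <- predict(fit, te, num.threads = 1)$predictions
      sqrt(mean((pred - te$.y)^2))
    }, numeric(1))
    mean(errs)
  }
  log <- combos
  log$cv_rmse <- if (nrow(combos) == 1L) {
    NA_real_ # nothing to compare; skip the tuning CV
  } else {
    vapply(seq_len(nrow(combos)),
           function(i) score_one(combos[i, ]), numeric(1))
  }
  best <- if (nrow(log) == 1L) log else log[which.min(log$cv_rmse), , drop = FALSE]
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = best$num_trees, max.depth = best$max_depth,
    min.node.size = best$min_node_size,
    seed = substream_seed(seed, "rf_final"), num.threads = 1
  )
  structure(list(
    forest = fit,
    best = as.list(best[, names(grid)]),
    tuning_log = tibble::as_tibble(log),
    features = names(x),
    seed = seed
  ), class = "vlur_rf")
}

#' @export
print.vlur_rf <- function(x, ...) {
  cat("<vlur_rf>", x$forest$num.trees, "trees; best:",
      paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted random-forest LUR
#'
#' @param object a `vlur_rf`.
#' @param newdata a `vlur_feature_matrix` or data frame with every training
#'   feature.
#' @param ... unused.
#' @return numeric vector of ensemble-mean predictions.
#' @export
predict.vlur_rf <- function(object, newdata, ...) {
  x <- extract_x(newdata, object$features)
  predict(object$forest, x, num.threads = 1)$predictions
}

#' Season-weighted prediction
#'
#' Final long-term estimate from a warm/cold model pair: for segments present
#' in both seasonal matrices the mean of the two seasonal predictions; for
#' segments present in only one, that season's prediction, flagged.
#'
#' @param pair named list `list(warm = , cold = )` of fitted models of the
#'   same learner type.
#' @param warm_matrix,cold_matrix `vlur_feature_matrix` objects for the two
#'   seasonal selections.
#' @return tibble: `segment_id`, `estimate`, `both_seasons`.
#' @export
season_weighted_predict <- function(pair, warm_matrix, cold_matrix) {
  pw <- tibble::tibble(segment_id = warm_matrix$segment_id,
                       warm = predict(pair$warm, warm_matrix))
  pc <- tibble::tibble(segment_id = cold_matrix$segment_id,
                       cold = predict(pair$cold, cold_matrix))
  j <- dplyr::full_join(pw, pc, by = "segment_id")
  tibble::tibble(
    segment_id = j$segment_id,
    estimate = rowMeans(cbind(j$warm, j$cold), na.rm = TRUE),
    both_seasons = !is.na(j$warm) & !is.na(j$cold)
  )
}

#' Serialise an SLR model to human-readable JSON
#'
#' @param model a `vlur_slr`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_slr_json <- function(model, path) {
  jsonlite::write_json(list(
    type = "slr", version = 1L,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    trace = model$trace,
    diagnostics = model$diagnostics
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
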