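# End-to-end orchestration: one configuration drives simulate -> preprocess
# -> image selection -> feature assembly -> fitting -> evaluation for all 12
# variants (2 learners x 2 feature sets x 3 temporal strategies). All
# randomness flows from the configuration's master seed through named
# substreams, so stages are independently reproducible.

#' Classic predictor columns of a road-segment table
#'
#' Everything except identifiers, geometry, road class, and the latent
#' visual (`obj.*` / `seg.*`) columns.
#'
#' @param segments road-segment table.
#' @return tibble: `segment_id` + classic predictor columns.
#' @export
classic_features <- function(segments) {
  drop <- c("x", "y", "x0", "y0", "x1", "y1", "road_class")
  keep <- setdiff(names(segments), c(drop, grep("^(obj|seg)\\.",
                                                names(segments), value = TRUE)))
  segments[, keep]
}

# Cross-validation for the season-weighted strategy: folds are over segments;
# each fold refits both seasonal models on the remaining segments and the
# held-out estimate is the season-weighted prediction, scored against the
# all-season aggregate.
cv_season_weighted <- function(warm_fm, cold_fm, obs, spec, k = 5, seed = 1L) {
  ids <- union(warm_fm$segment_id, cold_fm$segment_id)
  ids <- ids[ids %in% obs$segment_id]
  n <- length(ids)
  if (k < 2 || k > n) stop_invalid("`k` must be between 2 and the row count.")
  set.seed(substream_seed(seed, "cv_folds_season"))
  folds <- sample(rep(seq_len(k), length.out = n))
  pred <- rep(NA_real_, n)
  for (i in seq_len(k)) {
    test_ids <- ids[folds == i]
    w_tr <- subset_matrix(warm_fm, rows = which(!warm_fm$segment_id %in% test_ids))
    c_tr <- subset_matrix(cold_fm, rows = which(!cold_fm$segment_id %in% test_ids))
    pair <- list(warm = fit_learner(w_tr, spec, seed = seed + i),
                 cold = fit_learner(c_tr, spec, seed = seed + i))
    w_te <- subset_matrix(warm_fm, rows = which(warm_fm$segment_id %in% test_ids))
    c_te <- subset_matrix(cold_fm, rows = which(cold_fm$segment_id %in% test_ids))
    sw <- season_weighted_predict(pair, w_te, c_te)
    pred[match(sw$segment_id, ids)] <- sw$estimate
  }
  keep <- !is.na(pred)
  obs_v <- obs$value[match(ids, obs$segment_id)]
  list(
    oof = tibble::tibble(segment_id = ids[keep], obs = obs_v[keep],
                         pred = pred[keep]),
    metrics = score(pred[keep], obs_v[keep])
  )
}

#' Run the full pipeline for every model variant
#'
#' Simulates the scenario, preprocesses the mobile campaign, applies the
#' three temporal image-selection strategies, assembles classic and
#' classic+visual matrices per strategy (classic variants are restricted to
#' the same segments as their visual counterparts, so the comparison isolates
#' the visual columns), cross-validates both learners on each, optionally
#' validates externally against the fixed sites, and reports the street-view
#' Shapley contribution ratio of the visual variants.
#'
#' @param config a [scenario_config()].
#' @param slr_spec,rf_spec learner specifications (see [kfold_cv()]).
#' @param cv_k cross-validation folds.
#' @param winsor_pct winsorization percentiles handed to
#'   [preprocess_mobile()]; `c(0, 100)` disables trimming (appropriate for
#'   noiseless validation scenarios, where there are no artifacts to trim).
#' @param external also validate against the scenario's fixed sites.
#' @param shapley compute street-view Shapley ratios for visual variants.
#' @param pollutant label used in the report.
#' @return a list of class `vlur_run`: `summary` (one row per variant:
#'   metrics, deltas vs the classic baseline, Shapley ratio), `models`,
#'   `cv`, `matrices`, `scenario`, `manifest`.
#' @export
run_all <- function(config,
                    slr_spec = list(learner = "slr"),
                    rf_spec = list(learner = "rf", num_trees = 300,
                                   max_depth = 0, min_node_size = 5),
                    cv_k = 5, winsor_pct = c(2.5, 97.5),
                    external = TRUE, shapley = TRUE,
                    pollutant = "NO2") {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    t0 <<- Sys.time()
  }

  scn <- simulate_scenario(config)
  tick("simulate")
  prep <- preprocess_mobile(scn$measurements, scn$reference, scn$segments,
                            plausible_range = config$plausible_range,
                            winsor_pct = winsor_pct,
                            by_season = TRUE, quiet = TRUE)
  tick("preprocess")

  window <- c(config$campaign_start, config$campaign_end)
  assignments <- assign_panoramas(scn$panoramas, scn$segments)
  selections <- list(
    SpecificY = select_specific_year(assignments, window),
    MostnearY = select_most_near_year(assignments, window),
    SeasonWeighted = select_season_weighted(assignments, window)
  )
  tick("select_images")

  classic <- classic_features(scn$segments)
  agg_all <- prep$aggregates[prep$aggregates$season == "all", ]
  agg_season <- prep$aggregates_seasonal
  specs <- list(slr = slr_spec, rf = rf_spec)

  matrices <- list()
  models <- list()
  cvres <- list()
  rows <- list()
  matched <- if (external) {
    match_fixed_sites(scn$fixed_sites, scn$segments, max_distance = 20)
  } else {
    NULL
  }

  for (strategy in names(selections)) {
    sel <- selections[[strategy]]
    if (strategy == "SeasonWeighted") {
      vis_w <- build_visual_features(sel$warm, scn$panoramas)
      vis_c <- build_visual_features(sel$cold, scn$panoramas)
      aw <- agg_season[agg_season$season == "warm", ]
      ac <- agg_season[agg_season$season == "cold", ]
      fms <- list(
        classic = list(
          warm = assemble_matrix(aw[aw$segment_id %in% vis_w$segment_id, ], classic),
          cold = assemble_matrix(ac[ac$segment_id %in% vis_c$segment_id, ], classic)),
        visual = list(
          warm = assemble_matrix(aw, classic, vis_w),
          cold = assemble_matrix(ac, classic, vis_c))
      )
    } else {
      vis <- build_visual_features(sel, scn$panoramas)
      agg_sub <- agg_all[agg_all$segment_id %in% vis$segment_id, ]
      fms <- list(classic = assemble_matrix(agg_sub, classic),
                  visual = assemble_matrix(agg_sub, classic, vis))
    }
    matrices[[strategy]] <- fms

    for (learner in names(specs)) {
      base_metrics <- NULL
      for (variant in c("classic", "visual")) {
        key <- paste(strategy, learner, variant, sep = ".")
        fm <- fms[[variant]]
        if (strategy == "SeasonWeighted") {
          cv <- cv_season_weighted(fm$warm, fm$cold, agg_all, specs[[learner]],
                                   k = cv_k, seed = config$seed)
          model <- list(warm = fit_learner(fm$warm, specs[[learner]],
                                           seed = config$seed),
                        cold = fit_learner(fm$cold, specs[[learner]],
                                           seed = config$seed))
          n_train <- length(unique(c(fm$warm$segment_id, fm$cold$segment_id)))
        } else {
          cv <- kfold_cv(fm, specs[[learner]], k = cv_k, seed = config$seed)
          model <- fit_learner(fm, specs[[learner]], seed = config$seed)
          n_train <- length(fm$segment_id)
        }
        models[[key]] <- model
        cvres[[key]] <- cv
        m <- cv$metrics

        ext <- list(r2 = NA_real_, mae = NA_real_, rmse = NA_real_)
        n_ext <- NA_integer_
        if (external && nrow(matched) >= 2) {
          if (strategy == "SeasonWeighted") {
            est <- season_weighted_predict(model, fm$warm, fm$cold)
          } else {
            est <- tibble::tibble(segment_id = fm$segment_id,
                                  estimate = predict(model, fm))
          }
          j <- dplyr::inner_join(matched, est, by = "segment_id")
          n_ext <- nrow(j)
          if (n_ext >= 2) ext <- score(j$estimate, j$value)
        }

        ratio <- NA_real_
        if (shapley && variant == "visual") {
          if (strategy == "SeasonWeighted") {
            rw <- shapley_ratio(model$warm, fm$warm, seed = config$seed)
            rc <- shapley_ratio(model$cold, fm$cold, seed = config$seed)
            ratio <- (rw$streetview_ratio + rc$streetview_ratio) / 2
          } else {
            ratio <- shapley_ratio(model, fm, seed = config$seed)$streetview_ratio
          }
        }

        row <- tibble::tibble(
          pollutant = pollutant, strategy = strategy, learner = learner,
          variant = variant, n_train = n_train,
          cv_r2 = m$r2, cv_mae = m$mae, cv_rmse = m$rmse,
          ext_n = n_ext, ext_r2 = ext$r2, ext_mae = ext$mae,
          ext_rmse = ext$rmse, shapley_ratio = ratio
        )
        if (variant == "classic") {
          base_metrics <- row
          row$delta_r2 <- NA_real_
          row$delta_mae_pct <- NA_real_
          row$delta_rmse_pct <- NA_real_
        } else {
          row$delta_r2 <- row$cv_r2 - base_metrics$cv_r2
          row$delta_mae_pct <- 100 * (base_metrics$cv_mae - row$cv_mae) /
            base_metrics$cv_mae
          row$delta_rmse_pct <- 100 * (base_metrics$cv_rmse - row$cv_rmse) /
            base_metrics$cv_rmse
        }
        rows[[key]] <- row
      }
    }
  }
  tick("fit_evaluate")

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_segments = config$n_segments,
    n_measurements = nrow(scn$measurements),
    n_panoramas = nrow(scn$panoramas),
    timings_sec = timings
  )
  structure(list(summary = dplyr::bind_rows(rows), models = models,
                 cv = cvres, matrices = matrices, selections = selections,
                 scenario = scn, preprocessed = prep, manifest = manifest),
            class = "vlur_run")
}

#' @export
print.vlur_run <- function(x, ...) {
  cat(sprintf("<vlur_run> %d model variants; config %s\n",
              nrow(x$summary), x$manifest$config_hash))
  print(x$summary[, c("strategy", "learner", "variant", "n_train",
                      "cv_r2", "cv_mae", "delta_r2", "delta_mae_pct",
                      "shapley_ratio")])
  invisible(x)
}
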