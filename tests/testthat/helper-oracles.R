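# Independent brute-force reference implementations. These deliberately use
# naive loops and hand-written linear algebra so they share no code path with
# the package functions they check.

# Percentile by explicit sort-and-interpolate (linear interpolation rule).
oracle_percentile <- function(v, pct) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * pct / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_winsorize <- function(v, lower_pct, upper_pct) {
  lo <- oracle_percentile(v, lower_pct)
  hi <- oracle_percentile(v, upper_pct)
  out <- v
  for (i in seq_along(out)) {
    if (out[i] < lo) out[i] <- lo
    if (out[i] > hi) out[i] <- hi
  }
  out
}

# Scalar point-to-segment distance, looped over all pairs.
oracle_seg_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- ((px - x0) * dx + (py - y0) * dy) / l2
  t <- min(1, max(0, t))
  sqrt((px - x0 - t * dx)^2 + (py - y0 - t * dy)^2)
}

oracle_nearest <- function(px, py, segments, max_dist = Inf) {
  out_id <- character(length(px))
  out_d <- numeric(length(px))
  for (i in seq_along(px)) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(segments))) {
      d <- oracle_seg_dist(px[i], py[i], segments$x0[j], segments$y0[j],
                           segments$x1[j], segments$y1[j])
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    out_id[i] <- if (best_d <= max_dist) segments$segment_id[best_j] else NA
    out_d[i] <- best_d
  }
  data.frame(segment_id = out_id, distance = out_d)
}

# Pass counting by a single linear scan per (car, day, segment) group.
oracle_pass_count <- function(readings, gap_threshold = 10) {
  key <- paste(readings$car_id, readings$drive_day, readings$segment_id)
  total <- 0L
  for (k in unique(key)) {
    t <- sort(as.numeric(readings$timestamp[key == k]))
    n_pass <- 1L
    if (length(t) > 1) {
      for (i in 2:length(t)) if (t[i] - t[i - 1] > gap_threshold) {
        n_pass <- n_pass + 1L
      }
    }
    total <- total + n_pass
  }
  total
}

# Nested mean-of-means computed with explicit loops.
oracle_mean_of_means <- function(passes) {
  res <- list()
  for (s in unique(passes$segment_id)) {
    seg <- passes[passes$segment_id == s, ]
    day_means <- c()
    for (d in unique(as.character(seg$drive_day))) {
      day <- seg[as.character(seg$drive_day) == d, ]
      pm <- c()
      for (p in unique(day$pass_id)) {
        pm <- c(pm, mean(day$concentration[day$pass_id == p]))
      }
      day_means <- c(day_means, mean(pm))
    }
    res[[s]] <- mean(day_means)
  }
  res
}

# Ordinary least squares by hand (normal equations); returns coefficients,
# adjusted R2, and two-sided p-values.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  n <- nrow(X1); p <- ncol(X1)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(beta = drop(beta)[-1], intercept = drop(beta)[1], adj = adj,
       p = drop(pval)[-1])
}

oracle_sign_ok <- function(beta, priors) {
  for (nm in names(beta)) {
    pr <- priors[[nm]]
    if (is.null(pr) || pr == "0") next
    if (pr == "+" && beta[[nm]] <= 0) return(FALSE)
    if (pr == "-" && beta[[nm]] >= 0) return(FALSE)
  }
  TRUE
}

oracle_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(rep(1, ncol(X)))
  sapply(seq_len(ncol(X)), function(j) {
    fit <- oracle_ols(X[, -j, drop = FALSE], X[, j])
    pred <- fit$intercept + X[, -j, drop = FALSE] %*% fit$beta
    r2 <- 1 - sum((X[, j] - pred)^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - r2, 1e-12)
  })
}

# Independent re-implementation of the direction-constrained forward
# stepwise selection with identical stopping and pruning rules, evaluating
# every candidate extension exhaustively at each step.
oracle_slr_select <- function(X, y, priors, gain_threshold = 0.01,
                              p_remove = 0.1, vif_max = 3) {
  X <- as.data.frame(X)
  selected <- character(0)
  cur_adj <- 0
  repeat {
    best_f <- NULL; best_adj <- -Inf
    for (cand in setdiff(names(X), selected)) {
      cols <- c(selected, cand)
      fit <- tryCatch(oracle_ols(X[, cols, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$beta)) next
      names(fit$beta) <- cols
      if (!oracle_sign_ok(fit$beta, priors)) next
      if (fit$adj > best_adj) { best_adj <- fit$adj; best_f <- cand }
    }
    if (is.null(best_f) || best_adj - cur_adj < gain_threshold) break
    selected <- c(selected, best_f)
    cur_adj <- best_adj
  }
  # backward p-value prune, worst first
  repeat {
    if (length(selected) == 0) break
    fit <- oracle_ols(X[, selected, drop = FALSE], y)
    names(fit$p) <- selected
    if (max(fit$p) <= p_remove) break
    selected <- setdiff(selected, names(which.max(fit$p)))
  }
  # VIF prune, worst first
  while (length(selected) >= 2) {
    v <- oracle_vif(X[, selected, drop = FALSE])
    names(v) <- selected
    if (max(v) <= vif_max) break
    selected <- setdiff(selected, names(which.max(v)))
  }
  # drop constrained sign violations introduced by pruning
  repeat {
    if (length(selected) == 0) break
    fit <- oracle_ols(X[, selected, drop = FALSE], y)
    names(fit$beta) <- selected
    bad <- selected[!sapply(selected, function(nm) {
      pr <- priors[[nm]]
      is.null(pr) || pr == "0" ||
        (pr == "+" && fit$beta[[nm]] > 0) || (pr == "-" && fit$beta[[nm]] < 0)
    })]
    if (length(bad) == 0) break
    selected <- setdiff(selected, bad[1])
  }
  selected
}

# Exact Shapley values of an arbitrary model by full coalition enumeration
# over subsets generated with combn(), with the interventional value of a
# coalition averaged over background rows.
oracle_shapley <- function(predict_fun, x, background) {
  x <- as.data.frame(x); background <- as.data.frame(background)
  p <- ncol(x)
  feats <- names(x)
  phi <- matrix(0, nrow(x), p, dimnames = list(NULL, feats))
  vmemo <- new.env()
  vfun <- function(S) {
    key <- paste0("k:", paste(sort(S), collapse = ","))
    if (!is.null(vmemo[[key]])) return(vmemo[[key]])
    vals <- sapply(seq_len(nrow(x)), function(i) {
      d <- background
      for (f in S) d[[f]] <- x[i, f]
      mean(predict_fun(d))
    })
    vmemo[[key]] <- vals
    vals
  }
  for (j in feats) {
    others <- setdiff(feats, j)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(character(0)) else {
        asplit(utils::combn(others, k), 2)
      }
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) {
        S <- as.character(S)
        phi[, j] <- phi[, j] + w * (vfun(c(S, j)) - vfun(S))
      }
    }
  }
  phi
}

# Small random readings table for preprocessing property tests.
random_readings <- function(n, n_days = 3, n_segments = 5, seed = 1) {
  set.seed(seed)
  days <- as.Date("2019-06-03") + sort(sample(0:20, n_days))
  day <- sample(days, n, replace = TRUE)
  tibble::tibble(
    timestamp = as.POSIXct(day, tz = "UTC") + sample(3600 * 9:19, n, TRUE) +
      sample(0:59, n, TRUE),
    x = runif(n, 0, 200), y = runif(n, 0, 200),
    concentration = rnorm(n, 30, 8),
    car_id = sample(c("car1", "car2"), n, TRUE),
    drive_day = day,
    segment_id = sprintf("S%03d", sample(n_segments, n, TRUE))
  )
}

# Random regression dataset with mixed-sign truth and matching priors.
make_slr_dataset <- function(n, p, k_true, beta_abs = 1, noise_sd = 1,
                             seed = 1, rho = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0) {
    z <- rnorm(n)
    X <- sqrt(1 - rho) * X + sqrt(rho) * z
  }
  colnames(X) <- sprintf("f%02d", seq_len(p))
  true_idx <- sample(p, k_true)
  signs <- sample(c(-1, 1), k_true, replace = TRUE)
  beta <- signs * beta_abs
  y <- 10 + X[, true_idx, drop = FALSE] %*% beta + rnorm(n, 0, noise_sd)
  priors <- setNames(rep("0", p), colnames(X))
  priors[true_idx] <- ifelse(signs > 0, "+", "-")
  list(X = tibble::as_tibble(as.data.frame(X)), y = drop(y),
       priors = priors, true_features = colnames(X)[true_idx],
       beta = setNames(beta, colnames(X)[true_idx]))
}
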