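#' Assemble a design matrix for one nutrient model
#'
#' X is the raw-side composition over the 27 modelled components of the
#' dataset's variant (R' for SCS, R for PINS/unscaled); y is the
#' variant-scaled cooked amount of the nutrient (C' for PINS, C otherwise).
#' Rows with any missing required cell are dropped and logged in the
#' `dropped` element. The dataset must already be variant-scaled and
#' per-nutrient filtered, and must contain a single process class.
#'
#' @param dataset A paired dataset.
#' @param nutrient Target nutrient.
#' @param features Feature components (default [model_components()]
#'   intersected with the dataset).
#' @param min_rows Minimum usable rows (default 20).
#' @return A list of class `design_matrix`: `x` (matrix), `y`, `pair_id`,
#'   `category`, `nutrient`, `process_class`, `variant`, `features`,
#'   `dropped` (tibble `pair_id`, `reason`).
#' @export
assemble_design <- function(dataset, nutrient,
                            features = intersect(model_components(), dataset_components(dataset)),
                            min_rows = 20) {
  pc <- unique(dataset$process_class)
  if (length(pc) != 1) stop("dataset must contain a single process class; got: ", paste(pc, collapse = ", "))
  ycol <- paste0("cooked_", nutrient)
  if (!ycol %in% names(dataset)) stop("nutrient not present: ", nutrient)
  x <- side_matrix(dataset, "raw", features)
  y <- dataset[[ycol]]
  ok <- stats::complete.cases(x) & is.finite(y)
  dropped <- tibble::tibble(
    pair_id = dataset$pair_id[!ok], reason = "missing required component amount"
  )
  if (sum(ok) < min_rows) {
    stop("insufficient data: ", sum(ok), " usable rows (< ", min_rows, ") for ",
         nutrient, " [", dataset_variant(dataset), "]")
  }
  structure(
    list(
      x = x[ok, , drop = FALSE], y = y[ok], pair_id = dataset$pair_id[ok],
      category = dataset$category[ok], nutrient = nutrient, process_class = pc,
      variant = dataset_variant(dataset), features = features, dropped = dropped
    ),
    class = "design_matrix"
  )
}

#' Default hyperparameter grids over the six regressor families
#'
#' Six families: LASSO, elastic net, decision tree, random forest, gradient
#' boosting and a small multilayer perceptron. The `"compact"` grid
#' (35 candidates) is the experiment default; `"default"` (144 candidates)
#' widens every family's ranges. Candidate counts are always reported by
#' the search, never assumed.
#'
#' @param size `"compact"` or `"default"`.
#' @return A tibble `candidate_id`, `family`, `params` (list-column),
#'   `label`.
#' @export
default_grids <- function(size = c("compact", "default")) {
  size <- match.arg(size)
  expand_family <- function(family, ...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    tibble::tibble(
      family = family,
      params = purrr::map(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
    )
  }
  grids <- if (size == "compact") {
    dplyr::bind_rows(
      expand_family("lasso", lambda = c(1e-8, 1e-4, 1e-3, 1e-2, 1e-1)),
      expand_family("enet", alpha = c(0.3, 0.7), lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
      expand_family("tree", cp = c(0.001, 0.01), maxdepth = c(4, 8)),
      expand_family("rf", mtry_frac = c(0.2, 0.33, 0.6), min_node = c(2, 5), num_trees = 200),
      expand_family("gboost", eta = c(0.1, 0.3), nrounds = c(60, 150), max_depth = c(2, 4)),
      expand_family("mlp", size = c(3, 8), decay = c(0.01, 0.1), maxit = 200)
    )
  } else {
    dplyr::bind_rows(
      expand_family("lasso", lambda = c(1e-8, 1e-5, 1e-4, 1e-3, 1e-2, 3e-2, 1e-1, 3e-1)),
      expand_family("enet", alpha = seq(0.1, 0.9, by = 0.2),
                    lambda = c(1e-8, 1e-5, 1e-4, 1e-3, 1e-2, 3e-2, 1e-1, 3e-1)),
      expand_family("tree", cp = c(5e-4, 1e-3, 5e-3, 1e-2, 5e-2), maxdepth = c(3, 5, 8, 12)),
      expand_family("rf", mtry_frac = c(0.15, 0.25, 0.4, 0.6), min_node = c(1, 3, 5),
                    num_trees = c(200, 500)),
      expand_family("gboost", eta = c(0.05, 0.1, 0.3), nrounds = c(50, 100, 200),
                    max_depth = c(2, 3, 4, 6)),
      expand_family("mlp", size = c(2, 4, 8, 16), decay = c(1e-3, 1e-2, 1e-1, 0.5),
                    maxit = 200)
    )
  }
  grids |>
    dplyr::mutate(
      candidate_id = dplyr::row_number(),
      label = purrr::map2_chr(family, params, function(f, p) {
        paste0(f, "(", paste(names(p), unlist(p), sep = "=", collapse = ","), ")")
      }),
      .before = 1
    )
}

# fit one candidate on (x, y); returns a closure predicting on new x.
# glmnet standardizes x internally; y is standardized here so that lambda
# grids are comparable across nutrients with very different units; the MLP
# standardizes both. Tree families are fit unscaled.
fit_candidate <- function(family, params, x, y, seed) {
  set.seed(seed)
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  p <- ncol(x)
  if (family %in% c("lasso", "enet")) {
    alpha <- if (family == "lasso") 1 else params$alpha
    # glmnet requires >= 2 columns; pad single-feature designs with a
    # zero-variance column whose coefficient is necessarily zero
    pad <- ncol(x) < 2
    if (pad) x <- cbind(x, `.pad` = 0)
    fit <- glmnet::glmnet(x, ys, alpha = alpha, lambda = params$lambda,
                          standardize = TRUE, thresh = 1e-10, maxit = 10^7)
    function(newx) {
      if (pad) newx <- cbind(newx, `.pad` = 0)
      as.vector(stats::predict(fit, newx)) * y_sd + y_mu
    }
  } else if (family == "tree") {
    df <- data.frame(y = y, x, check.names = FALSE)
    fit <- rpart::rpart(
      y ~ ., data = df, method = "anova",
      control = rpart::rpart.control(cp = params$cp, maxdepth = params$maxdepth,
                                     minsplit = 5, xval = 0)
    )
    function(newx) unname(stats::predict(fit, data.frame(newx, check.names = FALSE)))
  } else if (family == "rf") {
    fit <- ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      mtry = max(1L, floor(params$mtry_frac * p)),
      min.node.size = params$min_node, seed = seed, num.threads = 1
    )
    function(newx) stats::predict(fit, data = newx, num.threads = 1)$predictions
  } else if (family == "gboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(eta = params$eta, max_depth = params$max_depth,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
    function(newx) {
      as.vector(stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1)))
    }
  } else if (family == "mlp") {
    x_mu <- colMeans(x)
    x_sd <- apply(x, 2, stats::sd)
    x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
    xs <- sweep(sweep(x, 2, x_mu), 2, x_sd, `/`)
    fit <- nnet::nnet(xs, ys, size = params$size, decay = params$decay,
                      linout = TRUE, maxit = params$maxit, trace = FALSE,
                      MaxNWts = 5000)
    function(newx) {
      newxs <- sweep(sweep(newx, 2, x_mu), 2, x_sd, `/`)
      as.vector(stats::predict(fit, newxs)) * y_sd + y_mu
    }
  } else {
    stop("unknown model family: ", family)
  }
}

make_folds <- function(n, k) {
  if (k > n) stop("folds > rows")
  split(sample.int(n), rep_len(seq_len(k), n)[order(sample.int(n))])
}

fit_seed <- function(seed, a, b) {
  as.integer((as.numeric(seed) + 7919 * a + 104729 * b) %% 2147483647L)
}

# seeded k-fold out-of-fold predictions for one candidate
cv_oof <- function(spec, x, y, folds_idx, seed) {
  pred <- rep(NA_real_, length(y))
  for (f in seq_along(folds_idx)) {
    test <- folds_idx[[f]]
    model <- fit_candidate(spec$family, spec$params, x[-test, , drop = FALSE],
                           y[-test], fit_seed(seed, f, 0))
    pred[test] <- model(x[test, , drop = FALSE])
  }
  pred
}

#' Grid-search cross-validated model selection
#'
#' Exhaustively evaluates every grid candidate under seeded k-fold
#' cross-validation (folds shared across candidates) and returns the
#' candidate minimizing the mean per-fold RMSE; ties break toward the
#' first candidate in deterministic grid order. The full per-candidate
#' score table is retained so the winner can always be re-derived as its
#' argmin.
#'
#' @param design A [assemble_design()] result.
#' @param grids Candidate grid (see [default_grids()]).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment and model fits.
#' @return A list of class `model_search_result`: `best` (list `family`,
#'   `params`, `label`), `cv_rmse_mean`, `cv_rmse_sd`, `candidates`
#'   (score table), `n_candidates`, `folds`, `seed`, plus design metadata.
#' @export
grid_search_train <- function(design, grids = default_grids("compact"),
                              folds = 5, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  if (nrow(grids) == 0) stop("empty grid")
  n <- length(design$y)
  if (folds > n) stop("folds > rows")
  folds_idx <- withr::with_seed(seed, make_folds(n, folds))

  scores <- purrr::pmap(
    list(grids$candidate_id, grids$family, grids$params),
    function(cid, family, params) {
      fold_rmse <- vapply(seq_along(folds_idx), function(f) {
        test <- folds_idx[[f]]
        model <- fit_candidate(family, params, design$x[-test, , drop = FALSE],
                               design$y[-test], fit_seed(seed, f, cid))
        sqrt(mean((design$y[test] - model(design$x[test, , drop = FALSE]))^2))
      }, numeric(1))
      tibble::tibble(rmse_mean = mean(fold_rmse), rmse_sd = stats::sd(fold_rmse))
    }
  )
  candidates <- dplyr::bind_cols(
    grids[, c("candidate_id", "family", "params", "label")],
    dplyr::bind_rows(scores)
  )
  best_i <- which.min(candidates$rmse_mean)
  structure(
    list(
      best = list(family = candidates$family[best_i],
                  params = candidates$params[[best_i]],
                  label = candidates$label[best_i]),
      cv_rmse_mean = candidates$rmse_mean[best_i],
      cv_rmse_sd = candidates$rmse_sd[best_i],
      candidates = candidates,
      n_candidates = nrow(candidates),
      folds = folds, seed = seed,
      nutrient = design$nutrient, process_class = design$process_class,
      variant = design$variant
    ),
    class = "model_search_result"
  )
}

#' @export
print.model_search_result <- function(x, ...) {
  cat("<model_search_result>", x$nutrient, x$process_class, x$variant, "\n",
      " best:", x$best$label, " cv RMSE", signif(x$cv_rmse_mean, 4),
      "over", x$n_candidates, "candidates\n")
  invisible(x)
}

#' Repeated (bootstrapped) k-fold evaluation of one model specification
#'
#' Runs `runs` repetitions of re-shuffled seeded k-fold cross-validation of
#' a fixed model specification, computes metrics on each run's out-of-fold
#' predictions, and retains the pooled predictions for per-category
#' breakdowns. `runs = 1` reduces to a single seeded k-fold CV. A config
#' switch (`resample = TRUE`) replaces the re-shuffling by true bootstrap
#' resampling of rows (sampling with replacement, evaluating on the
#' out-of-bag rows).
#'
#' @param design A [assemble_design()] result.
#' @param model_spec List with `family` and `params` (e.g. `$best` of a
#'   search result).
#' @param runs Number of repetitions (default 50).
#' @param folds CV folds per repetition (default 5).
#' @param seed Integer seed.
#' @param resample If `TRUE`, bootstrap-resample rows instead of
#'   re-shuffling folds.
#' @return A list of class `bootstrap_eval`: `per_run` (tibble of per-run
#'   metrics), `summary` (mean and sd per metric), `pooled` (metrics over
#'   all pooled predictions), `predictions` (tibble `run`, `pair_id`,
#'   `category`, `actual`, `predicted`).
#' @export
bootstrap_evaluate <- function(design, model_spec, runs = 50, folds = 5,
                               seed = 1L, resample = FALSE) {
  stopifnot(inherits(design, "design_matrix"))
  n <- length(design$y)
  if (folds > n) stop("folds > rows")
  runs_out <- purrr::map(seq_len(runs), function(r) {
    run_seed <- fit_seed(seed, r, 999)
    if (resample) {
      idx <- withr::with_seed(run_seed, sample.int(n, n, replace = TRUE))
      oob <- setdiff(seq_len(n), unique(idx))
      model <- fit_candidate(model_spec$family, model_spec$params,
                             design$x[idx, , drop = FALSE], design$y[idx],
                             fit_seed(run_seed, 1, 0))
      keep <- oob
      pred <- model(design$x[keep, , drop = FALSE])
    } else {
      folds_idx <- withr::with_seed(run_seed, make_folds(n, folds))
      pred <- cv_oof(model_spec, design$x, design$y, folds_idx, run_seed)
      keep <- seq_len(n)
    }
    list(
      metrics = dplyr::mutate(compute_metrics(design$y[keep], pred), run = r, .before = 1),
      predictions = tibble::tibble(
        run = r, pair_id = design$pair_id[keep], category = design$category[keep],
        actual = design$y[keep], predicted = pred
      )
    )
  })
  per_run <- dplyr::bind_rows(purrr::map(runs_out, "metrics"))
  predictions <- dplyr::bind_rows(purrr::map(runs_out, "predictions"))
  summary <- tidyr::pivot_longer(per_run, -"run", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(
    list(per_run = per_run, summary = summary,
         pooled = compute_metrics(predictions$actual, predictions$predicted),
         predictions = predictions,
         nutrient = design$nutrient, process_class = design$process_class,
         variant = design$variant, runs = runs, folds = folds, seed = seed),
    class = "bootstrap_eval"
  )
}

#' Sequential (greedy) feature selection
#'
#' Backward elimination by default: starting from the full feature set, the
#' feature whose removal yields the lowest cross-validated RMSE is removed
#' at each step; the rank of a feature is its elimination order reversed
#' (the last survivor has rank 1). Forward selection is the symmetric
#' variant. The returned curve records the CV RMSE of the selected subset
#' at every size k = 1..p.
#'
#' @param design A [assemble_design()] result (>= 2 features).
#' @param model_spec Model specification (family + params).
#' @param direction `"backward"` or `"forward"`.
#' @param folds CV folds (default 5).
#' @param seed Integer seed (fold assignment fixed across subsets).
#' @return A list of class `feature_selection_result`: `curve` (tibble `k`,
#'   `rmse`, `features` list-column), `ranks` (tibble `feature`, `rank`).
#' @export
sequential_feature_select <- function(design, model_spec,
                                      direction = c("backward", "forward"),
                                      folds = 5, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(design, "design_matrix"))
  feats <- design$features
  p <- length(feats)
  if (p < 2) stop("need at least 2 features")
  n <- length(design$y)
  folds_idx <- withr::with_seed(seed, make_folds(n, folds))
  score_subset <- function(subset) {
    pred <- cv_oof(model_spec, design$x[, subset, drop = FALSE], design$y,
                   folds_idx, seed)
    out <- sqrt(mean((design$y - pred)^2))
    if (!is.finite(out)) stop("non-finite CV score for subset: ", paste(subset, collapse = ","))
    out
  }

  curve <- vector("list", p)
  ranks <- stats::setNames(integer(p), feats)
  if (direction == "backward") {
    current <- feats
    curve[[p]] <- tibble::tibble(k = p, rmse = score_subset(current),
                                 features = list(current))
    while (length(current) > 1) {
      k <- length(current)
      scores <- vapply(current, function(f) score_subset(setdiff(current, f)), numeric(1))
      drop_f <- current[which.min(scores)]
      ranks[drop_f] <- k
      current <- setdiff(current, drop_f)
      curve[[k - 1]] <- tibble::tibble(k = k - 1, rmse = min(scores),
                                       features = list(current))
    }
    ranks[current] <- 1L
  } else {
    current <- character(0)
    remaining <- feats
    while (length(remaining) > 0) {
      scores <- vapply(remaining, function(f) score_subset(c(current, f)), numeric(1))
      add_f <- remaining[which.min(scores)]
      current <- c(current, add_f)
      remaining <- setdiff(remaining, add_f)
      ranks[add_f] <- length(current)
      curve[[length(current)]] <- tibble::tibble(
        k = length(current), rmse = min(scores), features = list(current)
      )
    }
  }
  structure(
    list(curve = dplyr::bind_rows(curve),
         ranks = tibble::tibble(feature = feats, rank = unname(ranks[feats])),
         direction = direction, nutrient = design$nutrient,
         process_class = design$process_class, variant = design$variant),
    class = "feature_selection_result"
  )
}

#' Combine feature ranks across models
#'
#' @param results List of [sequential_feature_select()] results sharing one
#'   feature universe.
#' @return A list: `ranks` (tibble `feature` x one column per model) and
#'   `ordering` (tibble `feature`, `mean_rank`, ascending — rank 1 is
#'   most important).
#' @export
rank_features_across_models <- function(results) {
  if (length(results) == 0) stop("no feature-selection results")
  universes <- purrr::map(results, function(r) sort(r$ranks$feature))
  if (!all(purrr::map_lgl(universes, identical, universes[[1]]))) {
    stop("feature universes differ across models")
  }
  names(results) <- names(results) %||%
    purrr::map_chr(results, function(r) paste(r$process_class, r$nutrient, sep = "_"))
  wide <- purrr::imap(results, function(r, nm) {
    stats::setNames(tibble::tibble(r$ranks$rank[match(universes[[1]], r$ranks$feature)]), nm)
  })
  ranks <- dplyr::bind_cols(tibble::tibble(feature = universes[[1]]), wide)
  ordering <- tibble::tibble(
    feature = ranks$feature,
    mean_rank = rowMeans(as.matrix(ranks[, -1, drop = FALSE]))
  ) |>
    dplyr::arrange(.data$mean_rank)
  list(ranks = ranks, ordering = ordering)
}
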