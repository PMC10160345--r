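#' Build an experiment configuration
#'
#' Bundles everything a full experiment needs: the data source (a synthetic
#' world configuration, or paths to SR-Legacy-style CSVs plus a retention
#' table), the scaling variants to run per process class, the nutrient
#' lists (14 micronutrients for wet heat; 13 for dry heat, where vitamin C
#' is excluded because it is absent from meats), grid size, CV settings and
#' the master seed. Models are always trained separately per process class;
#' pooling wet- and dry-heat pairs into one model is refused because food
#' source and process are confounded in this kind of data.
#'
#' @param data Either `list(type = "synthetic", config = synthetic_config(),
#'   n_per_class = c(WH = 200, DH = 200))` or `list(type = "csv",
#'   pairs = <path>, retention_table = <path>)`.
#' @param variants Named list (per process class) of variant labels among
#'   `"unscaled"`, `"scs"`, `"pins-<component>"`, `"pins-<component>-loss5"`.
#' @param nutrients Named list (per process class) of target nutrients.
#' @param grids `"compact"`, `"default"`, or a grid tibble.
#' @param folds,runs CV folds and bootstrap repetitions.
#' @param rf_group_by Aggregation level of the synthetic retention-factor
#'   table used as baseline (`"source"` emulates the coarseness of real RF
#'   tables; `"category"` is finer).
#' @param reliable_subset Nutrients treated as most reliably measured for
#'   the restricted per-category summary.
#' @param min_rows Minimum design rows per model.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for CSV outputs and the manifest.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(
    data = list(type = "synthetic", config = synthetic_config(),
                n_per_class = c(WH = 200, DH = 200)),
    variants = list(WH = c("unscaled", "scs"),
                    DH = c("unscaled", "scs", "pins-cholesterol")),
    nutrients = list(WH = micronutrients(),
                     DH = setdiff(micronutrients(), "vitamin_c")),
    grids = "compact",
    folds = 5, runs = 5,
    rf_group_by = "source",
    reliable_subset = c("niacin", "vitamin_b6", "calcium", "iron", "zinc"),
    min_rows = 20,
    seed = NULL,
    out_dir = NULL) {
  structure(
    list(data = data, variants = variants, nutrients = nutrients, grids = grids,
         folds = folds, runs = runs, rf_group_by = rf_group_by,
         reliable_subset = reliable_subset, min_rows = min_rows, seed = seed,
         out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Validate an experiment configuration
#'
#' Reports problems without raising: unknown nutrients or variants are
#' errors, vitamin C requested under dry heat is a warning (it is not a
#' significant source in meats), a missing seed is a warning (a seed is
#' auto-set and recorded by [run_experiment()]).
#'
#' @param config An [experiment_config()].
#' @return A tibble with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  problems <- list()
  add <- function(level, msg) {
    problems[[length(problems) + 1]] <<- tibble::tibble(level = level, message = msg)
  }
  if (length(unlist(config$variants)) == 0) add("error", "empty variant list")
  for (pc in names(config$variants)) {
    bad <- !grepl("^(unscaled|scs|pins-[a-z_]+(-loss5)?)$", config$variants[[pc]])
    if (any(bad)) {
      add("error", paste0("unknown variant(s) for ", pc, ": ",
                          paste(config$variants[[pc]][bad], collapse = ", ")))
    }
  }
  known <- component_catalogue()$component
  for (pc in names(config$nutrients)) {
    bad <- setdiff(config$nutrients[[pc]], known)
    if (length(bad) > 0) {
      add("error", paste0("unknown nutrient(s) for ", pc, ": ", paste(bad, collapse = ", ")))
    }
  }
  if ("vitamin_c" %in% config$nutrients$DH) {
    add("warning", "vitamin C requested under dry heat: not a significant source in meats; models are normally trained for the other 13 micronutrients")
  }
  if (is.null(config$seed)) add("warning", "no seed set; run_experiment() will auto-set and record one")
  if (config$folds < 2) add("error", "folds must be >= 2")
  if (config$runs < 1) add("error", "runs must be >= 1")
  if (length(problems) == 0) {
    tibble::tibble(level = character(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

parse_variant <- function(label) {
  if (label %in% c("unscaled", "scs")) {
    return(list(kind = label))
  }
  m <- regmatches(label, regexec("^pins-([a-z_]+?)(-loss5)?$", label))[[1]]
  if (length(m) == 0) stop("unknown variant label: ", label)
  list(kind = "pins", invariant = m[2],
       assumed_retention = if (nzchar(m[3])) 0.95 else 1.0)
}

apply_variant <- function(dataset, label) {
  v <- parse_variant(label)
  switch(v$kind,
    unscaled = set_variant(dataset, "unscaled"),
    scs = scs_scale(dataset),
    pins = pins_scale(dataset, invariant = v$invariant,
                      assumed_retention = v$assumed_retention)
  )
}

#' Run a full experiment
#'
#' Executes the pipeline end to end: simulate (or load) paired data, build
#' each scaling variant per process class, filter anomalous pairs
#' per nutrient, grid-search a model per (process class, variant,
#' nutrient), evaluate it with repeated k-fold CV, compute the RF100 and
#' RF-table baselines on identical rows, and assemble comparison tables.
#' Re-running with the same configuration (including seed) reproduces
#' identical tables. Any stage failure aborts with a stage-named error;
#' outputs written before the failure are retained.
#'
#' @param config An [experiment_config()].
#' @param progress Print per-model progress lines.
#' @return A list of class `experiment_result`: `models` (one row per
#'   trained model with search, evaluation and baseline columns),
#'   `anomaly` (per-variant anomaly summaries), `report` (see
#'   [build_report()]), `predictions` (pooled out-of-fold predictions of
#'   the best arm per process class), `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), progress = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  problems <- validate_config(config)
  if (any(problems$level == "error")) {
    stop("stage config: invalid configuration:\n  ",
         paste(problems$message[problems$level == "error"], collapse = "\n  "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir)) readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }

  # --- stage: data -----------------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop("stage ", name, " failed: ",
                                            conditionMessage(e), call. = FALSE))
  }
  data_in <- stage("data", {
    if (identical(config$data$type, "synthetic")) {
      world <- generate_world(config$data$config, seed = seed)
      n_class <- config$data$n_per_class
      cats <- world$categories
      n_per_cat <- unlist(lapply(seq_len(nrow(cats)), function(i) {
        pc <- cats$process_class[i]
        stats::setNames(max(1L, round(n_class[[pc]] / sum(cats$process_class == pc))),
                        cats$name[i])
      }))
      pairs <- generate_pairs(world, n_per_cat)
      rf_tab <- generate_retention_table(world, pairs, group_by = config$rf_group_by)
      list(dataset = pairs$dataset, rf_table = rf_tab, truth = pairs$truth)
    } else if (identical(config$data$type, "csv")) {
      list(dataset = read_pairs_csv(config$data$pairs),
           rf_table = read_retention_table(config$data$retention_table),
           truth = NULL)
    } else {
      stop("unknown data source type: ", config$data$type)
    }
  })
  emit("retention_table", data_in$rf_table)

  grids <- if (is.character(config$grids)) default_grids(config$grids) else config$grids

  # --- stages: scale, filter, train, baseline --------------------------------
  model_rows <- list()
  anomaly_rows <- list()
  predictions <- list()
  candidate_rows <- list()
  model_idx <- 0L
  for (pc in names(config$variants)) {
    ds_pc <- data_in$dataset[data_in$dataset$process_class == pc, , drop = FALSE]
    if (nrow(ds_pc) == 0) next
    for (variant in config$variants[[pc]]) {
      scaled <- stage(paste("scale", pc, variant), apply_variant(ds_pc, variant))
      an <- anomaly_summary(scaled, nutrients = config$nutrients[[pc]])
      anomaly_rows[[paste(pc, variant)]] <- dplyr::mutate(an, process_class = pc, .before = 1)
      for (nutrient in config$nutrients[[pc]]) {
        model_idx <- model_idx + 1L
        model_seed <- fit_seed(seed, model_idx, 0)
        row <- stage(paste("train", pc, variant, nutrient), {
          filtered <- filter_pairs(scaled, nutrient)
          design <- assemble_design(filtered, nutrient, min_rows = config$min_rows)
          search <- grid_search_train(design, grids = grids, folds = config$folds,
                                      seed = model_seed)
          eval <- bootstrap_evaluate(design, search$best, runs = config$runs,
                                     folds = config$folds, seed = model_seed)
          used <- filtered[match(design$pair_id, filtered$pair_id), , drop = FALSE]
          b100 <- rf100_predict(used, nutrient)
          btab <- rf_table_predict(used, nutrient, data_in$rf_table)
          rmse_tab <- if (nrow(btab) > 0) baseline_rmse(used, nutrient, btab) else NA_real_
          if (progress) {
            message(sprintf("[%s %s %s] best %s cv-rmse %.4g", pc, variant, nutrient,
                            search$best$label, search$cv_rmse_mean))
          }
          candidate_rows[[model_idx]] <- dplyr::mutate(
            search$candidates[, c("candidate_id", "family", "label", "rmse_mean", "rmse_sd")],
            process_class = pc, variant = dataset_variant(scaled),
            nutrient = nutrient, .before = 1
          )
          predictions[[model_idx]] <- dplyr::mutate(
            eval$predictions, process_class = pc,
            variant = dataset_variant(scaled), nutrient = nutrient, .before = 1
          )
          tibble::tibble(
            process_class = pc, variant = dataset_variant(scaled),
            nutrient = nutrient,
            n_pairs = length(design$y), n_candidates = search$n_candidates,
            best_label = search$best$label,
            cv_rmse = search$cv_rmse_mean,
            model_rmse_mean = mean(eval$per_run$rmse),
            model_rmse_sd = stats::sd(eval$per_run$rmse),
            model_rmse_pooled = eval$pooled$rmse,
            model_r2_pooled = eval$pooled$r2,
            model_pcc_pooled = eval$pooled$pcc,
            model_src_pooled = eval$pooled$src,
            actual_mean = mean(design$y), actual_sd = stats::sd(design$y),
            rf100_rmse = baseline_rmse(used, nutrient, b100),
            rftable_rmse = rmse_tab,
            seed = model_seed
          )
        })
        model_rows[[model_idx]] <- row
      }
    }
  }
  models <- dplyr::bind_rows(model_rows)
  anomaly <- dplyr::bind_rows(anomaly_rows)
  emit("anomaly", anomaly)
  emit("model_results", models)
  emit("candidate_scores", dplyr::bind_rows(candidate_rows))

  # --- stage: report ---------------------------------------------------------
  best_variant <- c(WH = "SCS", DH = grep("^PINS", unique(models$variant), value = TRUE)[1])
  predictions <- dplyr::bind_rows(predictions)
  report <- stage("report", build_report(models, predictions,
                                         best_variant = best_variant,
                                         reliable_subset = config$reliable_subset))
  if (!is.null(out_dir)) {
    for (nm in names(report$tables)) emit(nm, report$tables[[nm]])
  }
  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = seed, grids = if (is.character(config$grids)) config$grids else "custom",
    n_models = nrow(models),
    package_version = as.character(utils::packageVersion("nutricook")),
    r_version = as.character(getRversion())
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  structure(
    list(models = models, anomaly = anomaly, predictions = predictions,
         candidates = dplyr::bind_rows(candidate_rows),
         report = report, manifest = manifest,
         rf_table = data_in$rf_table, truth = data_in$truth),
    class = "experiment_result"
  )
}

#' Assemble comparison tables from trained-model results
#'
#' Produces machine-readable analogues of the study's result tables:
#' a variant-comparison table of per-nutrient model RMSE per process class
#' (with the across-nutrient average row), a baseline-comparison table for
#' the best arm per process class (model vs RF-table vs RF100 RMSE, with
#' relative-improvement percentages), per-category breakdowns of the pooled
#' out-of-fold predictions, win/loss tallies of model vs each baseline, and
#' paired tests between variants.
#'
#' @param models The `models` tibble of [run_experiment()].
#' @param predictions Pooled out-of-fold predictions with `process_class`,
#'   `variant`, `nutrient`, `category`, `actual`, `predicted`.
#' @param best_variant Named character: the arm per process class used for
#'   baseline comparison and category breakdown.
#' @param reliable_subset Nutrients for the restricted category summary.
#' @return A list with `tables` (named list of tibbles), `win_loss`, and
#'   `variant_tests`.
#' @export
build_report <- function(models, predictions,
                         best_variant = c(WH = "SCS", DH = "PINS-cholesterol"),
                         reliable_subset = c("niacin", "vitamin_b6", "calcium", "iron", "zinc")) {
  tables <- list()
  variant_tests <- list()
  win_loss <- list()
  for (pc in unique(models$process_class)) {
    m_pc <- models[models$process_class == pc, , drop = FALSE]
    t1 <- m_pc |>
      dplyr::select("nutrient", "variant", "model_rmse_mean") |>
      tidyr::pivot_wider(names_from = "variant", values_from = "model_rmse_mean")
    avg <- t1 |>
      dplyr::summarise(dplyr::across(-"nutrient", mean)) |>
      dplyr::mutate(nutrient = "AVERAGE", .before = 1)
    tables[[paste0("table1_", pc)]] <- dplyr::bind_rows(t1, avg)

    vars <- unique(m_pc$variant)
    if (length(vars) > 1) {
      combos <- utils::combn(vars, 2, simplify = FALSE)
      variant_tests[[pc]] <- dplyr::bind_rows(purrr::map(combos, function(vp) {
        a <- t1[[vp[1]]]
        b <- t1[[vp[2]]]
        ok <- is.finite(a) & is.finite(b)
        ct <- compare_arms(a[ok], b[ok])
        tibble::tibble(
          process_class = pc, variant_a = vp[1], variant_b = vp[2],
          mean_rmse_a = mean(a[ok]), mean_rmse_b = mean(b[ok]),
          statistic = ct$statistic, p_value = ct$p_value, method = ct$method
        )
      }))
    }

    bv <- best_variant[[pc]]
    if (!is.null(bv) && bv %in% m_pc$variant) {
      m_best <- m_pc[m_pc$variant == bv, , drop = FALSE]
      t2 <- tibble::tibble(
        nutrient = m_best$nutrient,
        actual_mean = m_best$actual_mean, actual_sd = m_best$actual_sd,
        model_rmse = m_best$model_rmse_pooled,
        rftable_rmse = m_best$rftable_rmse,
        rf100_rmse = m_best$rf100_rmse,
        rel_vs_rftable = relative_improvement(m_best$rftable_rmse, m_best$model_rmse_pooled),
        rel_vs_rf100 = relative_improvement(m_best$rf100_rmse, m_best$model_rmse_pooled),
        variant = bv
      )
      tables[[paste0("table2_", pc)]] <- t2
      win_loss[[pc]] <- tibble::tibble(
        process_class = pc,
        baseline = c("RF_table", "RF100"),
        wins = c(win_loss_tally(t2, "rftable_rmse")$wins,
                 win_loss_tally(t2, "rf100_rmse")$wins),
        n = c(win_loss_tally(t2, "rftable_rmse")$n,
              win_loss_tally(t2, "rf100_rmse")$n)
      )
      pred_best <- predictions[predictions$process_class == pc &
                                 predictions$variant == bv, , drop = FALSE]
      if (nrow(pred_best) > 0) {
        cb <- category_breakdown(pred_best)
        tables[[paste0("table3_cells_", pc)]] <- cb$cells
        tables[[paste0("table3_by_category_", pc)]] <- cb$by_category
        cbr <- category_breakdown(pred_best, reliable_subset = reliable_subset)
        tables[[paste0("table3_by_category_reliable_", pc)]] <- cbr$by_category
      }
    }
  }
  win_loss <- dplyr::bind_rows(win_loss)
  variant_tests <- dplyr::bind_rows(variant_tests)
  if (nrow(win_loss) > 0) tables$win_loss <- win_loss
  if (nrow(variant_tests) > 0) tables$variant_tests <- variant_tests
  list(tables = tables, win_loss = win_loss, variant_tests = variant_tests)
}

# baseline_rmse is defined with the baselines; win_loss_tally with evaluation.
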