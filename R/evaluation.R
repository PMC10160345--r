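#' Regression performance metrics
#'
#' Root mean squared error, coefficient of determination
#' (R2 = 1 - SSres/SStot, negative when predictions are worse than the
#' mean), Pearson and Spearman correlations. R2 and the correlations are
#' reported as `NA` (with attribute `reason`) when the actual series has
#' zero variance.
#'
#' @param actual,predicted Equal-length finite numeric vectors (length >= 2).
#' @return A one-row tibble `rmse`, `r2`, `pcc`, `src`, `n`.
#' @export
compute_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least 2 observations")
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) stop("non-finite values")
  rmse <- sqrt(mean((actual - predicted)^2))
  sstot <- sum((actual - mean(actual))^2)
  if (sstot == 0) {
    out <- tibble::tibble(rmse = rmse, r2 = NA_real_, pcc = NA_real_,
                          src = NA_real_, n = length(actual))
    attr(out, "reason") <- "zero variance in actual values"
    return(out)
  }
  ssres <- sum((actual - predicted)^2)
  pcc <- if (stats::sd(predicted) == 0) NA_real_ else stats::cor(actual, predicted)
  src <- if (stats::sd(predicted) == 0) NA_real_ else {
    stats::cor(actual, predicted, method = "spearman")
  }
  tibble::tibble(rmse = rmse, r2 = 1 - ssres / sstot, pcc = pcc, src = src,
                 n = length(actual))
}

#' Relative improvement of a model over a baseline, in percent
#'
#' `(baseline - predicted) / baseline * 100`; positive when the model beats
#' the baseline, negative when it is worse.
#'
#' @param baseline_rmse Baseline RMSE (> 0).
#' @param predicted_rmse Model RMSE.
#' @return Percentage.
#' @export
relative_improvement <- function(baseline_rmse, predicted_rmse) {
  if (any(baseline_rmse <= 0, na.rm = TRUE)) stop("baseline_rmse must be > 0")
  (baseline_rmse - predicted_rmse) / baseline_rmse * 100
}

#' Per-category breakdown of prediction performance
#'
#' Computes pooled out-of-fold metrics per (category, nutrient) cell and a
#' per-category mean and sd of R2 across nutrients, optionally restricted
#' to a subset of nutrients with the most reliable underlying data
#' (niacin, vitamin B6, calcium, iron, zinc in the USDA's assessment).
#' Cells with fewer than 2 predictions are reported as missing.
#'
#' @param predictions Tibble with columns `category`, `nutrient`, `actual`,
#'   `predicted`.
#' @param reliable_subset Optional character vector of nutrients to
#'   restrict the per-category summary to.
#' @return A list with tibbles `cells` (per category x nutrient: `rmse`,
#'   `r2`, `pcc`, `n`) and `by_category` (`category`, `mean_r2`, `sd_r2`,
#'   `n_nutrients`), ordered by decreasing `mean_r2`.
#' @export
category_breakdown <- function(predictions, reliable_subset = NULL) {
  stopifnot(all(c("category", "nutrient", "actual", "predicted") %in% names(predictions)))
  if (!is.null(reliable_subset)) {
    predictions <- predictions[predictions$nutrient %in% reliable_subset, , drop = FALSE]
  }
  cells <- predictions |>
    dplyr::group_by(.data$category, .data$nutrient) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble::tibble(rmse = NA_real_, r2 = NA_real_, pcc = NA_real_,
                              n = nrow(df)))
      }
      m <- compute_metrics(df$actual, df$predicted)
      tibble::tibble(rmse = m$rmse, r2 = m$r2, pcc = m$pcc, n = m$n)
    }) |>
    dplyr::ungroup()
  by_category <- cells |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      sd_r2 = stats::sd(.data$r2, na.rm = TRUE),
      n_nutrients = sum(!is.na(.data$r2)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_r2))
  list(cells = cells, by_category = by_category)
}

#' Paired comparison of two metric series
#'
#' Paired two-sided test on the differences between two aligned metric
#' series (e.g. per-nutrient RMSEs of two arms). The default is the
#' Wilcoxon signed-rank test; `"permutation"` runs an exact paired
#' sign-flip permutation test on the mean difference (all 2^n assignments
#' for n <= 20, otherwise 20,000 sampled flips); `"ttest"` a paired t-test.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @param method `"wilcoxon"`, `"permutation"` or `"ttest"`.
#' @return A list `statistic`, `p_value`, `method`.
#' @export
compare_arms <- function(a, b, method = c("wilcoxon", "permutation", "ttest")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, method = method))
  }
  if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = length(a) <= 20))
    list(statistic = unname(wt$statistic), p_value = wt$p.value, method = "wilcoxon signed-rank")
  } else if (method == "ttest") {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = "paired t-test")
  } else {
    n <- length(d)
    obs <- mean(d)
    if (n <= 20) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null <- as.vector(signs %*% d) / n
      p <- mean(abs(null) >= abs(obs) - 1e-12)
    } else {
      signs <- matrix(sample(c(-1, 1), 20000 * n, replace = TRUE), ncol = n)
      null <- as.vector(signs %*% d) / n
      p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (length(null) + 1)
    }
    list(statistic = obs, p_value = p, method = "exact paired permutation")
  }
}

#' Tally model-vs-baseline wins from a comparison table
#'
#' @param table Tibble with columns `model_rmse` and one column per
#'   baseline RMSE.
#' @param baseline_col Name of the baseline RMSE column.
#' @return A list `wins`, `n`, `fraction`.
#' @export
win_loss_tally <- function(table, baseline_col) {
  ok <- is.finite(table$model_rmse) & is.finite(table[[baseline_col]])
  wins <- sum(table$model_rmse[ok] < table[[baseline_col]][ok])
  list(wins = wins, n = sum(ok), fraction = wins / sum(ok))
}
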