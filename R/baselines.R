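#' Naive 100%-retention baseline
#'
#' Predicts that the cooked content of the nutrient equals its content in
#' the raw profile of the same dataset variant (retention factor 100%).
#' Because the prediction is taken from the variant's own raw side (R' for
#' SCS-scaled data, R otherwise), model and baseline are always compared on
#' identical rows and scales.
#'
#' @param dataset A paired dataset.
#' @param nutrient Component name.
#' @return A tibble `pair_id`, `nutrient`, `method`, `rf_used`, `predicted`.
#' @export
rf100_predict <- function(dataset, nutrient) {
  col <- paste0("raw_", nutrient)
  if (!col %in% names(dataset)) stop("nutrient not present: ", nutrient)
  tibble::tibble(
    pair_id = dataset$pair_id, nutrient = nutrient, method = "RF100",
    rf_used = 1.0, predicted = dataset[[col]]
  )
}

#' Retention-factor-table baseline
#'
#' Predicts the cooked content as the product of the table's retention
#' factor for (group, process, nutrient) and the nutrient's content in the
#' variant's raw profile. Pairs whose key cannot be resolved in the table
#' are omitted from the predictions and reported via the `"omitted"`
#' attribute — never silently defaulted to RF = 1.
#'
#' @param dataset A paired dataset.
#' @param nutrient Component name.
#' @param table A retention table (`group`, `process`, `nutrient`, `rf`),
#'   e.g. from [read_retention_table()] or [generate_retention_table()].
#' @param group_col Dataset column holding the table's group key
#'   (default `"rf_group"`, falling back to `"category"`).
#' @return A tibble as in [rf100_predict()] with `method = "RF_table"`.
#' @export
rf_table_predict <- function(dataset, nutrient, table, group_col = NULL) {
  col <- paste0("raw_", nutrient)
  if (!col %in% names(dataset)) stop("nutrient not present: ", nutrient)
  if (is.null(group_col)) {
    group_col <- if ("rf_group" %in% names(dataset)) "rf_group" else "category"
  }
  key <- paste(dataset[[group_col]], dataset$process_class, nutrient)
  rf <- table$rf[match(key, paste(table$group, table$process, table$nutrient))]
  ok <- !is.na(rf)
  out <- tibble::tibble(
    pair_id = dataset$pair_id[ok], nutrient = nutrient, method = "RF_table",
    rf_used = rf[ok], predicted = rf[ok] * dataset[[col]][ok]
  )
  attr(out, "omitted") <- tibble::tibble(
    pair_id = dataset$pair_id[!ok],
    reason = paste0("no retention factor for (", dataset[[group_col]][!ok], ", ",
                    dataset$process_class[!ok], ", ", nutrient, ")")
  )
  if (!all(ok)) {
    message(sum(!ok), " pair(s) omitted from RF-table baseline for ", nutrient,
            " (unresolvable table key)")
  }
  out
}

# RMSE of a baseline against the dataset's (variant-scaled) cooked values
baseline_rmse <- function(dataset, nutrient, predictions) {
  actual <- dataset[[paste0("cooked_", nutrient)]][
    match(predictions$pair_id, dataset$pair_id)
  ]
  sqrt(mean((actual - predictions$predicted)^2))
}
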