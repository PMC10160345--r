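#' Construct a paired dataset
#'
#' The container shared by all pipeline stages: a tibble with pair metadata
#' columns (`pair_id`, `process_class`, `category`, optionally `source` and
#' `rf_group`) and `raw_<component>` / `cooked_<component>` amount columns
#' in the components' native per-100 g units, plus attributes `components`
#' and `variant` (the scaling variant the data currently represents).
#'
#' @param df Data frame in the wide pairs layout.
#' @param components Component names (default: catalogue components whose
#'   `raw_` column is present, in catalogue order).
#' @param variant Variant label (default `"unscaled"`).
#' @return A `paired_dataset` tibble.
#' @export
paired_dataset <- function(df, components = NULL, variant = "unscaled") {
  if (is.null(components)) {
    cand <- component_catalogue()$component
    components <- cand[paste0("raw_", cand) %in% names(df)]
  }
  new_paired_dataset(df, components, variant)
}

new_paired_dataset <- function(df, components, variant = "unscaled") {
  stopifnot(all(c("pair_id", "process_class", "category") %in% names(df)))
  missing <- setdiff(c(paste0("raw_", components), paste0("cooked_", components)), names(df))
  if (length(missing) > 0) {
    stop("dataset is missing columns: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(
    tibble::as_tibble(df),
    components = components,
    variant = variant,
    class = c("paired_dataset", class(tibble::as_tibble(df)))
  )
}

#' Components carried by a paired dataset
#' @param dataset A paired dataset.
#' @return Character vector of component names.
#' @export
dataset_components <- function(dataset) {
  comps <- attr(dataset, "components")
  if (is.null(comps)) {
    cand <- component_catalogue()$component
    comps <- cand[paste0("raw_", cand) %in% names(dataset)]
  }
  comps
}

#' Scaling-variant label of a paired dataset
#' @param dataset A paired dataset.
#' @return Single string, e.g. "unscaled", "SCS", "PINS-cholesterol".
#' @export
dataset_variant <- function(dataset) {
  v <- attr(dataset, "variant")
  if (is.null(v)) "unscaled" else v
}

set_variant <- function(dataset, variant) {
  attr(dataset, "variant") <- variant
  dataset
}

# amount matrix for one side ("raw" or "cooked"), columns in component order
side_matrix <- function(dataset, side, components = dataset_components(dataset)) {
  cols <- paste0(side, "_", components)
  m <- as.matrix(as.data.frame(dataset)[, cols, drop = FALSE])
  colnames(m) <- components
  rownames(m) <- dataset$pair_id
  m
}

set_side_matrix <- function(dataset, side, m) {
  cols <- paste0(side, "_", colnames(m))
  for (j in seq_along(cols)) dataset[[cols[j]]] <- unname(m[, j])
  dataset
}

#' Write / read the tidy pairs CSV layout
#'
#' One row per raw/cooked pair: `pair_id`, `process_class`, `category`,
#' optional `source` and `rf_group`, then `raw_<component>` and
#' `cooked_<component>` columns in the components' declared units.
#'
#' @param dataset A paired dataset.
#' @param path CSV path.
#' @return `write_pairs_csv()` returns `path` invisibly; `read_pairs_csv()`
#'   returns a paired dataset (variant "unscaled" unless a `variant`
#'   attribute column comment is present).
#' @export
write_pairs_csv <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(dataset)), path)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cand <- component_catalogue()$component
  comps <- cand[paste0("raw_", cand) %in% names(df)]
  new_paired_dataset(df, comps)
}
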