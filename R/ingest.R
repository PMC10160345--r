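#' Read SR-Legacy-style composition tables
#'
#' Reads the three CSV tables of the FoodData Central SR Legacy dialect —
#' foods (`fdc_id`, `description`, `food_category`), nutrients (`id`,
#' `name`, `unit_name`) and food-nutrient amounts (`fdc_id`, `nutrient_id`,
#' `amount`) — joins them, maps nutrient names onto the component catalogue
#' (via the shipped `sr_component_map.csv` resource), and classifies every
#' food description with [classify_food()]. Foods with no amount rows are
#' kept with an empty profile. Duplicate (food, nutrient) amount rows are
#' deduplicated when identical and rejected with the offending food ids
#' when conflicting.
#'
#' @param food_table,nutrient_table,amount_table CSV paths.
#' @return A list of class `sr_records` with tibbles `foods` (one row per
#'   food, with `state`, `process`, `single_ingredient` classification
#'   columns) and `amounts` (long: `fdc_id`, `component`, `amount`, `unit`).
#' @export
read_sr_legacy <- function(food_table, nutrient_table, amount_table) {
  foods <- readr::read_csv(food_table, show_col_types = FALSE)
  nutrients <- readr::read_csv(nutrient_table, show_col_types = FALSE)
  amounts <- readr::read_csv(amount_table, show_col_types = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop("missing column(s) in ", what, " table: ", paste(miss, collapse = ", "))
    }
  }
  need(foods, c("fdc_id", "description", "food_category"), "food")
  need(nutrients, c("id", "name", "unit_name"), "nutrient")
  need(amounts, c("fdc_id", "nutrient_id", "amount"), "amount")

  bad_food <- setdiff(amounts$fdc_id, foods$fdc_id)
  if (length(bad_food) > 0) {
    stop("amount rows reference unknown food id(s): ",
         paste(utils::head(bad_food, 10), collapse = ", "))
  }
  bad_nut <- setdiff(amounts$nutrient_id, nutrients$id)
  if (length(bad_nut) > 0) {
    stop("amount rows reference unknown nutrient id(s): ",
         paste(utils::head(bad_nut, 10), collapse = ", "))
  }
  if (any(amounts$amount < 0, na.rm = TRUE)) stop("negative amounts in amount table")

  amounts <- dplyr::distinct(amounts, .data$fdc_id, .data$nutrient_id, .data$amount)
  dup <- amounts |>
    dplyr::count(.data$fdc_id, .data$nutrient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting duplicate amount rows for food id(s): ",
         paste(unique(utils::head(dup$fdc_id, 10)), collapse = ", "))
  }

  cmap <- readr::read_csv(
    system.file("extdata", "sr_component_map.csv", package = "nutricook"),
    show_col_types = FALSE
  )
  nutrients <- nutrients |>
    dplyr::mutate(
      component = cmap$component[match(.data$name, cmap$sr_name)],
      component = dplyr::coalesce(
        .data$component,
        gsub("[^a-z0-9]+", "_", tolower(.data$name))
      ),
      unit = c(G = "g", MG = "mg", UG = "ug", `µG` = "ug")[toupper(.data$unit_name)]
    )
  if (anyNA(nutrients$unit)) {
    stop("unsupported nutrient unit(s): ",
         paste(unique(nutrients$unit_name[is.na(nutrients$unit)]), collapse = ", "))
  }

  cls <- classify_food(foods$description)
  foods <- dplyr::bind_cols(
    tibble::tibble(
      fdc_id = foods$fdc_id, description = foods$description,
      category = foods$food_category
    ),
    cls,
    tibble::tibble(
      source_type = if ("source_type" %in% names(foods)) foods$source_type else "unknown"
    )
  )
  amounts <- amounts |>
    dplyr::left_join(
      dplyr::select(nutrients, "id", "component", "unit"),
      by = c(nutrient_id = "id")
    ) |>
    dplyr::select("fdc_id", "component", "amount", "unit")

  structure(list(foods = foods, amounts = amounts), class = "sr_records")
}

read_token_file <- function(file) {
  lines <- readLines(system.file("extdata", file, package = "nutricook"), warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tolower(lines)
}

#' Classify a food description
#'
#' Keyword-rule classification of SR-style descriptions into state
#' (raw/cooked/other), the cooking process (boil, steam, roast, grill,
#' broil, other, or none), and a single-ingredient flag. A description
#' matching any multi-ingredient/recipe marker (editable resource file
#' `multi_ingredient_markers.txt`) is flagged `single_ingredient = FALSE`.
#' Unknown descriptions classify as state `"other"`, never as an error.
#'
#' @param description Character vector of descriptions.
#' @return A tibble with columns `state`, `process`, `single_ingredient`.
#' @export
classify_food <- function(description) {
  if (any(!nzchar(description))) stop("empty description")
  d <- tolower(description)
  markers <- read_token_file("multi_ingredient_markers.txt")
  multi <- rep(FALSE, length(d))
  for (m in markers) multi <- multi | grepl(m, d, fixed = TRUE)

  proc_words <- c(
    boil = "boil(ed|ing)?", steam = "steam(ed|ing)?", roast = "roast(ed|ing)?",
    grill = "grill(ed|ing)?", broil = "broil(ed|ing)?"
  )
  process <- rep("none", length(d))
  for (p in names(proc_words)) {
    hit <- grepl(paste0("\\b", proc_words[[p]], "\\b"), d)
    process[hit & process == "none"] <- p
  }
  is_raw <- grepl("\\braw\\b", d)
  is_cooked <- process != "none" | grepl("\\bcooked\\b", d)
  state <- dplyr::case_when(
    is_raw & !is_cooked ~ "raw",
    is_cooked ~ "cooked",
    .default = "other"
  )
  process[state == "cooked" & process == "none"] <- "other"
  process[state != "cooked"] <- "none"
  tibble::tibble(state = state, process = process, single_ingredient = !multi)
}

process_class_of <- function(process) {
  dplyr::case_when(
    process %in% c("boil", "steam") ~ "WH",
    process %in% c("roast", "grill", "broil") ~ "DH",
    .default = NA_character_
  )
}

pairing_key <- function(description) {
  tokens <- read_token_file("preparation_tokens.txt")
  vapply(tolower(description), function(d) {
    parts <- trimws(strsplit(d, ",")[[1]])
    for (tok in tokens) {
      parts <- parts[parts != tok]
      parts <- trimws(gsub(paste0("\\b", gsub("([^a-z0-9 ])", "\\\\\\1", tok), "\\b"),
                           "", parts))
    }
    parts <- parts[nzchar(parts)]
    paste(parts, collapse = ", ")
  }, character(1), USE.NAMES = FALSE)
}

#' Pair raw and cooked single-ingredient foods
#'
#' Forms raw/cooked pairs by matching a normalized base description: the
#' lowercased description with state/process/preparation tokens (editable
#' resource file `preparation_tokens.txt`) removed. One raw food may anchor
#' several cooked forms (one pair per cooked record). Records that cannot
#' be paired are reported, never silently dropped: the result partitions
#' the input into pairs, an unmatched report and an excluded report.
#'
#' @param records An `sr_records` list (or its `foods` tibble).
#' @return A list of class `sr_pairing` with tibbles `pairs` (`pair_id`,
#'   `raw_fdc_id`, `cooked_fdc_id`, `process`, `process_class`, `category`),
#'   `unmatched` (`fdc_id`, `reason`) and `excluded` (`fdc_id`, `reason`).
#' @export
pair_foods <- function(records) {
  foods <- if (inherits(records, "sr_records")) records$foods else records
  foods <- dplyr::arrange(foods, .data$fdc_id)

  eligible_state <- foods$state %in% c("raw", "cooked")
  known_process <- foods$state != "cooked" | foods$process != "other"
  excluded <- dplyr::bind_rows(
    tibble::tibble(
      fdc_id = foods$fdc_id[!foods$single_ingredient],
      reason = "multi-ingredient or recipe food"
    ),
    tibble::tibble(
      fdc_id = foods$fdc_id[foods$single_ingredient & !eligible_state],
      reason = "state is neither raw nor cooked"
    ),
    tibble::tibble(
      fdc_id = foods$fdc_id[foods$single_ingredient & eligible_state & !known_process],
      reason = "cooked by an unmodelled process"
    )
  )
  pool <- foods[foods$single_ingredient & eligible_state & known_process, , drop = FALSE]
  pool$key <- pairing_key(pool$description)

  raws <- pool[pool$state == "raw", , drop = FALSE]
  cooked <- pool[pool$state == "cooked", , drop = FALSE]
  raw_count <- table(raws$key)
  ambiguous_keys <- names(raw_count)[raw_count > 1]

  unmatched <- dplyr::bind_rows(
    tibble::tibble(
      fdc_id = raws$fdc_id[raws$key %in% ambiguous_keys],
      reason = "ambiguous: several raw foods share the same base description"
    ),
    tibble::tibble(
      fdc_id = cooked$fdc_id[cooked$key %in% ambiguous_keys],
      reason = "ambiguous: several raw foods share the same base description"
    )
  )
  raws <- raws[!raws$key %in% ambiguous_keys, , drop = FALSE]
  cooked <- cooked[!cooked$key %in% ambiguous_keys, , drop = FALSE]

  matched <- cooked$key %in% raws$key
  unmatched <- dplyr::bind_rows(
    unmatched,
    tibble::tibble(fdc_id = cooked$fdc_id[!matched], reason = "no raw counterpart"),
    tibble::tibble(
      fdc_id = raws$fdc_id[!raws$key %in% cooked$key],
      reason = "no cooked counterpart"
    )
  )
  cooked <- cooked[matched, , drop = FALSE]
  idx <- match(cooked$key, raws$key)
  pairs <- tibble::tibble(
    raw_fdc_id = raws$fdc_id[idx],
    cooked_fdc_id = cooked$fdc_id,
    process = cooked$process,
    process_class = process_class_of(cooked$process),
    category = raws$category[idx]
  ) |>
    dplyr::arrange(.data$raw_fdc_id, .data$cooked_fdc_id) |>
    dplyr::mutate(pair_id = sprintf("pair_%04d", dplyr::row_number()), .before = 1)

  structure(
    list(pairs = pairs, unmatched = dplyr::arrange(unmatched, .data$fdc_id),
         excluded = dplyr::arrange(excluded, .data$fdc_id)),
    class = "sr_pairing"
  )
}

#' Select the modelled component set by reporting coverage
#'
#' Keeps the components whose (food, component) amount row exists — any
#' value, including explicit zeros — for at least `coverage` of the foods.
#' Returned in a stable order: catalogue components first (catalogue
#' order), then any others alphabetically.
#'
#' @param records An `sr_records` list.
#' @param coverage Required reporting fraction in (0, 1]; the boundary is
#'   inclusive (a component reported for exactly `coverage` of foods is
#'   kept).
#' @return Character vector of component names.
#' @export
select_components <- function(records, coverage = 0.8) {
  stopifnot(inherits(records, "sr_records"))
  if (!(coverage > 0 && coverage <= 1)) stop("coverage must lie in (0, 1]")
  n_foods <- nrow(records$foods)
  if (n_foods == 0) stop("no food records")
  cov <- records$amounts |>
    dplyr::distinct(.data$fdc_id, .data$component) |>
    dplyr::count(.data$component) |>
    dplyr::filter(.data$n >= coverage * n_foods)
  keep <- cov$component
  cat_order <- component_catalogue()$component
  c(intersect(cat_order, keep), sort(setdiff(keep, cat_order)))
}

#' Read a retention-factor table
#'
#' CSV with columns `group`, `process`, `nutrient` and `rf` (fractions) or
#' `rf_percent` (percentages, divided by 100 on read). Duplicate
#' (group, process, nutrient) keys and negative values are errors; lookups
#' into the returned table should treat missing keys as reportable, never
#' as a silent default.
#'
#' @param path CSV path.
#' @return A tibble `group`, `process`, `nutrient`, `rf`.
#' @export
read_retention_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if ("rf_percent" %in% names(tab)) {
    tab$rf <- tab$rf_percent / 100
    tab$rf_percent <- NULL
  }
  need <- setdiff(c("group", "process", "nutrient", "rf"), names(tab))
  if (length(need) > 0) stop("missing column(s) in retention table: ", paste(need, collapse = ", "))
  if (any(tab$rf < 0)) stop("negative retention factor(s) in table")
  dup <- tab |>
    dplyr::count(.data$group, .data$process, .data$nutrient) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate retention-table key(s): ",
         paste(utils::head(paste(dup$group, dup$process, dup$nutrient, sep = "/"), 5),
               collapse = ", "))
  }
  tab[, c("group", "process", "nutrient", "rf")]
}

#' Assemble a paired dataset from ingested records and a pairing
#'
#' Joins each pair's raw and cooked profiles into the tidy wide layout used
#' by the scaling and modelling modules (`raw_<component>`,
#' `cooked_<component>`); components missing for a food become `NA` and are
#' handled downstream by design-matrix assembly.
#'
#' @param records An `sr_records` list.
#' @param pairing A [pair_foods()] result.
#' @param components Component set to carry (default: catalogue components
#'   present in the amounts).
#' @return A paired dataset (variant `"unscaled"`).
#' @export
pairs_to_dataset <- function(records, pairing, components = NULL) {
  stopifnot(inherits(records, "sr_records"), inherits(pairing, "sr_pairing"))
  if (is.null(components)) {
    components <- intersect(component_catalogue()$component,
                            unique(records$amounts$component))
  }
  wide <- records$amounts |>
    dplyr::filter(.data$component %in% components) |>
    tidyr::pivot_wider(id_cols = "fdc_id", names_from = "component",
                       values_from = "amount")
  for (comp in setdiff(components, names(wide))) wide[[comp]] <- NA_real_
  wide <- wide[, c("fdc_id", components)]

  p <- pairing$pairs
  raw_side <- wide[match(p$raw_fdc_id, wide$fdc_id), components]
  names(raw_side) <- paste0("raw_", components)
  cooked_side <- wide[match(p$cooked_fdc_id, wide$fdc_id), components]
  names(cooked_side) <- paste0("cooked_", components)
  df <- dplyr::bind_cols(
    tibble::tibble(
      pair_id = p$pair_id, process_class = p$process_class, category = p$category
    ),
    raw_side, cooked_side
  )
  new_paired_dataset(df, components, variant = "unscaled")
}
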