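#' Component catalogue
#'
#' The catalogue of food components carried through the pipeline: water, seven
#' macronutrient aggregates, nine vitamins and ten minerals (the 27 modelled
#' components), plus cholesterol, which is not a model feature but is required
#' by process-invariant nutrient scaling (PINS). Each component has a fixed
#' reporting unit (per 100 g edible portion) and a class:
#' `macro_mass` components (water, protein, carbohydrate, fiber, total fat)
#' carry the mass closure of a 100 g portion; fat sub-fractions are part of
#' total fat and therefore excluded from mass sums.
#'
#' @return A tibble with columns `component`, `unit` (one of g, mg, ug) and
#'   `class` (macro_mass, fat_sub, vitamin, mineral, sterol).
#' @export
component_catalogue <- function() {
  tibble::tribble(
    ~component,              ~unit, ~class,
    "water",                 "g",   "macro_mass",
    "protein",               "g",   "macro_mass",
    "carbohydrate",          "g",   "macro_mass",
    "fiber",                 "g",   "macro_mass",
    "total_fat",             "g",   "macro_mass",
    "saturated_fat",         "g",   "fat_sub",
    "monounsaturated_fat",   "g",   "fat_sub",
    "polyunsaturated_fat",   "g",   "fat_sub",
    "thiamin",               "mg",  "vitamin",
    "riboflavin",            "mg",  "vitamin",
    "niacin",                "mg",  "vitamin",
    "pantothenic_acid",      "mg",  "vitamin",
    "vitamin_b6",            "mg",  "vitamin",
    "folate",                "ug",  "vitamin",
    "vitamin_c",             "mg",  "vitamin",
    "vitamin_a",             "ug",  "vitamin",
    "vitamin_e",             "mg",  "vitamin",
    "calcium",               "mg",  "mineral",
    "iron",                  "mg",  "mineral",
    "magnesium",             "mg",  "mineral",
    "phosphorus",            "mg",  "mineral",
    "potassium",             "mg",  "mineral",
    "sodium",                "mg",  "mineral",
    "zinc",                  "mg",  "mineral",
    "copper",                "mg",  "mineral",
    "manganese",             "mg",  "mineral",
    "selenium",              "ug",  "mineral",
    "cholesterol",           "mg",  "sterol"
  )
}

#' Names of the 27 modelled components (model feature set)
#'
#' All catalogue components except cholesterol, in catalogue order. These are
#' the input features of every regression model.
#' @return Character vector of length 27.
#' @export
model_components <- function() {
  cat <- component_catalogue()
  cat$component[cat$component != "cholesterol"]
}

#' Names of the 14 modelled micronutrients
#'
#' Seven vitamins (thiamin, riboflavin, niacin, B6, folate, C, A) and seven
#' minerals (calcium, iron, magnesium, phosphorus, potassium, sodium, zinc).
#' Vitamin C is excluded from dry-heat models because it is absent from meats.
#' @return Character vector of length 14.
#' @export
micronutrients <- function() {
  c(
    "thiamin", "riboflavin", "niacin", "vitamin_b6", "folate", "vitamin_c",
    "vitamin_a", "calcium", "iron", "magnesium", "phosphorus", "potassium",
    "sodium", "zinc"
  )
}

#' Mass-bearing components used for 100 g closure
#' @return Character vector: water, protein, carbohydrate, fiber, total_fat.
#' @export
mass_components <- function() {
  cat <- component_catalogue()
  cat$component[cat$class == "macro_mass"]
}

# grams per declared unit
unit_to_grams <- c(g = 1, mg = 1e-3, ug = 1e-6)

#' Unit of each component
#' @param components Character vector of component names (default: all).
#' @return Named character vector of units.
#' @export
component_units <- function(components = component_catalogue()$component) {
  cat <- component_catalogue()
  u <- stats::setNames(cat$unit, cat$component)
  missing <- setdiff(components, names(u))
  if (length(missing) > 0) {
    stop("unknown component(s): ", paste(missing, collapse = ", "))
  }
  u[components]
}

# multiply per-component amounts (native units) into grams
grams_factor <- function(components) {
  unname(unit_to_grams[component_units(components)])
}
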