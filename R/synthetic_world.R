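#' Default category specifications for the synthetic generator
#'
#' Nine food categories mirroring the curated composition dataset: five
#' plant categories cooked by wet heat (leafy greens, roots, vegetables,
#' legumes, cereals) and four animal categories cooked by dry heat (beef,
#' lamb, chicken, veal). Each category carries a mean raw composition per
#' 100 g edible portion, per-component coefficients of variation on the log
#' scale, a retention-scale multiplier that makes nutrient losses
#' category-heterogeneous, and the coarse group (`rf_group`) under which a
#' retention-factor table would file it.
#'
#' Composition means are realistic per-100 g values for the category (e.g.
#' leafy greens are water-rich, folate- and vitamin-A-dense; legumes and
#' cereals are paired from the dry state, as dried staples are in
#' composition tables, so their raw water content is low and boiling
#' produces a large water gain; meats carry cholesterol, B vitamins and
#' phosphorus, and no vitamin C or fiber).
#'
#' @return A tibble with one row per category and list-columns
#'   `profile_mean` and `profile_cv` (named numeric vectors over the
#'   component catalogue).
#' @export
default_categories <- function() {
  comps <- component_catalogue()$component

  plant_base <- c(
    thiamin = 0.08, riboflavin = 0.08, niacin = 0.8, pantothenic_acid = 0.3,
    vitamin_b6 = 0.12, folate = 60, vitamin_c = 30, vitamin_a = 50,
    vitamin_e = 0.8, calcium = 40, iron = 0.9, magnesium = 25,
    phosphorus = 50, potassium = 300, sodium = 20, zinc = 0.4,
    copper = 0.08, manganese = 0.3, selenium = 1, cholesterol = 0
  )
  animal_base <- c(
    thiamin = 0.07, riboflavin = 0.2, niacin = 5, pantothenic_acid = 0.8,
    vitamin_b6 = 0.4, folate = 8, vitamin_c = 0, vitamin_a = 10,
    vitamin_e = 0.3, calcium = 12, iron = 1.8, magnesium = 22,
    phosphorus = 190, potassium = 320, sodium = 65, zinc = 3.5,
    copper = 0.08, manganese = 0.012, selenium = 20, cholesterol = 65
  )

  spec <- list(
    leafy_greens = list(
      source = "plant", macro = c(water = 91, protein = 2.6, carbohydrate = 4.3, fiber = 1.6, total_fat = 0.5),
      mult = c(folate = 2.5, vitamin_a = 8, vitamin_c = 1.3, calcium = 2.5, iron = 2,
               magnesium = 1.6, potassium = 1.5, sodium = 3, vitamin_e = 2),
      retention_scale = 1.35
    ),
    roots = list(
      source = "plant", macro = c(water = 88, protein = 1.5, carbohydrate = 8.8, fiber = 1.4, total_fat = 0.3),
      mult = c(vitamin_a = 3, vitamin_c = 0.8, folate = 0.5, potassium = 1.1, sodium = 1.5),
      retention_scale = 0.70
    ),
    vegetables = list(
      source = "plant", macro = c(water = 92, protein = 1.6, carbohydrate = 4.7, fiber = 1.4, total_fat = 0.3),
      mult = c(),
      retention_scale = 1.00
    ),
    legumes = list(
      # dry pulses boiled from the dry state, as in SR raw/cooked pairs
      source = "plant", macro = c(water = 20, protein = 21, carbohydrate = 46, fiber = 12, total_fat = 1.5),
      mult = c(thiamin = 8, folate = 6, iron = 7, magnesium = 4.5, phosphorus = 7,
               zinc = 7, potassium = 2.2, vitamin_c = 0.15, vitamin_a = 0.1),
      retention_scale = 0.85
    ),
    cereals = list(
      # dry grains boiled from the dry state; no vitamin A/C data
      source = "plant", macro = c(water = 11, protein = 12, carbohydrate = 72, fiber = 3.5, total_fat = 1.8),
      mult = c(thiamin = 5, niacin = 6, folate = 1, vitamin_c = 0, vitamin_a = 0,
               magnesium = 4, phosphorus = 6, iron = 3.5, potassium = 0.9, calcium = 0.6,
               selenium = 15, zinc = 5),
      retention_scale = 1.20
    ),
    beef = list(
      source = "animal", macro = c(water = 70.5, protein = 20.8, carbohydrate = 0.05, fiber = 0, total_fat = 8.5),
      mult = c(iron = 1.2, zinc = 1.3, cholesterol = 0.95),
      retention_scale = 0.80
    ),
    lamb = list(
      source = "animal", macro = c(water = 70, protein = 20.3, carbohydrate = 0.05, fiber = 0, total_fat = 9.5),
      mult = c(zinc = 1.1, selenium = 0.5),
      retention_scale = 1.00
    ),
    chicken = list(
      source = "animal", macro = c(water = 74, protein = 21.3, carbohydrate = 0.05, fiber = 0, total_fat = 4.2),
      mult = c(iron = 0.5, zinc = 0.4, vitamin_b6 = 1.3, niacin = 1.6, cholesterol = 1.15),
      retention_scale = 1.25
    ),
    veal = list(
      source = "animal", macro = c(water = 73.5, protein = 21, carbohydrate = 0.05, fiber = 0, total_fat = 4.8),
      mult = c(iron = 0.5, zinc = 0.9, vitamin_b6 = 1.1, cholesterol = 1.25),
      retention_scale = 1.10
    )
  )

  subfat_prop <- list(
    plant = c(saturated_fat = 0.18, monounsaturated_fat = 0.25, polyunsaturated_fat = 0.57),
    animal = c(saturated_fat = 0.42, monounsaturated_fat = 0.46, polyunsaturated_fat = 0.12)
  )

  rows <- purrr::imap(spec, function(s, name) {
    base <- if (s$source == "plant") plant_base else animal_base
    micro <- base
    micro[names(s$mult)] <- micro[names(s$mult)] * s$mult
    mean_vec <- stats::setNames(numeric(length(comps)), comps)
    mean_vec[names(s$macro)] <- s$macro
    # sub-fat fractions: 95% of total fat split into sat/mono/poly
    mean_vec[names(subfat_prop[[s$source]])] <-
      subfat_prop[[s$source]] * 0.95 * s$macro[["total_fat"]]
    mean_vec[names(micro)] <- micro
    cv_vec <- stats::setNames(rep(0.35, length(comps)), comps)
    cv_vec[mass_components()] <- 0.08
    cv_vec["water"] <- 0.03
    cv_vec[c("saturated_fat", "monounsaturated_fat", "polyunsaturated_fat")] <- 0.10
    cv_vec["cholesterol"] <- 0.15
    cv_vec[mean_vec == 0] <- 0
    tibble::tibble(
      name = name,
      source = s$source,
      process_class = if (s$source == "plant") "WH" else "DH",
      rf_group = s$source,
      retention_scale = s$retention_scale,
      profile_mean = list(mean_vec),
      profile_cv = list(cv_vec)
    )
  })
  dplyr::bind_rows(rows)
}

#' Default true retention fractions per (component, process class)
#'
#' Single-fraction retentions in (0, 1] emulating the magnitudes of published
#' retention-factor tables: wet heat (boiling/steaming of plant foods) loses
#' water-soluble vitamins and potassium/sodium to the cooking water; dry heat
#' (roasting/grilling of meats) loses mostly fat and water with milder
#' nutrient losses (retentions 0.8-1.0). Water has no retention entry: the
#' cooked water content is determined by the yield (mass closure).
#'
#' @return A tibble with columns `component`, `process_class`, `retention`.
#' @export
default_retentions <- function() {
  wh <- c(
    protein = 0.95, carbohydrate = 0.92, fiber = 0.95, total_fat = 1.00,
    saturated_fat = 1.00, monounsaturated_fat = 1.00, polyunsaturated_fat = 1.00,
    thiamin = 0.55, riboflavin = 0.75, niacin = 0.70, pantothenic_acid = 0.65,
    vitamin_b6 = 0.65, folate = 0.55, vitamin_c = 0.50, vitamin_a = 0.85,
    vitamin_e = 0.90, calcium = 0.95, iron = 0.90, magnesium = 0.85,
    phosphorus = 0.90, potassium = 0.70, sodium = 0.60, zinc = 0.95,
    copper = 0.85, manganese = 0.90, selenium = 0.90, cholesterol = 1.00
  )
  dh <- c(
    protein = 0.98, carbohydrate = 1.00, fiber = 1.00, total_fat = 0.85,
    saturated_fat = 0.85, monounsaturated_fat = 0.85, polyunsaturated_fat = 0.85,
    thiamin = 0.80, riboflavin = 0.95, niacin = 0.85, pantothenic_acid = 0.90,
    vitamin_b6 = 0.82, folate = 0.90, vitamin_c = 0.80, vitamin_a = 0.90,
    vitamin_e = 0.95, calcium = 0.98, iron = 0.97, magnesium = 0.96,
    phosphorus = 0.95, potassium = 0.90, sodium = 0.92, zinc = 0.98,
    copper = 0.95, manganese = 0.95, selenium = 0.95, cholesterol = 1.00
  )
  dplyr::bind_rows(
    tibble::tibble(component = names(wh), process_class = "WH", retention = unname(wh)),
    tibble::tibble(component = names(dh), process_class = "DH", retention = unname(dh))
  )
}

#' Default per-component measurement noise
#'
#' Relative measurement CVs reflecting the precision hierarchy of food
#' composition assays: gravimetric moisture is very precise (~1%),
#' proximate macronutrient analyses (Kjeldahl protein, carbohydrate by
#' difference, fiber) ~2%, total fat ~3%, and chromatographic /
#' spectrometric micronutrient, fatty-acid-fraction and cholesterol assays
#' ~5%.
#'
#' @return Named numeric vector over the component catalogue.
#' @export
default_noise_cv <- function() {
  comps <- component_catalogue()$component
  cv <- stats::setNames(rep(0.05, length(comps)), comps)
  cv["water"] <- 0.01
  cv[c("protein", "carbohydrate", "fiber")] <- 0.02
  cv["total_fat"] <- 0.03
  cv["cholesterol"] <- 0.03
  cv
}

#' Default per-component sampling mismatch
#'
#' Relative CVs of the biological mismatch between the sample analysed raw
#' and the sample that was cooked (composition tables rarely guarantee the
#' two came from the same specimen). Fat content differs most between
#' specimens (trim and marbling), so total fat carries the largest
#' mismatch, shared by its sub-fractions; micronutrients vary moderately;
#' water and membrane-bound cholesterol track the tissue closely.
#'
#' @return Named numeric vector over the component catalogue.
#' @export
default_mismatch_cv <- function() {
  comps <- component_catalogue()$component
  cv <- stats::setNames(rep(0.06, length(comps)), comps)
  cv["water"] <- 0.02
  cv[c("protein", "carbohydrate", "fiber")] <- 0.04
  cv[c("total_fat", "saturated_fat", "monounsaturated_fat", "polyunsaturated_fat")] <- 0.12
  cv["cholesterol"] <- 0.03
  cv
}

#' Build a synthetic-generator configuration
#'
#' Bundles the settings of the synthetic world: category specifications,
#' true retentions, yield distributions (uniform support per process class,
#' in grams of cooked food per 100 g raw; above 100 for wet heat because of
#' water gain, below 100 for dry heat because of water/fat loss), the
#' process-invariant component used by PINS, and the noise model.
#'
#' @param categories Category specification tibble (see [default_categories()]).
#' @param retention Base retention tibble (see [default_retentions()]).
#' @param yield_range Named list of length-2 numeric ranges per process
#'   class; a degenerate range (min == max) yields a constant.
#' @param invariant_component Component assumed process-invariant
#'   (default cholesterol).
#' @param invariant_retention True retention of the invariant component
#'   (default 1; set 0.95 to emulate a small experimental loss).
#' @param noise_cv Relative measurement noise applied multiplicatively to
#'   every reported amount of both the raw and the cooked profile; a
#'   scalar, or a named per-component vector (see [default_noise_cv()]).
#'   A scalar is applied to every component uniformly.
#' @param mismatch_cv Relative biological mismatch between the analysed raw
#'   sample and the sample that was cooked (0 = same sample); scalar or
#'   named per-component vector (see [default_mismatch_cv()]). The fat
#'   sub-fractions always share total fat's per-pair mismatch factor.
#' @param components Component subset to simulate (must contain the mass
#'   components and the invariant component); defaults to the full catalogue.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(categories = default_categories(),
                             retention = default_retentions(),
                             yield_range = list(WH = c(105, 135), DH = c(60, 95)),
                             invariant_component = "cholesterol",
                             invariant_retention = 1.0,
                             noise_cv = default_noise_cv(),
                             mismatch_cv = default_mismatch_cv(),
                             components = component_catalogue()$component) {
  structure(
    list(
      categories = categories, retention = retention, yield_range = yield_range,
      invariant_component = invariant_component,
      invariant_retention = invariant_retention,
      noise_cv = noise_cv, mismatch_cv = mismatch_cv, components = components
    ),
    class = "synthetic_config"
  )
}

#' Materialize a synthetic world from a configuration and a seed
#'
#' Validates the configuration and resolves per-category retentions: each
#' category's loss is the base loss multiplied by its `retention_scale`
#' (clipped into (0, 1]), except for the invariant component whose retention
#' is fixed at `invariant_retention` everywhere. Re-calling with the same
#' configuration and seed returns an identical world, and all downstream
#' sampling is driven by the stored seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed stored in the world.
#' @return A list of class `synthetic_world`.
#' @export
generate_world <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  comps <- config$components
  known <- component_catalogue()$component
  bad <- setdiff(comps, known)
  if (length(bad) > 0) stop("unknown component(s) in config: ", paste(bad, collapse = ", "))
  need <- c(mass_components(), config$invariant_component)
  if (!all(need %in% comps)) {
    stop("components must include the mass components and the invariant component")
  }

  ret <- config$retention
  bad <- setdiff(ret$component, known)
  if (length(bad) > 0) stop("unknown component(s) in retention map: ", paste(bad, collapse = ", "))
  if (any(ret$retention <= 0 | ret$retention > 1)) {
    off <- ret[ret$retention <= 0 | ret$retention > 1, ]
    stop(
      "retention fractions must lie in (0, 1]; offending: ",
      paste(sprintf("%s/%s=%g", off$component, off$process_class, off$retention), collapse = ", ")
    )
  }
  if (!(config$invariant_retention > 0 && config$invariant_retention <= 1)) {
    stop("invariant_retention must lie in (0, 1]")
  }
  for (pc in names(config$yield_range)) {
    yr <- config$yield_range[[pc]]
    if (length(yr) != 2 || any(!is.finite(yr)) || any(yr <= 0) || yr[1] > yr[2]) {
      stop("yield support for ", pc, " must be a positive ordered range")
    }
  }
  cats <- config$categories
  if (nrow(cats) < 1) stop("config must name at least one category")
  missing_yield <- setdiff(unique(cats$process_class), names(config$yield_range))
  if (length(missing_yield) > 0) {
    stop("no yield support for process class(es): ", paste(missing_yield, collapse = ", "))
  }

  # per-(category, component) realized true retentions
  non_water <- setdiff(comps, "water")
  cat_ret <- purrr::pmap(
    list(cats$name, cats$process_class, cats$retention_scale),
    function(name, pc, scale) {
      base <- ret$retention[match(paste(non_water, pc), paste(ret$component, ret$process_class))]
      if (anyNA(base)) {
        stop(
          "retention map is missing entries for: ",
          paste(non_water[is.na(base)], "/", pc, collapse = ", ")
        )
      }
      r <- 1 - scale * (1 - base)
      r <- pmin(pmax(r, 0.02), 1)
      r[non_water == config$invariant_component] <- config$invariant_retention
      tibble::tibble(category = name, component = non_water, retention = r)
    }
  )

  structure(
    list(
      categories = cats,
      components = comps,
      retention = dplyr::bind_rows(cat_ret),
      yield_range = config$yield_range,
      invariant_component = config$invariant_component,
      invariant_retention = config$invariant_retention,
      noise_cv = expand_cv(config$noise_cv, comps, "noise_cv"),
      mismatch_cv = expand_cv(config$mismatch_cv, comps, "mismatch_cv"),
      seed = as.integer(seed)
    ),
    class = "synthetic_world"
  )
}

# recycle a scalar CV or subset a named per-component CV vector
expand_cv <- function(cv, comps, what) {
  if (any(cv < 0)) stop(what, " must be non-negative")
  if (length(cv) == 1 && is.null(names(cv))) {
    return(stats::setNames(rep(cv, length(comps)), comps))
  }
  missing <- setdiff(comps, names(cv))
  if (length(missing) > 0) {
    stop(what, " is missing entries for: ", paste(missing, collapse = ", "))
  }
  cv[comps]
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(
    "<synthetic_world>", nrow(x$categories), "categories,",
    length(x$components), "components, seed", x$seed, "\n"
  )
  invisible(x)
}
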