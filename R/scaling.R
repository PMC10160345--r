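#' Solid-content scaling (SCS) of the raw profile
#'
#' Corrects the per-100 g yield bias by equalizing, in order, each component
#' in `equalize` (by default water, then total fat) between the raw and
#' cooked profiles: the raw amount of the equalized component is set to the
#' cooked amount, and the mass difference is redistributed proportionally
#' over all components not yet equalized. The redistribution factor for pass
#' `e` is `1 + (R[e] - C[e]) / sum(R[X])`, where the gram-basis sum runs over
#' the mass-bearing components that are neither already equalized nor `e`
#' itself; micronutrients and fat sub-fractions receive the same factor but
#' do not enter the denominator (their mass is negligible, and excluding
#' them keeps the conservation identity exact). Once equalized, a component
#' is frozen: it is neither rescaled nor counted in later denominators,
#' which makes the result independent of the equalization order and
#' conserves the gram total of the mass-bearing components exactly.
#'
#' @param pair A paired dataset (any number of rows; each row is one pair).
#'   The raw side is replaced by the scaled profile R'.
#' @param equalize Ordered component names to equalize (must be
#'   mass-bearing and present in both profiles).
#' @return The dataset with the raw side replaced by R' and variant label
#'   `"SCS"`.
#' @export
scs_scale <- function(pair, equalize = c("water", "total_fat")) {
  comps <- dataset_components(pair)
  if (identical(dataset_variant(pair), "SCS")) {
    warning("dataset is already SCS-scaled; re-applying is a no-op by construction")
  }
  missing <- setdiff(equalize, comps)
  if (length(missing) > 0) stop("equalize component(s) not present: ", paste(missing, collapse = ", "))
  if (!all(equalize %in% mass_components())) {
    stop("equalize components must be mass-bearing (gram-unit) components")
  }
  raw <- side_matrix(pair, "raw", comps)
  cooked <- side_matrix(pair, "cooked", comps)
  if (any(!is.finite(cooked[, equalize]))) stop("cooked amounts for equalized components must be finite")

  g_fac <- stats::setNames(grams_factor(comps), comps)
  done <- character(0)
  for (e in equalize) {
    denom_comps <- setdiff(mass_components(), c(done, e))
    denom_comps <- intersect(denom_comps, comps)
    denom <- as.vector(raw[, denom_comps, drop = FALSE] %*% g_fac[denom_comps])
    if (any(denom == 0)) {
      stop("zero gram-basis denominator while equalizing ", e, " for pair(s): ",
           paste(utils::head(pair$pair_id[denom == 0], 5), collapse = ", "))
    }
    factor <- 1 + (raw[, e] - cooked[, e]) * g_fac[e] / denom
    scale_comps <- setdiff(comps, c(done, e))
    raw[, scale_comps] <- raw[, scale_comps, drop = FALSE] * factor
    raw[, e] <- cooked[, e]
    done <- c(done, e)
  }
  set_variant(set_side_matrix(pair, "raw", raw), "SCS")
}

#' Process-invariant nutrient scaling (PINS) of the cooked profile
#'
#' Estimates the unknown cooking yield from a component assumed invariant to
#' processing (cholesterol by default): the scaling factor is
#' `assumed_retention * R[invariant] / C[invariant]`, and every cooked
#' amount is multiplied by it, which re-expresses the cooked profile on the
#' basis of the 100 g raw sample. The implied yield estimate is
#' `100 * scaling_factor` grams of cooked food per 100 g raw. Pairs in which
#' the invariant component is missing, zero or non-finite on either side are
#' excluded and reported via the `"excluded"` attribute.
#'
#' @param pair A paired dataset; the cooked side is replaced by C'.
#' @param invariant Invariant component name (default `"cholesterol"`).
#' @param assumed_retention Retention assumed for the invariant component
#'   (1 by default; 0.95 emulates a 5% loss, labelling the variant
#'   `"PINS-<invariant>-loss5"`).
#' @return The dataset (possibly with rows dropped) with the cooked side
#'   replaced by C', extra columns `scaling_factor` and `yield_estimate`,
#'   variant label `"PINS-<invariant>"`, and attribute `"excluded"` (tibble
#'   `pair_id`, `reason`).
#' @export
pins_scale <- function(pair, invariant = "cholesterol", assumed_retention = 1.0) {
  comps <- dataset_components(pair)
  if (!invariant %in% comps) stop("invariant component not present: ", invariant)
  if (!(assumed_retention > 0 && assumed_retention <= 1)) {
    stop("assumed_retention must lie in (0, 1]")
  }
  if (startsWith(dataset_variant(pair), "PINS")) {
    warning("dataset is already PINS-scaled; applying PINS twice compounds the factor")
  }
  r_inv <- pair[[paste0("raw_", invariant)]]
  c_inv <- pair[[paste0("cooked_", invariant)]]
  ok <- is.finite(r_inv) & is.finite(c_inv) & r_inv > 0 & c_inv > 0
  excluded <- tibble::tibble(
    pair_id = pair$pair_id[!ok],
    reason = ifelse(!is.finite(r_inv[!ok]) | r_inv[!ok] <= 0,
                    paste0("raw ", invariant, " missing or <= 0"),
                    paste0("cooked ", invariant, " missing or <= 0"))
  )
  out <- pair[ok, , drop = FALSE]
  sf <- assumed_retention * r_inv[ok] / c_inv[ok]
  cooked <- side_matrix(out, "cooked", comps) * sf
  out <- set_side_matrix(out, "cooked", cooked)
  out$scaling_factor <- sf
  out$yield_estimate <- 100 * sf
  label <- paste0("PINS-", invariant, if (assumed_retention != 1) "-loss5" else "")
  out <- set_variant(out, label)
  attr(out, "excluded") <- excluded
  out
}

#' Build a scaled dataset variant
#'
#' Convenience dispatcher over [scs_scale()] and [pins_scale()].
#'
#' @param dataset A paired dataset.
#' @param variant `"unscaled"`, `"scs"`, or `"pins"`.
#' @param invariant,assumed_retention Passed to [pins_scale()].
#' @return The scaled dataset with its variant label set.
#' @export
scale_dataset <- function(dataset, variant = c("unscaled", "scs", "pins"),
                          invariant = "cholesterol", assumed_retention = 1.0) {
  variant <- match.arg(variant)
  switch(variant,
    unscaled = set_variant(dataset, "unscaled"),
    scs = scs_scale(dataset),
    pins = pins_scale(dataset, invariant = invariant, assumed_retention = assumed_retention)
  )
}

#' Detect the cooked-exceeds-raw anomaly for one nutrient
#'
#' A pair is anomalous for a nutrient when the cooked amount is strictly
#' greater than the raw amount on the variant's (scaled) values; ties count
#' as non-anomalous, so noise-free identity pairs are retained by the
#' filter.
#'
#' @param pair A paired dataset (scaled or not).
#' @param nutrient Component name.
#' @return Logical vector, one element per pair.
#' @export
detect_anomaly <- function(pair, nutrient) {
  rcol <- paste0("raw_", nutrient)
  ccol <- paste0("cooked_", nutrient)
  if (!all(c(rcol, ccol) %in% names(pair))) stop("nutrient not present in both profiles: ", nutrient)
  pair[[ccol]] > pair[[rcol]]
}

#' Filter a dataset variant to non-anomalous pairs for one nutrient
#'
#' Scaled variants keep only the pairs in which the nutrient is at least as
#' high in the raw as in the cooked profile; the unscaled variant is
#' returned unchanged (it is deliberately not filtered). Filtering is
#' per-nutrient, so the models for different nutrients see different
#' subsets.
#'
#' @param dataset A paired dataset with a variant label.
#' @param nutrient Component name.
#' @return The (possibly) filtered dataset.
#' @export
filter_pairs <- function(dataset, nutrient) {
  if (identical(dataset_variant(dataset), "unscaled")) {
    return(dataset)
  }
  keep <- !detect_anomaly(dataset, nutrient)
  if (!any(keep)) warning("all pairs are anomalous for ", nutrient, "; returning empty dataset")
  dataset[keep, , drop = FALSE]
}

#' Summarise anomaly prevalence per nutrient
#'
#' Computes, for each nutrient, the number of pairs, the number of
#' non-anomalous pairs (cooked <= raw on the variant's values) and their
#' fraction, split by food source, plus pooled rows (`source = "all"`) and
#' the across-nutrient mean as attribute `"overall"`.
#'
#' @param dataset A paired dataset.
#' @param nutrients Nutrients to summarise (default the 14 micronutrients
#'   present in the dataset).
#' @return A tibble with columns `variant`, `source`, `nutrient`, `n_pairs`,
#'   `n_non_anomalous`, `fraction_non_anomalous`.
#' @export
anomaly_summary <- function(dataset, nutrients = intersect(micronutrients(), dataset_components(dataset))) {
  src <- if ("source" %in% names(dataset)) dataset$source else rep("all", nrow(dataset))
  per <- purrr::map(nutrients, function(n) {
    anom <- detect_anomaly(dataset, n)
    by_src <- tibble::tibble(source = src, anom = anom) |>
      dplyr::group_by(.data$source) |>
      dplyr::summarise(
        n_pairs = dplyr::n(),
        n_non_anomalous = sum(!.data$anom),
        .groups = "drop"
      )
    pooled <- tibble::tibble(
      source = "all", n_pairs = length(anom), n_non_anomalous = sum(!anom)
    )
    dplyr::bind_rows(by_src, pooled) |>
      dplyr::mutate(nutrient = n, .before = 1)
  })
  out <- dplyr::bind_rows(per) |>
    dplyr::mutate(
      variant = dataset_variant(dataset),
      fraction_non_anomalous = .data$n_non_anomalous / .data$n_pairs,
      .before = 1
    ) |>
    dplyr::relocate("variant", "source", "nutrient")
  attr(out, "overall") <- out |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction_non_anomalous), .groups = "drop")
  out
}

#' Test whether two variants differ in non-anomalous prevalence
#'
#' Pools non-anomalous counts over nutrients within each summary and runs a
#' two-proportion test (chi-squared z-test, or Fisher's exact test when any
#' expected cell count is small).
#'
#' @param a,b [anomaly_summary()] results over the same pair universe
#'   (pooled `source = "all"` rows are used; restrict with `source`).
#' @param source Source stratum to compare (default `"all"`).
#' @return A list with elements `statistic`, `p_value`, `fraction_a`,
#'   `fraction_b`, and `method`.
#' @export
compare_anomaly_fractions <- function(a, b, source = "all") {
  pick <- function(s) {
    s <- s[s$source == source, , drop = FALSE]
    if (nrow(s) == 0) stop("empty anomaly summary for source ", source)
    c(non = sum(s$n_non_anomalous), n = sum(s$n_pairs))
  }
  ca <- pick(a)
  cb <- pick(b)
  if (identical(unname(ca), unname(cb))) {
    return(list(statistic = 0, p_value = 1, fraction_a = ca[["non"]] / ca[["n"]],
                fraction_b = cb[["non"]] / cb[["n"]], method = "identical counts"))
  }
  tab <- matrix(c(ca[["non"]], ca[["n"]] - ca[["non"]],
                  cb[["non"]], cb[["n"]] - cb[["non"]]), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(statistic = unname(ft$estimate), p_value = ft$p.value,
         fraction_a = ca[["non"]] / ca[["n"]], fraction_b = cb[["non"]] / cb[["n"]],
         method = "Fisher exact")
  } else {
    pt <- stats::prop.test(tab, correct = FALSE)
    list(statistic = unname(pt$statistic), p_value = pt$p.value,
         fraction_a = ca[["non"]] / ca[["n"]], fraction_b = cb[["non"]] / cb[["n"]],
         method = "two-proportion z-test")
  }
}
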