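#' Generate raw/cooked composition pairs with known ground truth
#'
#' Draws, for each category of the world, `n_per_category` raw composition
#' profiles (mass components on the 100 g simplex, micronutrients
#' log-normal), applies the cooking transformation with a per-pair true
#' yield Y (g cooked per 100 g raw) and the world's true retentions, and
#' renormalizes the retained masses to the per-100 g cooked representation.
#' The cooked water content closes the mass balance: it equals Y minus the
#' grams of retained solids, so the cooked profile sums to 100 g exactly
#' before noise. Optional sampling mismatch perturbs the profile that is
#' cooked relative to the profile that is reported raw; measurement noise is
#' applied multiplicatively to all reported amounts.
#'
#' With `noise_cv = 0` and `mismatch_cv = 0` the closed-form mass balance
#' holds exactly: `cooked[n] = r(n) * raw[n] * 100 / Y` for every non-water
#' component.
#'
#' @param world A [generate_world()] result.
#' @param n_per_category Number of pairs per category (scalar, or named
#'   vector keyed by category).
#' @return A list of class `synthetic_pairs` with elements `dataset` (a
#'   paired dataset), and `truth` (list: `yields` tibble `pair_id`, `yield`;
#'   `retention` long tibble of realized per-pair per-component retentions;
#'   `cooked_true` tibble of noise-free cooked per-100 g profiles).
#' @export
generate_pairs <- function(world, n_per_category) {
  stopifnot(inherits(world, "synthetic_world"))
  if (any(n_per_category < 1)) stop("n_per_category must be >= 1")

  comps <- world$components
  non_water <- setdiff(comps, "water")
  g_fac <- stats::setNames(grams_factor(comps), comps)
  solid_mass <- setdiff(mass_components(), "water")

  withr::with_seed(world$seed, {
    out <- purrr::pmap(
      list(
        world$categories$name, world$categories$source,
        world$categories$process_class,
        world$categories$profile_mean, world$categories$profile_cv,
        seq_len(nrow(world$categories))
      ),
      function(cat_name, source, pc, mu, cv, cat_idx) {
        n <- if (length(n_per_category) == 1) n_per_category else n_per_category[[cat_name]]
        mu <- mu[comps]
        cv <- cv[comps]
        raw <- draw_lognormal_matrix(n, mu, cv)
        # closure: mass components renormalized to sum exactly 100 g,
        # fat sub-fractions follow total fat
        msum <- rowSums(raw[, mass_components(), drop = FALSE])
        scale <- 100 / msum
        fat0 <- raw[, "total_fat"]
        raw[, mass_components()] <- raw[, mass_components(), drop = FALSE] * scale
        subfat <- intersect(c("saturated_fat", "monounsaturated_fat", "polyunsaturated_fat"), comps)
        if (length(subfat) > 0) {
          sf_scale <- ifelse(fat0 > 0, raw[, "total_fat"] / fat0, 0)
          raw[, subfat] <- raw[, subfat, drop = FALSE] * sf_scale
        }

        rmap <- world$retention[world$retention$category == cat_name, ]
        r <- stats::setNames(rmap$retention, rmap$component)[non_water]

        # biological mismatch: the sample that was cooked differs from the
        # sample analysed raw by a per-component log-normal factor
        ones <- stats::setNames(rep(1, length(comps)), comps)
        mis <- draw_lognormal_matrix(n, ones, world$mismatch_cv)
        # the same specimen-level fat factor drives all fat sub-fractions
        for (sf in intersect(c("saturated_fat", "monounsaturated_fat",
                               "polyunsaturated_fat"), comps)) {
          mis[, sf] <- mis[, "total_fat"]
        }
        precook <- raw * mis

        yr <- world$yield_range[[pc]]
        yield <- stats::runif(n, yr[1], yr[2])

        retained <- sweep(precook[, non_water, drop = FALSE], 2, r[non_water], `*`)
        solids_g <- as.vector(
          retained[, solid_mass, drop = FALSE] %*% g_fac[solid_mass]
        )
        water_g <- yield - solids_g
        if (any(water_g <= 0)) {
          stop("yield too small to cover retained solids in category ", cat_name)
        }
        cooked_true <- cbind(water = water_g, retained)[, comps, drop = FALSE]
        cooked_true <- cooked_true * (100 / yield)

        noise_r <- draw_lognormal_matrix(n, ones, world$noise_cv)
        noise_c <- draw_lognormal_matrix(n, ones, world$noise_cv)
        raw_rep <- raw * noise_r
        cooked_rep <- cooked_true * noise_c

        pair_id <- sprintf("%s_%03d", cat_name, seq_len(n))
        meta <- tibble::tibble(
          pair_id = pair_id, process_class = pc, category = cat_name,
          source = source, rf_group = world$categories$rf_group[cat_idx]
        )
        raw_df <- tibble::as_tibble(raw_rep)
        names(raw_df) <- paste0("raw_", comps)
        cooked_df <- tibble::as_tibble(cooked_rep)
        names(cooked_df) <- paste0("cooked_", comps)

        realized <- sweep(mis[, non_water, drop = FALSE], 2, r[non_water], `*`)
        truth_ret <- tibble::tibble(
          pair_id = rep(pair_id, times = length(non_water)),
          component = rep(non_water, each = n),
          retention = as.vector(realized)
        )
        ct <- tibble::as_tibble(cooked_true)
        names(ct) <- comps
        list(
          dataset = dplyr::bind_cols(meta, raw_df, cooked_df),
          yields = tibble::tibble(pair_id = pair_id, yield = yield),
          retention = truth_ret,
          cooked_true = dplyr::bind_cols(tibble::tibble(pair_id = pair_id), ct)
        )
      }
    )
  })

  dataset <- new_paired_dataset(
    dplyr::bind_rows(purrr::map(out, "dataset")), comps, variant = "unscaled"
  )
  structure(
    list(
      dataset = dataset,
      truth = list(
        yields = dplyr::bind_rows(purrr::map(out, "yields")),
        retention = dplyr::bind_rows(purrr::map(out, "retention")),
        cooked_true = dplyr::bind_rows(purrr::map(out, "cooked_true"))
      ),
      world = world
    ),
    class = "synthetic_pairs"
  )
}

# n draws per component around mean mu with coefficient of variation cv
# (log-normal, mean-preserving); zero mean or zero cv degenerate cleanly
draw_lognormal_matrix <- function(n, mu, cv) {
  p <- length(mu)
  m <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, names(mu)))
  for (j in seq_len(p)) {
    if (mu[j] == 0) {
      m[, j] <- 0
    } else if (cv[j] == 0) {
      m[, j] <- mu[j]
    } else {
      s <- sqrt(log(1 + cv[j]^2))
      m[, j] <- stats::rlnorm(n, meanlog = log(mu[j]) - s^2 / 2, sdlog = s)
    }
  }
  m
}

#' Build a retention-factor table from realized synthetic retentions
#'
#' The table entry for (group, process, nutrient) is the arithmetic mean of
#' the realized per-pair retentions within the group, so the table is
#' deliberately coarser than the per-food truth, exactly as real
#' retention-factor tables are representative averages over several foods.
#'
#' @param world The world the pairs were generated from.
#' @param pairs A [generate_pairs()] result (its ground truth supplies the
#'   realized retentions).
#' @param group_by Grouping column: `"category"` (finest), `"rf_group"`, or
#'   `"source"` (coarsest, one group per plant/animal source).
#' @return A tibble with columns `group`, `process`, `nutrient`, `rf` — the
#'   layout read back by [read_retention_table()].
#' @export
generate_retention_table <- function(world, pairs,
                                     group_by = c("category", "rf_group", "source")) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(pairs, "synthetic_pairs"))
  ds <- pairs$dataset
  if (nrow(ds) == 0) stop("empty group: pairs dataset has no rows")
  meta <- tibble::tibble(
    pair_id = ds$pair_id, group = ds[[group_by]], process = ds$process_class
  )
  dplyr::left_join(pairs$truth$retention, meta, by = "pair_id") |>
    dplyr::group_by(.data$group, .data$process, nutrient = .data$component) |>
    dplyr::summarise(rf = mean(.data$retention), .groups = "drop")
}

#' Write a synthetic experiment to CSV files
#'
#' Writes `pairs.csv` (tidy pairs layout), `ground_truth.csv` (per pair:
#' yield, then realized per-component retentions in wide form) and
#' `retention_table.csv` (group, process, nutrient, rf).
#'
#' @param pairs A [generate_pairs()] result.
#' @param dir Output directory (created if needed).
#' @param group_by Grouping for the retention table.
#' @return The directory, invisibly.
#' @export
write_synthetic_csv <- function(pairs, dir, group_by = "category") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs_csv(pairs$dataset, file.path(dir, "pairs.csv"))
  truth_wide <- pairs$truth$retention |>
    tidyr::pivot_wider(names_from = "component", values_from = "retention",
                       names_prefix = "retention_") |>
    dplyr::left_join(pairs$truth$yields, by = "pair_id") |>
    dplyr::relocate("yield", .after = "pair_id")
  readr::write_csv(truth_wide, file.path(dir, "ground_truth.csv"))
  readr::write_csv(
    generate_retention_table(pairs$world, pairs, group_by = group_by),
    file.path(dir, "retention_table.csv")
  )
  invisible(dir)
}
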