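# Shared fixtures: reduced synthetic worlds and hand-built pair datasets.

reduced_components <- function() {
  c("water", "protein", "carbohydrate", "fiber", "total_fat",
    "thiamin", "iron", "potassium", "cholesterol")
}

test_world <- function(seed = 1, noise_cv = 0, mismatch_cv = 0,
                       categories = c("vegetables", "beef"),
                       components = reduced_components(),
                       yield_range = list(WH = c(105, 135), DH = c(60, 95)),
                       invariant_retention = 1.0) {
  cats <- default_categories()
  cats <- cats[cats$name %in% categories, , drop = FALSE]
  generate_world(
    synthetic_config(
      categories = cats, yield_range = yield_range,
      noise_cv = noise_cv, mismatch_cv = mismatch_cv,
      invariant_retention = invariant_retention, components = components
    ),
    seed = seed
  )
}

# one-row (or multi-row) dataset from explicit named amount vectors
make_pairs <- function(raw, cooked, process_class = "DH", category = "beef",
                       source = "animal") {
  if (!is.data.frame(raw)) raw <- as.data.frame(as.list(raw))
  if (!is.data.frame(cooked)) cooked <- as.data.frame(as.list(cooked))
  comps <- names(raw)
  names(raw) <- paste0("raw_", comps)
  names(cooked) <- paste0("cooked_", comps)
  df <- dplyr::bind_cols(
    tibble::tibble(
      pair_id = sprintf("p%02d", seq_len(nrow(raw))),
      process_class = process_class, category = category, source = source,
      rf_group = source
    ),
    raw, cooked
  )
  paired_dataset(df, components = comps)
}
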