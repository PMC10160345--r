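# In-code SR-Legacy-style fixture: three foods x five nutrients.
write_sr_fixture <- function(dir,
                             foods = NULL, nutrients = NULL, amounts = NULL) {
  if (is.null(foods)) {
    foods <- tibble::tibble(
      fdc_id = c(101, 102, 103),
      description = c("Broccoli, raw", "Broccoli, cooked, boiled, drained, without salt",
                      "Beef, top round, separable lean only, raw"),
      food_category = c("Vegetables and Vegetable Products",
                        "Vegetables and Vegetable Products", "Beef Products")
    )
  }
  if (is.null(nutrients)) {
    nutrients <- tibble::tibble(
      id = 1:5,
      name = c("Water", "Protein", "Iron, Fe", "Potassium, K", "Vitamin C, total ascorbic acid"),
      unit_name = c("G", "G", "MG", "MG", "MG")
    )
  }
  if (is.null(amounts)) {
    amounts <- tidyr::expand_grid(fdc_id = foods$fdc_id, nutrient_id = nutrients$id) |>
      dplyr::mutate(amount = dplyr::row_number() / 10)
  }
  paths <- list(
    food = file.path(dir, "food.csv"),
    nutrient = file.path(dir, "nutrient.csv"),
    amount = file.path(dir, "food_nutrient.csv")
  )
  readr::write_csv(foods, paths$food)
  readr::write_csv(nutrients, paths$nutrient)
  readr::write_csv(amounts, paths$amount)
  paths
}

test_that("SR tables round-trip into classified records with unit-tagged amounts", {
  dir <- withr::local_tempdir()
  p <- write_sr_fixture(dir)
  rec <- read_sr_legacy(p$food, p$nutrient, p$amount)
  expect_s3_class(rec$foods, "tbl_df")
  expect_equal(nrow(rec$foods), 3)
  expect_equal(nrow(rec$amounts), 15)  # 3 foods x 5 nutrients
  expect_setequal(unique(rec$amounts$component),
                  c("water", "protein", "iron", "potassium", "vitamin_c"))
  expect_equal(unique(rec$amounts$unit[rec$amounts$component == "iron"]), "mg")
  expect_equal(rec$foods$state, c("raw", "cooked", "raw"))

  # a food with no amount rows is kept with an empty profile
  foods4 <- dplyr::bind_rows(
    readr::read_csv(p$food, show_col_types = FALSE),
    tibble::tibble(fdc_id = 104, description = "Spinach, raw",
                   food_category = "Vegetables and Vegetable Products")
  )
  readr::write_csv(foods4, p$food)
  rec4 <- read_sr_legacy(p$food, p$nutrient, p$amount)
  expect_equal(nrow(rec4$foods), 4)
  expect_false(104 %in% rec4$amounts$fdc_id)
})

test_that("referential and duplication errors are raised with offending ids", {
  dir <- withr::local_tempdir()
  p <- write_sr_fixture(dir)
  am <- readr::read_csv(p$amount, show_col_types = FALSE)
  readr::write_csv(dplyr::add_row(am, fdc_id = 999, nutrient_id = 1, amount = 5), p$amount)
  expect_error(read_sr_legacy(p$food, p$nutrient, p$amount), "unknown food id.*999")

  readr::write_csv(dplyr::add_row(am, fdc_id = 101, nutrient_id = 1, amount = 42), p$amount)
  expect_error(read_sr_legacy(p$food, p$nutrient, p$amount), "conflicting duplicate.*101")

  # identical duplicates are deduplicated silently
  readr::write_csv(dplyr::bind_rows(am, am[1, ]), p$amount)
  expect_equal(nrow(read_sr_legacy(p$food, p$nutrient, p$amount)$amounts), 15)

  readr::write_csv(am[, c("fdc_id", "amount")], p$amount)
  expect_error(read_sr_legacy(p$food, p$nutrient, p$amount), "missing column")
})

test_that("descriptions classify by keyword rules", {
  cls <- classify_food(c(
    "Luncheon meat, pork and chicken, minced, canned, includes SPAM Lite",
    "Broccoli, raw",
    "Beef, round, top round, separable lean only, trimmed to 0\" fat, broiled",
    "Cereal, oats, instant"
  ))
  expect_false(cls$single_ingredient[1])
  expect_equal(cls$state[2], "raw")
  expect_equal(cls$process[2], "none")
  expect_true(cls$single_ingredient[2])
  expect_equal(cls$state[3], "cooked")
  expect_equal(cls$process[3], "broil")
  expect_equal(cls$state[4], "other")
  expect_error(classify_food(""), "empty description")
})

test_that("pairing matches base descriptions, fans out processes, and partitions input", {
  foods <- tibble::tibble(
    fdc_id = 1:7,
    description = c(
      "Spinach, raw",
      "Spinach, cooked, boiled, drained, without salt",
      "Beef, top round, raw",
      "Beef, top round, broiled",
      "Beef, top round, roasted",
      "Carrots, raw",
      "Bread, banana, prepared from recipe"
    ),
    category = "x"
  )
  foods <- dplyr::bind_cols(foods, classify_food(foods$description))
  foods$source_type <- "unknown"
  res <- pair_foods(foods)

  expect_equal(nrow(res$pairs), 3)  # one raw may anchor several cooked forms
  expect_setequal(res$pairs$process_class[res$pairs$raw_fdc_id == 3], c("DH", "DH"))
  expect_equal(res$pairs$process_class[res$pairs$raw_fdc_id == 1], "WH")
  expect_equal(res$unmatched$reason[res$unmatched$fdc_id == 6], "no cooked counterpart")
  expect_equal(nrow(res$excluded), 1)  # the recipe bread

  # partition: every record lands in exactly one report
  paired_ids <- unique(c(res$pairs$raw_fdc_id, res$pairs$cooked_fdc_id))
  all_ids <- sort(c(paired_ids, res$unmatched$fdc_id, res$excluded$fdc_id))
  expect_equal(all_ids, foods$fdc_id)

  # order-independence: shuffling input yields the same pair set
  set.seed(9)
  res2 <- pair_foods(foods[sample.int(nrow(foods)), ])
  expect_equal(res2$pairs, res$pairs)

  # a lone raw food yields no pairs, one unmatched report
  lone <- foods[foods$fdc_id == 6, ]
  res3 <- pair_foods(lone)
  expect_equal(nrow(res3$pairs), 0)
  expect_equal(res3$unmatched$reason, "no cooked counterpart")

  # ambiguity: two raw foods with the same base are reported, not paired
  amb <- tibble::tibble(
    fdc_id = 11:13,
    description = c("Kale, raw", "Kale, fresh, raw", "Kale, cooked, boiled"),
    category = "x"
  )
  amb <- dplyr::bind_cols(amb, classify_food(amb$description))
  res4 <- pair_foods(amb)
  expect_equal(nrow(res4$pairs), 0)
  expect_true(all(grepl("ambiguous", res4$unmatched$reason)))
})

test_that("component selection honors the coverage boundary and is monotone", {
  dir <- withr::local_tempdir()
  foods <- tibble::tibble(
    fdc_id = 1:5, description = paste0("Food ", 1:5, ", raw"), food_category = "x"
  )
  nutrients <- tibble::tibble(
    id = 1:3, name = c("Iron, Fe", "Protein", "Zinc, Zn"), unit_name = c("MG", "G", "MG")
  )
  amounts <- dplyr::bind_rows(
    tibble::tibble(fdc_id = 1:4, nutrient_id = 1, amount = c(0, 1, 2, 3)),  # 4/5, incl. a zero
    tibble::tibble(fdc_id = 1:5, nutrient_id = 2, amount = 1),              # 5/5
    tibble::tibble(fdc_id = 1:3, nutrient_id = 3, amount = 1)               # 3/5
  )
  p <- write_sr_fixture(dir, foods, nutrients, amounts)
  rec <- read_sr_legacy(p$food, p$nutrient, p$amount)
  sel <- select_components(rec, coverage = 0.8)
  expect_setequal(sel, c("protein", "iron"))      # 0.8 boundary inclusive; zinc dropped
  expect_equal(sel[1], "protein")                 # catalogue order is stable
  expect_error(select_components(rec, coverage = 0), "coverage")
  expect_error(select_components(rec, coverage = 1.2), "coverage")

  # monotone: raising coverage never adds components
  covs <- c(0.2, 0.4, 0.6, 0.8, 1)
  sets <- lapply(covs, function(cv) select_components(rec, cv))
  for (i in seq_along(sets)[-1]) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("retention tables read fractions, percent flags, and reject bad input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rf.csv")
  readr::write_csv(tibble::tibble(
    group = "Vegetables", process = "boil", nutrient = "vitamin_c", rf = 0.55
  ), path)
  tab <- read_retention_table(path)
  expect_equal(tab$rf, 0.55)

  readr::write_csv(tibble::tibble(
    group = "Vegetables", process = "boil", nutrient = "vitamin_c", rf_percent = 55
  ), path)
  expect_equal(read_retention_table(path)$rf, 0.55)

  readr::write_csv(tibble::tibble(
    group = c("V", "V"), process = "boil", nutrient = "iron", rf = c(0.9, 0.8)
  ), path)
  expect_error(read_retention_table(path), "duplicate")

  readr::write_csv(tibble::tibble(
    group = "V", process = "boil", nutrient = "iron", rf = -0.1
  ), path)
  expect_error(read_retention_table(path), "negative")
})

test_that("ingested pairs assemble into the wide paired-dataset layout", {
  dir <- withr::local_tempdir()
  foods <- tibble::tibble(
    fdc_id = 1:2,
    description = c("Spinach, raw", "Spinach, cooked, boiled"),
    food_category = "Vegetables and Vegetable Products"
  )
  nutrients <- tibble::tibble(
    id = 1:3, name = c("Water", "Iron, Fe", "Potassium, K"), unit_name = c("G", "MG", "MG")
  )
  amounts <- tidyr::expand_grid(fdc_id = 1:2, nutrient_id = 1:3) |>
    dplyr::mutate(amount = c(91, 2.7, 558, 94, 2.2, 300))
  p <- write_sr_fixture(dir, foods, nutrients, amounts)
  rec <- read_sr_legacy(p$food, p$nutrient, p$amount)
  ds <- pairs_to_dataset(rec, pair_foods(rec))
  expect_equal(nrow(ds), 1)
  expect_equal(ds$process_class, "WH")
  expect_equal(ds$raw_iron, 2.7)
  expect_equal(ds$cooked_potassium, 300)
  expect_equal(dataset_variant(ds), "unscaled")
})
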