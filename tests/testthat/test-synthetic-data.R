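test_that("world generation is deterministic and validates its domain", {
  w1 <- test_world(seed = 7)
  w2 <- test_world(seed = 7)
  expect_identical(w1, w2)

  p1 <- generate_pairs(w1, 5)
  p2 <- generate_pairs(w2, 5)
  expect_identical(serialize(p1$dataset, NULL), serialize(p2$dataset, NULL))
  expect_false(identical(p1$dataset, generate_pairs(test_world(seed = 8), 5)$dataset))

  bad_ret <- default_retentions()
  bad_ret$retention[bad_ret$component == "iron" & bad_ret$process_class == "DH"] <- 1.2
  expect_error(
    generate_world(synthetic_config(retention = bad_ret, components = reduced_components())),
    "\\(0, 1\\]"
  )
  unknown_ret <- dplyr::bind_rows(
    default_retentions(),
    tibble::tibble(component = "unobtainium", process_class = "DH", retention = 0.5)
  )
  expect_error(
    generate_world(synthetic_config(retention = unknown_ret, components = reduced_components())),
    "unknown component"
  )
  expect_error(
    generate_world(synthetic_config(yield_range = list(WH = c(105, 135), DH = c(-5, 95)),
                                    components = reduced_components())),
    "positive"
  )
  expect_error(generate_pairs(test_world(), 0), "n_per_category")
})

test_that("sampled yields respect the configured support", {
  w <- test_world(seed = 3, categories = "beef", yield_range = list(DH = c(60, 95)))
  y <- generate_pairs(w, 10000)$truth$yields$yield
  expect_length(y, 10000)
  expect_true(all(y > 60 & y < 95))
})

test_that("noise-free pairs satisfy mass closure and the yield mass balance", {
  w <- test_world(seed = 11, categories = c("vegetables", "legumes", "beef", "chicken"))
  p <- generate_pairs(w, 25)
  d <- p$dataset
  raw_mass <- rowSums(as.data.frame(d)[, paste0("raw_", mass_components())])
  cooked_mass <- rowSums(as.data.frame(d)[, paste0("cooked_", mass_components())])
  expect_equal(raw_mass, rep(100, nrow(d)), tolerance = 1e-12)
  expect_equal(cooked_mass, rep(100, nrow(d)), tolerance = 1e-12)

  # cooked per-100 g x Y / 100 == r x raw, for every pair and component
  y <- p$truth$yields$yield[match(d$pair_id, p$truth$yields$pair_id)]
  comps <- setdiff(dataset_components(d), "water")
  ret <- tidyr::pivot_wider(p$truth$retention, names_from = "component",
                            values_from = "retention")
  ret <- as.matrix(ret[match(d$pair_id, ret$pair_id), comps])
  raw <- as.matrix(as.data.frame(d)[, paste0("raw_", comps)])
  cooked <- as.matrix(as.data.frame(d)[, paste0("cooked_", comps)])
  expected <- ret * raw
  rel_err <- abs(cooked * y / 100 - expected) / pmax(abs(expected), 1e-300)
  rel_err[expected == 0] <- abs(cooked * y / 100)[expected == 0]
  expect_lt(max(rel_err), 1e-9)
})

test_that("closed-form cooked amounts match hand-computed mass balance", {
  # one deterministic beef-like category: iron 10 mg/100 g raw, fixed yield
  cats <- default_categories()[default_categories()$name == "beef", ]
  cats$retention_scale <- 1
  cats$profile_mean[[1]]["iron"] <- 10
  cats$profile_cv[[1]][] <- 0
  ret <- default_retentions()
  ret$retention[ret$component == "iron" & ret$process_class == "DH"] <- 0.9

  world_at <- function(yr, iron_r) {
    r <- ret
    r$retention[r$component == "iron" & r$process_class == "DH"] <- iron_r
    generate_world(
      synthetic_config(categories = cats, retention = r, noise_cv = 0,
                       mismatch_cv = 0, yield_range = list(DH = c(yr, yr)),
                       components = reduced_components()),
      seed = 5
    )
  }
  # identity: r = 1, Y = 100 leaves the amount unchanged
  d <- generate_pairs(world_at(100, 1), 1)$dataset
  expect_equal(d$cooked_iron, d$raw_iron, tolerance = 1e-12)
  expect_equal(d$raw_iron, 10, tolerance = 1e-12)
  # concentration bias: r = 0.9, Y = 80 gives 0.9 * 10 * 100 / 80 = 11.25
  d <- generate_pairs(world_at(80, 0.9), 1)$dataset
  expect_equal(d$cooked_iron, 11.25, tolerance = 1e-9)
  expect_gt(d$cooked_iron, d$raw_iron)  # cooked > raw despite a 10% loss
})

test_that("dilution bias: a conserved solid at Y = 120 reads 5 * 100 / 120", {
  cats <- default_categories()[default_categories()$name == "vegetables", ]
  cats$retention_scale <- 1
  cats$profile_mean[[1]]["protein"] <- 5
  cats$profile_cv[[1]][] <- 0
  # scale other mass components so closure keeps protein at exactly 5
  mm <- cats$profile_mean[[1]]
  others <- setdiff(mass_components(), "protein")
  mm[others] <- mm[others] * (95 / sum(mm[others]))
  cats$profile_mean[[1]] <- mm
  ret <- default_retentions()
  ret$retention[ret$component == "protein" & ret$process_class == "WH"] <- 1
  w <- generate_world(
    synthetic_config(categories = cats, retention = ret, noise_cv = 0,
                     mismatch_cv = 0, yield_range = list(WH = c(120, 120)),
                     components = reduced_components()),
    seed = 2
  )
  d <- generate_pairs(w, 1)$dataset
  expect_equal(d$raw_protein, 5, tolerance = 1e-9)
  expect_equal(d$cooked_protein, 5 * 100 / 120, tolerance = 1e-9)
})

test_that("invariant component recovers the true yield when conserved", {
  w <- test_world(seed = 13, categories = c("beef", "chicken"))
  p <- generate_pairs(w, 20)
  d <- p$dataset
  y <- p$truth$yields$yield[match(d$pair_id, p$truth$yields$pair_id)]
  expect_equal(d$raw_cholesterol * 100 / d$cooked_cholesterol, y, tolerance = 1e-9)
})

test_that("per-100 g anomaly asymmetry: concentration under DH, dilution under WH", {
  w <- test_world(seed = 17, noise_cv = 0.05,
                  categories = c("vegetables", "legumes", "beef", "chicken"))
  d <- generate_pairs(w, 100)$dataset
  nutrients <- c("thiamin", "iron", "potassium")
  frac_above <- function(ds) {
    mean(vapply(nutrients, function(n) mean(detect_anomaly(ds, n)), numeric(1)))
  }
  expect_gt(frac_above(d[d$process_class == "DH", ]), 0.5)
  expect_lt(frac_above(d[d$process_class == "WH", ]), 0.5)
})

test_that("retention table averages realized retentions within groups", {
  fake <- structure(
    list(
      dataset = make_pairs(
        raw = data.frame(iron = c(1, 1, 1)),
        cooked = data.frame(iron = c(1, 1, 1))
      ),
      truth = list(retention = tibble::tibble(
        pair_id = c("p01", "p02", "p03"),
        component = "iron",
        retention = c(0.8, 1.0, 0.9)
      ))
    ),
    class = "synthetic_pairs"
  )
  tab <- generate_retention_table(NULL, fake, group_by = "category")
  expect_equal(tab$rf, 0.9)
  expect_equal(tab$group, "beef")

  # constant retentions give back the constant
  fake$truth$retention$retention <- 0.7
  expect_equal(generate_retention_table(NULL, fake)$rf, 0.7)

  # one row per (category, process, component) present
  w <- test_world(seed = 19, categories = c("vegetables", "legumes", "beef"))
  p <- generate_pairs(w, 3)
  tab <- generate_retention_table(w, p, group_by = "category")
  expected_rows <- expand.grid(
    category = unique(p$dataset$category),
    component = setdiff(dataset_components(p$dataset), "water")
  )
  expect_equal(nrow(tab), nrow(expected_rows))
  expect_setequal(paste(tab$group, tab$nutrient),
                  paste(expected_rows$category, expected_rows$component))
})

test_that("synthetic CSV round-trip preserves the dataset and RF layout", {
  w <- test_world(seed = 23)
  p <- generate_pairs(w, 4)
  dir <- withr::local_tempdir()
  write_synthetic_csv(p, dir)
  back <- read_pairs_csv(file.path(dir, "pairs.csv"))
  expect_equal(dataset_components(back), dataset_components(p$dataset))
  expect_equal(as.data.frame(back), as.data.frame(p$dataset), tolerance = 1e-12)
  rf <- read_retention_table(file.path(dir, "retention_table.csv"))
  expect_true(all(rf$rf > 0 & rf$rf <= 1))
})
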