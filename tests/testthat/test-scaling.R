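test_that("SCS reproduces the hand-worked water/fat equalization", {
  d <- make_pairs(
    raw = c(water = 90, protein = 4, carbohydrate = 5, total_fat = 1, fiber = 0),
    cooked = c(water = 93, protein = 2.8, carbohydrate = 3.5, total_fat = 0.7, fiber = 0)
  )
  s <- scs_scale(d)
  # pass 1 factor: 1 + (90 - 93) / (4 + 5 + 1) = 0.7; pass 2 is a no-op
  expect_equal(s$raw_water, 93)
  expect_equal(s$raw_protein, 2.8)
  expect_equal(s$raw_carbohydrate, 3.5)
  expect_equal(s$raw_total_fat, 0.7)
  expect_equal(dataset_variant(s), "SCS")
  # gram total conserved
  tot <- function(x) sum(unlist(x[paste0("raw_", mass_components())]))
  expect_equal(tot(s), tot(d), tolerance = 1e-12)
})

test_that("SCS is the identity when water and fat already match", {
  d <- make_pairs(
    raw = c(water = 80, protein = 10, carbohydrate = 5, total_fat = 5, fiber = 0, iron = 2),
    cooked = c(water = 80, protein = 9, carbohydrate = 5, total_fat = 5, fiber = 0, iron = 1.8)
  )
  s <- scs_scale(d)
  for (col in paste0("raw_", c("water", "protein", "carbohydrate", "total_fat", "iron"))) {
    expect_equal(s[[col]], d[[col]])
  }
})

test_that("closure forces the residual component under either equalization order", {
  d <- make_pairs(
    raw = c(water = 80, total_fat = 10, protein = 10, carbohydrate = 0, fiber = 0),
    cooked = c(water = 70, total_fat = 5, protein = 25, carbohydrate = 0, fiber = 0)
  )
  s1 <- scs_scale(d, equalize = c("water", "total_fat"))
  s2 <- scs_scale(d, equalize = c("total_fat", "water"))
  expect_equal(s1$raw_protein, 25, tolerance = 1e-12)
  expect_equal(s2$raw_protein, 25, tolerance = 1e-12)
})

test_that("SCS conserves mass and is order-invariant on random synthetic pairs", {
  w <- test_world(seed = 31, noise_cv = 0.05, mismatch_cv = 0.03,
                  categories = c("vegetables", "legumes", "beef", "chicken"))
  d <- generate_pairs(w, 250)$dataset
  s1 <- scs_scale(d)
  s2 <- scs_scale(d, equalize = c("total_fat", "water"))
  g <- rowSums(as.data.frame(d)[, paste0("raw_", mass_components())])
  g1 <- rowSums(as.data.frame(s1)[, paste0("raw_", mass_components())])
  expect_lt(max(abs(g1 - g) / g), 1e-9)
  m1 <- as.matrix(as.data.frame(s1)[, paste0("raw_", dataset_components(d))])
  m2 <- as.matrix(as.data.frame(s2)[, paste0("raw_", dataset_components(d))])
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), 1e-12)), 1e-9)
})

test_that("SCS guards against degenerate inputs and re-application", {
  d <- make_pairs(
    raw = c(water = 100, protein = 0, carbohydrate = 0, total_fat = 0, fiber = 0),
    cooked = c(water = 90, protein = 5, carbohydrate = 0, total_fat = 0, fiber = 0)
  )
  expect_error(scs_scale(d), "denominator")
  d2 <- make_pairs(
    raw = c(water = 90, protein = 5, carbohydrate = 4, total_fat = 1, fiber = 0),
    cooked = c(water = 91, protein = 4, carbohydrate = 4, total_fat = 1, fiber = 0)
  )
  expect_error(scs_scale(d2, equalize = c("water", "iron")), "not present|mass-bearing")
  s <- scs_scale(d2)
  expect_warning(s2 <- scs_scale(s), "already SCS-scaled")
  expect_equal(as.data.frame(s2)[, -1], as.data.frame(s)[, -1])  # no-op
})

test_that("PINS computes the closed-form scaling factor and yield estimate", {
  d <- make_pairs(
    raw = c(water = 70, protein = 20, carbohydrate = 0, total_fat = 8, fiber = 0,
            cholesterol = 50, iron = 2),
    cooked = c(water = 62, protein = 25, carbohydrate = 0, total_fat = 9, fiber = 0,
               cholesterol = 62.5, iron = 2.4)
  )
  p <- pins_scale(d)
  expect_equal(p$scaling_factor, 0.8)
  expect_equal(p$yield_estimate, 80)
  expect_equal(p$cooked_iron, 0.8 * 2.4)
  expect_equal(dataset_variant(p), "PINS-cholesterol")

  # identity when the invariant is unchanged
  d_id <- make_pairs(
    raw = c(water = 70, protein = 20, carbohydrate = 0, total_fat = 8, fiber = 0,
            cholesterol = 50, iron = 2),
    cooked = c(water = 70, protein = 20, carbohydrate = 0, total_fat = 8, fiber = 0,
               cholesterol = 50, iron = 2.4)
  )
  p_id <- pins_scale(d_id)
  expect_equal(p_id$scaling_factor, 1)
  expect_equal(p_id$cooked_iron, 2.4)

  # 5% assumed loss scales the factor: 0.95 * 0.8 = 0.76
  p5 <- pins_scale(d, assumed_retention = 0.95)
  expect_equal(p5$scaling_factor, 0.76)
  expect_equal(dataset_variant(p5), "PINS-cholesterol-loss5")
})

test_that("PINS excludes pairs with a missing or zero invariant amount", {
  d <- make_pairs(
    raw = data.frame(water = c(70, 70), protein = c(20, 20), carbohydrate = c(0, 0),
                     total_fat = c(8, 8), fiber = c(0, 0), cholesterol = c(50, 0)),
    cooked = data.frame(water = c(62, 62), protein = c(25, 25), carbohydrate = c(0, 0),
                        total_fat = c(9, 9), fiber = c(0, 0), cholesterol = c(62.5, 10))
  )
  p <- pins_scale(d)
  expect_equal(nrow(p), 1)
  excl <- attr(p, "excluded")
  expect_equal(excl$pair_id, "p02")
  expect_match(excl$reason, "raw cholesterol")
  expect_warning(pins_scale(p), "already PINS-scaled")
})

test_that("PINS recovers the true yield on synthetic data", {
  w <- test_world(seed = 37, categories = c("beef", "chicken"))
  p <- generate_pairs(w, 50)
  scaled <- pins_scale(p$dataset)
  y <- p$truth$yields$yield[match(scaled$pair_id, p$truth$yields$pair_id)]
  expect_equal(scaled$yield_estimate, y, tolerance = 1e-12)
})

test_that("anomaly detection is strict and tie-tolerant", {
  d <- make_pairs(
    raw = data.frame(iron = c(1, 1, 1)),
    cooked = data.frame(iron = c(1.2, 1.0, 0.8))
  )
  expect_identical(detect_anomaly(d, "iron"), c(TRUE, FALSE, FALSE))
  expect_error(detect_anomaly(d, "zinc"), "not present")
})

test_that("a concentration-biased DH pair stops being anomalous after PINS", {
  # r = 0.9, Y = 80: cooked reads 11.25 for raw 10 before scaling
  d <- make_pairs(
    raw = c(water = 70, protein = 20, carbohydrate = 0, total_fat = 10, fiber = 0,
            cholesterol = 50, iron = 10),
    cooked = c(water = 60, protein = 24, carbohydrate = 0, total_fat = 9, fiber = 0,
               cholesterol = 62.5, iron = 11.25)
  )
  expect_true(detect_anomaly(d, "iron"))
  expect_false(detect_anomaly(pins_scale(d), "iron"))
})

test_that("per-nutrient filtering removes anomalous pairs from scaled variants only", {
  set.seed(1)
  n <- 10
  d <- make_pairs(
    raw = data.frame(water = rep(70, n), protein = rep(20, n), carbohydrate = rep(0, n),
                     total_fat = rep(8, n), fiber = rep(0, n), cholesterol = rep(50, n),
                     iron = rep(1, n)),
    cooked = data.frame(water = rep(62, n), protein = rep(22, n), carbohydrate = rep(0, n),
                        total_fat = rep(8.5, n), fiber = rep(0, n), cholesterol = rep(50, n),
                        iron = c(rep(1.5, 3), rep(0.9, 7)))
  )
  scaled <- pins_scale(d)   # factor 1, values unchanged
  expect_equal(nrow(filter_pairs(scaled, "iron")), 7)
  expect_equal(nrow(filter_pairs(d, "iron")), 10)

  all_anom <- scaled
  all_anom$cooked_iron <- 2
  expect_warning(out <- filter_pairs(all_anom, "iron"), "all pairs are anomalous")
  expect_equal(nrow(out), 0)
})

test_that("anomaly summaries count fractions by source and overall", {
  d <- make_pairs(
    raw = data.frame(iron = rep(1, 10)),
    cooked = data.frame(iron = c(rep(1.2, 3), rep(0.9, 7)))
  )
  s <- anomaly_summary(d, nutrients = "iron")
  pooled <- s[s$source == "all", ]
  expect_equal(pooled$n_pairs, 10)
  expect_equal(pooled$n_non_anomalous, 7)
  expect_equal(pooled$fraction_non_anomalous, 0.7)

  # zero-noise wet-heat data is dilution-only: nothing is anomalous
  w <- test_world(seed = 41, categories = c("vegetables", "legumes"))
  dwh <- generate_pairs(w, 40)$dataset
  swh <- anomaly_summary(dwh, nutrients = c("thiamin", "iron", "potassium"))
  expect_true(all(swh$fraction_non_anomalous == 1))

  # on noisy DH data, PINS raises the non-anomalous fraction over unscaled
  wdh <- test_world(seed = 43, noise_cv = 0.05, categories = c("beef", "chicken"))
  ddh <- generate_pairs(wdh, 100)$dataset
  nuts <- c("thiamin", "iron", "potassium")
  f_un <- mean(anomaly_summary(ddh, nuts)$fraction_non_anomalous)
  f_pins <- mean(anomaly_summary(pins_scale(ddh), nuts)$fraction_non_anomalous)
  expect_gt(f_pins, f_un)
})

test_that("two-proportion comparison matches exact oracles", {
  mk <- function(non, n) {
    tibble::tibble(variant = "x", source = "all", nutrient = "iron",
                   n_pairs = n, n_non_anomalous = non,
                   fraction_non_anomalous = non / n)
  }
  same <- compare_anomaly_fractions(mk(30, 100), mk(30, 100))
  expect_equal(same$p_value, 1)

  big <- compare_anomaly_fractions(mk(30, 100), mk(70, 100))
  expect_lt(big$p_value, 0.01)
  # oracle: Fisher's exact test on the same 2x2 table
  oracle <- stats::fisher.test(matrix(c(30, 70, 70, 30), 2, byrow = TRUE))$p.value
  expect_lt(oracle, 0.01)

  small <- compare_anomaly_fractions(mk(50, 100), mk(52, 100))
  expect_gt(small$p_value, 0.05)
  expect_gt(stats::fisher.test(matrix(c(50, 50, 52, 48), 2, byrow = TRUE))$p.value, 0.05)
})
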