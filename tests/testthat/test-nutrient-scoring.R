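test_that("percent_dv matches the daily-value table", {
  expect_equal(percent_dv(50, "protein"), 100)
  expect_equal(percent_dv(0, "sodium"), 0)
  expect_equal(percent_dv(14, "fiber"), 50)
  expect_error(percent_dv(10, "zinc"), "unknown_nutrient")
  expect_error(percent_dv(-1, "protein"), "negative_amount")
})

test_that("daily-value table structure is consistent", {
  dv <- daily_values()
  expect_length(dv, 11)
  expect_true(all(dv > 0))
  expect_setequal(c(recommended_nutrients(), restricted_nutrients()),
                  names(dv))
  expect_length(intersect(recommended_nutrients(),
                          restricted_nutrients()), 0)
})

test_that("RRR and RRRmacro match their definitions on worked examples", {
  expect_equal(as.numeric(compute_rrr(profile_at_dv())), 1)
  expect_equal(as.numeric(compute_rrr_macro(profile_at_dv())), 1)

  # recommended at (100,100,50,50,50,50)%DV, restricted all at 50%DV
  p <- nutrient_profile(protein = 50, fiber = 28, vitamin_a = 450,
                        vitamin_c = 45, calcium = 650, iron = 9,
                        calories = 1000, total_sugar = 25,
                        cholesterol = 150, saturated_fat = 10,
                        sodium = 1150)
  expect_equal(as.numeric(compute_rrr(p)), 4 / 3, tolerance = 1e-10)

  # protein at DV, fiber zero, restricted all at DV
  p2 <- nutrient_profile(protein = 50, fiber = 0, calories = 2000,
                         total_sugar = 50, cholesterol = 300,
                         saturated_fat = 20, sodium = 2300)
  expect_equal(as.numeric(compute_rrr_macro(p2)), 0.5)
})

test_that("missing-nutrient policy and degenerate denominators", {
  p <- nutrient_profile(protein = 50, fiber = 28, calories = 2000,
                        total_sugar = 50, cholesterol = 300,
                        saturated_fat = 20, sodium = 2300)
  expect_error(compute_rrr(p), "missing_nutrient")
  # with missing treated as zero the micronutrients contribute 0 %DV
  expect_equal(as.numeric(compute_rrr(p, missing = "zero")),
               mean(c(100, 100, 0, 0, 0, 0)) / 100)
  zero <- nutrient_profile(protein = 50, fiber = 28, vitamin_a = 1,
                           vitamin_c = 1, calcium = 1, iron = 1,
                           calories = 0, total_sugar = 0, cholesterol = 0,
                           saturated_fat = 0, sodium = 0)
  expect_error(compute_rrr(zero), "undefined_denominator")
  # optional cap
  big <- nutrient_profile(protein = 500, fiber = 280, calories = 20,
                          total_sugar = 0.5, cholesterol = 3,
                          saturated_fat = 0.2, sodium = 23)
  expect_equal(as.numeric(compute_rrr_macro(big, max_score = 5)), 5)
})

test_that("scores are scale-invariant and monotone", {
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_profile()
      c_ <- stats::runif(1, 0.01, 50)
      scaled <- nutrient_profile(as.list(unclass(p) * c_))
      expect_equal(as.numeric(compute_rrr(scaled)),
                   as.numeric(compute_rrr(p)), tolerance = 1e-12)
      expect_equal(as.numeric(compute_rrr_macro(scaled)),
                   as.numeric(compute_rrr_macro(p)), tolerance = 1e-12)
      # bumping a recommended nutrient never decreases RRR, bumping a
      # restricted nutrient never increases it
      up <- unclass(p); up[["fiber"]] <- up[["fiber"]] + 1
      expect_gte(as.numeric(compute_rrr(nutrient_profile(as.list(up)))),
                 as.numeric(compute_rrr(p)))
      dn <- unclass(p); dn[["sodium"]] <- dn[["sodium"]] + 100
      expect_lte(as.numeric(compute_rrr(nutrient_profile(as.list(dn)))),
                 as.numeric(compute_rrr(p)))
    }
  })
})

test_that("both variants match an independent transcription on random profiles", {
  withr::with_seed(12, {
    for (i in 1:200) {
      p <- random_profile()
      expect_equal(as.numeric(compute_rrr(p)), oracle_rrr(p),
                   tolerance = 1e-12)
      expect_equal(as.numeric(compute_rrr_macro(p)),
                   oracle_rrr(p, macro = TRUE), tolerance = 1e-12)
    }
  })
})

test_that("score_items applies the chosen variant row-wise", {
  items <- small_corpus()$items
  scored <- score_items(items, variant = "rrr_macro")
  expect_equal(scored$score, items$rrr_macro, tolerance = 1e-12)
  scored_rrr <- score_items(items, variant = "rrr")
  expect_equal(scored_rrr$score, items$rrr, tolerance = 1e-12)
})
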