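test_that("food scores carry the 0/2/7 weights with signs by GI class", {
  expect_equal(score_food("rice", "most or all days per week"), -7L)
  expect_equal(score_food("pulses", "never or only occasionally"), 0L)
  expect_equal(score_food("fruits", "once or twice per week"), 2L)
  expect_equal(score_food("cereals", "once or twice per week"), -2L)
  # vectorized with mixed classes
  expect_equal(
    score_food(c("rice", "milk"), rep("most or all days per week", 2)),
    c(-7L, 7L)
  )
  expect_error(score_food("pasta", "never or only occasionally"), "pasta")
  expect_error(score_food("rice", "daily"), "invalid level")
  expect_error(score_food("chocolate", "never or only occasionally"), "unknown food")
})

test_that("score categories partition the attainable range", {
  expect_equal(categorize_qdgis(10L), "good")
  expect_equal(categorize_qdgis(2L), "moderate")
  expect_equal(categorize_qdgis(1L), "poor")
  expect_equal(categorize_qdgis(9L), "moderate")
  expect_equal(categorize_qdgis(-28L), "poor")
  expect_equal(categorize_qdgis(42L), "good")
  all_scores <- -28:42
  cats <- categorize_qdgis(all_scores)
  expect_false(anyNA(cats))
  expect_setequal(unique(cats), c("poor", "moderate", "good"))
  expect_error(categorize_qdgis(43L), "bounds")
  expect_error(categorize_qdgis(-29L), "bounds")
  expect_equal(categorize_qdgis(NA_integer_), NA_character_)
})

test_that("the diet score matches a hand-summed example and the extremes", {
  # rice most (-7), cereals once (-2), potatoes never (0), fast food never (0),
  # fruits most (+7), vegetables most (+7), pulses once (+2), milk once (+2),
  # nuts never (0), probiotic never (0) => +9, moderate
  d <- diet_row(
    rice = freq_levels[3], cereals = freq_levels[2],
    fruits = freq_levels[3], vegetables = freq_levels[3],
    pulses = freq_levels[2], milk = freq_levels[2]
  )
  q <- compute_qdgis(d)
  expect_equal(q$qdgis_score, 9L)
  expect_equal(q$qdgis_category, "moderate")
  expect_equal(q$n_missing_items, 0L)

  # extremes: all low-GI at most days + all high-GI never -> +42 (good);
  # all high-GI most days + all low-GI never -> -28 (poor)
  best <- diet_row(fruits = freq_levels[3], vegetables = freq_levels[3],
                   pulses = freq_levels[3], nuts = freq_levels[3],
                   milk = freq_levels[3], probiotic = freq_levels[3])
  worst <- diet_row(fastfood = freq_levels[3], cereals = freq_levels[3],
                    rice = freq_levels[3], potatoes = freq_levels[3])
  expect_equal(compute_qdgis(best)$qdgis_score, 42L)
  expect_equal(compute_qdgis(best)$qdgis_category, "good")
  expect_equal(compute_qdgis(worst)$qdgis_score, -28L)
  expect_equal(compute_qdgis(worst)$qdgis_category, "poor")
})

test_that("missing diet items propagate by default and zero-impute on request", {
  d <- diet_row(fruits = freq_levels[3], rice = freq_levels[3])
  d$food_milk <- NA_character_
  d$food_rice <- NA_character_
  prop <- compute_qdgis(d, missing_policy = "propagate")
  expect_true(is.na(prop$qdgis_score))
  expect_true(is.na(prop$qdgis_category))
  expect_equal(prop$n_missing_items, 2L)
  zi <- compute_qdgis(d, missing_policy = "zero-impute")
  expect_equal(zi$qdgis_score, 7L)  # fruits +7; missing rice/milk contribute 0
  expect_equal(zi$n_missing_items, 2L)
})

test_that("the score equals an independent naive summation on random diets", {
  set.seed(202)
  n <- 400
  d <- as.data.frame(
    stats::setNames(
      lapply(scored_foods, function(f) sample(freq_levels, n, replace = TRUE)),
      paste0("food_", scored_foods)
    ),
    stringsAsFactors = FALSE
  )
  got <- compute_qdgis(d)$qdgis_score
  want <- vapply(seq_len(n), function(i) {
    naive_qdgis(stats::setNames(as.list(d[i, ]), scored_foods))
  }, integer(1))
  expect_equal(got, want)
})

test_that("raising a low-GI frequency never lowers the score; high-GI never raises it", {
  set.seed(303)
  n <- 200
  base <- as.data.frame(
    stats::setNames(
      lapply(scored_foods, function(f) sample(freq_levels, n, replace = TRUE)),
      paste0("food_", scored_foods)
    ),
    stringsAsFactors = FALSE
  )
  s0 <- compute_qdgis(base)$qdgis_score
  cls <- gi_food_classes()
  for (f in scored_foods) {
    col <- paste0("food_", f)
    idx <- match(base[[col]], freq_levels)
    can_raise <- idx < 3
    bumped <- base
    bumped[[col]][can_raise] <- freq_levels[idx[can_raise] + 1]
    s1 <- compute_qdgis(bumped)$qdgis_score
    if (cls[[f]] == "low") {
      expect_true(all(s1[can_raise] >= s0[can_raise]), info = f)
    } else {
      expect_true(all(s1[can_raise] <= s0[can_raise]), info = f)
    }
  }
})

test_that("the GI class map is overridable and drives the attainable bounds", {
  # move pasta into the high-GI class: bounds become [-35, 42]
  map <- gi_food_classes()
  map["pasta"] <- "high"
  d <- diet_row()
  d$food_pasta <- freq_levels[3]
  q <- compute_qdgis(d, gi_map = map)
  expect_equal(q$qdgis_score, -7L)
  expect_equal(score_food("pasta", freq_levels[3], gi_map = map), -7L)
})
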