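test_that("frequency map is valid and daily grams follow it", {
  fm <- nps_frequency_map()
  expect_identical(nrow(fm), 9L)
  expect_identical(fm$servings_per_day[1], 0)
  expect_false(is.unsorted(fm$servings_per_day))
  expect_identical(daily_grams(1, 999), 0)        # never
  expect_identical(daily_grams(6, 30), 30)        # once per day
  expect_identical(daily_grams(7, 200), 500)      # 2-3/day midpoint 2.5
  expect_error(daily_grams(10, 30), "frequency category")
  expect_error(daily_grams(6, 0), "portion_size")
  bad <- nps_frequency_map(); bad$servings_per_day[1] <- 0.01
  expect_error(daily_grams(6, 30, bad), "never")
})

test_that("nutrient intake matches a brute-force per-response oracle", {
  comp <- toy_composition(); items <- toy_items()
  set.seed(9)
  resp <- toy_responses()
  resp$frequency_category <- sample(1:9, nrow(resp), replace = TRUE)
  fm <- nps_frequency_map()
  got <- nutrient_intake(resp, items, comp, fm)
  oracle <- bruteforce_intake(resp, items, comp, fm)
  for (i in seq_len(nrow(got$intakes))) {
    row <- got$intakes[i, ]
    key <- paste(row$participant_id, row$timepoint)
    for (nm in names(oracle[[key]])) {
      expect_equal(row[[nm]], unname(oracle[[key]][nm]), info = paste(key, nm))
    }
  }
  # total energy equals the sum of the per-item contributions exactly
  ie <- got$item_energy
  for (i in seq_len(nrow(got$intakes))) {
    row <- got$intakes[i, ]
    expect_equal(row$energy_kcal,
                 sum(ie$energy_kcal[ie$participant_id == row$participant_id &
                                      ie$timepoint == row$timepoint]))
  }
})

test_that("single-item and additive unit cases", {
  comp <- toy_composition(); items <- toy_items()
  one <- data.frame(participant_id = "p1", timepoint = "baseline",
                    item_id = "lentils", frequency_category = 6L)
  # 150 g/day at 9 g protein per 100 g -> 13.5 g/day
  got <- nutrient_intake(one, items, comp)
  expect_equal(got$intakes$protein_g, 13.5)
  two <- rbind(one, data.frame(participant_id = "p1", timepoint = "baseline",
                               item_id = "bread", frequency_category = 6L))
  got2 <- nutrient_intake(two, items, comp)
  expect_equal(got2$intakes$protein_g, 13.5 + 50 / 100 * 9)
})

test_that("intakes are linear in the frequency map", {
  comp <- toy_composition(); items <- toy_items()
  resp <- toy_responses()
  set.seed(11)
  resp$frequency_category <- sample(2:9, nrow(resp), replace = TRUE)
  fm <- nps_frequency_map()
  fm2 <- fm; fm2$servings_per_day <- fm$servings_per_day * 3
  a <- nutrient_intake(resp, items, comp, fm)$intakes
  b <- nutrient_intake(resp, items, comp, fm2)$intakes
  expect_equal(b$energy_kcal, 3 * a$energy_kcal)
  expect_equal(b$sodium_mg, 3 * a$sodium_mg)
})

test_that("duplicate and unresolvable responses are rejected", {
  comp <- toy_composition(); items <- toy_items()
  one <- data.frame(participant_id = "p1", timepoint = "baseline",
                    item_id = "lentils", frequency_category = 6L)
  expect_error(nutrient_intake(rbind(one, one), items, comp), "duplicate")
  ghost <- transform(one, item_id = "ghost")
  expect_error(nutrient_intake(ghost, items, comp), "ghost")
  expect_warning(nutrient_intake(one[0, ], items, comp), "no FFQ responses")
})

test_that("exclusion rules: limits strict, both timepoints, idempotent", {
  cohort <- data.frame(
    participant_id = c("w_low", "w_edge", "w_high", "m_ok", "m_high",
                       "no_y1"),
    sex = c("female", "female", "female", "male", "male", "male"),
    stringsAsFactors = FALSE)
  intakes <- rbind(
    data.frame(participant_id = cohort$participant_id, timepoint = "baseline",
               energy_kcal = c(450, 500, 3600, 3900, 4500, 2000)),
    data.frame(participant_id = setdiff(cohort$participant_id, "no_y1"),
               timepoint = "year1",
               energy_kcal = c(2000, 2000, 2000, 2000, 2000)))
  res <- apply_exclusions(cohort, intakes)
  expect_setequal(res$retained$participant_id, c("w_edge", "m_ok"))
  rs <- setNames(res$exclusions$reason, res$exclusions$participant_id)
  expect_identical(rs[["w_low"]], "energy_below_limit")
  expect_identical(rs[["w_high"]], "energy_above_limit")
  expect_identical(rs[["m_high"]], "energy_above_limit")
  expect_identical(rs[["no_y1"]], "missing_ffq_year1")
  # idempotence and partition
  again <- apply_exclusions(res$retained, intakes)
  expect_identical(again$retained, res$retained)
  expect_identical(nrow(again$exclusions), 0L)
  expect_setequal(c(res$retained$participant_id,
                    res$exclusions$participant_id),
                  cohort$participant_id)
  expect_error(apply_exclusions(transform(cohort, sex = "unknown"), intakes),
               "unknown sex")
})
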