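bands <- nps_bands()

test_that("component points follow the strict-threshold step functions", {
  # frozen hand lookups in the 2015 grids (strictly-greater semantics)
  cases <- list(
    list(0, "energy", "general", 0),      # below first threshold
    list(1500, "energy", "general", 4),   # > 1340, <= 1675
    list(46, "sugars", "general", 10),    # above the top band
    list(8.1, "protein", "general", 5),   # above the top band
    list(5, "satfat", "general", 4),      # exceeds 1..4 only (strict)
    list(500, "sodium", "general", 5),    # > 450, <= 540
    list(2, "fiber", "general", 2),
    list(50, "fvln", "general", 1),       # > 40, <= 60
    list(85, "fvln", "general", 5),
    list(85, "fvln", "beverage", 10),
    list(50, "satfat", "added_fat", 7),   # ratio 50% > 46, <= 52
    list(0.5, "energy", "beverage", 1),   # any energy > 0 scores
    list(0, "energy", "beverage", 0)
  )
  for (cs in cases) {
    expect_identical(component_points(cs[[1]], cs[[2]], cs[[3]], bands),
                     as.integer(cs[[4]]),
                     info = paste(cs[[2]], cs[[3]], cs[[1]]))
  }
  # boundary values do not earn the band (strict inequality)
  expect_identical(component_points(335, "energy", "general", bands), 0L)
  expect_identical(component_points(335.001, "energy", "general", bands), 1L)
})

test_that("unknown components or categories raise configuration errors", {
  expect_error(component_points(1, "transfat", "general", bands), "transfat")
  expect_error(component_points(1, "energy", "snack", bands), "snack")
})

test_that("A subtotal handles zero profiles, saturation and added fats", {
  zero <- nutrient_profile("zero")
  expect_identical(a_subtotal(zero, bands), 0L)
  worst <- nutrient_profile("worst", energy = 3400, sugars = 46, satfat = 11,
                            sodium = 950)
  expect_identical(a_subtotal(worst, bands), 40L)
  oil <- nutrient_profile("oil", satfat = 50, total_fat = 100,
                          category = "added_fat")
  # scored on the 50% ratio grid (7 pts), not the absolute grid (10 pts)
  expect_identical(score_food(oil, bands)$a_satfat, 7L)
  zf <- data.frame(item_id = "zf", category = "added_fat", energy = 0,
                   sugars = 0, satfat = 0, sodium = 0, fiber = 0,
                   protein = 0, fvln_pct = 0, total_fat = 0)
  expect_warning(s <- score_foods(zf, bands), "total_fat = 0")
  expect_identical(s$a_satfat, 0L)
})

test_that("protein-cap rule: discarded at high A unless fvln maximal or cheese", {
  p <- nutrient_profile("p", fiber = 2, protein = 8.1)  # fiber 2, protein 5, fvln 0
  capped <- c_subtotal(p, a_total = 12, bands)
  expect_identical(capped$c_total, 2L)
  expect_false(capped$protein_counted)
  below <- c_subtotal(p, a_total = 10, bands)
  expect_identical(below$c_total, 7L)
  expect_true(below$protein_counted)
  cheese <- nutrient_profile("ch", fiber = 2, protein = 8.1,
                             category = "cheese")
  ch <- c_subtotal(cheese, a_total = 12, bands)
  expect_identical(ch$c_total, 7L)
  expect_true(ch$protein_counted)
  maxfv <- nutrient_profile("fv", fiber = 2, protein = 8.1, fvln_pct = 90)
  fv <- c_subtotal(maxfv, a_total = 12, bands)
  expect_true(fv$protein_counted)   # fvln at its maximum re-enables protein
  expect_identical(fv$c_total, 12L)
})

test_that("worked example scores as the hand band lookup", {
  p <- nutrient_profile("ex", energy = 1500, sugars = 20, satfat = 5,
                        sodium = 500, fiber = 2, protein = 7, fvln_pct = 50)
  s <- score_food(p, bands)
  expect_identical(s$a_total, 17L)           # 4 + 4 + 4 + 5
  expect_false(s$protein_counted)            # 17 >= 11, fvln below max
  expect_identical(s$c_total, 3L)            # fvln 1 + fiber 2
  expect_identical(s$total, 14L)
})

test_that("score range: all-zero 0, saturated A 40, saturated C -15", {
  water <- nutrient_profile("water")
  expect_identical(score_food(water, bands)$total, 0L)
  worst <- nutrient_profile("worst", energy = 3400, sugars = 46, satfat = 11,
                            sodium = 950)
  expect_identical(score_food(worst, bands)$total, 40L)
  best <- nutrient_profile("best", fiber = 4, protein = 9, fvln_pct = 100)
  expect_identical(score_food(best, bands)$total, -15L)
})

test_that("score identities and monotonicity hold on random profiles", {
  set.seed(42)
  n <- 300
  comp <- data.frame(
    item_id = paste0("r", 1:n),
    category = sample(c("general", "beverage", "cheese", "added_fat"), n, TRUE),
    energy = runif(n, 0, 3600), sugars = runif(n, 0, 50),
    satfat = runif(n, 0, 12), sodium = runif(n, 0, 1000),
    fiber = runif(n, 0, 5), protein = runif(n, 0, 10),
    fvln_pct = runif(n, 0, 100), stringsAsFactors = FALSE
  )
  comp$total_fat <- comp$satfat * runif(n, 1, 3)
  s <- score_foods(comp, bands)
  expect_identical(s$total, s$a_total - s$c_total)
  expect_true(all(s$a_total >= 0 & s$a_total <= 40))
  gen <- s$category == "general"
  expect_true(all(s$c_total[gen] >= 0 & s$c_total[gen] <= 15))
  expect_true(all(s$total[gen] >= -15 & s$total[gen] <= 40))
  # determinism
  expect_identical(score_foods(comp, bands), s)

  # monotone: raising an A nutrient never lowers the total, raising a C
  # nutrient never raises it
  bump <- function(col, d) { c2 <- comp; c2[[col]] <- c2[[col]] + d; c2 }
  for (col in c("energy", "sugars", "sodium")) {
    expect_true(all(score_foods(bump(col, 50), bands)$total >= s$total),
                info = col)
  }
  up_fib <- score_foods(bump("fiber", 1), bands)
  up_pro <- score_foods(bump("protein", 1), bands)
  expect_true(all(up_fib$total <= s$total))
  expect_true(all(up_pro$total <= s$total))
})

test_that("exhaustive band-extreme audit attains exactly 40 and -15", {
  ext <- score_extremes(bands)
  expect_identical(ext$max_total, 40L)
  expect_identical(ext$min_total, -15L)
  expect_identical(ext$max_a, 40L)
  expect_identical(ext$max_c, 15L)
})

test_that("olive-oil reclassification sets -8 and is a no-op elsewhere", {
  s <- score_foods(toy_composition(), bands)
  r <- reclassify_olive_oil(s, "olive_oil")
  expect_identical(r$total[r$item_id == "olive_oil"], -8L)
  keep <- r$item_id != "olive_oil"
  expect_identical(r$total[keep], s$total[keep])
  expect_identical(reclassify_olive_oil(s, character(0)), s)
  expect_error(reclassify_olive_oil(s, "nonexistent"), "nonexistent")
})

test_that("composition reader converts kcal and salt units", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(item_id = "x", name = "x", category = "general",
                       energy_kcal = 100, sugars_g = 1, satfat_g = 1,
                       fat_g = 2, salt_g = 2.5, fiber_g = 1, protein_g = 1,
                       fvln_pct = 0), f, row.names = FALSE)
  co <- read_composition(f)
  expect_equal(co$energy, 418.4)
  expect_equal(co$sodium, 1000)
})
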