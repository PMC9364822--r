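# shared toy fixtures, built in code

toy_composition <- function() {
  data.frame(
    item_id = c("bread", "soda", "cheddar", "olive_oil", "lentils", "water"),
    category = c("general", "beverage", "cheese", "added_fat", "general",
                 "beverage"),
    energy = c(1000, 180, 1700, 3700, 450, 0),
    sugars = c(3, 10.5, 0.5, 0, 1.8, 0),
    satfat = c(0.4, 0, 21, 14, 0.1, 0),
    total_fat = c(1.5, 0, 34, 100, 0.5, 0),
    sodium = c(500, 10, 700, 1, 2, 5),
    fiber = c(3, 0, 0, 0, 8, 0),
    protein = c(9, 0, 25, 0, 9, 0),
    fvln_pct = c(0, 0, 0, 100, 100, 0),
    stringsAsFactors = FALSE
  )
}

toy_items <- function() {
  data.frame(item_id = toy_composition()$item_id,
             portion_size = c(50, 330, 30, 10, 150, 200),
             stringsAsFactors = FALSE)
}

toy_responses <- function(pids = c("p1", "p2"),
                          timepoints = c("baseline", "year1")) {
  comp <- toy_composition()
  expand.grid(participant_id = pids, timepoint = timepoints,
              item_id = comp$item_id, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(frequency_category = 6L)  # once per day everywhere
}

# brute-force clustered sandwich with the Stata small-sample factor
bruteforce_cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  e <- stats::resid(fit)
  n <- nrow(X); k <- ncol(X); G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    s <- crossprod(X[cluster == g, , drop = FALSE], e[cluster == g])
    meat <- meat + s %*% t(s)
  }
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}

# spreadsheet-style intake oracle: explicit per-response loop
bruteforce_intake <- function(responses, items, composition, fmap) {
  out <- list()
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    it <- items[items$item_id == r$item_id, ]
    co <- composition[composition$item_id == r$item_id, ]
    g <- fmap$servings_per_day[fmap$frequency_category ==
                                 r$frequency_category] * it$portion_size
    key <- paste(r$participant_id, r$timepoint)
    if (is.null(out[[key]])) {
      out[[key]] <- c(energy_kcal = 0, sugars_g = 0, satfat_g = 0,
                      sodium_mg = 0, fiber_g = 0, protein_g = 0)
    }
    out[[key]] <- out[[key]] + c(
      energy_kcal = g / 100 * co$energy / 4.184,
      sugars_g = g / 100 * co$sugars, satfat_g = g / 100 * co$satfat,
      sodium_mg = g / 100 * co$sodium, fiber_g = g / 100 * co$fiber,
      protein_g = g / 100 * co$protein)
  }
  out
}
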