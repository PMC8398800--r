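test_that("weighted aggregation is linear and additive under item splitting", {
  resp <- make_respondents(2)
  items <- make_items(c("P001", "P002"), energy_kcal = c(500, 1500),
                      total_fruits = c(0.2, 0.6))
  tot <- aggregate_components(items, resp)
  expect_equal(tot[["energy_kcal"]], 2000)
  expect_equal(tot[["total_fruits"]], 0.8)
  # doubling all weights doubles every total
  resp2 <- resp; resp2$day1_weight <- 2
  expect_equal(aggregate_components(items, resp2), 2 * tot)
  # splitting one item into two with halved amounts leaves totals unchanged
  split_items <- rbind(items[1, ], items[1, ], items[2, ])
  split_items$energy_kcal <- c(250, 250, 1500)
  split_items$total_fruits <- c(0.1, 0.1, 0.6)
  expect_equal(aggregate_components(split_items, resp), tot)
  # empty group gives zero totals
  expect_true(all(aggregate_components(items[0, ], resp) == 0))
  # missing weight is an error naming the respondent
  expect_error(aggregate_components(items, resp[1, , drop = FALSE]), "P002")
})

test_that("densities follow the population-ratio arithmetic", {
  resp <- make_respondents(1)
  items <- make_items("P001", energy_kcal = 2000, total_fruits = 1.6,
                      mufa_g = 20, pufa_g = 10, sfa_g = 12,
                      added_sugars_tsp = 25, sodium_mg = 3000)
  d <- pop_ratio_density(aggregate_components(items, resp))
  expect_equal(d[["total_fruits"]], 0.8)
  expect_equal(d[["fatty_acids"]], 2.5)
  expect_equal(d[["added_sugars"]], 20)          # 25 tsp * 16 kcal / 2000 * 100
  expect_equal(d[["sodium"]], 1.5)               # 3 g over 2 x 1000 kcal
  expect_equal(d[["saturated_fats"]], 12 * 9 / 2000 * 100)
  # zero energy refuses to score
  zero <- aggregate_components(items[0, ], resp)
  expect_error(pop_ratio_density(zero, group = "store"), "store")
  # degenerate fatty-acid denominators
  no_fat <- make_items("P001", energy_kcal = 1000)
  expect_equal(pop_ratio_density(aggregate_components(no_fat, resp))[["fatty_acids"]], 0)
  only_unsat <- make_items("P001", energy_kcal = 1000, mufa_g = 5)
  expect_equal(pop_ratio_density(aggregate_components(only_unsat, resp))[["fatty_acids"]], Inf)
})

test_that("component scoring is piecewise linear with floor and cap", {
  adequacy <- data.frame(component = "x", max_points = 5,
                         direction = "adequacy", unit = "u",
                         max_score_at = 0.8, zero_score_at = 0)
  expect_equal(score_component(0, adequacy), 0)
  expect_equal(score_component(0.8, adequacy), 5)
  expect_equal(score_component(2.5, adequacy), 5)
  expect_equal(score_component(0.4, adequacy), 2.5)
  moderation <- data.frame(component = "y", max_points = 10,
                           direction = "moderation", unit = "u",
                           max_score_at = 6.5, zero_score_at = 26)
  expect_equal(score_component(16.25, moderation), (26 - 16.25) / (26 - 6.5) * 10)
  expect_equal(score_component(30, moderation), 0)
  expect_equal(score_component(1, moderation), 10)
  degenerate <- adequacy; degenerate$zero_score_at <- 0.8
  expect_error(score_component(0.5, degenerate), "degenerate")
  # full-points ratio at infinite density
  ratio <- data.frame(component = "fa", max_points = 10, direction = "ratio",
                      unit = "u", max_score_at = 2.5, zero_score_at = 1.2)
  expect_equal(score_component(Inf, ratio), 10)
  expect_equal(score_component(0, ratio), 0)
})

test_that("monotonicity holds across all shipped standards", {
  std <- hei_standards()
  set.seed(1)
  for (i in seq_len(nrow(std))) {
    s <- std[i, , drop = FALSE]
    span <- abs(s$zero_score_at - s$max_score_at)
    d <- sort(runif(50, 0, max(s$zero_score_at, s$max_score_at) + 2 * span))
    sc <- score_component(d, s)
    expect_true(all(sc >= 0 & sc <= s$max_points))
    diffs <- diff(sc)
    if (s$direction == "moderation") {
      expect_true(all(diffs <= 1e-12))
    } else {
      expect_true(all(diffs >= -1e-12))
    }
  }
})

test_that("the fitted hei object carries scores, grade and methods", {
  cfg <- synthetic_config(n_respondents = 150, n_strata = 5)
  pop <- generate_recalls(cfg, seed = 5)
  fit <- hei(pop$items, pop$respondents, outlet = "store",
             cycle = "synthetic")
  expect_s3_class(fit, "hei")
  expect_length(coef(fit), 13)
  expect_equal(sum(coef(fit)), fit$total)
  expect_true(fit$total >= 0 && fit$total <= 100)
  expect_output(print(fit), "total")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.hei")
  expect_equal(nrow(sm$table), 13)
  expect_output(print(sm), "Total")
  expect_error(hei(pop$items[0, ], pop$respondents), "no items")
})

test_that("population ratio differs from mean of person ratios in general", {
  resp <- make_respondents(2)
  # person 1: tiny intake, perfect fruit density; person 2: large, none
  items <- make_items(c("P001", "P002"), energy_kcal = c(200, 3000),
                      total_fruits = c(0.8, 0))
  tot <- aggregate_components(items, resp)
  pop_density <- pop_ratio_density(tot)[["total_fruits"]]
  person_density <- c(0.8 / 0.2, 0) # per 1000 kcal, per person
  expect_false(isTRUE(all.equal(pop_density, mean(person_density))))
  # equality when energies are identical
  eq_items <- make_items(c("P001", "P002"), energy_kcal = c(1000, 1000),
                         total_fruits = c(0.8, 0))
  eq_pop <- pop_ratio_density(aggregate_components(eq_items, resp))[["total_fruits"]]
  expect_equal(eq_pop, mean(c(0.8, 0)))
})

test_that("letter grades follow the A-F bands with F covering [0, 60)", {
  expect_equal(hei_grade(65), "D")
  expect_equal(hei_grade(10, 10), "A")
  expect_equal(hei_grade(59.99), "F")
  expect_equal(hei_grade(c(95, 85, 75, 60, 0)),
               c("A", "B", "C", "D", "F"))
  expect_equal(hei_grade(4.5, 5), "A")
  expect_error(hei_grade(101), "outside")
})

test_that("calorie shares divide weighted energy across outlet buckets", {
  resp <- make_respondents(2, ages = c(30, 30))
  items <- make_items(c("P001", "P002"), energy_kcal = c(600, 400),
                      source_code = c("Grocery/supermarket",
                                      "Restaurant fast food/pizza"))
  sh <- suppressWarnings(calorie_shares(items, resp))
  row <- sh[sh$age_bin == "20-40", ]
  expect_equal(row$store, 60)
  expect_equal(row$quick_service, 40)
  expect_equal(sum(row[, -1]), 100)
  # single-outlet bin scores 100; weight scaling changes nothing
  resp2 <- resp; resp2$day1_weight <- 17
  expect_equal(suppressWarnings(calorie_shares(items, resp2))[, -1], sh[, -1])
  solo <- suppressWarnings(calorie_shares(items[1, ], resp))
  expect_equal(solo$store[solo$age_bin == "20-40"], 100)
  # empty bins are flagged and left at zero
  expect_warning(sh2 <- calorie_shares(items, resp), "no items")
  empty_rows <- sh2$age_bin != "20-40"
  expect_true(all(sh2[empty_rows, -1] == 0))
})
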