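test_that("replicate weights use the Fay factors on balanced half-samples", {
  resp <- make_respondents(8, n_strata = 2)
  rw <- build_replicates(resp, fay_k = 0.3)
  expect_equal(rw$R, 4)  # Hadamard order 4 for 2 strata
  factors <- rw$reps / rw$base
  expect_true(all(abs(factors - 1.7) < 1e-12 | abs(factors - 0.3) < 1e-12))
  # balance: replicate weights average back to the base weight
  expect_equal(unname(rowMeans(rw$reps)), unname(rw$base))
  # classic BRR at k = 0
  rw0 <- build_replicates(resp, fay_k = 0)
  f0 <- rw0$reps / rw0$base
  expect_true(all(abs(f0 - 2) < 1e-12 | abs(f0) < 1e-12))
  # within a stratum-replicate, the two PSUs get opposite factors
  s1 <- resp$stratum == 1
  for (r in seq_len(rw$R)) {
    got <- sort(unique(round(factors[s1, r][order(resp$psu[s1])], 6)))
    expect_equal(got, c(0.3, 1.7))
  }
  # single-PSU stratum is refused by name
  lone <- resp[resp$stratum == 2 | resp$psu == 1, ]
  expect_error(build_replicates(lone), "stratum '1'")
})

test_that("brr_se reproduces hand-computed and closed-form variances", {
  # deviations (1, -1, 1, -1) with R = 4, k = 0.3
  fake <- structure(list(base = c(v = 1),
                         reps = matrix(2:5, nrow = 1,
                                       dimnames = list("v", NULL)),
                         fay_k = 0.3, R = 4),
                    class = "brr_weights")
  lookup <- c(10, 11, 9, 11, 9)
  stat <- function(data, w) lookup[w]
  expect_equal(unname(brr_se(stat, NULL, fake)), sqrt(4 / (4 * 0.49)),
               tolerance = 1e-12)
  expect_equal(round(unname(brr_se(stat, NULL, fake)), 5), 1.42857)
  # all replicates equal the point estimate -> SE 0
  expect_equal(unname(brr_se(function(d, w) 42, NULL, fake)), 0)
  # order invariance
  shuffled <- fake
  shuffled$reps <- fake$reps[, c(3, 1, 4, 2), drop = FALSE]
  expect_equal(brr_se(stat, NULL, shuffled), brr_se(stat, NULL, fake))
})

test_that("BRR matches the textbook stratified estimator for a weighted total", {
  resp <- make_respondents(12, n_strata = 2,
                           weights = c(2, 1, 3, 1.5, 2, 1, 0.5, 2, 1, 1, 2, 3))
  y <- c(5, 3, 8, 2, 7, 4, 1, 6, 2, 9, 4, 3)
  names(y) <- resp$respondent_id
  rw <- build_replicates(resp, fay_k = 0.3)
  stat <- function(data, w) sum(w * y[names(w)])
  got <- unname(brr_se(stat, NULL, rw))
  # textbook two-PSU-per-stratum variance of a total: sum over strata of
  # the squared difference between the two PSU totals
  psu_tot <- tapply(resp$day1_weight * y, list(resp$stratum, resp$psu), sum)
  expected <- sqrt(sum((psu_tot[, 1] - psu_tot[, 2])^2))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("pairwise contrasts are symmetric and detect known gaps", {
  cfg <- make_null_config(n_respondents = 200, n_strata = 10)
  pop <- generate_recalls(cfg, seed = 21)
  rw <- build_replicates(pop$respondents)
  stat <- make_outlet_stat(pop$items, pop$respondents)
  ab <- pairwise_contrast(stat, NULL, rw, c("store", "school"))
  ba <- pairwise_contrast(stat, NULL, rw, c("school", "store"))
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$df, rw$df)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
  # identical groups: zero difference, p = 1
  same <- function(data, w) c(a = sum(w), b = sum(w))
  eq <- pairwise_contrast(same, NULL, rw, c("a", "b"))
  expect_equal(eq$estimate, 0)
  expect_equal(eq$p_value, 1)
  # a 10-point true gap at n = 2000 is found decisively
  std <- hei_standards()
  mid <- setNames(std$max_points / 2, std$component)
  hi <- mid + 10 * std$max_points / 100  # +10 total points, spread pro rata
  big <- synthetic_config(
    n_respondents = 2000, n_strata = 15,
    outlets = list(store = outlet_profile(scores = hi),
                   school = outlet_profile(scores = mid)),
    outlet_mix = c(store = 0.5, school = 0.5))
  pop2 <- generate_recalls(big, seed = 22)
  rw2 <- build_replicates(pop2$respondents)
  stat2 <- make_outlet_stat(pop2$items, pop2$respondents)
  gap <- pairwise_contrast(stat2, NULL, rw2, c("store", "school"))
  expect_true(gap$significant)
  expect_equal(gap$estimate, 10, tolerance = 0.2)
})

test_that("trend test recovers exact and injected linear trends", {
  resp <- make_respondents(12, n_strata = 3)
  rws <- lapply(1:4, function(i) build_replicates(resp))
  # cycle-level statistic independent of weights: exact fits
  const <- lapply(1:4, function(i) 7)
  tr0 <- trend_test(function(d, w) d, const, rws)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$p_value, 1)
  lin <- lapply(1:4, function(i) 3 + 2 * (i - 1))
  tr2 <- trend_test(function(d, w) d, lin, rws)
  expect_equal(tr2$slope, 2)
  expect_equal(tr2$se, 0)
  expect_error(trend_test(function(d, w) d, lin[1:2], rws[1:2]),
               "at least 3 cycles")
})
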