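# Shared builders for small in-code fixtures.

# A respondent table with unit weights and a 2-strata / 2-PSU design.
make_respondents <- function(n = 4, weights = rep(1, n), ages = rep(30, n),
                             n_strata = 2) {
  data.frame(
    respondent_id = sprintf("P%03d", seq_len(n)),
    cycle = "synthetic",
    age_years = ages,
    day1_weight = weights,
    stratum = ((seq_len(n) - 1) %% n_strata) + 1L,
    psu = (((seq_len(n) - 1) %/% n_strata) %% 2L) + 1L,
    recall_reliable = TRUE,
    consumes_human_milk = FALSE,
    stringsAsFactors = FALSE
  )
}

# Canonical item rows; amounts default to zero, overridable per column.
make_items <- function(respondent_id, energy_kcal,
                       source_code = "Grocery/supermarket", ...) {
  n <- length(energy_kcal)
  df <- data.frame(
    respondent_id = rep_len(respondent_id, n),
    cycle = "synthetic",
    source_code = rep_len(source_code, n),
    energy_kcal = energy_kcal,
    stringsAsFactors = FALSE
  )
  for (cc in item_components()) df[[cc]] <- 0
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

# Independent piecewise-linear scoring oracle built on stats::approx:
# clamped linear interpolation between the two cut-points, whatever the
# direction. Used to cross-check score_component.
oracle_score <- function(d, std) {
  xs <- c(std$zero_score_at, std$max_score_at)
  ys <- c(0, std$max_points)
  ord <- order(xs)
  d_cl <- pmin(pmax(d, min(xs)), max(xs))
  stats::approx(xs[ord], ys[ord], xout = d_cl)$y
}

# Mid-range synthetic config: every component at half its maximum, away from
# all scoring kinks; two analytic outlets drawn from the identical profile.
make_null_config <- function(n_respondents = 240, n_strata = 12, cv = 0.3) {
  std <- hei_standards()
  mid <- stats::setNames(std$max_points / 2, std$component)
  prof <- outlet_profile(scores = mid, energy_meanlog = log(180),
                         energy_sdlog = 0.7, cv = cv)
  synthetic_config(
    n_respondents = n_respondents, n_strata = n_strata,
    outlets = list(store = prof, school = prof),
    outlet_mix = c(store = 0.5, school = 0.5),
    items_per_person = 12
  )
}

# Whole-group HEI total as a reusable weighted statistic (precomputed
# matrix so replicate evaluation is a single weighted column sum).
make_group_stat <- function(items, respondents,
                            standards = hei_standards()) {
  cols <- c(item_components(), "energy_kcal")
  X <- as.matrix(items[, cols])
  idx <- match(items$respondent_id, respondents$respondent_id)
  function(data, w) {
    totals <- stats::setNames(colSums(X * w[idx]), cols)
    sum(score_densities(pop_ratio_density(totals), standards))
  }
}

# Precompute per-outlet matrices so a BRR statistic over both outlets is a
# pair of weighted column sums (fast enough to repeat across replicates).
make_outlet_stat <- function(items, respondents,
                             outlets = c("store", "school"),
                             standards = hei_standards()) {
  analytic <- map_source(items$source_code)$analytic
  cols <- c(item_components(), "energy_kcal")
  prep <- lapply(outlets, function(o) {
    sub <- items[analytic == o, , drop = FALSE]
    list(X = as.matrix(sub[, cols]),
         idx = match(sub$respondent_id, respondents$respondent_id))
  })
  names(prep) <- outlets
  function(data, w) {
    vapply(outlets, function(o) {
      p <- prep[[o]]
      totals <- stats::setNames(colSums(p$X * w[p$idx]), cols)
      sum(score_densities(pop_ratio_density(totals), standards))
    }, numeric(1))
  }
}
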