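#' Invert the piecewise-linear scoring map
#'
#' Returns, for each component, the density (in scoring units) at which the
#' component earns exactly the requested score. Since scoring is linear
#' between the cut-points, the inverse is
#' `zero_score_at + (score / max_points) * (max_score_at - zero_score_at)`
#' for every direction. Scores at the maximum map exactly onto
#' `max_score_at`.
#'
#' @param scores Named vector of target component scores.
#' @param standards Standards table.
#' @return Named vector of scoring-unit densities.
#' @export
densities_for_scores <- function(scores, standards = hei_standards()) {
  missing_s <- setdiff(standards$component, names(scores))
  if (length(missing_s)) {
    stop("scores lack component(s): ", paste(missing_s, collapse = ", "))
  }
  out <- vapply(seq_len(nrow(standards)), function(i) {
    std <- standards[i, ]
    s <- scores[[std$component]]
    if (s < 0 || s > std$max_points) {
      stop("target score out of range for ", std$component)
    }
    std$zero_score_at +
      (s / std$max_points) * (std$max_score_at - std$zero_score_at)
  }, numeric(1))
  setNames(out, standards$component)
}

# Scoring-unit densities (13) -> item-level amount densities per 1000 kcal
# (14 storage columns). The fatty-acid ratio is realised by splitting the
# required unsaturated fat equally between MUFA and PUFA.
.scoring_to_item_densities <- function(d) {
  sfa_g <- d[["saturated_fats"]] * 10 / .KCAL_PER_G_FAT
  unsat <- d[["fatty_acids"]] * sfa_g
  c(
    total_fruits = d[["total_fruits"]],
    whole_fruits = d[["whole_fruits"]],
    total_vegetables = d[["total_vegetables"]],
    greens_and_beans = d[["greens_and_beans"]],
    whole_grains = d[["whole_grains"]],
    refined_grains = d[["refined_grains"]],
    dairy = d[["dairy"]],
    total_protein = d[["total_protein"]],
    seafood_plant_protein = d[["seafood_plant_protein"]],
    mufa_g = unsat / 2,
    pufa_g = unsat / 2,
    sfa_g = sfa_g,
    sodium_mg = d[["sodium"]] * 1000,
    added_sugars_tsp = d[["added_sugars"]] * 10 / .KCAL_PER_TSP_ADDED_SUGAR
  )
}

# Item-amount densities per 1000 kcal (14) -> scoring-unit densities (13).
.item_to_scoring_densities <- function(d) {
  sfa <- d[["sfa_g"]]
  unsat <- d[["mufa_g"]] + d[["pufa_g"]]
  c(
    total_fruits = d[["total_fruits"]],
    whole_fruits = d[["whole_fruits"]],
    total_vegetables = d[["total_vegetables"]],
    greens_and_beans = d[["greens_and_beans"]],
    whole_grains = d[["whole_grains"]],
    dairy = d[["dairy"]],
    total_protein = d[["total_protein"]],
    seafood_plant_protein = d[["seafood_plant_protein"]],
    fatty_acids = if (sfa > 0) unsat / sfa else if (unsat > 0) Inf else 0,
    refined_grains = d[["refined_grains"]],
    sodium = d[["sodium_mg"]] / 1000,
    added_sugars = d[["added_sugars_tsp"]] * .KCAL_PER_TSP_ADDED_SUGAR / 10,
    saturated_fats = d[["sfa_g"]] * .KCAL_PER_G_FAT / 10
  )
}

#' Define one outlet's generative profile
#'
#' An outlet profile fixes the true (noise-free) amount density of every
#' canonical component per 1000 kcal, the lognormal item-energy
#' distribution, and the coefficient of variation of the multiplicative
#' item-level noise. Profiles are most conveniently built from target
#' component scores, which are inverted through the standards.
#'
#' @param scores Named vector of 13 target component scores (alternative to
#'   `item_densities`).
#' @param item_densities Named vector of the 14 amount densities per 1000
#'   kcal (storage units: cup/oz-eq, g, mg, tsp-eq).
#' @param energy_meanlog,energy_sdlog Lognormal parameters of item energy
#'   (kcal).
#' @param cv Coefficient of variation of the mean-1 gamma noise applied to
#'   each amount (0 = noise-free).
#' @param standards Standards table used to invert `scores`.
#' @return List with `item_densities`, `energy_meanlog`, `energy_sdlog`,
#'   `cv`.
#' @export
outlet_profile <- function(scores = NULL, item_densities = NULL,
                           energy_meanlog = log(180), energy_sdlog = 0.8,
                           cv = 0.3, standards = hei_standards()) {
  if (is.null(item_densities)) {
    if (is.null(scores)) stop("supply scores or item_densities")
    item_densities <-
      .scoring_to_item_densities(densities_for_scores(scores, standards))
  }
  missing_d <- setdiff(.ITEM_COMPONENTS, names(item_densities))
  if (length(missing_d)) {
    stop("item_densities lack: ", paste(missing_d, collapse = ", "))
  }
  if (any(item_densities < 0)) stop("densities must be non-negative")
  if (cv < 0) stop("cv must be non-negative")
  list(item_densities = item_densities[.ITEM_COMPONENTS],
       energy_meanlog = energy_meanlog, energy_sdlog = energy_sdlog,
       cv = cv)
}

# Target component scores near the 2017-2018 row of the published score
# table, used by the packaged demonstration profiles.
.paperlike_scores <- function() {
  comps <- hei_components()
  list(
    store = setNames(c(3.52, 5, 3.05, 3.10, 3.50, 5.85, 5, 5, 3.95,
                       7.02, 5.59, 5.50, 6.19), comps),
    school = setNames(c(5, 5, 2.17, 1.43, 7.24, 10, 3.57, 2.52, 2.10,
                        5.79, 5.76, 8.43, 6.0), comps),
    full_service = setNames(c(0.47, 0.53, 4.61, 4.25, 0.82, 3.83, 5, 5,
                              6.21, 5.63, 0.00, 5.11, 9.25), comps),
    quick_service = setNames(c(0.66, 0.84, 3.08, 1.87, 0.76, 5.64, 5, 2.32,
                               4.01, 2.79, 2.06, 2.83, 7.55), comps),
    other = setNames(c(2.77, 4.15, 3.24, 2.94, 2.68, 5.63, 5, 5, 4.16,
                       6.12, 4.23, 6.69, 4.95), comps)
  )
}

#' Configuration for the synthetic recall-data generator
#'
#' Describes an NHANES-like population: respondents assigned round-robin to
#' strata with two PSUs each, lognormal day-1 weights, Poisson item counts
#' split across outlets by an (optionally age-dependent) mixture, and
#' per-outlet item-energy and true-density profiles. The default outlet
#' profiles ("paperlike") place each outlet's expected scores near the
#' published 2017-2018 pattern (schools ~65, stores ~62, full-service ~51,
#' quick-service ~39 total points) and are for demonstration and testing
#' with known ground truth, not a reproduction of survey estimates.
#'
#' @param n_respondents Number of respondents.
#' @param n_strata Number of design strata (two PSUs each).
#' @param cycle Cycle label stamped on the records (the shipped dictionary's
#'   `"synthetic"` cycle maps columns one-to-one).
#' @param outlets Named list of [outlet_profile()]s keyed by detailed outlet
#'   category.
#' @param outlet_mix Either a named probability vector over `names(outlets)`
#'   or a matrix with one row per age bin (see `age_breaks`), rows summing
#'   to 1.
#' @param age_breaks Left edges of the age bins indexing `outlet_mix` rows.
#' @param items_per_person Poisson mean of the per-respondent item count.
#' @param weight_meanlog,weight_sdlog Lognormal parameters of the day-1
#'   weights.
#' @param age_range Uniform age range of respondents (years).
#' @return Validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_respondents = 2000, n_strata = 15,
                             cycle = "synthetic",
                             outlets = NULL, outlet_mix = NULL,
                             age_breaks = c(2, 6, 12, 20, 41, 51, 71),
                             items_per_person = 15,
                             weight_meanlog = 0, weight_sdlog = 0.3,
                             age_range = c(2, 85)) {
  if (is.null(outlets)) {
    targets <- .paperlike_scores()
    energy <- list(store = c(log(150), 0.9), school = c(log(120), 0.7),
                   full_service = c(log(280), 0.8),
                   quick_service = c(log(250), 0.8), other = c(log(130), 0.9))
    outlets <- lapply(names(targets), function(o) {
      outlet_profile(scores = targets[[o]],
                     energy_meanlog = energy[[o]][1],
                     energy_sdlog = energy[[o]][2])
    })
    names(outlets) <- names(targets)
  }
  if (is.null(outlet_mix)) {
    defaults <- c(store = 0.70, school = 0.05, full_service = 0.08,
                  quick_service = 0.15, other = 0.02)
    outlet_mix <- defaults[names(outlets)]
    if (anyNA(outlet_mix)) {
      outlet_mix <- setNames(rep(1 / length(outlets), length(outlets)),
                             names(outlets))
    }
    outlet_mix <- outlet_mix / sum(outlet_mix)
  }
  cfg <- structure(list(
    n_respondents = n_respondents, n_strata = n_strata, cycle = cycle,
    outlets = outlets, outlet_mix = outlet_mix, age_breaks = age_breaks,
    items_per_person = items_per_person, weight_meanlog = weight_meanlog,
    weight_sdlog = weight_sdlog, age_range = age_range
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic-data configuration
#'
#' @param config A `"synthetic_config"` object.
#' @return The config, invisibly, or an error before any generation.
#' @export
validate_synthetic_config <- function(config) {
  with(config, {
    if (n_respondents < 1) stop("n_respondents must be positive")
    if (n_strata < 1 || n_respondents < 2 * n_strata) {
      stop("need at least 2 respondents per stratum")
    }
    if (!length(outlets) || is.null(names(outlets))) {
      stop("outlets must be a named list")
    }
    mix <- if (is.matrix(outlet_mix)) outlet_mix else
      matrix(outlet_mix, nrow = 1, dimnames = list(NULL, names(outlet_mix)))
    if (!setequal(colnames(mix), names(outlets))) {
      stop("outlet_mix names must match outlets")
    }
    if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8)) {
      stop("outlet_mix rows must be probabilities summing to 1")
    }
    if (is.matrix(outlet_mix) && nrow(outlet_mix) != length(age_breaks)) {
      stop("outlet_mix needs one row per age bin")
    }
    for (o in names(outlets)) {
      p <- outlets[[o]]
      if (any(p$item_densities < 0)) stop("negative density in outlet ", o)
      if (p$cv < 0) stop("negative cv in outlet ", o)
    }
    if (items_per_person <= 0) stop("items_per_person must be positive")
  })
  invisible(config)
}

#' Generate synthetic recall microdata
#'
#' Draws a population from a [synthetic_config()]: respondents are assigned
#' round-robin to `n_strata` strata with PSUs alternating within stratum;
#' day-1 weights are lognormal; each respondent reports a Poisson number of
#' items allocated across outlets by the (age-bin) mixture; item energy is
#' lognormal per outlet; and every amount is
#' `energy/1000 * true_density * noise` with mean-1 gamma noise of the
#' configured CV, so the population-ratio density of any large group
#' converges to the configured truth (and equals it exactly at `cv = 0`).
#' Each item's `source_code` is a label drawn from the outlet's detailed
#' category in the mapping table. Output is fully reproducible from `seed`.
#'
#' @param config A validated `"synthetic_config"`.
#' @param seed Integer seed.
#' @return List with data.frames `respondents` and `items` in the canonical
#'   layouts read by the package.
#' @export
generate_recalls <- function(config, seed = 1) {
  validate_synthetic_config(config)
  set.seed(seed)
  n <- config$n_respondents
  resp <- data.frame(
    respondent_id = sprintf("R%06d", seq_len(n)),
    cycle = config$cycle,
    age_years = runif(n, config$age_range[1], config$age_range[2]),
    day1_weight = rlnorm(n, config$weight_meanlog, config$weight_sdlog),
    stratum = ((seq_len(n) - 1) %% config$n_strata) + 1L,
    psu = (((seq_len(n) - 1) %/% config$n_strata) %% 2L) + 1L,
    recall_reliable = TRUE,
    consumes_human_milk = FALSE,
    stringsAsFactors = FALSE
  )
  mix <- config$outlet_mix
  if (!is.matrix(mix)) {
    mix <- matrix(mix, nrow = 1, dimnames = list(NULL, names(mix)))
    bin_of <- rep(1L, n)
  } else {
    bin_of <- findInterval(resp$age_years, config$age_breaks)
    bin_of[bin_of < 1] <- 1L
  }
  counts <- rpois(n, config$items_per_person)
  m <- sum(counts)
  item_resp <- rep(seq_len(n), counts)
  outlet <- character(m)
  for (b in seq_len(nrow(mix))) {
    sel <- bin_of[item_resp] == b
    if (any(sel)) {
      outlet[sel] <- sample(colnames(mix), sum(sel), replace = TRUE,
                            prob = mix[b, ])
    }
  }
  src_table <- outlet_sources()
  items <- data.frame(
    respondent_id = resp$respondent_id[item_resp],
    cycle = config$cycle,
    source_code = character(m),
    energy_kcal = numeric(m),
    stringsAsFactors = FALSE
  )
  for (cc in .ITEM_COMPONENTS) items[[cc]] <- numeric(m)
  for (o in names(config$outlets)) {
    sel <- outlet == o
    if (!any(sel)) next
    prof <- config$outlets[[o]]
    k <- sum(sel)
    labels <- src_table$label[src_table$detailed == o]
    if (!length(labels)) stop("no source labels for outlet category ", o)
    items$source_code[sel] <- sample(labels, k, replace = TRUE)
    energy <- rlnorm(k, prof$energy_meanlog, prof$energy_sdlog)
    items$energy_kcal[sel] <- energy
    for (cc in .ITEM_COMPONENTS) {
      noise <- if (prof$cv > 0) {
        rgamma(k, shape = 1 / prof$cv^2, rate = 1 / prof$cv^2)
      } else 1
      items[[cc]][sel] <- energy / 1000 * prof$item_densities[[cc]] * noise
    }
  }
  list(respondents = resp, items = items)
}

#' Expected HEI scores implied by a configuration
#'
#' Scores each outlet's configured true densities directly against the
#' standards — the values the pipeline's population-ratio estimates converge
#' to as the sample grows (the noise has mean 1).
#'
#' @param config A `"synthetic_config"`.
#' @param standards Standards table.
#' @return Named list per outlet, each with `scores` (13 components) and
#'   `total`.
#' @export
expected_scores <- function(config, standards = hei_standards()) {
  lapply(config$outlets, function(prof) {
    dens <- .item_to_scoring_densities(prof$item_densities)
    s <- score_densities(dens, standards)
    list(scores = s, total = sum(s))
  })
}
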