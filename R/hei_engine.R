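#' Weighted component totals for a group of items
#'
#' The first step of the population ratio method: every item amount and its
#' energy are summed over the group with each item weighted by its
#' respondent's day-1 sampling weight, giving the group's weighted total
#' pattern equivalents and energy.
#'
#' @param items Linked item data.frame (canonical amount columns +
#'   `energy_kcal`).
#' @param weights Either a numeric vector named by respondent id, or a
#'   respondent data.frame carrying `respondent_id` and `day1_weight`.
#' @return Named numeric vector of weighted sums over the 14 amount columns
#'   and `energy_kcal`.
#' @export
aggregate_components <- function(items, weights) {
  if (is.data.frame(weights)) {
    weights <- setNames(weights$day1_weight,
                        as.character(weights$respondent_id))
  }
  cols <- c(.ITEM_COMPONENTS, "energy_kcal")
  missing_cols <- setdiff(cols, names(items))
  if (length(missing_cols)) {
    stop("items lack canonical column(s): ",
         paste(missing_cols, collapse = ", "), "; run link_components first")
  }
  if (!nrow(items)) return(setNames(numeric(length(cols)), cols))
  w <- weights[as.character(items$respondent_id)]
  if (anyNA(w)) {
    stop("no weight for respondent(s): ",
         paste(unique(items$respondent_id[is.na(w)]), collapse = ", "))
  }
  vapply(cols, function(cc) sum(w * items[[cc]]), numeric(1))
}

#' Population-ratio densities from weighted totals
#'
#' Converts weighted group totals into the densities the HEI-2015 scores:
#' amounts per 1000 kcal for the food groups and refined grains; grams per
#' 1000 kcal for sodium; percent of energy for added sugars (16 kcal per
#' tsp-eq) and saturated fat (9 kcal per g); and the dimensionless
#' (MUFA+PUFA)/SFA fatty-acid ratio. A group with zero SFA but positive
#' unsaturated fat has an infinite ratio (full points downstream); zero of
#' both gives a zero ratio.
#'
#' @param totals Named totals from [aggregate_components()].
#' @param group Optional group label used in error messages.
#' @return Named numeric vector of 13 densities in scoring units.
#' @export
pop_ratio_density <- function(totals, group = NULL) {
  energy <- totals[["energy_kcal"]]
  if (!is.finite(energy) || energy <= 0) {
    stop("group ", if (!is.null(group)) paste0("'", group, "' "),
         "has non-positive total energy; cannot form densities")
  }
  per1000 <- function(x) x / (energy / 1000)
  pct_energy <- function(kcal) 100 * kcal / energy
  sfa <- totals[["sfa_g"]]
  unsat <- totals[["mufa_g"]] + totals[["pufa_g"]]
  fa_ratio <- if (sfa > 0) unsat / sfa else if (unsat > 0) Inf else 0
  c(
    total_fruits = per1000(totals[["total_fruits"]]),
    whole_fruits = per1000(totals[["whole_fruits"]]),
    total_vegetables = per1000(totals[["total_vegetables"]]),
    greens_and_beans = per1000(totals[["greens_and_beans"]]),
    whole_grains = per1000(totals[["whole_grains"]]),
    dairy = per1000(totals[["dairy"]]),
    total_protein = per1000(totals[["total_protein"]]),
    seafood_plant_protein = per1000(totals[["seafood_plant_protein"]]),
    fatty_acids = fa_ratio,
    refined_grains = per1000(totals[["refined_grains"]]),
    sodium = per1000(totals[["sodium_mg"]] / 1000),
    added_sugars =
      pct_energy(totals[["added_sugars_tsp"]] * .KCAL_PER_TSP_ADDED_SUGAR),
    saturated_fats = pct_energy(totals[["sfa_g"]] * .KCAL_PER_G_FAT)
  )
}

#' Score one component density against its standard
#'
#' Piecewise-linear HEI-2015 scoring: adequacy and ratio components earn
#' `max_points * clamp((d - zero_at) / (max_at - zero_at), 0, 1)`; moderation
#' components earn `max_points * clamp((zero_at - d) / (zero_at - max_at),
#' 0, 1)`. Vectorised over `density`.
#'
#' @param density Density value(s) in the standard's unit (`Inf` allowed for
#'   the fatty-acid ratio).
#' @param standard One row of a standards table.
#' @return Score(s) in `[0, max_points]`.
#' @export
score_component <- function(density, standard) {
  if (standard$max_score_at == standard$zero_score_at) {
    stop("degenerate standard for ", standard$component)
  }
  frac <- if (standard$direction %in% c("adequacy", "ratio")) {
    (density - standard$zero_score_at) /
      (standard$max_score_at - standard$zero_score_at)
  } else {
    (standard$zero_score_at - density) /
      (standard$zero_score_at - standard$max_score_at)
  }
  frac[is.nan(frac)] <- 1  # Inf density on a ratio component
  standard$max_points * pmin(pmax(frac, 0), 1)
}

#' Score a full density set
#'
#' @param densities Named density vector from [pop_ratio_density()].
#' @param standards Standards table.
#' @return Named vector of 13 component scores in the standards' row order.
#' @export
score_densities <- function(densities, standards = hei_standards()) {
  missing_d <- setdiff(standards$component, names(densities))
  if (length(missing_d)) {
    stop("densities lack component(s): ", paste(missing_d, collapse = ", "))
  }
  scores <- vapply(seq_len(nrow(standards)), function(i) {
    score_component(densities[[standards$component[i]]],
                    standards[i, , drop = FALSE])
  }, numeric(1))
  setNames(scores, standards$component)
}

#' Fit HEI-2015 population-ratio scores for a group of foods
#'
#' The central fitting function: selects the items of one outlet (or the
#' all-outlets aggregate) in one survey cycle, forms weighted totals with the
#' respondents' day-1 weights, converts them to densities and scores them
#' against the HEI-2015 standards. When a replicate-weight set is supplied,
#' every component score and the total are re-estimated under each
#' Fay-adjusted replicate and BRR standard errors are attached.
#'
#' @param items Linked item data.frame.
#' @param respondents Respondent data.frame (weights, and design variables if
#'   `replicates` were built from it).
#' @param outlet `"store"`, `"school"`, `"full_service"`, `"quick_service"`
#'   or `"all_outlets"`.
#' @param cycle Optional cycle label to restrict to.
#' @param standards Standards table ([hei_standards()] by default).
#' @param replicates Optional `"brr_weights"` object from
#'   [build_replicates()] on the same respondents.
#' @param source_table Outlet mapping table.
#' @return An object of class `"hei"`: list with `scores` (13 components),
#'   `total`, `grade`, `densities`, `totals`, `se` (or NULL), `group`,
#'   `n_items`, `n_respondents`, `standards`.
#' @examples
#' cfg <- synthetic_config(n_respondents = 100)
#' pop <- generate_recalls(cfg, seed = 1)
#' fit <- hei(pop$items, pop$respondents, outlet = "store")
#' fit$total
#' @export
hei <- function(items, respondents, outlet = "all_outlets", cycle = NULL,
                standards = hei_standards(), replicates = NULL,
                source_table = outlet_sources()) {
  validate_standards(standards)
  group_items <- select_group(items, outlet, cycle = cycle,
                              table = source_table)
  if (!nrow(group_items)) {
    stop("no items in group (outlet=", outlet,
         if (!is.null(cycle)) paste0(", cycle=", cycle), ")")
  }
  base_w <- setNames(respondents$day1_weight,
                     as.character(respondents$respondent_id))
  group_label <- paste0(outlet, if (!is.null(cycle)) paste0("/", cycle))
  score_with <- function(w) {
    totals <- aggregate_components(group_items, w)
    dens <- pop_ratio_density(totals, group = group_label)
    score_densities(dens, standards)
  }
  totals <- aggregate_components(group_items, base_w)
  densities <- pop_ratio_density(totals, group = group_label)
  scores <- score_densities(densities, standards)
  total <- sum(scores)
  se <- NULL
  if (!is.null(replicates)) {
    stat <- function(data, w) {
      s <- score_with(setNames(w, names(replicates$base)))
      c(s, total = sum(s))
    }
    se <- brr_se(stat, NULL, replicates)
  }
  structure(list(
    scores = scores,
    total = total,
    grade = hei_grade(total, sum(standards$max_points)),
    densities = densities,
    totals = totals,
    se = se,
    group = list(outlet = outlet, cycle = cycle),
    n_items = nrow(group_items),
    n_respondents = length(unique(group_items$respondent_id)),
    standards = standards
  ), class = "hei")
}

#' @export
print.hei <- function(x, ...) {
  cat("HEI-2015 population-ratio score\n")
  cat("  group : ", x$group$outlet,
      if (!is.null(x$group$cycle)) paste0(" (", x$group$cycle, ")"), "\n",
      sep = "")
  cat("  items : ", x$n_items, " from ", x$n_respondents, " respondents\n",
      sep = "")
  cat(sprintf("  total : %.2f / %d  (grade %s)\n", x$total,
              sum(x$standards$max_points), x$grade))
  if (!is.null(x$se)) {
    cat(sprintf("  BRR SE of total: %.3f\n", x$se[["total"]]))
  }
  invisible(x)
}

#' @export
summary.hei <- function(object, ...) {
  std <- object$standards
  tab <- data.frame(
    component = std$component,
    max_points = std$max_points,
    density = unname(object$densities[std$component]),
    score = unname(object$scores[std$component]),
    pct_of_max = unname(100 * object$scores[std$component] / std$max_points),
    grade = hei_grade(unname(object$scores[std$component]), std$max_points),
    stringsAsFactors = FALSE
  )
  if (!is.null(object$se)) tab$se <- unname(object$se[std$component])
  structure(list(table = tab, total = object$total, grade = object$grade,
                 total_se = if (!is.null(object$se)) object$se[["total"]],
                 group = object$group),
            class = "summary.hei")
}

#' @export
print.summary.hei <- function(x, digits = 2, ...) {
  cat("HEI-2015 component scores (", x$group$outlet,
      if (!is.null(x$group$cycle)) paste0(", ", x$group$cycle), ")\n\n",
      sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nTotal: %.2f (grade %s)", x$total, x$grade))
  if (!is.null(x$total_se)) cat(sprintf("  SE %.3f", x$total_se))
  cat("\n")
  invisible(x)
}

#' @export
coef.hei <- function(object, ...) object$scores

#' @export
plot.hei <- function(x, ...) {
  radar_plot(list(x), ...)
}

#' Letter grade for an HEI score
#'
#' Grades a total or component score as a percentage of its maximum:
#' 90-100\% "A", 80-89.99 "B", 70-79.99 "C", 60-69.99 "D", below 60 "F".
#'
#' @param score Score value(s).
#' @param max_possible Maximum attainable (100 for the total).
#' @return Character vector of letter grades.
#' @examples
#' hei_grade(65)   # "D"
#' @export
hei_grade <- function(score, max_possible = 100) {
  if (any(score < 0 | score > max_possible)) {
    stop("score outside [0, max_possible]")
  }
  pct <- 100 * score / max_possible
  cut_levels <- c("F", "D", "C", "B", "A")
  as.character(cut(pct, breaks = c(-Inf, 60, 70, 80, 90, Inf),
                   labels = cut_levels, right = FALSE))
}

#' Share of calories by outlet and age group
#'
#' For each age bin, the weighted calories obtained from each detailed outlet
#' category divided by the weighted calories across all outlets, times 100.
#' Every item belongs to exactly one of the seven detailed buckets, so rows
#' sum to 100 (empty bins yield a zero row and a warning).
#'
#' @param items Linked item data.frame.
#' @param respondents Respondent data.frame (ages and weights).
#' @param age_breaks Left edges of the age bins; the last bin is open-ended.
#'   Defaults to the 2-5, 6-11, 12-19, 20-40, 41-50, 51-70, 71+ grouping.
#' @param table Outlet mapping table.
#' @return data.frame: one row per age bin, one percent column per detailed
#'   category.
#' @export
calorie_shares <- function(items, respondents,
                           age_breaks = c(2, 6, 12, 20, 41, 51, 71),
                           table = outlet_sources()) {
  breaks <- c(age_breaks, Inf)
  bin_labels <- paste0(age_breaks, "-",
                       c(age_breaks[-1] - 1, Inf))
  bin_labels[length(bin_labels)] <- paste0(age_breaks[length(age_breaks)], "+")
  ages <- setNames(respondents$age_years,
                   as.character(respondents$respondent_id))
  w <- setNames(respondents$day1_weight,
                as.character(respondents$respondent_id))
  id <- as.character(items$respondent_id)
  bin <- cut(ages[id], breaks = breaks, labels = bin_labels, right = FALSE)
  detailed <- factor(map_source(items$source_code, table)$detailed,
                     levels = .detailed_levels())
  kcal_w <- w[id] * items$energy_kcal
  totals <- tapply(kcal_w, list(bin, detailed), sum, default = 0)
  totals[is.na(totals)] <- 0
  row_sums <- rowSums(totals)
  empty <- row_sums == 0
  if (any(empty)) {
    warning("age bin(s) with no items: ",
            paste(rownames(totals)[empty], collapse = ", "))
    row_sums[empty] <- 1  # leave the zero row as zeros
  }
  shares <- 100 * sweep(totals, 1, row_sums, "/")
  out <- data.frame(age_bin = rownames(shares), shares,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
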