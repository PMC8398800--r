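#' Food-source to outlet-category mapping table
#'
#' Loads the editable two-way table mapping each food-source label (and its
#' numeric survey code) to one of seven mutually exclusive detailed outlet
#' categories: store, school, full_service, quick_service,
#' community_food_program, homegrown, other. The analytic category collapses
#' the last three to `none`; stores, schools and the two restaurant types are
#' the four analytic outlets. Labels not present in the table are never
#' silently bucketed — mapping an unknown label is an error.
#'
#' @param path Mapping CSV (`code,label,detailed`); defaults to the shipped
#'   file transcribed from the survey's source-of-food option list.
#' @return data.frame with columns `code`, `label`, `detailed`, `analytic`.
#' @export
outlet_sources <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "outlet_sources.csv", package = "heipop")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("code", "label", "detailed")
  if (!all(req %in% names(tab))) {
    stop("outlet table needs columns: ", paste(req, collapse = ", "))
  }
  valid <- c("store", "school", "full_service", "quick_service",
             "community_food_program", "homegrown", "other")
  bad <- setdiff(tab$detailed, valid)
  if (length(bad)) stop("unknown detailed categories: ",
                        paste(bad, collapse = ", "))
  analytic_set <- c("store", "school", "full_service", "quick_service")
  tab$analytic <- ifelse(tab$detailed %in% analytic_set, tab$detailed, "none")
  tab
}

.detailed_levels <- function() {
  c("store", "school", "full_service", "quick_service",
    "community_food_program", "homegrown", "other")
}

.normalize_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Map food-source labels or codes to outlet categories
#'
#' Deterministically maps each source label (string) or numeric source code
#' to its detailed and analytic outlet category. Unknown values raise an
#' error listing them.
#'
#' @param source Vector of source labels or numeric codes.
#' @param table Mapping table from [outlet_sources()].
#' @return data.frame with one row per input and columns `detailed`,
#'   `analytic`.
#' @examples
#' map_source("Restaurant fast food/pizza")$detailed  # "quick_service"
#' @export
map_source <- function(source, table = outlet_sources()) {
  if (is.numeric(source) ||
      all(grepl("^[0-9]+$", as.character(source[!is.na(source)])))) {
    idx <- match(as.numeric(as.character(source)), table$code)
  } else {
    idx <- match(.normalize_label(as.character(source)),
                 .normalize_label(table$label))
  }
  if (anyNA(idx)) {
    unknown <- unique(as.character(source)[is.na(idx)])
    stop("unknown food-source value(s): ", paste(unknown, collapse = "; "))
  }
  data.frame(detailed = table$detailed[idx], analytic = table$analytic[idx],
             stringsAsFactors = FALSE)
}

#' Tabulate detailed outlet categories, optionally by cycle
#'
#' Counts mapped items per detailed category (all seven levels always
#' present) and, when the item table has a `cycle` column, per cycle.
#'
#' @param items Item data.frame with a `source_code` column.
#' @param by_cycle Cross-tabulate against the `cycle` column?
#' @param table Mapping table.
#' @return A contingency table (category, or category x cycle).
#' @export
tabulate_categories <- function(items, by_cycle = FALSE,
                                table = outlet_sources()) {
  detailed <- factor(character(0), levels = .detailed_levels())
  if (nrow(items)) {
    detailed <- factor(map_source(items$source_code, table)$detailed,
                       levels = .detailed_levels())
  }
  if (by_cycle) {
    if (!"cycle" %in% names(items)) stop("items have no cycle column")
    base::table(category = detailed, cycle = items$cycle)
  } else {
    base::table(category = detailed)
  }
}

#' Select the items of one analytic outlet (or the all-outlets aggregate)
#'
#' `"all_outlets"` returns every item, including those from community food
#' programs, homegrown food and other sources; a named analytic outlet
#' returns the items whose source maps to it.
#'
#' @param items Item data.frame.
#' @param outlet One of `"store"`, `"school"`, `"full_service"`,
#'   `"quick_service"`, `"all_outlets"`.
#' @param cycle Optional cycle filter (requires a `cycle` column).
#' @param table Mapping table.
#' @return The item subset.
#' @export
select_group <- function(items, outlet, cycle = NULL,
                         table = outlet_sources()) {
  allowed <- c("store", "school", "full_service", "quick_service",
               "all_outlets")
  if (!outlet %in% allowed) {
    stop("unknown outlet '", outlet, "'; expected one of: ",
         paste(allowed, collapse = ", "))
  }
  if (!is.null(cycle)) {
    if (!"cycle" %in% names(items)) stop("items have no cycle column")
    items <- items[items$cycle == cycle, , drop = FALSE]
  }
  if (outlet == "all_outlets" || !nrow(items)) return(items)
  analytic <- map_source(items$source_code, table)$analytic
  items[analytic == outlet, , drop = FALSE]
}
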