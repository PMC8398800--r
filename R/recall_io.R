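#' Read a respondent (demographics + design) table
#'
#' Reads one row per respondent from CSV or SAS transport (XPT). The table
#' must carry the canonical columns `respondent_id`, `cycle`, `age_years`,
#' `day1_weight`, `stratum`, `psu`, `recall_reliable`,
#' `consumes_human_milk`; survey-specific column names (which drift across
#' NHANES cycles) are renamed through `col_map` rather than hard-coded.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"xpt"`.
#' @param col_map Optional named character vector mapping canonical names to
#'   source column names, e.g. `c(day1_weight = "WTDRD1", stratum =
#'   "SDMVSTRA", psu = "SDMVPSU")`.
#' @return A data.frame of respondents with the canonical columns.
#' @export
read_respondents <- function(path, format = c("auto", "csv", "xpt"),
                             col_map = NULL) {
  df <- .read_table(path, match.arg(format))
  df <- .apply_col_map(df, col_map)
  req <- c("respondent_id", "cycle", "age_years", "day1_weight", "stratum",
           "psu", "recall_reliable", "consumes_human_milk")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("respondent file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$respondent_id <- as.character(df$respondent_id)
  df$recall_reliable <- .as_logical(df$recall_reliable, "recall_reliable")
  df$consumes_human_milk <-
    .as_logical(df$consumes_human_milk, "consumes_human_milk")
  bad <- which(is.na(df$day1_weight) | df$day1_weight < 0)
  if (length(bad)) {
    stop("negative or missing day1_weight at row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(is.na(df$age_years) | df$age_years < 0)
  if (length(bad)) {
    stop("negative or missing age_years at row(s): ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a raw food-item table
#'
#' Reads item-level recall rows (one reported food/beverage per row) from CSV
#' or XPT. Only `respondent_id`, `source_code` and `energy_kcal` are required
#' here; pattern-equivalent columns stay in whatever per-cycle naming the
#' source uses until [link_components()] canonicalises them.
#'
#' @inheritParams read_respondents
#' @return A data.frame of raw item rows.
#' @export
read_food_items <- function(path, format = c("auto", "csv", "xpt"),
                            col_map = NULL) {
  df <- .read_table(path, match.arg(format))
  df <- .apply_col_map(df, col_map)
  req <- c("respondent_id", "source_code", "energy_kcal")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("food-item file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$respondent_id <- as.character(df$respondent_id)
  bad <- which(!is.na(df$energy_kcal) & df$energy_kcal < 0)
  if (length(bad)) {
    stop("negative energy_kcal at row(s): ", paste(bad, collapse = ", "))
  }
  df
}

.read_table <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xpt$", path, ignore.case = TRUE)) "xpt" else "csv"
  }
  if (format == "xpt") {
    df <- foreign::read.xport(path)
    names(df) <- tolower(names(df))
    df
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

.apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canonical in names(col_map)) {
    src <- col_map[[canonical]]
    hit <- match(tolower(src), tolower(names(df)))
    if (is.na(hit)) stop("mapped column not found in file: ", src)
    names(df)[hit] <- canonical
  }
  df
}

.as_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- x %in% c(1, "1", "TRUE", "true", "T", "yes")
  bad <- !(x %in% c(0, 1, "0", "1", "TRUE", "FALSE", "true", "false",
                    "T", "F", "yes", "no"))
  if (any(bad)) stop("column ", name, " is not interpretable as logical")
  out
}

#' Per-cycle component dictionary
#'
#' Loads the dictionary mapping each canonical component to the source
#' column(s) holding it in a given survey cycle. The `source` field is either
#' a single column name or a small linear expression over column names
#' (`+`/`-` separated terms, each optionally scaled, e.g.
#' `"F_TOTAL-F_JUICE"`), which is how derived quantities such as whole fruits
#' or the legume additions into vegetables and protein are expressed.
#'
#' @param path Dictionary CSV; defaults to the shipped file, which covers the
#'   `"synthetic"` identity cycle and a 2017-2018 FPED example.
#' @return data.frame with columns `cycle`, `canonical`, `source`.
#' @export
component_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "component_dictionary.csv",
                        package = "heipop")
  }
  dict <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cycle", "canonical", "source")
  if (!all(req %in% names(dict))) {
    stop("dictionary needs columns: ", paste(req, collapse = ", "))
  }
  key <- paste(dict$cycle, dict$canonical)
  if (anyDuplicated(key)) {
    stop("dictionary maps a canonical name more than once within a cycle")
  }
  dict
}

# Evaluate one dictionary expression ("A", "A+B", "A-B", "A+B*0.5") against
# the raw item table. Returns list(values, n_missing, all_na): NA cells are
# imputed to 0 (absence encodes "none consumed") and counted.
.eval_source_expr <- function(expr, items) {
  expr <- gsub(" ", "", expr)
  # split into signed terms
  terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
  values <- numeric(nrow(items))
  n_missing <- 0L
  na_all <- rep(TRUE, nrow(items))
  for (term in terms) {
    sign <- if (startsWith(term, "-")) -1 else 1
    term <- sub("^[+-]", "", term)
    parts <- strsplit(term, "*", fixed = TRUE)[[1]]
    scale <- 1
    col <- parts[[1]]
    if (length(parts) == 2) {
      if (grepl("^[0-9.]+$", parts[[1]])) {
        scale <- as.numeric(parts[[1]]); col <- parts[[2]]
      } else {
        scale <- as.numeric(parts[[2]])
      }
    }
    hit <- match(tolower(col), tolower(names(items)))
    if (is.na(hit)) stop("dictionary references missing item column: ", col)
    v <- items[[hit]]
    miss <- is.na(v)
    n_missing <- n_missing + sum(miss)
    na_all <- na_all & miss
    v[miss] <- 0
    values <- values + sign * scale * v
  }
  list(values = values, n_missing = n_missing, all_na = na_all)
}

#' Link raw item rows to canonical pattern-equivalent components
#'
#' Resolves, for one survey cycle, every canonical component (the 14 amounts
#' plus `energy_kcal`) from the raw columns named in the dictionary, so that
#' downstream scoring never sees cycle-specific column names. Missing cells
#' are imputed to zero (recall files encode "none consumed" as absence) and
#' the imputed count is reported to stderr, as is the count of rows whose
#' every referenced source cell was missing (unmatched rows).
#'
#' @param items Raw item data.frame (from [read_food_items()]).
#' @param dictionary Dictionary data.frame (from [component_dictionary()]).
#' @param cycle Cycle label to link under.
#' @return A data.frame with `respondent_id`, `source_code`, `cycle`,
#'   `energy_kcal` and the 14 canonical amount columns.
#' @export
link_components <- function(items, dictionary = component_dictionary(),
                            cycle) {
  dict <- dictionary[dictionary$cycle == cycle, , drop = FALSE]
  if (!nrow(dict)) stop("cycle not covered by dictionary: ", cycle)
  canon <- c(.ITEM_COMPONENTS, "energy_kcal")
  missing_canon <- setdiff(canon, dict$canonical)
  if (length(missing_canon)) {
    stop("dictionary for cycle ", cycle, " lacks canonical component(s): ",
         paste(missing_canon, collapse = ", "))
  }
  out <- data.frame(
    respondent_id = as.character(items$respondent_id),
    source_code = items$source_code,
    cycle = cycle,
    stringsAsFactors = FALSE
  )
  n_imputed <- 0L
  unmatched <- rep(TRUE, nrow(items))
  for (cc in canon) {
    expr <- dict$source[dict$canonical == cc]
    ev <- .eval_source_expr(expr, items)
    if (any(ev$values < 0)) {
      # derived differences (e.g. total minus juice) can round below zero
      ev$values <- pmax(ev$values, 0)
    }
    out[[cc]] <- ev$values
    n_imputed <- n_imputed + ev$n_missing
    unmatched <- unmatched & ev$all_na
  }
  if (n_imputed > 0) {
    message("link_components: imputed ", n_imputed,
            " missing component cell(s) to 0")
  }
  if (any(unmatched)) {
    message("link_components: ", sum(unmatched),
            " item row(s) had no linked component data")
  }
  out
}

#' Apply the analytic-sample eligibility filters
#'
#' Keeps respondents aged 2 years and older with a reliable day-1 recall who
#' are not consuming human milk, drops the rest, and restricts the item table
#' to kept respondents. Each excluded respondent is tallied under exactly one
#' reason, checked in the order under_2, unreliable, human_milk.
#'
#' @param respondents Respondent data.frame.
#' @param items Item data.frame (linked or raw; only `respondent_id` is used).
#' @return A list with elements `respondents`, `items` and `tally` (named
#'   integer vector of exclusion counts).
#' @export
apply_eligibility_filters <- function(respondents, items) {
  under_2 <- respondents$age_years < 2
  unreliable <- !under_2 & !respondents$recall_reliable
  human_milk <- !under_2 & !unreliable & respondents$consumes_human_milk
  keep <- !(under_2 | unreliable | human_milk)
  tally <- c(under_2 = sum(under_2), unreliable = sum(unreliable),
             human_milk = sum(human_milk))
  kept_resp <- respondents[keep, , drop = FALSE]
  kept_items <- items[items$respondent_id %in% kept_resp$respondent_id, ,
                      drop = FALSE]
  if (sum(tally) > 0) {
    message("apply_eligibility_filters: excluded ", sum(tally),
            " respondent(s) [",
            paste(names(tally), tally, sep = "=", collapse = ", "), "]")
  }
  list(respondents = kept_resp, items = kept_items, tally = tally)
}

#' Write respondent and item tables as CSV
#'
#' Writes the two tables in the exact dialect [read_respondents()] and
#' [read_food_items()] read back, with numerics formatted so doubles
#' round-trip bit-exactly.
#'
#' @param respondents,items Data frames as produced by [generate_recalls()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_recalls <- function(respondents, items, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(respondents = file.path(dir, "respondents.csv"),
             items = file.path(dir, "items.csv"))
  .write_exact_csv(respondents, paths[["respondents"]])
  .write_exact_csv(items, paths[["items"]])
  invisible(paths)
}

.write_exact_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}
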