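#' HEI-2015 scoring standards
#'
#' Reads the shipped table of HEI-2015 component scoring standards: for each
#' of the 13 components, its maximum points (5 or 10), direction (adequacy,
#' moderation, or the fatty-acid ratio), the density unit, and the two
#' cut-points — the density earning the maximum score and the density earning
#' zero. Scores vary piecewise-linearly between the cut-points. The table is
#' plain CSV so alternative (e.g. synthetic) standards can be supplied to any
#' scoring function.
#'
#' Densities are expressed per 1000 kcal (cup/oz equivalents, or grams for
#' sodium), as percent of energy (added sugars at 16 kcal per tsp-eq,
#' saturated fat at 9 kcal per g), or as the dimensionless
#' (MUFA+PUFA)/SFA ratio.
#'
#' @param path Path to a standards CSV. Defaults to the file shipped with the
#'   package.
#' @return A data.frame with columns `component`, `max_points`, `direction`,
#'   `unit`, `max_score_at`, `zero_score_at`, one row per component.
#' @examples
#' std <- hei_standards()
#' sum(std$max_points)  # 100
#' @export
hei_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hei2015_standards.csv", package = "heipop")
  }
  std <- read.csv(path, stringsAsFactors = FALSE)
  validate_standards(std)
  std
}

#' Validate a standards table
#'
#' Checks structural invariants: required columns; max points in \{5, 10\};
#' adequacy/ratio components have `zero_score_at < max_score_at`, moderation
#' components the reverse; no degenerate (equal) cut-points.
#'
#' @param standards A standards data.frame as returned by [hei_standards()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_standards <- function(standards) {
  req <- c("component", "max_points", "direction", "unit",
           "max_score_at", "zero_score_at")
  missing_cols <- setdiff(req, names(standards))
  if (length(missing_cols)) {
    stop("standards table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(standards$component)) {
    stop("duplicate component in standards table")
  }
  if (!all(standards$max_points %in% c(5, 10))) {
    stop("max_points must be 5 or 10")
  }
  bad_dir <- setdiff(standards$direction, c("adequacy", "moderation", "ratio"))
  if (length(bad_dir)) {
    stop("unknown direction(s): ", paste(bad_dir, collapse = ", "))
  }
  eq <- standards$max_score_at == standards$zero_score_at
  if (any(eq)) {
    stop("degenerate cut-points (equal) for: ",
         paste(standards$component[eq], collapse = ", "))
  }
  up <- standards$direction %in% c("adequacy", "ratio")
  if (any(up & standards$zero_score_at >= standards$max_score_at)) {
    stop("adequacy/ratio components need zero_score_at < max_score_at")
  }
  if (any(!up & standards$zero_score_at <= standards$max_score_at)) {
    stop("moderation components need zero_score_at > max_score_at")
  }
  invisible(standards)
}
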