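#' Scale component scores to percent of maximum
#'
#' Maps each of the 13 component scores to `100 * score / max_points`, in
#' the canonical axis order, for radar plotting and grading.
#'
#' @param scores Named score vector, or an object of class `"hei"`.
#' @param standards Standards table.
#' @return Named numeric vector (percent of maximum, canonical order).
#' @export
to_percent_of_max <- function(scores, standards = hei_standards()) {
  if (inherits(scores, "hei")) {
    standards <- scores$standards
    scores <- scores$scores
  }
  ord <- intersect(hei_components(), standards$component)
  if (!length(ord)) ord <- standards$component
  maxp <- setNames(standards$max_points, standards$component)[ord]
  s <- scores[ord]
  if (any(s < 0 | s > maxp)) stop("score outside [0, max_points]")
  setNames(100 * s / maxp, ord)
}

.axis_labels <- c(
  total_fruits = "Total Fruits", whole_fruits = "Whole Fruits",
  total_vegetables = "Total Vegetables", greens_and_beans = "Greens & Beans",
  whole_grains = "Whole Grains", dairy = "Dairy",
  total_protein = "Total Protein", seafood_plant_protein = "Seafood & Plant Prot.",
  fatty_acids = "Fatty Acids", refined_grains = "Refined Grains",
  sodium = "Sodium", added_sugars = "Added Sugars",
  saturated_fats = "Saturated Fats"
)

#' Radar plot of component-score patterns
#'
#' Draws one closed polygon per series over the 13 component axes, each axis
#' scaled as percent of the maximum component score: the centre is 0 and the
#' outer ring 100 (a mix of foods optimally aligned with the guidelines).
#' Axis order is fixed to the canonical component listing so patterns are
#' comparable across plots.
#'
#' @param series A list of `"hei"` objects, a single named percent vector, or
#'   a matrix/list of percent vectors (values in `[0, 100]`, names matching
#'   [hei_components()]).
#' @param labels Optional series labels for the legend (defaults to outlet
#'   names for `"hei"` objects).
#' @param standards Standards table used when `series` contains raw scores.
#' @param main Plot title.
#' @param ... Ignored.
#' @return The percent matrix (series x 13), invisibly.
#' @export
radar_plot <- function(series, labels = NULL, standards = hei_standards(),
                       main = "HEI-2015 component scores", ...) {
  if (inherits(series, "hei")) series <- list(series)
  if (is.list(series) && !is.data.frame(series)) {
    rows <- lapply(series, function(s) {
      if (inherits(s, "hei")) to_percent_of_max(s) else s[hei_components()]
    })
    if (is.null(labels)) {
      labels <- vapply(seq_along(series), function(i) {
        s <- series[[i]]
        if (inherits(s, "hei")) {
          paste0(s$group$outlet,
                 if (!is.null(s$group$cycle)) paste0(" ", s$group$cycle))
        } else paste0("series ", i)
      }, character(1))
    }
    mat <- do.call(rbind, rows)
  } else {
    mat <- if (is.matrix(series)) series else matrix(series, nrow = 1,
                                                    dimnames = list(NULL,
                                                                    names(series)))
    if (is.null(labels)) labels <- paste0("series ", seq_len(nrow(mat)))
  }
  if (ncol(mat) != length(hei_components())) {
    stop("each series needs ", length(hei_components()), " component values")
  }
  if (any(mat < 0 | mat > 100)) stop("percent values must lie in [0, 100]")
  n_axes <- ncol(mat)
  angles <- pi / 2 - 2 * pi * (seq_len(n_axes) - 1) / n_axes
  old <- par(mar = c(1, 1, 3, 1), xpd = TRUE)
  on.exit(par(old))
  plot(NA, xlim = c(-1.55, 1.55), ylim = c(-1.45, 1.45), axes = FALSE,
       xlab = "", ylab = "", asp = 1, main = main)
  for (ring in c(25, 50, 75, 100) / 100) {
    polygon(ring * cos(angles), ring * sin(angles), border = "grey80")
  }
  segments(0, 0, cos(angles), sin(angles), col = "grey80")
  lab <- .axis_labels[colnames(mat)]
  lab[is.na(lab)] <- colnames(mat)[is.na(lab)]
  text(1.18 * cos(angles), 1.18 * sin(angles), lab, cex = 0.7)
  cols <- rep_len(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                    "#e6ab02", "#a6761d", "#666666"), nrow(mat))
  for (i in seq_len(nrow(mat))) {
    r <- mat[i, ] / 100
    polygon(r * cos(angles), r * sin(angles), border = cols[i], lwd = 2,
            col = adjustcolor(cols[i], alpha.f = 0.08))
  }
  legend("topleft", inset = c(-0.02, -0.06), legend = labels, col = cols,
         lwd = 2, bty = "n", cex = 0.75)
  invisible(mat)
}

#' Render a radar plot to an image file
#'
#' Writes the radar plot to PNG or SVG, chosen by the file extension.
#' Rendering is deterministic for identical inputs.
#'
#' @inheritParams radar_plot
#' @param path Output file ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_radar <- function(series, path, labels = NULL,
                         standards = hei_standards(),
                         main = "HEI-2015 component scores",
                         width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png(path, width = width, height = height, units = "in", res = 150)
  } else if (ext == "svg") {
    svg(path, width = width, height = height)
  } else {
    stop("unsupported image format: .", ext)
  }
  on.exit(dev.off())
  radar_plot(series, labels = labels, standards = standards, main = main)
  invisible(path)
}

#' Write a score report table
#'
#' One row per fitted group (outlet x cycle) with the total, its grade, the
#' 13 component scores and, where available, the BRR standard error of the
#' total. Values are rounded to 2 decimals (round-half-even); an empty input
#' yields a header-only file.
#'
#' @param fits List of `"hei"` objects.
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_score_report <- function(fits, path) {
  comps <- hei_components()
  header <- c("outlet", "cycle", "total", "grade", comps, "total_se")
  if (!length(fits)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                 header))
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  rows <- lapply(fits, function(f) {
    row <- data.frame(outlet = f$group$outlet,
                      cycle = if (is.null(f$group$cycle)) NA_character_
                              else f$group$cycle,
                      total = round(f$total, 2), grade = f$grade,
                      stringsAsFactors = FALSE)
    for (cc in comps) row[[cc]] <- round(f$scores[[cc]], 2)
    row$total_se <- if (is.null(f$se)) NA_real_ else round(f$se[["total"]], 2)
    row
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
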