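# Reporting: relative-change summaries of prevalence/share trajectories, the
# code-by-month heatmap matrix behind the DTM figure, and delimited-text
# exports of the IGT embedding. All acceptance-relevant output is the text
# export; images are a thin optional layer over the exported matrices.

# round half away from zero (so 36.25 -> 36.3 at 1 dp, -64.5 -> -65 at 0 dp),
# unlike base round()'s round-half-to-even. A few-ulp nudge keeps exact
# decimal ties (whose binary representation may fall a hair below .5) on the
# away-from-zero side without disturbing genuinely smaller values.
round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  y <- abs(x) * f
  sign(x) * floor(y + 0.5 + 8 * .Machine$double.eps * y) / f
}

#' Relative change between two proportions, in percent
#'
#' `100 * (end - start) / start`, rounded half-away-from-zero to `decimals`
#' digits — the convention behind printed values like "+36%" for a code
#' share moving from 8.0% to 10.9%.
#'
#' @param start,end Proportions (or any positive quantities on a common
#'   scale); `start` must be strictly positive.
#' @param decimals Digits to round to (0 for integer percentages).
#' @return The rounded percent change.
#' @export
#' @examples
#' relative_change(8.0, 10.9)          # +36
#' relative_change(18.8, 10.2, 1)      # -45.7
relative_change <- function(start, end, decimals = 0L) {
  if (any(start <= 0)) stop("relative change is undefined for start <= 0")
  round_half_away(100 * (end - start) / start, decimals)
}

#' Start/end trajectory summary for each category of a variable
#'
#' For one variable of a temporal map, reports the marginal proportion of
#' each category in the first and last month of `period`, with absolute and
#' relative changes.
#'
#' @param dtm A `data_temporal_map`.
#' @param variable Variable to summarise.
#' @param period Optional length-2 month vector (default: full window).
#' @param decimals Digits for the relative change.
#' @return A data.frame with `category`, `period_start`, `period_end`,
#'   `start_value`, `end_value`, `absolute_change`, `relative_change_pct`.
#' @export
trend_summary <- function(dtm, variable, period = NULL, decimals = 1L) {
  mg <- marginalize(dtm, variable)
  months <- mg$months
  if (is.null(period)) period <- range(months)
  period <- as_month(period)
  i <- which(months >= period[1])[1]
  j <- rev(which(months <= period[2]))[1]
  if (is.na(i) || is.na(j) || i >= j) stop("period does not span the map")
  start_v <- mg$probabilities[i, ]
  end_v <- mg$probabilities[j, ]
  data.frame(
    category = mg$support[[variable]],
    period_start = months[i], period_end = months[j],
    start_value = start_v, end_value = end_v,
    absolute_change = end_v - start_v,
    relative_change_pct = ifelse(
      start_v > 0, relative_change(start_v, end_v, decimals), NA_real_),
    row.names = NULL
  )
}

#' Category-by-month heatmap matrix of a marginal temporal map
#'
#' Rows are the categories of the (single) variable, columns are months, and
#' each cell is the proportion of that month's observations in the category
#' — the matrix behind a code-by-month heatmap. Optionally written as
#' delimited text with month headers and rendered as an image.
#'
#' @param dtm A single-variable `data_temporal_map` (see [marginalize()]);
#'   passing a joint map is an error.
#' @param file Optional CSV path for the matrix export.
#' @param image Optional PNG path; rendered with [graphics::image()].
#' @return The categories x months proportion matrix, invisibly if `file`
#'   is given.
#' @export
dtm_heatmap <- function(dtm, file = NULL, image = NULL) {
  stopifnot(inherits(dtm, "data_temporal_map"))
  if (length(dtm$schema) != 1L) {
    stop("dtm_heatmap needs a single-variable map; marginalize() the joint ",
         "map first")
  }
  m <- t(dtm$probabilities)
  rownames(m) <- dtm$support[[1L]]
  colnames(m) <- format_month(dtm$months)
  if (!is.null(file)) {
    out <- data.frame(category = rownames(m), m, check.names = FALSE)
    utils::write.csv(out, file, row.names = FALSE)
  }
  if (!is.null(image)) {
    grDevices::png(image, width = 900, height = 80 + 24 * nrow(m))
    on.exit(grDevices::dev.off())
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "month", ylab = "", axes = FALSE)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                   cex.axis = 0.7)
    ticks <- seq(1L, ncol(m), by = max(1L, ncol(m) %/% 12L))
    graphics::axis(1, at = ticks, labels = colnames(m)[ticks], las = 2,
                   cex.axis = 0.7)
  }
  if (is.null(file) && is.null(image)) m else invisible(m)
}

#' Export an IGT embedding as delimited text
#'
#' Writes one record per month — glyph label, month and the first (up to)
#' three coordinates — plus an optional JSON sidecar with the eigenvalue
#' diagnostics (spectrum, variance explained, clamped negative mass).
#' Exports are byte-stable: re-exporting a reloaded file reproduces it
#' exactly.
#'
#' @param embedding An `igt_embedding`.
#' @param file Optional CSV path.
#' @param diagnostics_file Optional JSON sidecar path.
#' @return The export data.frame (invisibly when `file` is given).
#' @export
igt_export <- function(embedding, file = NULL, diagnostics_file = NULL) {
  stopifnot(inherits(embedding, "igt_embedding"))
  d <- min(3L, ncol(embedding$coordinates))
  out <- data.frame(
    label = embedding$month_labels,
    month = format_month(embedding$months),
    embedding$coordinates[, seq_len(d), drop = FALSE],
    row.names = NULL
  )
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  if (!is.null(diagnostics_file)) {
    jsonlite::write_json(
      list(eigenvalues = embedding$eigenvalues,
           raw_eigenvalues = embedding$raw_eigenvalues,
           variance_explained = embedding$variance_explained,
           clamped_mass = embedding$clamped_mass,
           scale = embedding$scale),
      diagnostics_file, auto_unbox = TRUE, digits = NA)
  }
  if (is.null(file)) out else invisible(out)
}
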