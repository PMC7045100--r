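# Reproducible stand-ins for the visual inspection of IGT plots: SPC-style
# abrupt-change flags on the consecutive dissimilarity series, gradual-trend
# detection on the leading embedding coordinate, period-cluster scoring by
# silhouette on the dissimilarity matrix, and per-variable attribution of a
# flagged change via marginal temporal maps. Thresholds are this package's
# choices (defaults k = 5, |rho| >= 0.8, silhouette >= 0.5), justified by the
# null-scenario false-positive suites; all are exposed as arguments.

new_change_report <- function(df) {
  structure(df, class = c("change_report", "data.frame"))
}

#' Flag abrupt month-to-month changes (control-chart rule)
#'
#' Flags every consecutive-month transition whose dissimilarity exceeds
#' `median + k * 1.4826 * MAD` of the full series (robust location and scale,
#' so a handful of genuine breaks does not inflate the threshold). For a
#' constant series (MAD = 0) the rule degenerates to flagging any value
#' strictly above the median.
#'
#' @param series A data.frame from [consecutive_series()], or a numeric
#'   vector of consecutive dissimilarities.
#' @param k Threshold multiplier (default 5).
#' @return A `change_report` data.frame with one row per flag: `type`
#'   (`"abrupt"`), `step_index`, `from`, `to`, `value`, `score` (robust
#'   z-score; `Inf` under the degenerate rule).
#' @export
detect_abrupt <- function(series, k = 5) {
  if (is.numeric(series)) {
    series <- data.frame(step_index = seq_along(series),
                         from = NA, to = NA, value = series)
  }
  stopifnot(is.data.frame(series), "value" %in% names(series))
  v <- series$value
  if (length(v) < 12L) stop("series must cover at least 12 month-steps")
  med <- stats::median(v)
  s <- 1.4826 * stats::mad(v, constant = 1)
  if (s == 0) {
    hit <- v > med
    score <- ifelse(hit, Inf, 0)
  } else {
    score <- (v - med) / s
    hit <- score > k
  }
  new_change_report(data.frame(
    type = if (any(hit)) "abrupt" else character(0),
    series[hit, c("step_index", "from", "to", "value")],
    score = score[hit],
    row.names = NULL
  ))
}

#' Flag a gradual trend in the leading embedding coordinate
#'
#' Computes the Spearman rank correlation between month index and the
#' dimension-1 coordinate over `period` and flags when its magnitude reaches
#' `rho_threshold`. A sustained drift in the underlying distributions shows
#' up as a near-monotone dimension-1 trajectory; rank correlation makes the
#' rule invariant to the (arbitrary) axis sign up to the reported sign of
#' rho.
#'
#' @param embedding An `igt_embedding`.
#' @param period Optional length-2 month vector restricting the window; at
#'   least 12 months are required.
#' @param rho_threshold Flag when `|rho| >=` this value (default 0.8).
#' @return A `change_report` with zero or one row: `type` (`"trend"`),
#'   `period_start`, `period_end`, `score` (signed rho).
#' @export
detect_trend <- function(embedding, period = NULL, rho_threshold = 0.8) {
  stopifnot(inherits(embedding, "igt_embedding"))
  months <- embedding$months
  keep <- rep(TRUE, length(months))
  if (!is.null(period)) {
    period <- as_month(period)
    keep <- months >= period[1] & months <= period[2]
  }
  if (sum(keep) < 12L) stop("trend detection needs at least 12 months")
  x <- seq_len(sum(keep))
  y <- embedding$coordinates[keep, 1L]
  rho <- stats::cor(x, y, method = "spearman")
  hit <- is.finite(rho) && abs(rho) >= rho_threshold
  new_change_report(data.frame(
    type = if (hit) "trend" else character(0),
    period_start = if (hit) min(months[keep]) else as.Date(character(0)),
    period_end = if (hit) max(months[keep]) else as.Date(character(0)),
    score = if (hit) rho else numeric(0)
  ))
}

# Mean silhouette width computed directly from a dissimilarity matrix.
# Points in singleton groups are excluded (their silhouette is undefined
# here rather than set to 0).
silhouette_mean <- function(values, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  singletons <- names(sizes)[sizes == 1L]
  if (length(singletons)) {
    warning("singleton group(s) excluded from silhouette: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  valid <- !(groups %in% singletons)
  if (length(unique(groups[valid])) < 2L) {
    stop("silhouette is undefined with fewer than 2 non-singleton groups")
  }
  s <- numeric(0)
  for (i in which(valid)) {
    own <- which(groups == groups[i] & seq_along(groups) != i)
    a <- mean(values[i, own])
    others <- setdiff(unique(groups[valid]), groups[i])
    b <- min(vapply(others, function(g) {
      mean(values[i, groups == g])
    }, numeric(1)))
    s <- c(s, (b - a) / max(a, b))
  }
  mean(s)
}

period_grouping <- function(months, name) {
  switch(name,
    calendar_year = as.character(month_year(months)),
    financial_year = {
      # NHS financial year: April to March, labelled by its starting year
      fy <- month_year(months) - as.integer(month_of_year(months) < 4L)
      paste0("FY", fy)
    },
    month_of_year = sprintf("M%02d", month_of_year(months)),
    stop("unknown grouping '", name, "'")
  )
}

#' Score candidate period groupings of the months (cluster detection)
#'
#' For each candidate grouping of the analysed months — calendar year, NHS
#' financial year (April-March), month-of-year (a seasonality probe), or any
#' user-supplied grouping — computes the mean silhouette width on the
#' dissimilarity matrix and flags groupings whose silhouette reaches the
#' threshold: months then sit in tight, well-separated period clusters
#' rather than evolving gradually.
#'
#' @param matrix A `dissimilarity_matrix`.
#' @param groupings Character vector of built-in grouping names and/or a
#'   named list mixing built-in names with custom group vectors (one group
#'   label per month).
#' @param silhouette_threshold Flag when mean silhouette `>=` this value
#'   (default 0.5).
#' @return A `change_report` with one row per *flagged* grouping (`type`
#'   `"cluster"`, `grouping`, `score`), with the scores of all evaluated
#'   groupings in `attr(, "all_scores")`.
#' @export
detect_period_clusters <- function(matrix,
                                   groupings = c("calendar_year",
                                                 "financial_year",
                                                 "month_of_year"),
                                   silhouette_threshold = 0.5) {
  stopifnot(inherits(matrix, "dissimilarity_matrix"))
  months <- matrix$months
  if (is.character(groupings)) {
    groupings <- stats::setNames(as.list(groupings), groupings)
  }
  scores <- vapply(names(groupings), function(nm) {
    g <- groupings[[nm]]
    if (is.character(g) && length(g) == 1L) g <- period_grouping(months, g)
    if (length(g) != length(months)) {
      stop("grouping '", nm, "' must assign one group per month")
    }
    silhouette_mean(matrix$values, g)
  }, numeric(1))
  hit <- scores >= silhouette_threshold
  out <- new_change_report(data.frame(
    type = rep("cluster", sum(hit)),
    grouping = names(scores)[hit],
    score = unname(scores[hit]),
    row.names = NULL
  ))
  attr(out, "all_scores") <- scores
  out
}

#' Attribute a flagged change to the variables that drive it
#'
#' Recomputes the dissimilarity at a flagged month transition on each
#' single-variable marginal temporal map and ranks the variables by that
#' marginal dissimilarity: the variable whose marginal moves most is the
#' most likely source of the joint-map change.
#'
#' @param dtm The joint `data_temporal_map` the flag was produced on.
#' @param location Either a step index `i` (the transition between months
#'   `i` and `i + 1`) or a length-2 month vector.
#' @param scale,log_base Dissimilarity scale for the marginal comparison
#'   (divergence scale by default, matching how rates are quoted).
#' @return A data.frame with `variable`, `score`, `rank`, ordered by
#'   decreasing score.
#' @export
attribute_source <- function(dtm, location, scale = c("divergence", "distance"),
                             log_base = 2) {
  stopifnot(inherits(dtm, "data_temporal_map"))
  scale <- match.arg(scale)
  log_base <- check_log_base(log_base)
  if (is.numeric(location) && length(location) == 1L) {
    i <- as.integer(location)
    if (i < 1L || i >= length(dtm$months)) stop("step index out of range")
    pair <- c(i, i + 1L)
  } else {
    pair <- match(as_month(location), dtm$months)
    if (anyNA(pair)) stop("location months not in the temporal map")
  }
  scores <- vapply(names(dtm$schema), function(v) {
    mg <- marginalize(dtm, v)
    d <- js_div_raw(mg$probabilities[pair[1], ], mg$probabilities[pair[2], ],
                    log_base)
    if (scale == "distance") sqrt(d) else d
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  data.frame(variable = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(scores), row.names = NULL)
}
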