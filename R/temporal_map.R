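# Data temporal maps: per-month empirical joint distributions over a declared
# set of categorical variables, on a support aligned across all months. The
# DTM is the object behind the code-by-month heatmap and the input to all
# dissimilarity computations. Variables here are categorical throughout, so
# the estimate is the plain joint histogram divided by the monthly total; no
# smoothing is applied by default and counts remain exactly recoverable from
# probabilities and denominators.

new_dtm <- function(months, support, counts, probabilities, schema,
                    denominators, excluded_months = as.Date(character())) {
  structure(
    list(months = months, support = support, counts = counts,
         probabilities = probabilities, schema = schema,
         denominators = denominators, excluded_months = excluded_months),
    class = "data_temporal_map"
  )
}

#' @export
print.data_temporal_map <- function(x, ...) {
  cat("Data temporal map: ", length(x$months), " months x ",
      nrow(x$support), " support cells\n", sep = "")
  cat("  variables:", paste(names(x$schema), collapse = ", "), "\n")
  cat("  window: ", format_month(x$months[1]), " .. ",
      format_month(x$months[length(x$months)]), "\n", sep = "")
  if (length(x$excluded_months)) {
    cat("  excluded empty months:",
        paste(format_month(x$excluded_months), collapse = ", "), "\n")
  }
  invisible(x)
}

support_key <- function(support) {
  do.call(paste, c(as.list(support), sep = "\r"))
}

order_support <- function(support, schema) {
  keys <- lapply(names(schema), function(v) {
    factor(support[[v]], levels = schema[[v]])
  })
  do.call(order, keys)
}

#' Estimate a data temporal map from monthly slices
#'
#' Builds the months x support matrix of empirical joint probabilities: row
#' `i` is the joint histogram of month `i` divided by that month's total. The
#' support is the union of category combinations observed in any month,
#' ordered lexicographically by variable order then category order, and is
#' identical across rows; combinations never observed in a month are exactly
#' zero. Empty months (zero denominator) are excluded with a warning and
#' recorded in the result.
#'
#' @param slices A `monthly_slices` object.
#' @param variables Variables to retain (default: all in the slice schema).
#'   Restricting variables marginalises the counts accordingly.
#' @return A `data_temporal_map` with fields `months`, `support` (data.frame),
#'   `counts`, `probabilities`, `variable schema`, `denominators`.
#' @seealso [marginalize()], [pairwise_matrix()]
#' @export
estimate_dtm <- function(slices, variables = NULL) {
  stopifnot(inherits(slices, "monthly_slices"))
  schema <- attr(slices, "schema")
  if (is.null(variables)) variables <- names(schema)
  unknown <- setdiff(variables, names(schema))
  if (length(unknown)) {
    stop("variables not in slice schema: ", paste(unknown, collapse = ", "))
  }
  schema <- schema[variables]

  empty <- vapply(slices, function(s) s$denominator == 0L, logical(1))
  excluded <- as.Date(vapply(slices[empty], function(s) as.character(s$month),
                             character(1)), format = "%Y-%m-%d")
  if (any(empty)) {
    warning(sum(empty), " empty month(s) excluded from the temporal map: ",
            paste(format_month(excluded), collapse = ", "), call. = FALSE)
  }
  keep <- which(!empty)
  if (length(keep) == 0L) stop("all months are empty")

  count <- NULL # data.table NSE
  cells <- lapply(keep, function(i) {
    cc <- slices[[i]]$cells[, c(variables, "count"), with = FALSE]
    cc[, .(count = sum(count)), by = variables]
  })

  support <- unique(data.table::rbindlist(lapply(cells, function(cc) {
    cc[, variables, with = FALSE]
  })))
  support <- as.data.frame(support)
  support <- support[order_support(support, schema), , drop = FALSE]
  rownames(support) <- NULL
  skey <- support_key(support)

  months <- as.Date(vapply(slices[keep], function(s) as.character(s$month),
                           character(1)), format = "%Y-%m-%d")
  counts <- matrix(0, length(keep), nrow(support),
                   dimnames = list(format_month(months), NULL))
  for (r in seq_along(keep)) {
    cc <- cells[[r]]
    j <- match(support_key(cc[, variables, with = FALSE]), skey)
    counts[r, j] <- cc$count
  }
  denominators <- rowSums(counts)
  probabilities <- counts / denominators

  new_dtm(months, support, counts, probabilities, schema,
          denominators, excluded)
}

#' Build a single-variable temporal map from a count matrix
#'
#' Convenience constructor for data that is already a months x categories
#' count (or probability) matrix of a single categorical variable.
#'
#' @param counts Numeric matrix, one row per month, one column per category;
#'   rows are normalised to probabilities.
#' @param months Month vector, one per row.
#' @param categories Category labels (default: column names).
#' @param variable Variable name for the schema.
#' @return A `data_temporal_map`.
#' @export
dtm_from_counts <- function(counts, months, categories = colnames(counts),
                            variable = "category") {
  counts <- as.matrix(counts)
  months <- as_month(months)
  if (length(months) != nrow(counts)) stop("one month per row required")
  if (is.null(categories)) categories <- paste0("c", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("negative counts")
  denom <- rowSums(counts)
  if (any(denom <= 0)) stop("every month needs a positive total")
  ord <- order(months)
  counts <- counts[ord, , drop = FALSE]
  dimnames(counts) <- list(format_month(months[ord]), NULL)
  support <- data.frame(x = as.character(categories), stringsAsFactors = FALSE)
  names(support) <- variable
  schema <- stats::setNames(list(as.character(categories)), variable)
  new_dtm(months[ord], support, counts, counts / denom[ord], schema, denom[ord])
}

#' Marginalise a data temporal map onto one variable
#'
#' Collapses the joint support to the categories of a single variable by
#' summing all joint cells consistent with each category; rows still sum
#' to 1. Per-variable marginal maps isolate which variable drives a change
#' found on the joint map.
#'
#' @param dtm A `data_temporal_map`.
#' @param variable Name of a variable in the map's schema.
#' @return A `data_temporal_map` over the single variable.
#' @export
marginalize <- function(dtm, variable) {
  stopifnot(inherits(dtm, "data_temporal_map"))
  if (length(variable) != 1L || !variable %in% names(dtm$schema)) {
    stop("unknown variable: ", paste(variable, collapse = ", "))
  }
  cats <- dtm$schema[[variable]]
  cats <- cats[cats %in% unique(dtm$support[[variable]])]
  counts <- vapply(cats, function(cat) {
    cols <- which(dtm$support[[variable]] == cat)
    rowSums(dtm$counts[, cols, drop = FALSE])
  }, numeric(length(dtm$months)))
  counts <- matrix(counts, nrow = length(dtm$months),
                   dimnames = list(format_month(dtm$months), NULL))
  support <- data.frame(x = cats, stringsAsFactors = FALSE)
  names(support) <- variable
  new_dtm(dtm$months, support, counts, counts / rowSums(counts),
          dtm$schema[variable], dtm$denominators, dtm$excluded_months)
}
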