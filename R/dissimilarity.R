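# Jensen-Shannon dissimilarities between monthly distributions. Two scales
# are always available and explicitly labelled: the divergence
# 1/2 KL(p||m) + 1/2 KL(q||m) with m = (p+q)/2, and its square root, which is
# a metric ("distance"). With log base 2 both are bounded by 1: 0 means equal
# distributions, 1 means no overlap. The metric scale feeds the Euclidean
# embedding; the divergence scale is used when quoting JSD/month rates.

check_log_base <- function(log_base) {
  if (!(identical(log_base, 2) || identical(log_base, 2L) ||
        isTRUE(all.equal(log_base, exp(1))))) {
    stop("log_base must be 2 or exp(1)")
  }
  as.numeric(log_base)
}

check_prob_pair <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must have the same length (got ", length(p), " and ",
         length(q), ")")
  }
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > PROB_TOL || abs(sum(q) - 1) > PROB_TOL) {
    stop("probability vectors must each sum to 1 within 1e-9")
  }
}

js_div_raw <- function(p, q, log_base) {
  # 0 * log(0/x) = 0 by convention; m > 0 wherever p or q is, so the only
  # singularities are removed by restricting each KL sum to its positive terms
  m <- (p + q) / 2
  ip <- p > 0
  iq <- q > 0
  kl_p <- sum(p[ip] * log(p[ip] / m[ip]))
  kl_q <- sum(q[iq] * log(q[iq] / m[iq]))
  max((kl_p + kl_q) / 2, 0) / log(log_base)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' Computes `1/2 KL(p||m) + 1/2 KL(q||m)` with `m = (p+q)/2`, using the
#' `0 log 0 = 0` convention. With `log_base = 2` (the default) the result
#' lies in `[0, 1]`; with natural logs, in `[0, ln 2]`.
#'
#' @param p,q Non-negative vectors of equal length, each summing to 1 within
#'   1e-9.
#' @param log_base 2 (default) or `exp(1)`.
#' @return A single non-negative number.
#' @seealso [js_distance()], [pairwise_matrix()]
#' @export
#' @examples
#' js_divergence(c(0.990, 0.010), c(0.978, 0.022)) # ~1.7e-3 bits
#' js_divergence(c(1, 0), c(0, 1))                 # 1: disjoint supports
js_divergence <- function(p, q, log_base = 2) {
  log_base <- check_log_base(log_base)
  check_prob_pair(p, q)
  js_div_raw(p, q, log_base)
}

#' Jensen-Shannon distance (square root of the divergence)
#'
#' The square root of [js_divergence()] is a metric, which is what makes the
#' month-by-month dissimilarity matrix embeddable in Euclidean space.
#'
#' @inheritParams js_divergence
#' @return A single number in `[0, 1]` for `log_base = 2`.
#' @export
js_distance <- function(p, q, log_base = 2) {
  sqrt(js_divergence(p, q, log_base))
}

new_dissimilarity_matrix <- function(months, values, scale, log_base) {
  dimnames(values) <- list(format_month(months), format_month(months))
  structure(list(months = months, values = values, scale = scale,
                 log_base = log_base),
            class = "dissimilarity_matrix")
}

#' Package a precomputed dissimilarity matrix
#'
#' Validates and wraps an externally computed month x month dissimilarity
#' matrix so it can be fed to [classical_mds()], [consecutive_series()] and
#' the detectors.
#'
#' @param values Square numeric matrix: symmetric within 1e-12, zero
#'   diagonal, non-negative.
#' @param months Month vector, one per row/column.
#' @param scale `"distance"` or `"divergence"`.
#' @param log_base 2 or `exp(1)`.
#' @return A `dissimilarity_matrix` object.
#' @export
as_dissimilarity_matrix <- function(values, months,
                                    scale = c("distance", "divergence"),
                                    log_base = 2) {
  scale <- match.arg(scale)
  log_base <- check_log_base(log_base)
  values <- as.matrix(values)
  months <- as_month(months)
  n <- length(months)
  if (!all(dim(values) == n)) stop("values must be a ", n, " x ", n, " matrix")
  if (max(abs(values - t(values))) > 1e-12) stop("values must be symmetric")
  if (any(abs(diag(values)) > 0)) stop("diagonal must be zero")
  if (any(values < 0)) stop("dissimilarities must be non-negative")
  ord <- order(months)
  new_dissimilarity_matrix(months[ord], values[ord, ord, drop = FALSE],
                           scale, log_base)
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("Jensen-Shannon dissimilarity matrix (", x$scale, " scale, log base ",
      if (x$log_base == 2) "2" else "e", ")\n", sep = "")
  cat("  ", length(x$months), " months: ", format_month(x$months[1]), " .. ",
      format_month(x$months[length(x$months)]), "\n", sep = "")
  off <- x$values[upper.tri(x$values)]
  cat("  off-diagonal range: ", format(min(off), digits = 4), " .. ",
      format(max(off), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise Jensen-Shannon dissimilarity matrix of a temporal map
#'
#' Computes the symmetric month x month matrix of Jensen-Shannon
#' dissimilarities between the rows of a data temporal map. The `"distance"`
#' scale (default) is a metric and is what the multidimensional-scaling
#' embedding expects; the `"divergence"` scale is the one on which JSD/month
#' rates are quoted.
#'
#' @param dtm A `data_temporal_map` with at least 2 months.
#' @param scale `"distance"` or `"divergence"`.
#' @param log_base 2 (default) or `exp(1)`.
#' @return A `dissimilarity_matrix` object.
#' @export
pairwise_matrix <- function(dtm, scale = c("distance", "divergence"),
                            log_base = 2) {
  stopifnot(inherits(dtm, "data_temporal_map"))
  scale <- match.arg(scale)
  log_base <- check_log_base(log_base)
  n <- length(dtm$months)
  if (n < 2L) stop("need at least 2 non-empty months")
  P <- dtm$probabilities
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    pi <- P[i, ]
    for (j in seq.int(i + 1L, n)) {
      d <- js_div_raw(pi, P[j, ], log_base)
      if (scale == "distance") d <- sqrt(d)
      v[i, j] <- d
      v[j, i] <- d
    }
  }
  new_dissimilarity_matrix(dtm$months, v, scale, log_base)
}

#' Consecutive-month dissimilarity series
#'
#' Extracts the superdiagonal of a dissimilarity matrix in month order: one
#' value per transition between calendar-adjacent months. Gaps (missing or
#' excluded months) split the series into segments; no value is reported
#' across a gap.
#'
#' @param matrix A `dissimilarity_matrix`.
#' @return A data.frame with columns `step_index` (position of the earlier
#'   month), `from`, `to` (months), `value` and `segment`.
#' @export
consecutive_series <- function(matrix) {
  stopifnot(inherits(matrix, "dissimilarity_matrix"))
  months <- matrix$months
  n <- length(months)
  if (n < 2L) stop("need at least 2 months")
  adj <- months_adjacent(months)
  seg <- month_segments(months)
  idx <- which(adj)
  data.frame(
    step_index = idx,
    from = months[idx],
    to = months[idx + 1L],
    value = matrix$values[cbind(idx, idx + 1L)],
    segment = seg[idx]
  )
}

#' Average dissimilarity rate over a period (JSD/month)
#'
#' Arithmetic mean of the consecutive-month values whose transition lies
#' entirely inside `period`.
#'
#' @param series A data.frame from [consecutive_series()].
#' @param period Optional length-2 vector of months (inclusive); default is
#'   the whole series.
#' @return A single number, in JSD per month on the series' scale.
#' @export
mean_rate <- function(series, period = NULL) {
  stopifnot(is.data.frame(series), all(c("from", "to", "value") %in% names(series)))
  if (is.null(period)) {
    keep <- rep(TRUE, nrow(series))
  } else {
    period <- as_month(period)
    keep <- series$from >= period[1] & series$to <= period[2]
  }
  if (!any(keep)) stop("no consecutive steps inside the requested period")
  mean(series$value[keep])
}
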