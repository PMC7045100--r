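# Information-geometric temporal (IGT) embedding: classical multidimensional
# scaling of the month-by-month dissimilarity matrix, giving each month a
# position in a low-dimensional Euclidean space whose trajectory over time is
# read for trends, breaks, clusters and outliers. Axes have no inherent
# meaning beyond ordered directions of highest variability; sign and rotation
# are arbitrary, so a fixed sign convention is applied for stable
# serialisation and all comparisons should be made on distances.

MONTH_GLYPHS <- c("J", "F", "M", "A", "m", "j", "x", "a", "S", "O", "N", "D")

#' Month glyph labels for IGT plots
#'
#' Labels each month with the last two digits of the year plus a one-letter
#' month glyph: J January, F February, M March, A April, m May, j June,
#' x July, a August, S September, O October, N November, D December (lower
#' case and `x` disambiguate the repeated initials).
#'
#' @param months Month vector.
#' @return Character vector like `"12A"` for April 2012.
#' @export
#' @examples
#' label_months(c("2012-04", "2001-07")) # "12A" "01x"
label_months <- function(months) {
  months <- as_month(months)
  sprintf("%02d%s", month_year(months) %% 100L,
          MONTH_GLYPHS[month_of_year(months)])
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Torgerson's procedure: square the dissimilarities, double-centre
#' (`B = -1/2 J D^2 J`), eigendecompose, and scale the leading eigenvectors
#' by the square roots of their eigenvalues. Negative eigenvalues (which
#' arise when the input is not exactly Euclidean, e.g. on the divergence
#' scale) are clamped to zero and their mass recorded; clamped mass above
#' 10% of the total triggers a warning that a non-metric scale was probably
#' used. For serialisation stability each retained dimension is flipped so
#' its largest-magnitude coordinate is positive.
#'
#' @param matrix A `dissimilarity_matrix`.
#' @param dims Number of dimensions to retain (default 3, matching the usual
#'   3-D visual inspection); must be at most `n - 1` for `n` months.
#' @return An `igt_embedding` with months, an `n x dims` coordinate matrix,
#'   the full clamped eigenvalue spectrum, per-dimension variance-explained
#'   fractions, month glyph labels and the clamped negative mass.
#' @seealso [trajectory()], [igt_export()]
#' @export
classical_mds <- function(matrix, dims = 3L) {
  stopifnot(inherits(matrix, "dissimilarity_matrix"))
  n <- length(matrix$months)
  dims <- as.integer(dims)
  if (dims < 1L) stop("dims must be at least 1")
  if (dims > n - 1L) stop("dims must be at most the number of months minus 1")

  D2 <- matrix$values^2
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values # non-increasing by construction

  neg_mass <- if (sum(abs(ev)) > 0) sum(abs(pmin(ev, 0))) / sum(abs(ev)) else 0
  if (neg_mass > 0.10) {
    warning("clamped negative-eigenvalue mass is ",
            sprintf("%.1f%%", 100 * neg_mass),
            " of the spectrum; the matrix is probably on the (non-metric) ",
            "divergence scale", call. = FALSE)
  }
  ev_clamped <- pmax(ev, 0)

  coords <- e$vectors[, seq_len(dims), drop = FALSE] *
    rep(sqrt(ev_clamped[seq_len(dims)]), each = n)
  for (d in seq_len(dims)) {
    peak <- which.max(abs(coords[, d]))
    if (length(peak) && coords[peak, d] < 0) coords[, d] <- -coords[, d]
  }
  colnames(coords) <- paste0("Dim", seq_len(dims))
  rownames(coords) <- format_month(matrix$months)

  total <- sum(ev_clamped)
  variance_explained <- if (total > 0) ev_clamped / total else rep(0, n)

  structure(
    list(months = matrix$months, coordinates = coords,
         eigenvalues = ev_clamped, raw_eigenvalues = ev,
         variance_explained = variance_explained,
         month_labels = label_months(matrix$months),
         clamped_mass = neg_mass, scale = matrix$scale),
    class = "igt_embedding"
  )
}

#' @export
print.igt_embedding <- function(x, ...) {
  d <- ncol(x$coordinates)
  cat("IGT embedding: ", length(x$months), " months in ", d,
      " dimensions\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(d)]),
            collapse = ", "), "\n")
  if (x$clamped_mass > 0) {
    cat("  clamped negative-eigenvalue mass:",
        sprintf("%.2f%%", 100 * x$clamped_mass), "\n")
  }
  invisible(x)
}

#' Temporal trajectory of an IGT embedding
#'
#' Orders the embedded coordinates by month, splitting the polyline wherever
#' the month sequence has a gap (e.g. an excluded empty month), so plots do
#' not draw segments across missing data.
#'
#' @param embedding An `igt_embedding` with at least 2 months.
#' @return A data.frame with `month`, `label`, the coordinate columns and a
#'   `segment` id; consecutive rows within a segment are calendar-adjacent.
#' @export
trajectory <- function(embedding) {
  stopifnot(inherits(embedding, "igt_embedding"))
  if (length(embedding$months) < 2L) stop("need at least 2 months")
  ord <- order(embedding$months)
  months <- embedding$months[ord]
  data.frame(
    month = months,
    label = embedding$month_labels[ord],
    embedding$coordinates[ord, , drop = FALSE],
    segment = month_segments(months),
    row.names = NULL
  )
}

#' Plot an IGT embedding as a labelled temporal trajectory
#'
#' @param x An `igt_embedding`.
#' @param dims Length-2 integer vector: which dimensions to draw.
#' @param cex Label size.
#' @param ... Passed to [graphics::plot()].
#' @return The trajectory data.frame, invisibly.
#' @export
plot.igt_embedding <- function(x, dims = c(1L, 2L), cex = 0.7, ...) {
  tr <- trajectory(x)
  cn <- paste0("Dim", dims)
  graphics::plot(tr[[cn[1]]], tr[[cn[2]]], type = "n",
                 xlab = sprintf("%s (%.1f%% var)", cn[1],
                                100 * x$variance_explained[dims[1]]),
                 ylab = sprintf("%s (%.1f%% var)", cn[2],
                                100 * x$variance_explained[dims[2]]), ...)
  for (s in unique(tr$segment)) {
    sub <- tr[tr$segment == s, ]
    graphics::lines(sub[[cn[1]]], sub[[cn[2]]], col = "grey70")
  }
  graphics::text(tr[[cn[1]]], tr[[cn[2]]], tr$label, cex = cex)
  invisible(tr)
}
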