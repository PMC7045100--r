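# Calendar-month helpers. Months are represented throughout as Date objects
# pinned to the first day of the month; "the beginning of the month" always
# means day 1, 00:00.

#' Coerce to a calendar month
#'
#' Accepts `Date` vectors or character vectors in `"YYYY-MM"` / `"YYYY-MM-DD"`
#' form and returns a `Date` vector pinned to the first day of each month.
#'
#' @param x A `Date` or character vector.
#' @return A `Date` vector, one first-of-month date per input element.
#' @export
#' @examples
#' as_month("2012-04")
#' as_month(as.Date("2012-04-17"))
as_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  if (is.character(x)) {
    x <- ifelse(nchar(x) == 7L, paste0(x, "-01"), x)
    d <- as.Date(x)
    if (anyNA(d) && !anyNA(x)) {
      stop("unparseable month: ", paste(unique(x[is.na(d)]), collapse = ", "))
    }
    return(as.Date(format(d, "%Y-%m-01")))
  }
  stop("cannot interpret object of class '", class(x)[1], "' as a calendar month")
}

#' Sequence of consecutive calendar months
#'
#' @param start,end First and last month (anything accepted by [as_month()]).
#' @return `Date` vector of first-of-month dates from `start` to `end`.
#' @export
month_seq <- function(start, end) {
  start <- as_month(start)
  end <- as_month(end)
  if (start > end) stop("start month must not be after end month")
  seq(start, end, by = "month")
}

#' Shift a month by a number of calendar months
#'
#' @param month Month (anything accepted by [as_month()]).
#' @param k Integer number of months to add (may be negative).
#' @return Shifted first-of-month `Date` vector.
#' @export
month_add <- function(month, k) {
  month <- as_month(month)
  y <- as.integer(format(month, "%Y"))
  m <- as.integer(format(month, "%m"))
  t <- y * 12L + (m - 1L) + as.integer(k)
  as.Date(sprintf("%d-%02d-01", t %/% 12L, t %% 12L + 1L))
}

#' Number of whole calendar months from `a` to `b`
#'
#' @param a,b Months.
#' @return Integer vector, `b - a` in months.
#' @export
month_diff <- function(b, a) {
  a <- as_month(a); b <- as_month(b)
  ya <- as.integer(format(a, "%Y")); ma <- as.integer(format(a, "%m"))
  yb <- as.integer(format(b, "%Y")); mb <- as.integer(format(b, "%m"))
  (yb * 12L + mb) - (ya * 12L + ma)
}

#' Format a month as "YYYY-MM"
#' @param month Month vector.
#' @return Character vector.
#' @export
format_month <- function(month) format(as_month(month), "%Y-%m")

month_year <- function(month) as.integer(format(as_month(month), "%Y"))

month_of_year <- function(month) as.integer(format(as_month(month), "%m"))

# TRUE where consecutive elements of a sorted month vector are calendar-adjacent
months_adjacent <- function(months) {
  n <- length(months)
  if (n < 2L) return(logical(0))
  month_diff(months[-1L], months[-n]) == 1L
}

# Split a sorted month vector into runs of calendar-consecutive months;
# returns an integer segment id per month.
month_segments <- function(months) {
  if (length(months) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(!months_adjacent(months))))
}
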