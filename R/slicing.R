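# Monthly cross-sectional slicing. Longitudinal patient/event records (or
# preaggregated hospital counts) are converted into one categorical count
# table per month under the eligibility, ascertainment and stratification
# rules used for UK primary-care and hospital extracts: ascertainment on the
# first day of each month, ever-recorded condition flags (any qualifying code
# strictly before the month), age 20-110 with at least one year of
# registration, and the July age-increment convention for year-of-birth-only
# data.

#' Build a condition codelist
#'
#' @param condition Condition label.
#' @param codes Non-empty character vector of clinical codes.
#' @param terminology `"read"` (exact matching) or `"icd10-3char"` (event
#'   codes truncated to 3 characters before matching).
#' @return A data.frame with columns `condition`, `code`, `terminology`.
#' @export
#' @examples
#' codelist("chd", c("G30..", "G33.."), "read")
codelist <- function(condition, codes, terminology = c("read", "icd10-3char")) {
  terminology <- match.arg(terminology)
  stopifnot(is.character(condition), length(condition) == 1L,
            is.character(codes), length(codes) >= 1L)
  data.frame(condition = condition, code = codes, terminology = terminology,
             stringsAsFactors = FALSE)
}

validate_codelists <- function(codelists) {
  if (inherits(codelists, "data.frame")) {
    cl <- as.data.frame(codelists)
  } else {
    cl <- do.call(rbind, codelists)
  }
  if (!all(c("condition", "code", "terminology") %in% names(cl))) {
    stop("codelists need columns condition, code, terminology")
  }
  bad <- setdiff(unique(cl$terminology), c("read", "icd10-3char"))
  if (length(bad)) stop("unknown code terminology: ", paste(bad, collapse = ", "))
  u <- unique(cl[c("code", "terminology", "condition")])
  if (anyDuplicated(u[c("code", "terminology")])) {
    stop("a code appears in two conditions of the same codelist set")
  }
  cl
}

band_lower_edges <- function(labels) {
  vapply(labels, function(l) parse_band_range(l)[1], integer(1),
         USE.NAMES = FALSE)
}

band_labels <- function(edges) {
  edges <- sort(as.integer(edges))
  n <- length(edges)
  c(paste0(edges[-n], "-", edges[-1] - 1L), paste0(edges[n], "+"))
}

# vectorised over year_of_birth for a single month
cut_age_band <- function(year_of_birth, month, band_edges) {
  month <- as_month(month)
  age <- month_year(month) - year_of_birth -
    as.integer(month_of_year(month) < 7L)
  if (any(age < 0, na.rm = TRUE)) {
    stop("computed age is negative for year_of_birth ",
         year_of_birth[which(age < 0)[1]], " at ", format_month(month))
  }
  labs <- band_labels(band_edges)
  cut(age, breaks = c(sort(band_edges), Inf), right = FALSE, labels = labs)
}

#' Age band at the first day of a month (July increment convention)
#'
#' With year-of-birth-only data, age cannot be computed exactly; the
#' convention used here increments every patient's age in July, so
#' `age = year(month) - year_of_birth` from July onward and one less before.
#' Bands are assigned by inclusive lower edges; ages below the lowest edge
#' map to `NA`.
#'
#' @param year_of_birth Integer vector of plausible birth years (1880-2015).
#' @param month A single month.
#' @param band_edges Integer vector of inclusive lower band edges, e.g.
#'   `c(20, 40, 60, 80)` giving bands 20-39, 40-59, 60-79, 80+.
#' @return Factor of band labels.
#' @export
#' @examples
#' compute_age_band(1941, "2001-06", c(20, 40, 60, 80)) # 40-59
#' compute_age_band(1941, "2001-07", c(20, 40, 60, 80)) # 60-79: July jump
compute_age_band <- function(year_of_birth, month, band_edges) {
  if (any(year_of_birth < 1880L | year_of_birth > 2015L, na.rm = TRUE)) {
    stop("year_of_birth outside the plausible range 1880-2015")
  }
  cut_age_band(year_of_birth, month, band_edges)
}

new_monthly_slice <- function(month, cells, denominator) {
  structure(list(month = month, cells = cells,
                 denominator = as.integer(denominator)),
            class = "monthly_slice")
}

new_monthly_slices <- function(slices, schema) {
  structure(slices, schema = schema, class = "monthly_slices")
}

#' @export
print.monthly_slices <- function(x, ...) {
  months <- vapply(x, function(s) format_month(s$month), character(1))
  dens <- vapply(x, function(s) s$denominator, integer(1))
  cat("Monthly slices: ", length(x), " months (",
      months[1], " .. ", months[length(x)], ")\n", sep = "")
  cat("  variables:", paste(names(attr(x, "schema")), collapse = ", "), "\n")
  cat("  denominators: ", min(dens), " .. ", max(dens),
      if (any(dens == 0L)) paste0(" (", sum(dens == 0L), " empty)"), "\n",
      sep = "")
  invisible(x)
}

#' Build monthly slices from an already-aggregated cell table
#'
#' For data that is already a long table of categorical cell counts per month
#' (one row per month x category combination), bypasses the record-level
#' slicing rules and packages the table as `monthly_slices` ready for
#' [estimate_dtm()].
#'
#' @param cells Data frame with a `month` column, one column per categorical
#'   variable, and a `count` column.
#' @param schema Optional named list of category levels per variable
#'   (defaults to the sorted observed categories).
#' @return A `monthly_slices` object.
#' @export
as_monthly_slices <- function(cells, schema = NULL) {
  cells <- data.table::as.data.table(cells)
  if (!all(c("month", "count") %in% names(cells))) {
    stop("cells must have 'month' and 'count' columns")
  }
  if (any(cells$count < 0)) stop("negative counts")
  vars <- setdiff(names(cells), c("month", "count"))
  if (length(vars) == 0L) stop("cells must have at least one variable column")
  cells[, month := as_month(month)]
  for (v in vars) data.table::set(cells, j = v, value = as.character(cells[[v]]))
  if (is.null(schema)) {
    schema <- lapply(cells[, vars, with = FALSE], function(x) sort(unique(x)))
  }
  months <- sort(unique(cells$month))
  month <- count <- NULL # data.table NSE
  slices <- lapply(months, function(m) {
    sub <- cells[month == m, c(vars, "count"), with = FALSE]
    sub <- sub[, .(count = sum(count)), by = vars]
    new_monthly_slice(m, sub, sum(sub$count))
  })
  new_monthly_slices(slices, schema)
}

#' Monthly cross-sectional slices of primary-care records
#'
#' A patient contributes to month `m` iff their age on the first day of `m`
#' is within `age_range` (July convention by default), their registration
#' started at least `min_registration_days` before that day, and their
#' registration had not ended before it — a registration end any time within
#' the month keeps the patient in that month. Each condition flag is 1 iff
#' any code from the condition's codelist is dated strictly before the first
#' day of the month (ever-recorded ascertainment). Patients with missing
#' age, gender or deprivation data are excluded up front.
#'
#' @param patients Data frame with columns `patient_id`, `year_of_birth`,
#'   `gender`, `imd_quintile`, `registration_start`, `registration_end`
#'   (NA = still registered).
#' @param events Data frame with columns `patient_id`, `event_date`, `code`.
#' @param codelists One codelist data.frame (see [codelist()]) or a list of
#'   them; one condition flag per distinct condition.
#' @param months Months to slice (anything accepted by [as_month()]).
#' @param age_range Inclusive age limits at the first of the month.
#' @param min_registration_days Minimum days registered before the first of
#'   the month ("registered for at least 1 year" = 365 days, the default).
#' @param age_bands Inclusive lower band edges for the age stratifier.
#' @param age_mode `"july"` (year-of-birth data; ages jump each July) or
#'   `"exact"` (requires a `date_of_birth` column on `patients`).
#' @return A `monthly_slices` object; empty months (no eligible patients) are
#'   retained as explicit gaps with a warning.
#' @export
build_primary_care_slices <- function(patients, events, codelists, months,
                                      age_range = c(20L, 110L),
                                      min_registration_days = 365L,
                                      age_bands = c(20L, 40L, 60L, 80L),
                                      age_mode = c("july", "exact")) {
  age_mode <- match.arg(age_mode)
  months <- as_month(months)
  months <- months[order(months)]
  cl <- validate_codelists(codelists)
  conditions <- unique(cl$condition)

  pt <- data.table::as.data.table(patients)
  required <- c("patient_id", "year_of_birth", "gender", "imd_quintile",
                "registration_start", "registration_end")
  if (!all(required %in% names(pt))) {
    stop("patients must have columns ",
         paste(setdiff(required, names(pt)), collapse = ", "))
  }
  complete <- !(is.na(pt$year_of_birth) | is.na(pt$gender) |
                  is.na(pt$imd_quintile))
  if (any(!complete)) {
    message(sum(!complete),
            " patient(s) with missing age/gender/IMD excluded")
    pt <- pt[complete]
  }
  if (!all(pt$imd_quintile %in% 1:5)) stop("imd_quintile must be in 1..5")
  both <- !is.na(pt$registration_end)
  if (any(pt$registration_start[both] > pt$registration_end[both])) {
    stop("registration_start after registration_end")
  }

  # first qualifying code date per patient x condition
  ev <- data.table::as.data.table(events)
  ev <- ev[!is.na(ev$event_date)]
  match_code <- ev$code
  icd <- cl$terminology == "icd10-3char"
  lut <- stats::setNames(cl$condition, cl$code)
  cond_hit <- lut[match_code]
  if (any(icd)) {
    lut3 <- stats::setNames(cl$condition[icd], cl$code[icd])
    miss <- is.na(cond_hit)
    cond_hit[miss] <- lut3[substr(match_code[miss], 1L, 3L)]
  }
  ev <- ev[!is.na(cond_hit)]
  ev[, condition := cond_hit[!is.na(cond_hit)]]
  patient_id <- event_date <- condition <- NULL # data.table NSE
  firsts <- if (nrow(ev)) {
    ev[, .(first_date = min(event_date)), by = .(patient_id, condition)]
  } else {
    data.table::data.table(patient_id = character(), condition = character(),
                           first_date = as.Date(character()))
  }

  n <- nrow(pt)
  fd <- matrix(NA_real_, n, length(conditions),
               dimnames = list(NULL, conditions))
  row_of <- stats::setNames(seq_len(n), as.character(pt$patient_id))
  ridx <- row_of[as.character(firsts$patient_id)]
  known <- !is.na(ridx)
  fd[cbind(ridx[known], match(firsts$condition[known], conditions))] <-
    as.numeric(firsts$first_date[known])

  gender_levels <- sort(unique(as.character(pt$gender)))
  schema <- c(
    list(age_band = band_labels(age_bands),
         gender = gender_levels,
         imd_quintile = as.character(1:5)),
    stats::setNames(rep(list(c("0", "1")), length(conditions)), conditions)
  )

  reg_start <- as.numeric(pt$registration_start)
  reg_end <- as.numeric(pt$registration_end)
  yob <- pt$year_of_birth
  gender_chr <- as.character(pt$gender)
  imd_chr <- as.character(pt$imd_quintile)

  slices <- vector("list", length(months))
  for (i in seq_along(months)) {
    m <- months[i]
    m_num <- as.numeric(m)
    age <- if (age_mode == "july") {
      month_year(m) - yob - as.integer(month_of_year(m) < 7L)
    } else {
      floor(as.numeric(m - as.Date(pt$date_of_birth)) / 365.25)
    }
    elig <- age >= age_range[1] & age <= age_range[2] &
      reg_start <= m_num - min_registration_days &
      (is.na(reg_end) | reg_end >= m_num)
    idx <- which(elig)
    if (length(idx) == 0L) {
      warning("no eligible patients in ", format_month(m),
              "; month retained as an explicit gap", call. = FALSE)
      slices[[i]] <- new_monthly_slice(m, NULL, 0L)
      next
    }
    dt <- data.table::data.table(
      age_band = as.character(cut(age[idx], c(sort(age_bands), Inf),
                                  right = FALSE, labels = band_labels(age_bands))),
      gender = gender_chr[idx],
      imd_quintile = imd_chr[idx]
    )
    for (cond in conditions) {
      f <- fd[idx, cond]
      dt[[cond]] <- ifelse(!is.na(f) & f < m_num, "1", "0")
    }
    cells <- dt[, .N, by = names(dt)]
    data.table::setnames(cells, "N", "count")
    data.table::setorderv(cells, names(schema))
    slices[[i]] <- new_monthly_slice(m, cells, length(idx))
  }
  new_monthly_slices(slices, schema)
}

#' Monthly slices of preaggregated hospital code counts
#'
#' Filters a (month, age band, gender, deprivation quintile, 3-character
#' code, count) table to the codes in `codelist`, truncating ICD-10 codes to
#' 3 characters before matching, and sums counts per demographic x code cell.
#' The monthly denominator is the total number of included codes in that
#' month — codes outside the codelist are dropped before the denominator is
#' formed.
#'
#' @param count_table Data frame with columns `month`, `age_band`, `gender`,
#'   `imd_quintile`, `code`, `count`.
#' @param codelist A codelist data.frame (see [codelist()]) or character
#'   vector of included 3-character codes.
#' @param months Months to slice.
#' @param age_bands Optional character vector of valid age-band labels;
#'   unknown labels in the data are an error. Defaults to the labels observed.
#' @return A `monthly_slices` object over variables `age_band`, `gender`,
#'   `imd_quintile`, `code`.
#' @export
build_hospital_slices <- function(count_table, codelist, months,
                                  age_bands = NULL) {
  months <- sort(as_month(months))
  ct <- data.table::as.data.table(count_table)
  required <- c("month", "age_band", "gender", "imd_quintile", "code", "count")
  if (!all(required %in% names(ct))) {
    stop("count_table must have columns ",
         paste(setdiff(required, names(ct)), collapse = ", "))
  }
  if (any(ct$count < 0)) stop("negative counts in count_table")
  if (is.data.frame(codelist)) codelist <- codelist$code
  codelist <- unique(substr(as.character(codelist), 1L, 3L))

  ct[, month := as_month(month)]
  ct[, code := substr(as.character(code), 1L, 3L)]
  if (is.null(age_bands)) {
    age_bands <- sort(unique(as.character(ct$age_band)))
  } else {
    unknown <- setdiff(unique(as.character(ct$age_band)), age_bands)
    if (length(unknown)) {
      stop("unknown age band label(s): ", paste(unknown, collapse = ", "))
    }
  }
  code <- count <- NULL # data.table NSE
  ct <- ct[code %in% codelist]

  schema <- list(
    age_band = age_bands,
    gender = sort(unique(as.character(ct$gender))),
    imd_quintile = as.character(sort(unique(ct$imd_quintile))),
    code = sort(codelist)
  )
  ct[, `:=`(age_band = as.character(age_band),
            gender = as.character(gender),
            imd_quintile = as.character(imd_quintile))]

  slices <- vector("list", length(months))
  for (i in seq_along(months)) {
    m <- months[i]
    sub <- ct[month == m,
              .(count = sum(count)),
              by = .(age_band, gender, imd_quintile, code)]
    denom <- sum(sub$count)
    if (denom == 0L) {
      warning("no included codes in ", format_month(m),
              "; month retained as an explicit gap", call. = FALSE)
      slices[[i]] <- new_monthly_slice(m, NULL, 0L)
      next
    }
    data.table::setorderv(sub, names(schema))
    slices[[i]] <- new_monthly_slice(m, sub, denom)
  }
  new_monthly_slices(slices, schema)
}
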