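# Delimited-text readers/writers for the package's table schemas (RFC-4180
# CSV via data.table). Dates are ISO "YYYY-MM-DD"; months "YYYY-MM".

read_csv_checked <- function(file, required, what) {
  d <- data.table::fread(file, na.strings = c("", "NA"))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(what, " file is missing column(s): ", paste(missing, collapse = ", "))
  }
  d <- as.data.frame(d)
  if ("code" %in% names(d)) d$code <- as.character(d$code)
  d
}

as_date_col <- function(x) as.Date(as.character(x))

#' Read and write the package's delimited-text tables
#'
#' Patient tables (`patient_id`, `year_of_birth`, `gender`, `imd_quintile`,
#' `registration_start`, `registration_end`), event tables (`patient_id`,
#' `event_date`, `code`), hospital count tables (`month`, `age_band`,
#' `gender`, `imd_quintile`, `code`, `count`) and codelists (`condition`,
#' `code`, `terminology`) are exchanged as RFC-4180 CSV.
#'
#' @param file Path to a CSV file.
#' @param x Table to write.
#' @return Readers return a data.frame; writers return `file` invisibly.
#' @name ehr_io
NULL

#' @rdname ehr_io
#' @export
read_patients <- function(file) {
  p <- read_csv_checked(file, c("patient_id", "year_of_birth", "gender",
                                "imd_quintile", "registration_start",
                                "registration_end"), "patients")
  p$registration_start <- as_date_col(p$registration_start)
  p$registration_end <- as_date_col(p$registration_end)
  p
}

#' @rdname ehr_io
#' @export
read_events <- function(file) {
  e <- read_csv_checked(file, c("patient_id", "event_date", "code"), "events")
  e$event_date <- as_date_col(e$event_date)
  e
}

#' @rdname ehr_io
#' @export
read_counts <- function(file) {
  ct <- read_csv_checked(file, c("month", "age_band", "gender", "imd_quintile",
                                 "code", "count"), "counts")
  ct$month <- as_month(as.character(ct$month))
  ct
}

#' @rdname ehr_io
#' @export
read_codelist <- function(file) {
  validate_codelists(read_csv_checked(file, c("condition", "code",
                                              "terminology"), "codelist"))
}

#' @rdname ehr_io
#' @export
write_table_csv <- function(x, file) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (inherits(x[[nm]], "Date")) x[[nm]] <- format(x[[nm]])
  }
  data.table::fwrite(x, file, quote = TRUE, na = "")
  invisible(file)
}
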