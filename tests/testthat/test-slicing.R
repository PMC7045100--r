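mk_patient <- function(id = 1L, yob = 1960L, gender = "F", imd = 3L,
                       start = "2000-01-15", end = NA) {
  data.frame(patient_id = id, year_of_birth = yob, gender = gender,
             imd_quintile = imd, registration_start = as.Date(start),
             registration_end = as.Date(end), stringsAsFactors = FALSE)
}

test_that("condition flags obey the strict 'before the month' boundary", {
  patients <- mk_patient()
  events <- data.frame(patient_id = 1L, event_date = as.Date("2003-05-10"),
                       code = "G30..", stringsAsFactors = FALSE)
  sl <- build_primary_care_slices(patients, events, pc_codelists(),
                                  month_seq("2003-05", "2003-06"))
  dtm <- estimate_dtm(sl)
  chd <- marginalize(dtm, "chd")
  expect_equal(unname(chd$probabilities[1, chd$support$chd == "1"]), 0)
  expect_equal(unname(chd$probabilities[2, chd$support$chd == "1"]), 1)
})

test_that("ages increment in July under the year-of-birth convention", {
  # born 1980: age 20 in Jan-Jun 2001, 21 from Jul 2001
  bands <- c(20L, 21L)
  for (m in 1:6) {
    expect_equal(as.character(compute_age_band(1980L, sprintf("2001-%02d", m),
                                               bands)), "20-20")
  }
  for (m in 7:12) {
    expect_equal(as.character(compute_age_band(1980L, sprintf("2001-%02d", m),
                                               bands)), "21+")
  }
  # born 1941: band 40-59 in June 2001, 60-79 from July 2001
  std <- c(20L, 40L, 60L, 80L)
  expect_equal(as.character(compute_age_band(1941L, "2001-06", std)), "40-59")
  expect_equal(as.character(compute_age_band(1941L, "2001-07", std)), "60-79")
})

test_that("age banding agrees with a brute-force reference over all birth years", {
  edges <- c(20L, 40L, 60L, 80L)
  labs <- c("20-39", "40-59", "60-79", "80+")
  for (mo in 1:12) {
    month <- sprintf("2001-%02d", mo)
    # before July the age of someone born in 2001 would be negative (rejected)
    yobs <- 1891:(if (mo >= 7) 2001 else 2000)
    got <- as.character(compute_age_band(yobs, month, edges))
    ref <- vapply(yobs, function(y) {
      age <- if (mo >= 7) 2001L - y else 2001L - y - 1L
      if (age < 20L) return(NA_character_)
      if (age < 40L) labs[1] else if (age < 60L) labs[2]
      else if (age < 80L) labs[3] else labs[4]
    }, character(1))
    expect_identical(got, ref)
  }
  expect_error(compute_age_band(2010L, "2001-01", edges), "negative")
  expect_error(compute_age_band(1850L, "2001-01", edges), "plausible")
})

test_that("eligibility rules match the stated registration and age windows", {
  patients <- rbind(
    mk_patient(1L, start = "2002-06-15"),            # <1 year registered mid-2003
    mk_patient(2L, start = "2000-01-01", end = "2003-06-10"), # leaves mid-June
    mk_patient(3L, yob = 1995L, start = "2000-01-01"),        # under 20
    mk_patient(4L, yob = NA, start = "2000-01-01")            # incomplete
  )
  events <- data.frame(patient_id = integer(), event_date = as.Date(character()),
                       code = character())
  expect_message(
    sl <- build_primary_care_slices(patients, events, pc_codelists(),
                                    month_seq("2003-06", "2003-07")),
    "missing age/gender/IMD")
  # June: patient 1 not yet 1 year (2003-06-01 - 2002-06-15 < 365); patient 2
  # still contributes despite leaving mid-month; patient 3 under age
  expect_equal(sl[[1]]$denominator, 1L)
  # July: patient 1 passes 1 year on 2003-06-15; patient 2 has left
  expect_equal(sl[[2]]$denominator, 1L)
})

test_that("slice denominators match a brute-force interval scan under churn", {
  sc <- small_pc_scenario(n = 3000L, seed = 8L, churn_rate = 0.01,
                          entry_prevalence_factor = 0.5, end = "2002-12")
  gen <- generate_primary_care(sc)
  months <- month_seq("2001-01", "2002-12")
  sl <- build_primary_care_slices(gen$patients, gen$events, pc_codelists(),
                                  months)
  for (i in seq(1, 24, by = 5)) {
    expect_equal(sl[[i]]$denominator,
                 oracle_denominator(gen$patients, months[i]))
  }
  # conservation: cell counts sum to the eligible denominator
  for (i in seq_along(sl)) {
    expect_equal(sum(sl[[i]]$cells$count), sl[[i]]$denominator)
  }
  # slicing is reproducible
  sl2 <- build_primary_care_slices(gen$patients, gen$events, pc_codelists(),
                                   months)
  expect_identical(lapply(sl, `[[`, "cells"), lapply(sl2, `[[`, "cells"))
})

test_that("ever-recorded flags are monotone in a closed cohort", {
  sc <- small_pc_scenario(n = 5000L, seed = 3L, end = "2002-12")
  gen <- generate_primary_care(sc)
  sl <- build_primary_care_slices(gen$patients, gen$events, pc_codelists(),
                                  month_seq("2001-01", "2002-12"))
  dtm <- estimate_dtm(sl)
  for (cond in c("chd", "stroke")) {
    mg <- marginalize(dtm, cond)
    n_flagged <- mg$counts[, mg$support[[cond]] == "1"]
    expect_true(all(diff(n_flagged) >= 0))
  }
})

test_that("hospital slices drop excluded codes before forming the denominator", {
  ct <- data.frame(month = "2001-01", age_band = "40-44", gender = "M",
                   imd_quintile = 1L, code = c("I21", "Z99"),
                   count = c(10L, 5L))
  sl <- build_hospital_slices(ct, "I21", "2001-01")
  expect_equal(sl[[1]]$denominator, 10L)

  ct2 <- data.frame(month = "2001-01", age_band = "60-64", gender = "F",
                    imd_quintile = 2L, code = c("I20", "I21"),
                    count = c(188L, 812L))
  dtm <- estimate_dtm(build_hospital_slices(ct2, c("I20", "I21"), "2001-01"))
  code <- marginalize(dtm, "code")
  expect_equal(unname(code$probabilities[1, ]), c(0.188, 0.812))
})

test_that("hospital slice shares match generator targets within multinomial error", {
  n <- 50000L
  sc <- small_hes_scenario(n_months = 3L, volume = n, seed = 4L)
  gen <- generate_hospital_counts(sc)
  dtm <- marginalize(hes_dtm(gen), "code")
  shares <- vapply(sc$conditions, condition_targets, numeric(3L), sc$months)
  for (code in names(sc$conditions)) {
    p <- shares[1, code]
    ci <- 2.58 * sqrt(p * (1 - p) / n) # binomial 99% interval
    got <- dtm$probabilities[, dtm$support$code == code]
    expect_true(all(abs(got - p) <= ci))
  }
})

test_that("invalid hospital inputs are rejected", {
  ct <- data.frame(month = "2001-01", age_band = "40-44", gender = "M",
                   imd_quintile = 1L, code = "I21", count = -1L)
  expect_error(build_hospital_slices(ct, "I21", "2001-01"), "negative")
  ct$count <- 1L
  expect_error(build_hospital_slices(ct, "I21", "2001-01",
                                     age_bands = c("40-49", "50+")),
               "unknown age band")
  patients <- mk_patient()
  no_events <- data.frame(patient_id = integer(),
                          event_date = as.Date(character()),
                          code = character())
  expect_error(
    build_primary_care_slices(patients, no_events,
                              data.frame(condition = "x", code = "I21",
                                         terminology = "snomed"),
                              "2003-01"),
    "unknown code terminology")
  expect_error(
    build_primary_care_slices(patients, no_events,
                              rbind(codelist("a", "G30.."),
                                    codelist("b", "G30..")),
                              "2003-01"),
    "two conditions")
})

test_that("ICD-10 codes are truncated to 3 characters before matching", {
  ct <- data.frame(month = "2001-01", age_band = "40-44", gender = "M",
                   imd_quintile = 1L, code = c("I219", "I210", "I639"),
                   count = c(5L, 5L, 10L))
  sl <- build_hospital_slices(ct, c("I21", "I63"), "2001-01")
  expect_equal(sl[[1]]$denominator, 20L)
  expect_equal(nrow(sl[[1]]$cells), 2L) # I219 + I210 pooled into I21
})
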