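# Small scenario builders shared across test files. Sizes are scaled down
# from the preset scenarios where a check is about mechanics rather than
# statistical power.

small_pc_scenario <- function(n = 20000L, seed = 1L, churn_rate = 0,
                              entry_prevalence_factor = 1,
                              conditions = NULL, end = "2003-12",
                              dropout_schedule = NULL, mix_shifts = NULL) {
  if (is.null(conditions)) {
    conditions <- list(
      condition_spec("chd", codes = c("G30..", "G33.."),
                     trajectory = data.frame(month = c("2001-01", end),
                                             value = c(0.045, 0.048))),
      condition_spec("stroke", codes = c("G61..", "G64.."),
                     trajectory = 0.0144)
    )
  }
  scenario_config(
    mode = "primary_care", start_month = "2001-01", end_month = end,
    n_patients = n, conditions = conditions, churn_rate = churn_rate,
    entry_prevalence_factor = entry_prevalence_factor,
    dropout_schedule = dropout_schedule, mix_shifts = mix_shifts, seed = seed
  )
}

pc_codelists <- function() {
  rbind(codelist("chd", c("G30..", "G33..")),
        codelist("stroke", c("G61..", "G64..")))
}

small_hes_scenario <- function(n_months = 24L, volume = 50000L,
                               step_index = NULL, seed = 1L) {
  scenario_hes_like(monthly_volume = volume, n_months = n_months,
                    step_index = step_index, seed = seed)
}

# run the hospital pipeline up to a joint DTM
hes_dtm <- function(gen) {
  months <- sort(unique(gen$counts$month))
  sl <- build_hospital_slices(gen$counts, unique(gen$counts$code), months)
  estimate_dtm(sl)
}
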