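test_that("generation is byte-identical under a fixed seed", {
  sc <- function() small_pc_scenario(n = 2000L, seed = 11L, end = "2001-12")
  expect_identical(generate_primary_care(sc()), generate_primary_care(sc()))
  hs <- function() small_hes_scenario(n_months = 6L, volume = 5000L, seed = 11L)
  expect_identical(generate_hospital_counts(hs()),
                   generate_hospital_counts(hs()))
  # a different seed changes the draw
  other <- small_pc_scenario(n = 2000L, seed = 12L, end = "2001-12")
  expect_false(identical(generate_primary_care(sc())$events,
                         generate_primary_care(other)$events))
})

test_that("hospital monthly totals equal the configured volume", {
  gen <- generate_hospital_counts(small_hes_scenario(n_months = 8L,
                                                     volume = 30000L))
  totals <- tapply(gen$counts$count, format_month(gen$counts$month), sum)
  expect_true(all(totals == 30000L))
})

test_that("constant trajectories give flat prevalence up to rounding", {
  sc <- small_pc_scenario(
    n = 20000L, seed = 5L, end = "2002-12",
    conditions = list(condition_spec("chd", codes = c("G30..", "G33.."),
                                     trajectory = 0.045),
                      condition_spec("stroke", codes = c("G61..", "G64.."),
                                     trajectory = 0.0144)))
  gen <- generate_primary_care(sc)
  sl <- build_primary_care_slices(gen$patients, gen$events, pc_codelists(),
                                  month_seq("2001-01", "2002-12"))
  dtm <- estimate_dtm(sl)
  for (cond in c("chd", "stroke")) {
    mg <- marginalize(dtm, cond)
    prev <- mg$probabilities[, mg$support[[cond]] == "1"]
    target <- if (cond == "chd") 0.045 else 0.0144
    expect_lt(max(abs(prev - target)), 1e-4) # count-matching: rounding only
  }
})

test_that("a planted linear rise reproduces the configured relative change", {
  # stroke 14.4 -> 23.4 per 1000 over 84 months at the default cohort size
  sc <- scenario_cprd_like(n_patients = 200000L, seed = 2L)
  gen <- generate_primary_care(sc)
  cl <- rbind(codelist("chd", c("G30..", "G33..")),
              codelist("heart_failure", c("G58..", "G580.")),
              codelist("pad", c("G73..", "G731.")),
              codelist("stroke", c("G61..", "G64..")))
  sl <- build_primary_care_slices(gen$patients, gen$events, cl,
                                  month_seq("2001-01", "2007-12"))
  dtm <- estimate_dtm(sl)
  mg <- marginalize(dtm, "stroke")
  prev <- mg$probabilities[, mg$support$stroke == "1"]
  rel <- 100 * (prev[84] - prev[1]) / prev[1]
  expect_lt(abs(rel - 62.5), 5) # within +-5 percentage points of the target
  # heart failure roughly doubles over the same window
  mh <- marginalize(dtm, "heart_failure")
  ph <- mh$probabilities[, mh$support$heart_failure == "1"]
  expect_lt(abs(ph[1] - 0.0067), 5e-4)
  expect_lt(abs(ph[84] - 0.0108), 5e-4)
})

test_that("selective dropout shifts the deprivation mix beyond baseline JSD", {
  sc <- small_pc_scenario(
    n = 30000L, seed = 7L, end = "2003-12",
    dropout_schedule = data.frame(month = "2003-01", retained = 0.6),
    mix_shifts = list(mix_shift_spec("imd_quintile", "2003-01", "2003-01",
                                     weights = c(`4` = 8, `5` = 8))))
  gen <- generate_primary_care(sc)
  sl <- build_primary_care_slices(gen$patients, gen$events, pc_codelists(),
                                  month_seq("2001-01", "2003-12"))
  imd <- marginalize(estimate_dtm(sl), "imd_quintile")
  # oracle: the dissimilarity module itself, on the generator output
  pre <- imd$probabilities[1:24, ]
  baseline <- max(vapply(1:23, function(i) {
    js_divergence(pre[i, ], pre[i + 1, ])
  }, numeric(1)))
  shift <- js_divergence(imd$probabilities[24, ], imd$probabilities[30, ])
  expect_gt(shift, baseline)
  expect_equal(nrow(gen$manifest$planted_mix_shifts), 2L) # weights + schedule
})

test_that("degenerate demographic marginals concentrate all hospital counts", {
  sc <- scenario_config(
    mode = "hospital", start_month = "2001-01", end_month = "2001-06",
    monthly_volume = 2000L,
    demographics = list(age_band = c("60-64" = 1), gender = c(M = 1),
                        imd_quintile = c(`3` = 1)),
    conditions = list(condition_spec("I21", trajectory = 0.5)),
    seed = 3L)
  gen <- generate_hospital_counts(sc)
  expect_true(all(gen$counts$age_band == "60-64"))
  expect_true(all(gen$counts$gender == "M"))
  expect_true(all(gen$counts$imd_quintile == 3L))
  expect_setequal(unique(gen$counts$code), c("I21", "OTH"))
})

test_that("a planted share step reproduces the configured +36% change", {
  sc <- scenario_hes_like(monthly_volume = 50000L, n_months = 24L,
                          step_index = 12L, seed = 6L)
  gen <- generate_hospital_counts(sc)
  dtm <- marginalize(hes_dtm(gen), "code")
  share <- dtm$probabilities[, dtm$support$code == "I21"]
  before <- mean(share[1:12])
  after <- mean(share[13:24])
  expect_lt(abs(before - 0.080), 0.005)
  expect_lt(abs(after - 0.109), 0.005)
  rel <- 100 * (after - before) / before
  expect_lt(abs(rel - 36.25), 5)
  # the step lands exactly at the configured transition
  expect_gt(abs(share[13] - share[12]), 5 * max(abs(diff(share[1:12]))))
})

test_that("a share swap between codes leaves the demographic margin unchanged", {
  sc <- scenario_config(
    mode = "hospital", start_month = "2001-01", end_month = "2002-12",
    monthly_volume = 50000L,
    demographics = default_demographics("hospital"),
    conditions = list(
      condition_spec("I20", trajectory = 0.2,
                     step_changes = data.frame(month = "2002-01", factor = 1.5)),
      condition_spec("I21", trajectory = 0.3,
                     step_changes = data.frame(month = "2002-01",
                                               factor = 2 / 3))),
    seed = 9L)
  gen <- generate_hospital_counts(sc)
  dtm <- hes_dtm(gen)
  # oracle: marginalisation in the temporal-map module
  code <- marginalize(dtm, "code")
  step_jsd_code <- js_divergence(code$probabilities[12, ],
                                 code$probabilities[13, ])
  for (v in c("age_band", "gender", "imd_quintile")) {
    mg <- marginalize(dtm, v)
    step_jsd <- js_divergence(mg$probabilities[12, ], mg$probabilities[13, ])
    noise <- vapply(1:11, function(i) {
      js_divergence(mg$probabilities[i, ], mg$probabilities[i + 1, ])
    }, numeric(1))
    expect_lt(step_jsd, max(noise) * 3 + 1e-6)
    expect_gt(step_jsd_code, 50 * step_jsd)
  }
})

test_that("churn entrants let recorded prevalence fall as configured", {
  decline <- list(condition_spec(
    "chd", codes = c("G30..", "G33.."),
    trajectory = data.frame(month = c("2001-01", "2003-12"),
                            value = c(0.06, 0.04))))
  sc <- scenario_config("primary_care", "2001-01", "2003-12",
                        conditions = decline, n_patients = 20000L,
                        churn_rate = 0.04, entry_prevalence_factor = 0.3,
                        seed = 13L)
  gen <- generate_primary_care(sc)
  cl <- codelist("chd", c("G30..", "G33.."))
  sl <- build_primary_care_slices(gen$patients, gen$events, cl,
                                  month_seq("2001-01", "2003-12"))
  mg <- marginalize(estimate_dtm(sl), "chd")
  prev <- mg$probabilities[, mg$support$chd == "1"]
  expect_lt(prev[36], prev[1] - 0.005) # a real decline materialises
})
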