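# Synthetic EHR generator with planted temporal structure. Two shapes are
# emulated: longitudinal primary-care-style records (patient + event tables,
# ever-recorded diagnoses ascertained from dated codes) and hospital-style
# monthly counts preaggregated by demography and 3-character code. Both emit
# a ground-truth manifest of every planted effect so downstream detectors can
# be scored against known labels.

parse_band_range <- function(label, open_width = 15L) {
  # "40-59" -> c(40, 59); "80+" -> c(80, 80 + open_width)
  if (grepl("\\+$", label)) {
    lo <- as.integer(sub("\\+$", "", label))
    c(lo, lo + open_width)
  } else {
    as.integer(strsplit(label, "-", fixed = TRUE)[[1]])
  }
}

sample_demographics <- function(n, demographics, month) {
  bands <- names(demographics$age_band)
  band <- sample(bands, n, replace = TRUE, prob = demographics$age_band)
  ranges <- lapply(bands, parse_band_range)
  names(ranges) <- bands
  age <- vapply(band, function(b) {
    r <- ranges[[b]]
    sample(r[1]:r[2], 1L)
  }, integer(1))
  # invert the July age convention so the sampled age holds at `month`
  yob <- month_year(month) - age - as.integer(month_of_year(month) < 7L)
  list(
    year_of_birth = unname(yob),
    gender = sample(names(demographics$gender), n, replace = TRUE,
                    prob = demographics$gender),
    imd_quintile = sample(names(demographics$imd_quintile), n, replace = TRUE,
                          prob = demographics$imd_quintile)
  )
}

#' Generate a synthetic primary-care cohort with planted temporal effects
#'
#' Simulates a CPRD-GOLD-shaped dataset: a patient table (year of birth,
#' gender, deprivation quintile, registration interval) and an event table of
#' dated first-ever diagnosis codes, such that after ever-recorded
#' ascertainment the monthly recorded prevalence of each condition tracks its
#' configured trajectory. Prevalence is matched by deterministic
#' count-matching: each month, exactly enough unaffected eligible patients
#' (chosen uniformly at random) receive a first code dated in the previous
#' month to bring the affected count to `round(target * n_eligible)`.
#' Declines are only possible through registration churn (leavers replaced by
#' entrants seeded at `entry_prevalence_factor` times the target), mirroring
#' how recorded prevalence genuinely falls in an open cohort; the
#' configuration is rejected otherwise. A dropout schedule removes patients
#' without replacement, optionally biased by mix-shift weights (e.g. towards
#' particular deprivation quintiles) to emulate selective practice dropout.
#'
#' @param config A [scenario_config()] in `"primary_care"` mode.
#' @return A list with elements `patients` (data.frame), `events`
#'   (data.frame with `patient_id`, `event_date`, `code`) and `manifest`
#'   (ground-truth labels for every planted effect).
#' @seealso [generate_hospital_counts()], [build_primary_care_slices()]
#' @export
generate_primary_care <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "primary_care") {
    stop("config is not in primary_care mode")
  }
  months <- config$months
  n_months <- length(months)
  conds <- config$conditions
  k <- length(conds)
  targets <- vapply(conds, condition_targets, numeric(n_months), months)
  targets <- matrix(targets, nrow = n_months,
                    dimnames = list(NULL, names(conds)))

  # dropout weights by category, if any weighted mix shift is configured
  dropout_ws <- Filter(function(ms) !is.null(ms$weights),
                       config$mix_shifts %||% list())

  set.seed(split_seed(config$seed, 1L))
  n0 <- config$n_patients
  demo <- sample_demographics(n0, config$demographics, months[1])
  start_num <- as.numeric(months[1])
  st <- list(
    id = seq_len(n0),
    yob = demo$year_of_birth,
    gender = demo$gender,
    imd = demo$imd_quintile,
    reg_start = start_num - sample(366:4017, n0, replace = TRUE),
    reg_end = rep(NA_real_, n0),
    first_date = matrix(NA_real_, n0, k, dimnames = list(NULL, names(conds)))
  )
  next_id <- n0 + 1L

  active_at <- function(m_num) {
    st$reg_start <= m_num & (is.na(st$reg_end) | st$reg_end >= m_num)
  }
  eligible_at <- function(m, m_num) {
    age <- month_year(m) - st$yob - as.integer(month_of_year(m) < 7L)
    age >= 20L & age <= 110L &
      st$reg_start <= m_num - 365 &
      (is.na(st$reg_end) | st$reg_end >= m_num)
  }

  ds <- config$dropout_schedule
  for (t in seq_len(n_months)) {
    m <- months[t]
    m_num <- as.numeric(m)
    set.seed(split_seed(config$seed, 2L, t))

    # registration churn: leavers (still contributing to this month) are
    # replaced one-for-one by new registrants, eligible 12 months later
    if (t > 1L && config$churn_rate > 0) {
      act <- which(active_at(m_num))
      n_leave <- stats::rbinom(1L, length(act), config$churn_rate)
      if (n_leave > 0L) {
        leavers <- sample(act, n_leave)
        st$reg_end[leavers] <- m_num + sample(0:27, n_leave, replace = TRUE)
        demo <- sample_demographics(n_leave, config$demographics, m)
        st$id <- c(st$id, seq.int(next_id, length.out = n_leave))
        next_id <- next_id + n_leave
        st$yob <- c(st$yob, demo$year_of_birth)
        st$gender <- c(st$gender, demo$gender)
        st$imd <- c(st$imd, demo$imd_quintile)
        st$reg_start <- c(st$reg_start, rep(m_num, n_leave))
        st$reg_end <- c(st$reg_end, rep(NA_real_, n_leave))
        fd_new <- matrix(NA_real_, n_leave, k)
        # entrants carry conditions at a configurable fraction of the target
        for (j in seq_len(k)) {
          p_entry <- min(config$entry_prevalence_factor * targets[t, j], 1)
          hit <- stats::runif(n_leave) < p_entry
          fd_new[hit, j] <- m_num - sample(30:365, sum(hit), replace = TRUE)
        }
        st$first_date <- rbind(st$first_date, fd_new)
      }
    }

    # scheduled practice dropout: shrink the active population to the
    # retained fraction, optionally biased by mix-shift weights
    if (!is.null(ds) && any(ds$month == m)) {
      retained <- ds$retained[ds$month == m]
      act <- which(active_at(m_num))
      excess <- length(act) - round(retained * n0)
      if (excess > 0L) {
        w <- rep(1, length(act))
        for (ms in dropout_ws) {
          cat_vals <- switch(ms$variable,
                             age_band = as.character(cut_age_band(
                               st$yob[act], m,
                               band_lower_edges(names(config$demographics$age_band)))),
                             gender = st$gender[act],
                             imd_quintile = st$imd[act])
          w <- w * ifelse(cat_vals %in% names(ms$weights),
                          ms$weights[cat_vals], 1)
        }
        leavers <- sample(act, excess, prob = w)
        st$reg_end[leavers] <- m_num + sample(0:27, excess, replace = TRUE)
      }
    }

    # deterministic count-matching of ever-recorded prevalence to target
    elig <- which(eligible_at(m, m_num))
    n_elig <- length(elig)
    if (n_elig == 0L) next
    for (j in seq_len(k)) {
      set.seed(split_seed(config$seed, 3L, t, j))
      affected <- !is.na(st$first_date[elig, j]) & st$first_date[elig, j] < m_num
      need <- round(targets[t, j] * n_elig) - sum(affected)
      if (need > 0L) {
        pool <- elig[!affected]
        need <- min(need, length(pool))
        conv <- if (length(pool) == 1L) pool else sample(pool, need)
        lag <- if (t == 1L) sample(30:3650, need, replace = TRUE)
               else sample(1:28, need, replace = TRUE)
        st$first_date[conv, j] <- m_num - lag
      }
      # need < 0 can only arise under churn/dropout; ever-recorded status is
      # monotone within a patient, so the surplus decays via entry/exit
    }
  }

  patients <- data.frame(
    patient_id = st$id,
    year_of_birth = st$yob,
    gender = st$gender,
    imd_quintile = as.integer(st$imd),
    registration_start = as.Date(st$reg_start, origin = "1970-01-01"),
    registration_end = as.Date(st$reg_end, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  ev <- list()
  for (j in seq_len(k)) {
    set.seed(split_seed(config$seed, 4L, j))
    hit <- which(!is.na(st$first_date[, j]))
    if (length(hit) == 0L) next
    ev[[j]] <- data.frame(
      patient_id = st$id[hit],
      event_date = as.Date(st$first_date[hit, j], origin = "1970-01-01"),
      code = sample(conds[[j]]$codes, length(hit), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  events <- if (length(ev)) do.call(rbind, ev) else {
    data.frame(patient_id = integer(), event_date = as.Date(character()),
               code = character())
  }
  events <- events[order(events$patient_id, events$event_date), ]
  rownames(events) <- NULL

  list(patients = patients, events = events, manifest = build_manifest(config))
}

# code used for the remainder bucket absorbing unallocated hospital share
REMAINDER_CODE <- "OTH"

#' Generate synthetic hospital-style monthly code counts
#'
#' Simulates a HES-APC-shaped extract: monthly counts preaggregated by age
#' band, gender, deprivation quintile and 3-character code. Each month's
#' counts are one multinomial draw of the configured volume over
#' code x demographic cells, with cell probabilities the product of the
#' month's code shares and demographic marginals (codes and demography
#' independent by construction, so planted code steps leave the demographic
#' marginal untouched). A remainder pseudo-code (`"OTH"`) absorbs the share
#' not allocated to named codes, so monthly shares always normalise; step
#' changes apply exactly from the first day of their month. Mix shifts move
#' the affected demographic marginal linearly across their period.
#'
#' @param config A [scenario_config()] in `"hospital"` mode; condition names
#'   are interpreted as 3-character codes and trajectories as shares of the
#'   monthly coded volume.
#' @return A list with elements `counts` (data.frame: `month`, `age_band`,
#'   `gender`, `imd_quintile`, `code`, `count`; zero cells omitted) and
#'   `manifest`.
#' @seealso [generate_primary_care()], [build_hospital_slices()]
#' @export
generate_hospital_counts <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "hospital") stop("config is not in hospital mode")
  months <- config$months
  n_months <- length(months)
  conds <- config$conditions
  codes <- names(conds)
  shares <- vapply(conds, condition_targets, numeric(n_months), months)
  shares <- matrix(shares, nrow = n_months, dimnames = list(NULL, codes))
  remainder <- 1 - rowSums(shares)
  if (any(remainder < 0)) {
    stop("code shares exceed 1 in month ",
         format_month(months[which(remainder < 0)[1]]))
  }
  shares <- cbind(shares, structure(remainder, names = NULL))
  colnames(shares) <- c(codes, REMAINDER_CODE)

  demo <- config$demographics
  cells <- expand.grid(
    imd_quintile = names(demo$imd_quintile),
    gender = names(demo$gender),
    age_band = names(demo$age_band),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("age_band", "gender", "imd_quintile")]

  marginal_at <- function(variable, t) {
    base <- demo[[variable]]
    for (ms in config$mix_shifts %||% list()) {
      if (ms$variable != variable || is.null(ms$target)) next
      m <- months[t]
      frac <- if (m < ms$start_month) 0
              else if (m >= ms$end_month) 1
              else month_diff(m, ms$start_month) /
                   month_diff(ms$end_month, ms$start_month)
      base <- (1 - frac) * base + frac * ms$target[names(base)]
    }
    base
  }

  out <- vector("list", n_months)
  for (t in seq_len(n_months)) {
    w_age <- marginal_at("age_band", t)
    w_gen <- marginal_at("gender", t)
    w_imd <- marginal_at("imd_quintile", t)
    cell_p <- w_age[cells$age_band] * w_gen[cells$gender] * w_imd[cells$imd_quintile]
    p <- as.vector(outer(cell_p, shares[t, ]))
    set.seed(split_seed(config$seed, 5L, t))
    n <- stats::rmultinom(1L, config$monthly_volume, p)[, 1L]
    keep <- n > 0L
    if (!any(keep)) next
    code_col <- rep(colnames(shares), each = nrow(cells))
    out[[t]] <- data.frame(
      month = months[t],
      age_band = cells$age_band[rep(seq_len(nrow(cells)), ncol(shares))][keep],
      gender = cells$gender[rep(seq_len(nrow(cells)), ncol(shares))][keep],
      imd_quintile = as.integer(cells$imd_quintile[rep(seq_len(nrow(cells)),
                                                       ncol(shares))][keep]),
      code = code_col[keep],
      count = n[keep],
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  list(counts = counts, manifest = build_manifest(config))
}

# --- preset scenarios --------------------------------------------------------

#' Preset scenario: primary-care cohort with gradually rising CVD prevalence
#'
#' A stylised English primary-care world for 2001-2007: four cardiovascular
#' conditions whose recorded prevalence rises linearly across the window
#' (coronary heart disease 44.7 to 48.2 per 1000 patients, heart failure 6.7
#' to 10.8, peripheral arterial disease 7.0 to 10.3, stroke 14.4 to 23.4),
#' reflecting the kind of gradual coding drift seen in UK primary care over
#' that period. Codes are synthetic Read-style strings.
#'
#' @param n_patients Baseline cohort size.
#' @param seed Master seed.
#' @return A `"primary_care"` [scenario_config()].
#' @export
scenario_cprd_like <- function(n_patients = 200000L, seed = 1L) {
  traj <- function(v0, v1) data.frame(month = c("2001-01", "2007-12"),
                                      value = c(v0, v1))
  scenario_config(
    mode = "primary_care",
    start_month = "2001-01", end_month = "2007-12",
    n_patients = n_patients,
    conditions = list(
      condition_spec("chd", codes = c("G30..", "G33.."),
                     trajectory = traj(0.0447, 0.0482)),
      condition_spec("heart_failure", codes = c("G58..", "G580."),
                     trajectory = traj(0.0067, 0.0108)),
      condition_spec("pad", codes = c("G73..", "G731."),
                     trajectory = traj(0.0070, 0.0103)),
      condition_spec("stroke", codes = c("G61..", "G64.."),
                     trajectory = traj(0.0144, 0.0234))
    ),
    seed = seed
  )
}

#' Preset scenario: hospital code counts with an abrupt coding change
#'
#' A stylised hospital world over 180 months from January 2001: six
#' cardiovascular 3-character codes with stable shares of the monthly coded
#' volume, except that the acute myocardial infarction code I21 steps from
#' 8.0% to 10.9% of included codes on the first day of month
#' `step_index + 1` (default month 136, i.e. the transition between months
#' 135 and 136 — the March/April 2012 financial-year boundary). The remainder
#' bucket absorbs the unallocated share.
#'
#' @param monthly_volume Included codes per month.
#' @param n_months Number of months from 2001-01.
#' @param step_index Index of the month-to-month transition at which the step
#'   lands (`NULL` for a null scenario with no planted step).
#' @param seed Master seed.
#' @return A `"hospital"` [scenario_config()].
#' @export
scenario_hes_like <- function(monthly_volume = 50000L, n_months = 180L,
                              step_index = 135L, seed = 1L) {
  months <- month_seq("2001-01", month_add("2001-01", n_months - 1L))
  step <- if (!is.null(step_index)) {
    data.frame(month = months[step_index + 1L], factor = 0.109 / 0.080)
  }
  scenario_config(
    mode = "hospital",
    start_month = months[1], end_month = months[n_months],
    monthly_volume = monthly_volume,
    demographics = default_demographics("hospital"),
    conditions = list(
      condition_spec("I20", trajectory = 0.188),
      condition_spec("I21", trajectory = 0.080, step_changes = step),
      condition_spec("I22", trajectory = 0.014),
      condition_spec("I25", trajectory = 0.200),
      condition_spec("I63", trajectory = 0.100),
      condition_spec("I64", trajectory = 0.080)
    ),
    seed = seed
  )
}
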