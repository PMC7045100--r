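# Scenario configuration for the synthetic cohort generator: a declarative
# description of the temporal structure to plant (prevalence/share
# trajectories, step changes, population-mix shifts, practice dropout and
# registration churn), validated up front so the generators can assume a
# consistent world.

PROB_TOL <- 1e-9

check_prob_vector <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(what, " must be a named probability vector")
  }
  if (any(p < 0)) stop(what, " has negative entries")
  if (abs(sum(p) - 1) > PROB_TOL) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  invisible(p)
}

#' Specify a condition (or hospital code) and its planted temporal behaviour
#'
#' A `condition_spec` describes one clinical condition for the synthetic
#' generator: its label, the clinical codes used to record it, a
#' piecewise-linear target trajectory (recorded prevalence among eligible
#' patients in primary-care mode; share of monthly coded volume in hospital
#' mode) and optional multiplicative step changes. A step listed for month
#' `m` takes effect on the first day of `m`, mirroring how coding-guidance
#' updates hit at financial-year boundaries.
#'
#' @param name Condition label (e.g. `"heart_failure"` or an ICD-10 3-character
#'   code such as `"I21"`).
#' @param codes Character vector of clinical codes used to record the
#'   condition. Defaults to `name` itself (hospital mode, where the code *is*
#'   the category).
#' @param trajectory Either a single value in (0, 1) (constant target) or a
#'   data frame with columns `month` and `value` giving piecewise-linear knots;
#'   values are linearly interpolated between knots and held flat outside them.
#' @param step_changes Optional data frame with columns `month` and `factor`;
#'   from each step month onward the target is multiplied by `factor`
#'   (cumulatively across steps).
#' @return An object of class `condition_spec`.
#' @seealso [scenario_config()], [condition_targets()]
#' @export
#' @examples
#' condition_spec("stroke", codes = c("G61..", "G64.."),
#'   trajectory = data.frame(month = c("2001-01", "2007-12"),
#'                           value = c(0.0144, 0.0234)))
condition_spec <- function(name, codes = name, trajectory, step_changes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(codes), length(codes) >= 1L)
  if (is.numeric(trajectory) && length(trajectory) == 1L) {
    trajectory <- data.frame(month = NA, value = trajectory)
  } else {
    trajectory <- as.data.frame(trajectory)
    if (!all(c("month", "value") %in% names(trajectory))) {
      stop("trajectory must have columns 'month' and 'value'")
    }
    trajectory$month <- as_month(trajectory$month)
    trajectory <- trajectory[order(trajectory$month), c("month", "value")]
  }
  if (any(trajectory$value <= 0 | trajectory$value >= 1)) {
    stop("trajectory values for '", name, "' must lie strictly in (0, 1)")
  }
  if (!is.null(step_changes)) {
    step_changes <- as.data.frame(step_changes)
    if (!all(c("month", "factor") %in% names(step_changes))) {
      stop("step_changes must have columns 'month' and 'factor'")
    }
    step_changes$month <- as_month(step_changes$month)
    if (any(step_changes$factor <= 0)) stop("step factors must be positive")
    step_changes <- step_changes[order(step_changes$month), c("month", "factor")]
  }
  structure(
    list(name = name, codes = codes, trajectory = trajectory,
         step_changes = step_changes),
    class = "condition_spec"
  )
}

#' Evaluate a condition's monthly targets
#'
#' Interpolates the piecewise-linear trajectory over `months` and applies all
#' step changes (each from the first day of its month onward, cumulatively).
#'
#' @param spec A [condition_spec()].
#' @param months `Date` vector of months.
#' @return Numeric vector of per-month targets, strictly in (0, 1).
#' @export
condition_targets <- function(spec, months) {
  stopifnot(inherits(spec, "condition_spec"))
  months <- as_month(months)
  traj <- spec$trajectory
  if (nrow(traj) == 1L) {
    v <- rep(traj$value, length(months))
  } else {
    # linear in month index, so equal monthly increments between knots
    x0 <- traj$month[1]
    v <- stats::approx(month_diff(traj$month, x0), traj$value,
                       xout = month_diff(months, x0), rule = 2)$y
  }
  if (!is.null(spec$step_changes)) {
    for (i in seq_len(nrow(spec$step_changes))) {
      hit <- months >= spec$step_changes$month[i]
      v[hit] <- v[hit] * spec$step_changes$factor[i]
    }
  }
  if (any(v <= 0 | v >= 1)) {
    stop("targets for '", spec$name,
         "' leave (0, 1) after applying step changes")
  }
  v
}

#' Specify a population-mix shift
#'
#' Describes a change in the demographic make-up of the population over a
#' period. In hospital mode the marginal distribution of `variable` moves
#' linearly from its baseline to `target` across `[start_month, end_month]`
#' and stays there. In primary-care mode, `weights` bias which patients are
#' removed by the dropout schedule (e.g. concentrating practice attrition in
#' particular deprivation quintiles).
#'
#' @param variable One of `"age_band"`, `"gender"`, `"imd_quintile"`.
#' @param start_month,end_month Period over which the shift unfolds. Equal
#'   months give an abrupt shift.
#' @param target Named probability vector: the post-shift marginal (hospital
#'   mode).
#' @param weights Named non-negative vector of relative dropout propensities
#'   per category (primary-care mode).
#' @return An object of class `mix_shift_spec`.
#' @export
mix_shift_spec <- function(variable, start_month, end_month,
                           target = NULL, weights = NULL) {
  variable <- match.arg(variable, c("age_band", "gender", "imd_quintile"))
  start_month <- as_month(start_month)
  end_month <- as_month(end_month)
  if (start_month > end_month) stop("mix shift start_month after end_month")
  if (!is.null(target)) check_prob_vector(target, "mix shift target")
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(weights < 0)) {
      stop("mix shift weights must be a named non-negative vector")
    }
  }
  if (is.null(target) && is.null(weights)) {
    stop("a mix shift needs either a target marginal or dropout weights")
  }
  structure(
    list(variable = variable, start_month = start_month,
         end_month = end_month, target = target, weights = weights),
    class = "mix_shift_spec"
  )
}

#' Default demographic marginals for the synthetic generators
#'
#' Primary-care mode uses the four adult age bands 20-39/40-59/60-79/80+;
#' hospital mode uses eight five-year bands from 40-44 up to 75+. Gender is
#' balanced and deprivation quintiles are uniform; these are deliberately
#' plain baselines that planted mix shifts then perturb.
#'
#' @param mode `"primary_care"` or `"hospital"`.
#' @return Named list of named probability vectors (`age_band`, `gender`,
#'   `imd_quintile`).
#' @export
default_demographics <- function(mode = c("primary_care", "hospital")) {
  mode <- match.arg(mode)
  age_band <- if (mode == "primary_care") {
    c("20-39" = 0.30, "40-59" = 0.35, "60-79" = 0.27, "80+" = 0.08)
  } else {
    stats::setNames(rep(1 / 8, 8),
                    c("40-44", "45-49", "50-54", "55-59",
                      "60-64", "65-69", "70-74", "75+"))
  }
  list(
    age_band = age_band,
    gender = c(F = 0.5, M = 0.5),
    imd_quintile = stats::setNames(rep(0.2, 5), as.character(1:5))
  )
}

#' Configure a synthetic EHR scenario
#'
#' Bundles every generative knob of the synthetic cohort module into one
#' validated object: population size or monthly coded volume, study window,
#' demographic marginals, condition trajectories with step changes,
#' population-mix shifts, a practice-dropout schedule and registration churn.
#' All randomness downstream flows from the single integer `seed` through a
#' fixed per-month/per-condition splitting scheme, so a scenario is fully
#' reproducible.
#'
#' @param mode `"primary_care"` (patient + event tables, ever-recorded
#'   diagnoses) or `"hospital"` (preaggregated monthly code counts).
#' @param start_month,end_month Study window (inclusive); `start_month` must
#'   be strictly before `end_month`.
#' @param conditions List of [condition_spec()] objects.
#' @param n_patients Primary-care mode: number of patients registered and
#'   eligible at the start of the window. The default 200000 is chosen for
#'   statistical stability of monthly prevalence estimates.
#' @param monthly_volume Hospital mode: total included codes per month.
#' @param demographics Named list of probability vectors over `age_band`,
#'   `gender` and `imd_quintile`; see [default_demographics()].
#' @param mix_shifts Optional list of [mix_shift_spec()] objects.
#' @param dropout_schedule Optional data frame with columns `month` and
#'   `retained`: the fraction of the baseline population still contributing
#'   from each listed month onward. Fractions must be non-increasing and in
#'   (0, 1]. Primary-care mode only.
#' @param churn_rate Monthly probability that an active patient deregisters
#'   and is replaced by a new registrant (primary-care mode). Churn is the
#'   only mechanism by which ever-recorded prevalence can fall, so a
#'   decreasing trajectory with `churn_rate = 0` is rejected.
#' @param entry_prevalence_factor Multiplier applied to the target prevalence
#'   when seeding conditions in newly eligible churn entrants; values below 1
#'   make recorded prevalence drift downward as entrants replace leavers.
#' @param seed Integer master seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("primary_care", "hospital"),
                            start_month, end_month,
                            conditions,
                            n_patients = 200000L,
                            monthly_volume = 50000L,
                            demographics = default_demographics(mode),
                            mix_shifts = NULL,
                            dropout_schedule = NULL,
                            churn_rate = 0,
                            entry_prevalence_factor = 1,
                            seed = 1L) {
  mode <- match.arg(mode)
  start_month <- as_month(start_month)
  end_month <- as_month(end_month)
  if (!(start_month < end_month)) {
    stop("start_month must be strictly before end_month")
  }
  months <- month_seq(start_month, end_month)

  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (!all(vapply(conditions, inherits, logical(1), "condition_spec"))) {
    stop("conditions must be a list of condition_spec objects")
  }
  names(conditions) <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(names(conditions))) stop("duplicate condition names")

  for (v in c("age_band", "gender", "imd_quintile")) {
    if (is.null(demographics[[v]])) stop("demographics must include ", v)
    check_prob_vector(demographics[[v]], paste0("demographics$", v))
  }

  for (cs in conditions) {
    bad <- !is.null(cs$step_changes) &&
      (any(cs$step_changes$month < start_month) ||
         any(cs$step_changes$month > end_month))
    if (bad) stop("step month for '", cs$name, "' outside the study window")
    # validates (0,1) after steps as a side effect
    tgt <- condition_targets(cs, months)
    if (mode == "primary_care" && churn_rate == 0 &&
        any(diff(tgt) < -PROB_TOL)) {
      stop("trajectory for '", cs$name, "' decreases, but ever-recorded ",
           "prevalence cannot fall in a closed cohort; enable registration ",
           "churn (churn_rate > 0) to allow declines via differential ",
           "entry/exit")
    }
  }
  if (mode == "hospital") {
    share_sum <- Reduce(`+`, lapply(conditions, condition_targets, months))
    if (any(share_sum >= 1)) {
      stop("hospital code shares exceed 1 in month ",
           format_month(months[which(share_sum >= 1)[1]]),
           " (no room left for the remainder bucket)")
    }
  }

  if (!is.null(mix_shifts)) {
    stopifnot(is.list(mix_shifts))
    if (!all(vapply(mix_shifts, inherits, logical(1), "mix_shift_spec"))) {
      stop("mix_shifts must be a list of mix_shift_spec objects")
    }
    for (ms in mix_shifts) {
      base <- demographics[[ms$variable]]
      if (!is.null(ms$target) &&
          !setequal(names(ms$target), names(base))) {
        stop("mix shift target categories must match the ", ms$variable,
             " marginal")
      }
    }
  }

  if (!is.null(dropout_schedule)) {
    dropout_schedule <- as.data.frame(dropout_schedule)
    if (!all(c("month", "retained") %in% names(dropout_schedule))) {
      stop("dropout_schedule must have columns 'month' and 'retained'")
    }
    dropout_schedule$month <- as_month(dropout_schedule$month)
    dropout_schedule <-
      dropout_schedule[order(dropout_schedule$month), c("month", "retained")]
    r <- dropout_schedule$retained
    if (any(r <= 0 | r > 1)) stop("dropout fractions must lie in (0, 1]")
    if (any(diff(r) > 0)) stop("dropout fractions must be non-increasing")
  }

  stopifnot(churn_rate >= 0, churn_rate < 1,
            entry_prevalence_factor >= 0)

  structure(
    list(mode = mode, start_month = start_month, end_month = end_month,
         months = months, conditions = conditions,
         n_patients = as.integer(n_patients),
         monthly_volume = as.integer(monthly_volume),
         demographics = demographics, mix_shifts = mix_shifts,
         dropout_schedule = dropout_schedule, churn_rate = churn_rate,
         entry_prevalence_factor = entry_prevalence_factor,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic EHR scenario (", x$mode, " mode)\n", sep = "")
  cat("  window: ", format_month(x$start_month), " .. ",
      format_month(x$end_month), " (", length(x$months), " months)\n", sep = "")
  if (x$mode == "primary_care") {
    cat("  patients at baseline:", x$n_patients, "\n")
  } else {
    cat("  coded volume per month:", x$monthly_volume, "\n")
  }
  cat("  conditions:", paste(names(x$conditions), collapse = ", "), "\n")
  n_steps <- sum(vapply(x$conditions, function(cs) {
    if (is.null(cs$step_changes)) 0L else nrow(cs$step_changes)
  }, integer(1)))
  cat("  planted steps:", n_steps,
      "| mix shifts:", length(x$mix_shifts %||% list()),
      "| churn rate:", x$churn_rate, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- ground-truth manifest ---------------------------------------------------

# Assembles the labels the detector suites score against. planted_steps carry
# both the calendar month on whose first day the new level applies and the
# index of the month-to-month transition it creates in a consecutive series
# over the scenario's months (step_index = index of the preceding month).
build_manifest <- function(config) {
  months <- config$months
  steps <- list(); trends <- list()
  for (cs in config$conditions) {
    if (!is.null(cs$step_changes)) {
      for (i in seq_len(nrow(cs$step_changes))) {
        f <- cs$step_changes$factor[i]
        m <- cs$step_changes$month[i]
        steps[[length(steps) + 1L]] <- data.frame(
          month = m,
          step_index = month_diff(m, months[1]),
          condition = cs$name,
          direction = ifelse(f > 1, "up", "down"),
          magnitude = f
        )
      }
    }
    traj <- cs$trajectory
    if (nrow(traj) > 1L) {
      for (i in seq_len(nrow(traj) - 1L)) {
        dv <- traj$value[i + 1L] - traj$value[i]
        if (abs(dv) > PROB_TOL) {
          trends[[length(trends) + 1L]] <- data.frame(
            start_month = traj$month[i], end_month = traj$month[i + 1L],
            condition = cs$name, slope_sign = sign(dv)
          )
        }
      }
    }
  }
  shifts <- list()
  for (ms in config$mix_shifts %||% list()) {
    shifts[[length(shifts) + 1L]] <- data.frame(
      start_month = ms$start_month, end_month = ms$end_month,
      variable = ms$variable
    )
  }
  if (!is.null(config$dropout_schedule)) {
    ds <- config$dropout_schedule
    shifts[[length(shifts) + 1L]] <- data.frame(
      start_month = ds$month[1], end_month = ds$month[nrow(ds)],
      variable = "imd_quintile"
    )
  }
  empty_steps <- data.frame(month = as.Date(character()),
                            step_index = integer(), condition = character(),
                            direction = character(), magnitude = numeric())
  empty_trend <- data.frame(start_month = as.Date(character()),
                            end_month = as.Date(character()),
                            condition = character(), slope_sign = numeric())
  empty_shift <- data.frame(start_month = as.Date(character()),
                            end_month = as.Date(character()),
                            variable = character())
  structure(
    list(
      planted_steps = if (length(steps)) do.call(rbind, steps) else empty_steps,
      planted_trends = if (length(trends)) do.call(rbind, trends) else empty_trend,
      planted_mix_shifts = if (length(shifts)) do.call(rbind, shifts) else empty_shift
    ),
    class = "ground_truth_manifest"
  )
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat("Ground-truth manifest:",
      nrow(x$planted_steps), "step(s),",
      nrow(x$planted_trends), "trend period(s),",
      nrow(x$planted_mix_shifts), "mix shift(s)\n")
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest A ground-truth manifest as produced by the generators.
#' @param file Path to a JSON file.
#' @return `read_manifest` returns the manifest; `write_manifest` its file
#'   path, invisibly.
#' @export
write_manifest <- function(manifest, file) {
  stopifnot(inherits(manifest, "ground_truth_manifest"))
  out <- lapply(unclass(manifest), function(d) {
    d[] <- lapply(d, function(col) if (inherits(col, "Date")) format(col) else col)
    d
  })
  jsonlite::write_json(out, file, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  fix <- function(d, date_cols) {
    d <- as.data.frame(d)
    for (dc in intersect(date_cols, names(d))) d[[dc]] <- as.Date(d[[dc]])
    d
  }
  structure(
    list(
      planted_steps = fix(raw$planted_steps, "month"),
      planted_trends = fix(raw$planted_trends, c("start_month", "end_month")),
      planted_mix_shifts = fix(raw$planted_mix_shifts,
                               c("start_month", "end_month"))
    ),
    class = "ground_truth_manifest"
  )
}

# --- deterministic seed splitting -------------------------------------------

# Derives a 32-bit sub-seed from the master seed and small stream indices
# (month index, condition index, ...). Linear-congruential folding keeps
# intermediate values inside the exactly-representable double range, and the
# result below 2^31 as required by set.seed(). Streams with distinct indices
# are distinct; the same (seed, indices) always maps to the same sub-seed.
split_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (x in idx) {
    s <- (s * 48271 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(s)
}
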