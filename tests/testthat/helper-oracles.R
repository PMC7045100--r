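# Independent oracles, deliberately written with different mechanics from the
# package implementation.

# Jensen-Shannon divergence by direct elementwise KL evaluation (scalar loop)
oracle_jsd <- function(p, q, base = 2) {
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * (log(p[i]) - log(m[i]))
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * (log(q[i]) - log(m[i]))
  }
  acc / log(base)
}

# worked-example values, frozen from an exact rational-arithmetic evaluation
# of the KL sums (computed once with a symbolic system, 20 significant digits)
JSD_WORKED_NATS <- 1.1712656923581384e-3
JSD_WORKED_BITS <- 1.6897792059284645e-3

rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# mean silhouette width by the textbook per-point formula, plain loops
oracle_silhouette <- function(d, groups) {
  groups <- as.character(groups)
  keep <- groups %in% names(which(table(groups) > 1))
  s <- c()
  for (i in which(keep)) {
    same <- setdiff(which(groups == groups[i] & keep), i)
    a <- mean(d[i, same])
    b <- Inf
    for (g in setdiff(unique(groups[keep]), groups[i])) {
      b <- min(b, mean(d[i, which(groups == g)]))
    }
    s <- c(s, (b - a) / max(a, b))
  }
  mean(s)
}

# relative change with exact integer arithmetic: start and end are supplied
# as integer numerators over a common power-of-ten denominator, so
# 100 * (e - s) / s is evaluated and rounded half-away-from-zero without any
# floating-point division
oracle_relative_change <- function(start_int, end_int, decimals) {
  num <- 100 * (end_int - start_int) * 10^decimals
  den <- start_int
  sgn <- sign(num) * sign(den)
  num <- abs(num); den <- abs(den)
  q <- (2 * num + den) %/% (2 * den) # floor(num/den + 1/2)
  sgn * q / 10^decimals
}

# brute-force eligibility scan over registration intervals, independent of
# the slicing module's vectorised logic
oracle_denominator <- function(patients, month) {
  month <- as.Date(paste0(format(month, "%Y-%m"), "-01"))
  n <- 0L
  for (i in seq_len(nrow(patients))) {
    yob <- patients$year_of_birth[i]
    if (is.na(yob) || is.na(patients$gender[i]) ||
        is.na(patients$imd_quintile[i])) next
    age <- as.integer(format(month, "%Y")) - yob
    if (as.integer(format(month, "%m")) < 7L) age <- age - 1L
    if (age < 20L || age > 110L) next
    if (as.numeric(month - patients$registration_start[i]) < 365) next
    re <- patients$registration_end[i]
    if (!is.na(re) && re < month) next
    n <- n + 1L
  }
  n
}

# small joint-slice fixture: gender x one condition flag over given months
toy_joint_slices <- function() {
  cells <- expand.grid(
    month = c("2001-01", "2001-02", "2001-03"),
    gender = c("F", "M"), flag = c("0", "1"),
    stringsAsFactors = FALSE
  )
  cells$count <- c(45, 40, 35, 40, 40, 40, 5, 10, 15, 10, 10, 10)
  as_monthly_slices(cells)
}
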