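test_that("a single planted spike is the only abrupt flag", {
  v <- rep(0.01, 30)
  v[15] <- 0.1
  set.seed(1)
  v <- v + stats::runif(30, 0, 1e-4) # tiny jitter so MAD > 0
  fl <- detect_abrupt(v)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$step_index, 15L)
  expect_true(is.finite(fl$score))
})

test_that("constant series fall back to flagging strictly larger values", {
  expect_equal(nrow(detect_abrupt(rep(0.02, 20))), 0L)
  v <- rep(0.02, 20)
  v[7] <- 0.03
  fl <- detect_abrupt(v)
  expect_equal(fl$step_index, 7L)
  expect_equal(fl$score, Inf)
  expect_error(detect_abrupt(rep(0.01, 5)), "at least 12")
})

test_that("abrupt detection works on a consecutive series data frame", {
  months <- month_seq("2001-01", "2002-12")
  prev <- c(rep(0.08, 12), rep(0.15, 12))
  set.seed(2)
  counts <- t(vapply(prev, function(p) {
    stats::rmultinom(1, 50000, c(1 - p, p))[, 1]
  }, numeric(2)))
  dtm <- dtm_from_counts(counts, months, c("0", "1"))
  ser <- consecutive_series(pairwise_matrix(dtm, scale = "divergence"))
  fl <- detect_abrupt(ser)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$step_index, 12L)
  expect_equal(format_month(fl$to), "2002-01")
})

test_that("planted drifts are flagged as trends, with reversals split by period", {
  n <- 48
  prev <- c(seq(0.05, 0.20, length.out = 24), seq(0.20, 0.05, length.out = 24))
  counts <- cbind(round(2e5 * (1 - prev)), round(2e5 * prev))
  months <- month_seq("2001-01", "2004-12")
  dtm <- dtm_from_counts(counts, months, c("0", "1"))
  emb <- classical_mds(pairwise_matrix(dtm), dims = 3)
  up <- detect_trend(emb, period = c("2001-01", "2002-12"))
  down <- detect_trend(emb, period = c("2003-01", "2004-12"))
  expect_equal(up$type, "trend")
  expect_equal(down$type, "trend")
  expect_gte(abs(up$score), 0.95)
  expect_gte(abs(down$score), 0.95)
  expect_lt(up$score * down$score, 0) # opposite-signed rho
  expect_error(detect_trend(emb, period = c("2001-01", "2001-06")),
               "at least 12")
})

test_that("trend detection is invariant to the arbitrary axis sign", {
  prev <- seq(0.05, 0.2, length.out = 24)
  counts <- cbind(round(1e5 * (1 - prev)), round(1e5 * prev))
  emb <- classical_mds(pairwise_matrix(dtm_from_counts(
    counts, month_seq("2001-01", "2002-12"), c("0", "1"))), dims = 2)
  flipped <- emb
  flipped$coordinates <- -emb$coordinates
  a <- detect_trend(emb)
  b <- detect_trend(flipped)
  expect_equal(a$type, b$type)
  expect_equal(abs(a$score), abs(b$score), tolerance = 1e-12)
})

test_that("biennial April steps cluster by financial-year pair, not calendar year", {
  months <- month_seq("2001-01", "2008-12")
  sc <- scenario_config(
    mode = "hospital", start_month = months[1], end_month = months[96],
    monthly_volume = 50000L,
    demographics = default_demographics("hospital"),
    conditions = list(
      condition_spec("I21", trajectory = 0.2,
                     step_changes = data.frame(
                       month = c("2003-04", "2005-04", "2007-04"),
                       factor = c(1.5, 1.5, 1.5))),
      condition_spec("I20", trajectory = 0.3)),
    seed = 14L)
  gen <- generate_hospital_counts(sc)
  dm <- pairwise_matrix(hes_dtm(gen), scale = "distance")
  fy <- month_year(months) - as.integer(as.integer(format(months, "%m")) < 4L)
  # financial-year pairs aligned to the biennial April steps; the Jan-Mar 2001
  # stub belongs to the same coding regime as the first full pair
  fy_pair <- paste0("P", pmax(0, (fy - 2001) %/% 2))
  rep <- detect_period_clusters(
    dm, groupings = list(calendar_year = "calendar_year", fy_pair = fy_pair))
  expect_true("fy_pair" %in% rep$grouping)
  expect_false("calendar_year" %in% rep$grouping)
  scores <- attr(rep, "all_scores")
  expect_gt(scores["fy_pair"], scores["calendar_year"])
})

test_that("silhouette agrees with a brute-force per-point oracle", {
  set.seed(30)
  X <- rbind(matrix(stats::rnorm(24, 0), 12, 2),
             matrix(stats::rnorm(24, 4), 12, 2))
  d <- as.matrix(stats::dist(X))
  groups <- rep(c("a", "b"), each = 12)
  dm <- as_dissimilarity_matrix(d / max(d), month_seq("2001-01", "2002-12"))
  rep <- detect_period_clusters(dm, groupings = list(g = groups))
  expect_equal(unname(attr(rep, "all_scores")["g"]),
               oracle_silhouette(dm$values, groups), tolerance = 1e-12)
})

test_that("singleton groups are excluded and single-group partitions rejected", {
  dm <- as_dissimilarity_matrix(as.matrix(stats::dist(1:5)) / 10,
                                month_seq("2001-01", "2001-05"))
  groups <- c("a", "a", "b", "b", "c")
  expect_warning(detect_period_clusters(dm, groupings = list(g = groups)),
                 "singleton")
  expect_error(
    suppressWarnings(detect_period_clusters(
      dm, groupings = list(g = c("a", "a", "a", "a", "b")))),
    "fewer than 2")
  expect_error(detect_period_clusters(
    dm, groupings = list(g = rep("a", 5))), "fewer than 2")
})

test_that("flagged changes are attributed to the variable that moved", {
  # step planted in one code only: 'code' must rank first
  sc <- scenario_hes_like(monthly_volume = 50000L, n_months = 24L,
                          step_index = 12L, seed = 15L)
  dtm <- hes_dtm(generate_hospital_counts(sc))
  att <- attribute_source(dtm, 12L)
  expect_equal(att$variable[1], "code")
  expect_true(all(diff(att$score) <= 0))

  # abrupt demographic mix shift: deprivation quintile must rank first
  sc2 <- scenario_config(
    mode = "hospital", start_month = "2001-01", end_month = "2002-12",
    monthly_volume = 50000L,
    demographics = default_demographics("hospital"),
    mix_shifts = list(mix_shift_spec(
      "imd_quintile", "2002-01", "2002-01",
      target = c(`1` = 0.10, `2` = 0.15, `3` = 0.20, `4` = 0.25, `5` = 0.30))),
    conditions = list(condition_spec("I21", trajectory = 0.2)),
    seed = 16L)
  dtm2 <- hes_dtm(generate_hospital_counts(sc2))
  att2 <- attribute_source(dtm2, 12L)
  expect_equal(att2$variable[1], "imd_quintile")

  # identical months: every marginal score is zero
  cells <- rbind(
    data.frame(month = "2001-01", gender = c("M", "F"), flag = c("1", "0"),
               count = c(30, 70)),
    data.frame(month = "2001-02", gender = c("M", "F"), flag = c("1", "0"),
               count = c(30, 70)))
  dtm3 <- estimate_dtm(as_monthly_slices(cells))
  att3 <- attribute_source(dtm3, 1L)
  expect_true(all(att3$score == 0))
  expect_error(attribute_source(dtm3, 5L), "out of range")
})
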