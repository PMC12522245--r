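# synthetic cohort, eligibility filter, descriptives

test_that("generator validates its spec", {
  expect_error(generator_spec(n = 0), "n must be")
  expect_error(generator_spec(female_fraction = 1.2), "female_fraction")
  expect_error(generator_spec(excluded_shift = 10), "excluded_shift")
  expect_error(generate_cohort(list()), "generator_spec")
})

test_that("generation is deterministic and exclusion routing partitions the cohort", {
  spec <- generator_spec(n = 4000, seed = 42)
  coh <- generate_cohort(spec)
  expect_identical(coh, generate_cohort(spec))
  parts <- apply_exclusions(coh)
  expect_equal(
    nrow(parts$included) + nrow(parts$excluded) + nrow(parts$missing_dropped),
    nrow(coh)
  )
  expect_length(
    intersect(parts$included$id, c(parts$excluded$id, parts$missing_dropped$id)), 0
  )
  # included records are exactly the flag-free complete ones
  expect_true(all(!parts$included$uses_gait_aid &
    !parts$included$needs_adl_iadl_assist &
    !is.na(parts$included$pase_total)))
  expect_true(all(parts$excluded$uses_gait_aid |
    parts$excluded$needs_adl_iadl_assist, na.rm = TRUE))
})

test_that("single records route by flag state", {
  rec <- function(gait, adl, score = 100) {
    data.frame(
      id = "x", age = 60, sex = "male",
      uses_gait_aid = gait, needs_adl_iadl_assist = adl, pase_total = score
    )
  }
  expect_equal(nrow(apply_exclusions(rec(TRUE, FALSE))$excluded), 1)
  expect_equal(nrow(apply_exclusions(rec(FALSE, FALSE))$included), 1)
  expect_equal(nrow(apply_exclusions(rec(FALSE, NA))$missing_dropped), 1)
  expect_equal(nrow(apply_exclusions(rec(FALSE, FALSE, NA))$missing_dropped), 1)
  # a known-positive flag dominates missingness in the other
  expect_equal(nrow(apply_exclusions(rec(TRUE, NA))$excluded), 1)
})

test_that("excluded_fraction = 0 yields a flag-free cohort", {
  coh <- generate_cohort(generator_spec(
    n = 500, seed = 1,
    excluded_fraction = 0, missing_fraction = 0
  ))
  expect_false(any(coh$uses_gait_aid | coh$needs_adl_iadl_assist, na.rm = FALSE))
})

test_that("seasons map by month, totally and purely", {
  expect_equal(assign_season(as.Date("2014-02-14")), "winter")
  expect_equal(assign_season(as.Date("2014-07-01")), "summer")
  expect_equal(assign_season(as.Date("2014-12-31")), "fall")
  expect_equal(assign_season(as.Date("2014-04-01")), "spring")
  all_days <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  s <- assign_season(all_days)
  expect_true(all(s %in% c("winter", "spring", "summer", "fall")))
  expect_equal(
    unname(table(s)[c("winter", "spring", "summer", "fall")]),
    c(90, 91, 92, 92),
    ignore_attr = TRUE
  )
  expect_error(assign_season("not-a-date"))
})

test_that("weighted descriptives match hand arithmetic and a replication oracle", {
  d <- data.frame(pase_total = c(100, 200), inflation_weight = c(1, 3))
  out <- weighted_descriptives(d, variables = "pase_total")
  expect_equal(out$value[out$statistic == "mean"], 175)

  # equal weights = unweighted
  d2 <- data.frame(pase_total = c(3, 9, 12), inflation_weight = rep(2, 3))
  out2 <- weighted_descriptives(d2, variables = "pase_total")
  expect_equal(out2$value[out2$statistic == "mean"], mean(d2$pase_total))
  expect_equal(
    out2$value[out2$statistic == "sd"],
    stats::sd(d2$pase_total) * sqrt(2 / 3)
  )

  # integer weights equal physically replicating each record
  withr::with_seed(8, {
    d3 <- data.frame(
      pase_total = rnorm(30, 150, 40),
      sex = sample(c("male", "female"), 30, replace = TRUE),
      inflation_weight = sample(1:5, 30, replace = TRUE)
    )
  })
  expanded <- d3[rep(seq_len(30), d3$inflation_weight), ]
  out3 <- weighted_descriptives(d3, variables = c("pase_total", "sex"))
  expect_equal(
    out3$value[out3$variable == "pase_total" & out3$statistic == "mean"],
    mean(expanded$pase_total)
  )
  expect_equal(
    out3$value[out3$variable == "pase_total" & out3$statistic == "sd"],
    stats::sd(expanded$pase_total) * sqrt((nrow(expanded) - 1) / nrow(expanded))
  )
  expect_equal(
    out3$value[out3$variable == "sex" & out3$level == "female"],
    mean(expanded$sex == "female")
  )
  expect_error(weighted_descriptives(data.frame(
    pase_total = 1, inflation_weight = -1
  )), "positive")
})

test_that("included/excluded comparison reproduces the textbook t statistic", {
  inc <- data.frame(age = rep(50, 3), pase_total = c(1, 2, 3))
  exc <- data.frame(age = rep(50, 3), pase_total = c(4, 5, 6))
  out <- compare_included_excluded(inc, exc)
  row <- out[out$band == "45-54", ]
  # hand Welch: diff -3, se = sqrt(1/3 + 1/3)
  expect_equal(row$t, -3 / sqrt(2 / 3))
  expect_equal(row$mean_diff, -3)
  expect_true(all(out$skipped[out$band != "45-54"]))

  same <- compare_included_excluded(inc, inc)
  expect_equal(same$t[same$band == "45-54"], 0)
})

test_that("the generator's own exclusion shift is detected in every age band", {
  spec <- generator_spec(n = 5000, seed = 77)
  parts <- apply_exclusions(generate_cohort(spec))
  out <- compare_included_excluded(parts$included, parts$excluded)
  expect_false(any(out$skipped))
  expect_true(all(out$mean_diff > 0)) # excluded score lower
  expect_true(all(out$p_value < 0.001))
})

test_that("included analytic-weighted means sit at the calibration anchors", {
  spec <- generator_spec(n = 20000, seed = 5)
  inc <- apply_exclusions(generate_cohort(spec))$included
  for (sx in c("male", "female")) {
    d <- inc[inc$sex == sx, ]
    wm <- sum(d$analytic_weight * d$pase_total) / sum(d$analytic_weight)
    anchor <- c(male = 172.57, female = 147.39)[[sx]]
    # Monte-Carlo tolerance: ~3 SE at this stratum size
    expect_lt(abs(wm - anchor), 3)
  }
})

test_that("cohort CSV round-trips with typed columns", {
  coh <- generate_cohort(generator_spec(n = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_s3_class(back$interview_date, "Date")
  expect_type(back$uses_gait_aid, "logical")
  expect_equal(back$pase_total, coh$pase_total)
})
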