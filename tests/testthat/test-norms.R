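# norm tables, lookup, charts, pipeline

test_that("a constant model gives identical rows, increasing across percentiles", {
  flat <- centile_fn(function(age, p) 100 + 30 * stats::qnorm(p))
  tbl <- build_norm_table(flat, "male")
  expect_equal(dim(tbl$values), c(41, 9))
  expect_true(all(apply(tbl$values, 2, function(col) all(col == col[1]))))
  expect_true(all(apply(tbl$values, 1, diff) > 0))
  expect_error(build_norm_table(flat, "male", percentiles = numeric(0)), "percentile")
})

test_that("tables from a fitted model are monotone, floored at 0, and reproducible from disk", {
  spec <- generator_spec(n = 1000, seed = 1)
  d <- make_truth_data(spec, "male", 3000, seed = 19)
  m <- fit_distributional_model(d, "SHASHo2")
  tbl <- build_norm_table(m, "male")
  expect_true(all(tbl$values >= 0))
  expect_true(all(apply(tbl$values, 1, diff) >= 0))

  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, path)
  tbl2 <- build_norm_table(deserialize_model(path), "male")
  expect_identical(tbl$values, tbl2$values)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_norm_table(tbl, csv)
  back <- read_norm_table(csv)
  expect_equal(unname(back$values), unname(tbl$values))

  short <- centile_fn(function(age, p) age, age_range = c(50, 60))
  expect_error(build_norm_table(short, "male"), "cover")
})

test_that("model-based lookup inverts the centile function", {
  spec <- generator_spec(n = 1000, seed = 1)
  d <- make_truth_data(spec, "female", 3000, seed = 23)
  m <- fit_distributional_model(d, "SEP4")
  for (a in c(45, 63.5, 85)) {
    for (p in c(0.05, 0.5, 0.9)) {
      sc <- centile(m, a, p)
      lk <- lookup_percentile(m, a, sc)
      expect_equal(lk$percentile, 100 * p, tolerance = 1e-6)
    }
  }
  expect_error(lookup_percentile(m, 30, 100), "age")
  expect_error(lookup_percentile(m, 60, -5), "score")
})

test_that("table-based lookup brackets, round-trips cells, and flags the tails", {
  flat <- centile_fn(function(age, p) 100 + 30 * stats::qnorm(p))
  tbl <- build_norm_table(flat, "male")
  # a score equal to the P50 cell reads back as the 50th percentile
  cell <- tbl$values["60", "50"]
  lk <- lookup_percentile(tbl, 60, cell)
  expect_equal(lk$percentile, 50)
  # interpolation brackets between neighbouring percentiles
  mid <- mean(tbl$values["60", c("50", "75")])
  lk2 <- lookup_percentile(tbl, 60, mid)
  expect_equal(lk2$bracket, c(50, 75))
  expect_true(lk2$percentile > 50 && lk2$percentile < 75)
  # outside the tabulated range
  expect_equal(lookup_percentile(tbl, 60, 0)$statement, "<5")
  expect_equal(lookup_percentile(tbl, 60, 1e5)$statement, ">95")
})

test_that("chart rendering is deterministic and rejects empty tables", {
  flat <- centile_fn(function(age, p) 100 + 30 * stats::qnorm(p))
  tbl <- build_norm_table(flat, "female")
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_norm_chart(tbl, f1)
  render_norm_chart(tbl, f2)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
  tbl$percentiles <- numeric(0)
  expect_error(render_norm_chart(tbl, f1), "nothing to draw")
})

test_that("the pipeline emits per-sex tables, charts, models and CV reports", {
  out <- withr::local_tempdir()
  cfg <- pipeline_config(
    n = 5000, seed = 31, cv_reps = 2,
    families = list(male = "SHASHo2", female = "SEP4"),
    quantreg_bases = c("linear", "fractional_polynomial")
  )
  man <- run_pipeline(cfg, out_dir = out)
  files <- list.files(out)
  for (need in c(
    "norms_male.csv", "norms_female.csv", "chart_male.svg",
    "chart_female.svg", "model_male.json", "model_female.json",
    "cv_male_summary.csv", "cv_female_summary.csv", "manifest.json"
  )) {
    expect_true(need %in% files, label = need)
  }
  expect_equal(
    man$counts$total,
    man$counts$included + man$counts$excluded + man$counts$missing_dropped
  )
  # the selected model and config hash are recorded
  expect_true(nchar(man$config_hash) == 32)
  expect_true(man$strata$male$selected_model %in%
    c("gamlss_SHASHo2", "qr_linear", "qr_fp"))

  # norm tables encode the expected qualitative structure
  tm <- read_norm_table(file.path(out, "norms_male.csv"))
  tf <- read_norm_table(file.path(out, "norms_female.csv"))
  expect_true(all(apply(tm$values, 1, diff) >= 0))
  p50m <- tm$values[, "50"]
  expect_gt(p50m[1] - p50m[41], 50) # median declines with age
})

test_that("season mode emits eight stratified tables", {
  out <- withr::local_tempdir()
  cfg <- pipeline_config(
    n = 8000, seed = 13, cv_reps = 1,
    families = list(male = "SHASHo2", female = "SEP4"),
    quantreg_bases = "linear",
    season_mode = TRUE
  )
  run_pipeline(cfg, out_dir = out)
  season_files <- list.files(out, pattern = "norms_(male|female)_(winter|spring|summer|fall)\\.csv")
  expect_length(season_files, 8)
})

test_that("a failing stage halts with its name and preserves partial output", {
  out <- withr::local_tempdir()
  cfg <- pipeline_config(
    n = 120, seed = 1, cv_reps = 1, # far too small to fit anything
    families = list(male = "SHASHo2", female = "SEP4"),
    quantreg_bases = "linear"
  )
  expect_error(run_pipeline(cfg, out_dir = out), "failed at stage")
  expect_true(file.exists(file.path(out, "failed", "manifest.json")))
})
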