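# pinball-loss quantile regression

test_that("intercept-only fits return the exact weighted sample quantile", {
  d <- data.frame(age = 50:54, score = c(1, 2, 3, 4, 5))
  f <- fit_quantile(d, smoother_spec("constant"), 0.5)
  expect_equal(unname(f$coef), 3)
  # the quantile property: residual fraction below the fit within 1/n of tau
  withr::with_seed(2, {
    d2 <- data.frame(age = runif(200, 45, 85), score = rnorm(200))
  })
  for (tau in c(0.05, 0.25, 0.5, 0.9)) {
    f2 <- fit_quantile(d2, smoother_spec("constant"), tau)
    expect_lte(abs(mean(d2$score < f2$coef) - tau), 1 / 200 + 1e-12)
  }
})

test_that("exact linear data is interpolated with zero loss at any tau", {
  ages <- c(46, 50, 60, 70, 80, 84)
  d <- data.frame(age = ages, score = 2 * ages)
  for (tau in c(0.1, 0.5, 0.8)) {
    f <- fit_quantile(d, smoother_spec("linear"), tau)
    expect_equal(f$loss, 0, tolerance = 1e-10)
    X <- pasenorms:::eval_basis(f$basis, ages)
    expect_equal(drop(X %*% f$coef), 2 * ages, tolerance = 1e-8)
  }
})

test_that("small instances attain the brute-force pinball optimum", {
  for (s in 1:8) {
    withr::with_seed(300 + s, {
      n <- sample(5:8, 1)
      d <- data.frame(
        age = runif(n, 45, 85),
        score = rnorm(n, 100, 30),
        weight = sample(c(1, 1, 2, 3), n, replace = TRUE)
      )
      tau <- sample(c(0.25, 0.5, 0.75, 0.9), 1)
    })
    f <- fit_quantile(d, smoother_spec("linear"), tau)
    X <- pasenorms:::eval_basis(f$basis, d$age)
    oracle <- pinball_oracle(X, d$score, d$weight, tau)
    expect_equal(f$loss, oracle, tolerance = 1e-9)
  }
})

test_that("fractional-polynomial bases follow the FP conventions", {
  ages <- c(45, 55, 65, 85)
  b1 <- expand_fractional_polynomial(ages, 1)
  expect_equal(drop(b1), ages / 10)
  b0 <- expand_fractional_polynomial(10 * exp(1), 0)
  expect_equal(unname(drop(b0)), 1)
  b11 <- expand_fractional_polynomial(ages, c(1, 1))
  a <- ages / 10
  expect_equal(unname(b11), unname(cbind(a, a * log(a))))
  bm <- expand_fractional_polynomial(ages, c(-0.5, 2))
  expect_equal(unname(bm), unname(cbind(a^-0.5, a^2)))
  expect_error(expand_fractional_polynomial(c(-1, 2), 1), "positive")
  expect_error(expand_fractional_polynomial(ages, c(1, 2, 3)), "degree")
  expect_error(expand_fractional_polynomial(ages, 1.7), "powers")
})

test_that("rank-deficient designs are rejected with the offending columns", {
  d <- data.frame(age = rep(60, 10), score = rnorm(10))
  expect_error(fit_quantile(d, smoother_spec("linear"), 0.5), "collinear")
})

test_that("smoothed additive fits obey the penalty limits", {
  withr::with_seed(5, {
    d <- data.frame(age = runif(150, 45, 85))
    d$score <- 0.02 * d$age^2 + rnorm(150)
  })
  lin <- fit_quantile(d, smoother_spec("linear"), 0.5)
  big <- fit_smoothed_additive_quantile(d, 0.5, penalty = 1e8)
  lin_vals <- drop(pasenorms:::eval_basis(lin$basis, big$nodes) %*% lin$coef)
  expect_lt(max(abs(big$values - lin_vals)), 1e-4)

  pts <- data.frame(age = c(46, 55, 65, 75, 84), score = c(10, 12, 9, 14, 11))
  interp <- fit_smoothed_additive_quantile(pts, 0.5, penalty = 0)
  expect_equal(interp$values, pts$score, tolerance = 1e-8)

  # a monotone true median stays monotone at moderate penalty
  withr::with_seed(6, {
    d2 <- data.frame(age = runif(2000, 45, 85))
    d2$score <- 300 - 2.5 * d2$age + rnorm(2000, 0, 20)
  })
  sm <- fit_smoothed_additive_quantile(d2, 0.5, penalty = 50)
  expect_true(all(diff(sm$values) < 0))
  expect_error(fit_smoothed_additive_quantile(d2, 0.5, penalty = -1), "penalty")
})

test_that("monotone rearrangement sorts curves per age and is idempotent", {
  ages <- 45:50
  mono <- rbind(p5 = rep(10, 6), p50 = rep(20, 6), p95 = rep(30, 6))
  expect_identical(rearrange_noncrossing(mono), apply(mono, 2, sort))
  expect_equal(unname(rearrange_noncrossing(mono)), unname(mono))

  crossed <- rbind(p5 = rep(10, 6), p95 = rep(5, 6))
  out <- rearrange_noncrossing(crossed)
  expect_equal(unname(out), unname(rbind(rep(5, 6), rep(10, 6))))

  withr::with_seed(11, {
    rnd <- matrix(rnorm(40), nrow = 5)
  })
  expect_equal(unname(rearrange_noncrossing(rnd)), unname(apply(rnd, 2, sort)))
})

test_that("rearrangement never increases the total pinball loss", {
  withr::with_seed(13, {
    n <- 400
    d <- data.frame(age = runif(n, 45, 85))
    d$score <- 200 - 2 * d$age + rnorm(n, 0, 25)
  })
  taus <- c(0.05, 0.5, 0.95)
  # deliberately bad, crossing curves: random constant levels
  ages_grid <- 45:85
  withr::with_seed(14, {
    curves <- matrix(runif(3 * 41, 0, 150), nrow = 3)
  })
  sorted <- rearrange_noncrossing(curves)
  loss_of <- function(cv) {
    sum(vapply(seq_along(taus), function(i) {
      pred <- approx(ages_grid, cv[i, ], xout = d$age, rule = 2)$y
      u <- d$score - pred
      sum(u * (taus[i] - (u < 0)))
    }, numeric(1)))
  }
  expect_lte(loss_of(sorted), loss_of(curves))
})

test_that("a model set shares one basis and serializes round-trip", {
  spec <- generator_spec(n = 1000, seed = 1)
  d <- make_truth_data(spec, "male", 1200, seed = 77)
  qs <- fit_quantile_set(d, smoother_spec("fractional_polynomial"),
    taus = c(0.05, 0.5, 0.95)
  )
  expect_s3_class(qs, "quantile_model_set")
  expect_equal(nrow(qs$coef), 3)
  p5 <- predict_centile(qs, 45:85, 0.05)
  p95 <- predict_centile(qs, 45:85, 0.95)
  expect_true(all(p5 < p95))
  expect_error(predict_centile(qs, 60, 0.33), "not fitted")

  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(qs, path)
  qs2 <- deserialize_model(path)
  expect_identical(
    predict_centile(qs, 45:85, 0.5),
    predict_centile(qs2, 45:85, 0.5)
  )
})
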