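# distributional centile regression

test_that("GAIC is -2*loglik + k*df and monotone in the penalty", {
  expect_equal(gaic(-100, 5, 2), 210)
  expect_equal(gaic(-100, 5, 3.84), 219.2)
  expect_equal(gaic(-100, 5, 9), 245)
  dfs <- 0:10
  expect_true(all(diff(gaic(-100, dfs, 3.84)) > 0))
  expect_error(gaic(-100, -1, 2), "df")
})

test_that("constant-smoother fit matches a direct 4-parameter ML oracle", {
  truth <- list(mu = 150, sigma = 60, nu = -0.3, tau = 1.15)
  d <- make_iid_data("SHASHo2", 10000, truth, seed = 21)
  m <- fit_distributional_model(d, "SHASHo2", smoothers = const_smoothers())
  expect_true(m$converged)
  fit <- predict_params(m, 65)

  # independent oracle: direct quasi-Newton ML over the 4 natural
  # parameters (log scale for sigma, tau), no basis machinery
  nll <- function(th) {
    lp <- dist_pdf("SHASHo2", d$score,
      list(mu = th[1], sigma = exp(th[2]), nu = th[3], tau = exp(th[4])),
      log = TRUE
    )
    if (any(!is.finite(lp))) {
      return(1e10)
    }
    -sum(lp)
  }
  o <- stats::optim(c(mean(d$score), log(stats::sd(d$score)), 0, 0), nll,
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12), hessian = TRUE
  )
  ose <- sqrt(diag(solve(o$hessian)))
  oracle <- c(o$par[1], exp(o$par[2]), o$par[3], exp(o$par[4]))

  # same optimum: identical maximized log-likelihood...
  expect_lt(abs(-o$value - m$loglik), 0.01)
  # ...and parameters within 3 oracle standard errors (on the link scale)
  fit_link <- c(fit$mu[1], log(fit$sigma[1]), fit$nu[1], log(fit$tau[1]))
  expect_true(all(abs(fit_link - o$par) < 3 * ose + 1e-6))
  expect_equal(m$df, 4)
})

test_that("the normal-limit submodel reproduces the weighted Gaussian MLE", {
  d <- make_iid_data("SHASHo", 2000, list(mu = 100, sigma = 30, nu = 0, tau = 1),
    seed = 9, weighted = TRUE
  )
  m <- fit_distributional_model(d, "SHASHo",
    smoothers = const_smoothers(),
    controls = fit_controls(fixed = list(nu = 0, tau = 1))
  )
  p <- predict_params(m, 60)
  wm <- sum(d$weight * d$score) / sum(d$weight)
  wsd_ml <- sqrt(sum(d$weight * (d$score - wm)^2) / sum(d$weight))
  expect_equal(p$mu[1], wm, tolerance = 1e-6)
  expect_equal(p$sigma[1], wsd_ml, tolerance = 1e-6)
  expect_equal(m$df, 2) # fixed parameters carry no coefficients
})

test_that("cubic-spline fit recovers the generator's declining median", {
  spec <- generator_spec(n = 1000, seed = 1) # only the curves are used
  d <- make_truth_data(spec, "male", 8000, seed = 33)
  m <- fit_distributional_model(d, "SHASHo2")
  expect_true(m$converged)
  ages <- 45:85
  rmse <- sqrt(mean((centile(m, ages, 0.5, floor0 = FALSE) -
    dist_quantile("SHASHo2", rep(0.5, 41), true_params(spec, "male", ages)))^2))
  expect_lt(rmse, 0.05 * stats::sd(d$score))
  # deviance trace is non-increasing (likelihood ascent)
  expect_true(all(diff(m$deviance_trace) <= 1e-6))
})

test_that("centiles are monotone in p and reduce to mu at the median of a symmetric fit", {
  d <- make_iid_data("SHASHo", 500, list(mu = 50, sigma = 10, nu = 0, tau = 1), seed = 4)
  m <- fit_distributional_model(d, "SHASHo",
    smoothers = list(
      mu = smoother_spec("linear"), sigma = smoother_spec("constant"),
      nu = smoother_spec("constant"), tau = smoother_spec("constant")
    ),
    controls = fit_controls(fixed = list(nu = 0, tau = 1))
  )
  ages <- seq(46, 84, by = 2)
  expect_equal(
    centile(m, ages, 0.5, floor0 = FALSE), predict_params(m, ages)$mu,
    tolerance = 1e-9
  )
  for (a in c(50, 70)) {
    ps <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    expect_true(all(diff(centile(m, rep(a, 5), ps)) > 0))
  }
  expect_error(centile(m, 20, 0.5), "age")
})

test_that("fitted centile curves never cross anywhere on the grid", {
  spec <- generator_spec(n = 1000, seed = 1)
  d <- make_truth_data(spec, "female", 4000, seed = 12)
  m <- fit_distributional_model(d, "SEP4")
  ages <- 45:85
  ps <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  curves <- sapply(ps, function(p) centile(m, ages, p))
  expect_true(all(apply(curves, 1, diff) > 0))
})

test_that("family ranking sorts by GAIC with df tie-breaks", {
  d <- make_iid_data("SHASHo2", 1500, list(mu = 120, sigma = 40, nu = -0.5, tau = 1),
    seed = 14
  )
  # singleton candidate comes back alone
  r1 <- rank_families(d, "SHASHo2", smoothers = const_smoothers())
  expect_equal(nrow(r1$table), 1)
  expect_equal(r1$table$family, "SHASHo2")

  # same family, extra useless df: with a coarse tie window the smaller
  # model must rank first
  cands <- list(
    list(family = "SHASHo2", smoothers = list(
      mu = smoother_spec("linear"), sigma = smoother_spec("constant"),
      nu = smoother_spec("constant"), tau = smoother_spec("constant")
    )),
    list(family = "SHASHo2", smoothers = const_smoothers())
  )
  r2 <- rank_families(d, cands, tie_tol = 25)
  expect_equal(r2$table$df, sort(r2$table$df))
})

test_that("the true skew family outranks a symmetric-only competitor on skewed data", {
  wins <- 0
  for (s in 1:10) {
    d <- make_iid_data("SHASHo2", 2000,
      list(mu = 150, sigma = 55, nu = -0.6, tau = 1.1),
      seed = 4000 + s
    )
    cands <- list(
      list(family = "SHASHo2", smoothers = const_smoothers()),
      list(
        family = "SHASHo2", smoothers = const_smoothers(),
        controls = fit_controls(fixed = list(nu = 0, tau = 1))
      )
    )
    r <- rank_families(d, cands)
    if (r$table$df[1] == 4) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("models serialize to text and restore with bit-identical predictions", {
  spec <- generator_spec(n = 1000, seed = 1)
  d <- make_truth_data(spec, "male", 2500, seed = 55)
  m <- fit_distributional_model(d, "SHASHo2")
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, path)
  m2 <- deserialize_model(path)
  ages <- seq(45, 85, by = 0.5)
  expect_identical(
    centile(m, ages, 0.05), centile(m2, ages, 0.05)
  )
  expect_identical(
    predict_params(m, ages), predict_params(m2, ages)
  )
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(age = runif(30, 45, 85), score = rnorm(30, 100, 10))
  expect_error(fit_distributional_model(d, "SHASHo2"), "50 observations")
  d2 <- data.frame(age = rep(60, 100), score = rnorm(100, 100, 10))
  expect_error(fit_distributional_model(d2, "SHASHo2"), "span")
})
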