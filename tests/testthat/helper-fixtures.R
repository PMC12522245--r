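# Shared fixtures built in code.

# all-constant smoother set (iid model, no age effect)
const_smoothers <- function() {
  list(
    mu = smoother_spec("constant"), sigma = smoother_spec("constant"),
    nu = smoother_spec("constant"), tau = smoother_spec("constant")
  )
}

# linear location + linear log-scale, constant shape: matches the
# generator's ground-truth curve family exactly
linear_smoothers <- function() {
  list(
    mu = smoother_spec("linear"), sigma = smoother_spec("linear"),
    nu = smoother_spec("constant"), tau = smoother_spec("constant")
  )
}

# draw an iid age/score/weight frame straight from a family (no censoring)
make_iid_data <- function(family, n, params, seed, weighted = FALSE) {
  withr::with_seed(seed, {
    age <- stats::runif(n, 45, 85)
    data.frame(
      age = age,
      score = dist_sample(family, n, params),
      weight = if (weighted) stats::rgamma(n, 20, 20) else rep(1, n)
    )
  })
}

# age-varying data from the synthetic generator's ground truth for one sex
# (uncensored, so the generating model is exactly the fitted family)
make_truth_data <- function(spec, sex, n, seed) {
  withr::with_seed(seed, {
    age <- stats::runif(n, 45, 85)
    pars <- true_params(spec, sex, age)
    data.frame(
      age = age,
      score = dist_sample(spec[[sex]]$family, n, pars),
      weight = stats::rgamma(n, 20, 20)
    )
  })
}

# in-domain random parameter draws for a family (standardized scale)
random_params <- function(fam, seed) {
  withr::with_seed(seed, {
    nu <- if (fam$nu_domain == "positive") {
      stats::runif(1, 0.6, 1.8) * unname(fam$start["nu"])
    } else {
      stats::runif(1, -0.8, 0.8)
    }
    list(
      mu = stats::runif(1, -1, 1),
      sigma = stats::runif(1, 0.6, 2),
      nu = nu,
      tau = unname(fam$start["tau"]) * stats::runif(1, 0.75, 1.4)
    )
  })
}

# exact small-instance pinball oracle: enumerate all p-subsets of rows as
# interpolating basic solutions (every weighted QR has an optimum of this
# form) and return the minimal achievable loss
pinball_oracle <- function(X, y, w, tau) {
  p <- ncol(X)
  loss <- function(b) sum(w * (y - X %*% b) * (tau - ((y - X %*% b) < 0)))
  best <- Inf
  for (rows in utils::combn(nrow(X), p, simplify = FALSE)) {
    b <- tryCatch(solve(X[rows, , drop = FALSE], y[rows]), error = function(e) NULL)
    if (!is.null(b)) best <- min(best, loss(b))
  }
  best
}
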