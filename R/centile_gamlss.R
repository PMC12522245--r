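# Distributional (GAMLSS-style) centile regression.
#
# Each of the four distribution parameters (mu, sigma, nu, tau) is modelled
# on its link scale as a linear combination of an age basis (constant,
# linear, regression spline or fractional polynomial).  Fitting maximizes
# the weighted log-likelihood directly (penalized ML over the basis
# coefficients) by cyclic block ascent with a quasi-Newton (BFGS) update per
# parameter block plus a joint polish, which guarantees a non-decreasing
# likelihood trace across outer iterations.  Effective degrees of freedom
# equal the number of free basis coefficients (the bases are unpenalized
# regression splines of fixed dimension, so the smoother "hat" trace is
# exactly the coefficient count).

#' Fitting controls for distributional centile models
#'
#' @param rel_tol Relative deviance change declaring convergence.
#' @param max_outer Maximum outer (block-cycle) iterations.
#' @param fixed Optional named list pinning parameters at fixed natural-scale
#'   values (e.g. \code{list(nu = 0, tau = 1)} fits the family's
#'   normal-limit submodel); fixed parameters carry no coefficients and do
#'   not count towards the effective df.
#' @return A list of controls.
#' @export
fit_controls <- function(rel_tol = 1e-6, max_outer = 200, fixed = list()) {
  list(rel_tol = rel_tol, max_outer = as.integer(max_outer), fixed = fixed)
}

.default_smoothers <- function() {
  list(
    mu = smoother_spec("cubic_spline", df = 3),
    sigma = smoother_spec("cubic_spline", df = 3),
    nu = smoother_spec("constant"),
    tau = smoother_spec("constant")
  )
}

.link_fns <- function(link) {
  switch(link,
    identity = list(inv = function(x) x, fwd = function(x) x),
    log = list(inv = exp, fwd = log),
    stop_pn("unknown link '", link, "'")
  )
}

#' Fit a four-parameter distributional centile model
#'
#' @param data Data frame with columns \code{age}, \code{score} and
#'   optionally \code{weight} (analytic survey weights; default 1).
#' @param family Family name (see \code{\link{family_names}}).
#' @param smoothers Named list of \code{\link{smoother_spec}}s for
#'   \code{mu}, \code{sigma}, \code{nu}, \code{tau}.  Default: cubic
#'   splines (df 3) for mu and sigma, constants for nu and tau.
#' @param controls See \code{\link{fit_controls}}.
#' @return A \code{centile_model}: family, per-parameter frozen bases and
#'   coefficients, maximized weighted log-likelihood, effective df, GAIC at
#'   the conventional penalties k = 2, 3.84, 5, 9, the deviance trace and a
#'   convergence flag.
#' @export
fit_distributional_model <- function(data, family,
                                     smoothers = .default_smoothers(),
                                     controls = fit_controls()) {
  fam <- get_family(family)
  if (!all(c("age", "score") %in% names(data))) {
    stop_pn("data must have columns age and score")
  }
  y <- data$score
  age <- data$age
  w <- if ("weight" %in% names(data)) data$weight else rep(1, length(y))
  keep <- !is.na(y) & !is.na(age)
  y <- y[keep]; age <- age[keep]; w <- w[keep]
  if (length(y) < 50) stop_pn("need at least 50 observations")
  if (diff(range(age)) <= 1) stop_pn("ages must span more than 1 year")
  if (any(w <= 0)) stop_pn("weights must be strictly positive")

  pnames <- c("mu", "sigma", "nu", "tau")
  smo <- utils::modifyList(.default_smoothers(), smoothers)
  fixed <- controls$fixed
  free <- setdiff(pnames, names(fixed))

  bases <- list()
  X <- list()
  for (pn in free) {
    bases[[pn]] <- fit_basis(smo[[pn]], age)
    X[[pn]] <- eval_basis(bases[[pn]], age)
  }
  links <- lapply(fam$links, .link_fns)

  # coefficient vector layout
  sizes <- vapply(free, function(pn) ncol(X[[pn]]), integer(1))
  offs <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offs) <- free
  idx <- lapply(free, function(pn) offs[[pn]] + seq_len(sizes[[pn]]))
  names(idx) <- free

  param_at <- function(theta, pn) {
    if (pn %in% names(fixed)) {
      rep(fixed[[pn]], length(y))
    } else {
      links[[pn]]$inv(drop(X[[pn]] %*% theta[idx[[pn]]]))
    }
  }
  negll <- function(theta) {
    p <- lapply(pnames, function(pn) param_at(theta, pn))
    names(p) <- pnames
    if (any(!is.finite(unlist(p, use.names = FALSE))) ||
      any(p$sigma <= 0) || any(p$tau <= 0) ||
      (fam$nu_domain == "positive" && any(p$nu <= 0))) {
      return(1e10)
    }
    lp <- fam$logpdf(y, p$mu, p$sigma, p$nu, p$tau)
    if (any(!is.finite(lp))) {
      return(1e10)
    }
    -sum(w * lp)
  }

  # initialization: weighted LS for mu, residual spread for sigma,
  # family symmetry values for nu/tau
  theta <- numeric(sum(sizes))
  if ("mu" %in% free) {
    fitw <- stats::lm.wfit(X$mu, y, w)
    theta[idx$mu] <- ifelse(is.na(fitw$coefficients), 0, fitw$coefficients)
    res <- y - drop(X$mu %*% theta[idx$mu])
  } else {
    res <- y - fixed$mu
  }
  if ("sigma" %in% free) {
    theta[idx$sigma][1] <- links$sigma$fwd(max(wsd(res, w), 1e-3))
  }
  for (pn in c("nu", "tau")) {
    if (pn %in% free) {
      theta[idx[[pn]]][1] <- links[[pn]]$fwd(unname(fam$start[pn]))
    }
  }

  dev_trace <- numeric(0)
  dev <- 2 * negll(theta)
  converged <- FALSE
  iter <- 0L
  for (outer in seq_len(controls$max_outer)) {
    iter <- outer
    for (pn in free) {
      block <- idx[[pn]]
      f_blk <- function(b) {
        th <- theta
        th[block] <- b
        negll(th)
      }
      opt <- stats::optim(theta[block], f_blk,
        method = "BFGS",
        control = list(maxit = 60, reltol = 1e-10)
      )
      if (opt$value <= negll(theta)) theta[block] <- opt$par
    }
    # joint polish over all coefficients
    optj <- stats::optim(theta, negll,
      method = "BFGS",
      control = list(maxit = 100, reltol = 1e-12)
    )
    if (optj$value <= negll(theta)) theta <- optj$par
    new_dev <- 2 * negll(theta)
    dev_trace <- c(dev_trace, new_dev)
    if (is.finite(dev) && abs(dev - new_dev) < controls$rel_tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev <- new_dev
      break
    }
    dev <- new_dev
  }

  loglik <- -dev / 2
  edf <- sum(sizes)
  coefs <- lapply(free, function(pn) unname(theta[idx[[pn]]]))
  names(coefs) <- free

  model <- structure(
    list(
      family = fam$name,
      links = fam$links,
      smoothers = smo[free],
      bases = bases,
      coef = coefs,
      fixed = fixed,
      loglik = loglik,
      df = edf,
      n = length(y),
      # widen to whole years so the integer norm-table grid is covered
      # (natural splines extrapolate linearly past the boundary knots)
      age_range = c(floor(min(age)), ceiling(max(age))),
      gaic = vapply(c(2, 3.84, 5, 9), function(k) gaic(loglik, edf, k), numeric(1)),
      converged = converged,
      iterations = iter,
      deviance_trace = dev_trace
    ),
    class = "centile_model"
  )
  names(model$gaic) <- c("2", "3.84", "5", "9")
  # in-domain check on the evaluation grid
  grid <- seq(model$age_range[1], model$age_range[2], length.out = 81)
  pg <- predict_params(model, grid)
  if (any(pg$sigma <= 0) || any(pg$tau <= 0) ||
    (fam$nu_domain == "positive" && any(pg$nu <= 0)) ||
    any(!is.finite(unlist(pg)))) {
    stop_pn("fitted parameter curves leave the family domain on the age grid")
  }
  model
}

#' @export
print.centile_model <- function(x, ...) {
  cat(
    "Distributional centile model (", x$family, "), n = ", x$n,
    ", edf = ", x$df, "\n", sep = ""
  )
  cat(
    "  log-likelihood ", format(x$loglik), "; GAIC(k=2) ",
    format(x$gaic[["2"]]), "; converged: ", x$converged,
    " in ", x$iterations, " iterations\n", sep = ""
  )
  invisible(x)
}

#' Evaluate fitted parameter curves at given ages
#'
#' @param model A \code{centile_model}.
#' @param age Numeric vector of ages within the fitted range.
#' @return List of natural-scale parameter vectors \code{mu}, \code{sigma},
#'   \code{nu}, \code{tau}.
#' @export
predict_params <- function(model, age) {
  out <- list()
  for (pn in c("mu", "sigma", "nu", "tau")) {
    if (pn %in% names(model$fixed)) {
      out[[pn]] <- rep(model$fixed[[pn]], length(age))
    } else {
      eta <- drop(eval_basis(model$bases[[pn]], age) %*% model$coef[[pn]])
      out[[pn]] <- .link_fns(model$links[[pn]])$inv(eta)
    }
  }
  out
}

#' Generalized Akaike information criterion
#'
#' \code{GAIC = -2 loglik + k * df}; \code{k = 2} is the AIC.
#'
#' @param loglik Maximized log-likelihood.
#' @param df Effective degrees of freedom (>= 0).
#' @param k Complexity penalty (conventional values 2, 3.84, 5, 9).
#' @return Numeric GAIC value.
#' @export
gaic <- function(loglik, df, k = 2) {
  if (any(df < 0)) stop_pn("df must be non-negative")
  -2 * loglik + k * df
}

#' Centile (quantile) curve of a fitted distributional model
#'
#' @param model A \code{centile_model}.
#' @param age Ages within the fitted range.
#' @param p Probabilities in (0, 1).
#' @param floor0 Floor reported scores at 0 (the instrument cannot go
#'   negative; the fitted families are unbounded below)?
#' @return Score at the requested centile(s); \code{age} and \code{p}
#'   recycle against each other.
#' @export
centile <- function(model, age, p, floor0 = TRUE) {
  rng <- model$age_range
  if (any(age < rng[1] - 1e-9 | age > rng[2] + 1e-9)) {
    stop_pn("age outside the fitted range [", rng[1], ", ", rng[2], "]")
  }
  n <- max(length(age), length(p))
  pars <- predict_params(model, rep_len(age, n))
  q <- dist_quantile(model$family, rep_len(p, n), pars)
  if (floor0) pmax(q, 0) else q
}

#' Rank candidate families by GAIC
#'
#' Fits every candidate family (optionally with per-family smoother
#' overrides) and sorts converged fits by ascending GAIC.  Ties (GAIC within
#' \code{tie_tol}) are broken by smaller effective df, then by candidate
#' order.
#'
#' @inheritParams fit_distributional_model
#' @param families Character vector of at least two family names, or a list
#'   of specs \code{list(family=, smoothers=)}.
#' @param k GAIC penalty used for ranking.
#' @param top_m Keep the best m models (default all).
#' @param tie_tol Absolute GAIC difference treated as a tie.
#' @return List with \code{table} (data frame: family, df, loglik, gaic,
#'   converged) and \code{models} (fitted models in ranked order).
#' @export
rank_families <- function(data, families, smoothers = .default_smoothers(),
                          k = 2, top_m = Inf, controls = fit_controls(),
                          tie_tol = 1e-6) {
  if (length(families) < 1) stop_pn("need at least one candidate family")
  specs <- lapply(families, function(f) {
    if (is.character(f)) list(family = f, smoothers = smoothers) else f
  })
  fits <- vector("list", length(specs))
  errs <- character(length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      fit_distributional_model(data, specs[[i]]$family,
        smoothers = specs[[i]]$smoothers,
        controls = if (is.null(specs[[i]]$controls)) controls else specs[[i]]$controls
      ),
      error = function(e) {
        errs[i] <<- conditionMessage(e)
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(m) isTRUE(m$converged), logical(1))
  if (!any(ok)) {
    stop_pn(
      "no candidate family converged; diagnostics: ",
      paste(sprintf("[%s] %s", vapply(specs, `[[`, "", "family"), errs),
        collapse = "; "
      )
    )
  }
  fits <- fits[ok]
  g <- vapply(fits, function(m) gaic(m$loglik, m$df, k), numeric(1))
  df_ <- vapply(fits, function(m) m$df, numeric(1))
  ord <- order(round(g / tie_tol), df_, seq_along(fits))
  fits <- fits[ord]
  g <- g[ord]
  keep <- seq_len(min(length(fits), top_m))
  fits <- fits[keep]
  table <- data.frame(
    family = vapply(fits, function(m) m$family, character(1)),
    df = vapply(fits, function(m) m$df, numeric(1)),
    loglik = vapply(fits, function(m) m$loglik, numeric(1)),
    gaic = g[keep],
    converged = TRUE
  )
  list(table = table, models = fits)
}

#' Serialize / restore a fitted model (structured text)
#'
#' Models are written as JSON with full floating-point precision: family and
#' link names, frozen basis descriptions (kind, df, knots, boundary knots,
#' FP powers) and coefficients, so that a restored model reproduces centile
#' tables bit-for-bit.
#'
#' @param model A \code{centile_model} or \code{quantile_model_set}.
#' @param path Output path.
#' @return \code{serialize_model} returns \code{path} invisibly;
#'   \code{deserialize_model} returns the restored model object.
#' @export
serialize_model <- function(model, path) {
  if (inherits(model, "centile_model")) {
    obj <- list(
      type = "centile_model",
      family = model$family, links = as.list(model$links),
      bases = model$bases, coef = model$coef, fixed = model$fixed,
      loglik = model$loglik, df = model$df, n = model$n,
      age_range = model$age_range, gaic = as.list(model$gaic),
      converged = model$converged, iterations = model$iterations
    )
  } else if (inherits(model, "quantile_model_set")) {
    obj <- list(
      type = "quantile_model_set",
      basis = model$basis, taus = model$taus, coef = model$coef,
      loss = model$loss, weighted = model$weighted,
      age_range = model$age_range, n = model$n,
      nodes = model$nodes, values = model$values
    )
  } else {
    stop_pn("cannot serialize object of class ", paste(class(model), collapse = "/"))
  }
  # I(17) significant digits: exact IEEE-754 round trip through text
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "centile_model")) {
    model <- obj[setdiff(names(obj), "type")]
    model$links <- unlist(model$links)
    model$gaic <- unlist(model$gaic)
    model$coef <- lapply(model$coef, as.numeric)
    model$bases <- lapply(model$bases, function(b) {
      b$knots <- as.numeric(b$knots)
      b
    })
    if (length(model$fixed) == 0) model$fixed <- list()
    structure(model, class = "centile_model")
  } else if (identical(obj$type, "quantile_model_set")) {
    model <- obj[setdiff(names(obj), "type")]
    if (!is.null(model$coef)) model$coef <- as.data.frame(model$coef)
    structure(model, class = "quantile_model_set")
  } else {
    stop_pn("unrecognized serialized model type")
  }
}
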