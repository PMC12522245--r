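# Per-percentile quantile regression.
#
# The tau-quantile fit minimizes the weighted pinball (check) loss
#   L(beta) = sum_i w_i rho_tau(y_i - x_i' beta),
#   rho_tau(u) = u (tau - 1{u < 0}).
# The solver is the Hunter-Lange majorize-minimize (MM) iteration: each step
# solves a weighted least-squares system obtained from an
# epsilon-perturbation of |u|, with epsilon driven towards zero, followed by
# a vertex polish — the exact optimum of a quantile regression interpolates
# p data points (p = number of coefficients), so the fit is refined by
# enumerating interpolating candidates among the observations with the
# smallest MM residuals and keeping whichever attains the lowest exact loss.
# Intercept-only fits use the exact weighted-quantile solution directly.
#
# The smoothed additive variant fits node values on the distinct-age grid,
# penalizing the total variation of the fitted curve's derivative (the sum
# of absolute second-order slope changes); as the penalty grows the fit
# collapses to the best straight line.

.pinball <- function(u, tau) u * (tau - (u < 0))

.qr_design <- function(age, basis) {
  info <- if (is.list(basis) && !is.null(basis$kind)) basis else NULL
  if (is.null(info)) stop_pn("basis must be a frozen basis or smoother_spec")
  eval_basis(info, age)
}

# MM iterations for weighted quantile regression on design matrix X.
.qr_mm <- function(X, y, w, tau, max_iter = 400) {
  p <- ncol(X)
  beta <- tryCatch(
    qr.coef(qr(X * sqrt(w)), y * sqrt(w)),
    error = function(e) rep(0, p)
  )
  beta[is.na(beta)] <- 0
  eps <- 1e-3
  sw <- (2 * tau - 1) * crossprod(X, w)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    a <- w / (eps + abs(r))
    XtA <- crossprod(X, X * a)
    rhs <- crossprod(X, a * y) + sw
    new_beta <- tryCatch(solve(XtA, rhs), error = function(e) NULL)
    if (is.null(new_beta)) break
    delta <- max(abs(new_beta - beta))
    beta <- drop(new_beta)
    if (delta < 1e-10 * max(1, max(abs(beta)))) {
      if (eps <= 1e-11) break
      eps <- eps / 10
    }
  }
  beta
}

# Exact-loss polish: try interpolating fits through p small-residual points.
.qr_polish <- function(X, y, w, tau, beta) {
  p <- ncol(X)
  n <- nrow(X)
  loss <- function(b) sum(w * .pinball(y - drop(X %*% b), tau))
  best <- beta
  best_loss <- loss(beta)
  r <- abs(y - drop(X %*% beta))
  m <- min(n, max(3 * p, 12))
  cand <- order(r)[seq_len(m)]
  if (choose(m, p) > 5000) {
    return(list(coef = best, loss = best_loss))
  }
  combs <- utils::combn(cand, p)
  for (j in seq_len(ncol(combs))) {
    rows <- combs[, j]
    b <- tryCatch(solve(X[rows, , drop = FALSE], y[rows]), error = function(e) NULL)
    if (is.null(b)) next
    l <- loss(b)
    if (l < best_loss - 1e-12) {
      best <- drop(b)
      best_loss <- l
    }
  }
  list(coef = best, loss = best_loss)
}

#' Fit a single weighted quantile regression
#'
#' @param data Data frame with columns \code{age}, \code{score} and
#'   optionally \code{weight}.
#' @param basis A \code{\link{smoother_spec}} of kind \code{"linear"},
#'   \code{"polynomial"} (order 2-4), or \code{"fractional_polynomial"};
#'   \code{"constant"} gives the exact weighted sample quantile.
#' @param tau Quantile level in (0, 1).
#' @return List with \code{coef} (named, intercept first), \code{loss} (the
#'   achieved weighted pinball loss), \code{basis} (frozen basis) and
#'   \code{tau}.
#' @export
fit_quantile <- function(data, basis, tau) {
  if (tau <= 0 || tau >= 1) stop_pn("tau must lie strictly inside (0, 1)")
  y <- data$score
  age <- data$age
  w <- if ("weight" %in% names(data)) data$weight else rep(1, length(y))
  keep <- !is.na(y) & !is.na(age)
  y <- y[keep]; age <- age[keep]; w <- w[keep]
  info <- fit_basis(basis, age)
  X <- eval_basis(info, age)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_pn(
      "design matrix is rank deficient; collinear columns: ",
      paste(dropped, collapse = ", ")
    )
  }
  if (ncol(X) == 1) {
    b <- weighted_quantile_pinball(y, w, tau)
    return(list(
      coef = c(intercept = b),
      loss = sum(w * .pinball(y - b, tau)),
      basis = info, tau = tau
    ))
  }
  beta <- .qr_mm(X, y, w, tau)
  pol <- .qr_polish(X, y, w, tau, beta)
  names(pol$coef) <- colnames(X)
  list(coef = pol$coef, loss = pol$loss, basis = info, tau = tau)
}

#' Smoothed additive quantile regression
#'
#' Fits a piecewise-linear curve over the distinct-age nodes minimizing
#' weighted pinball loss plus \code{penalty} times the total variation of
#' the curve's derivative (sum of absolute slope changes across interior
#' nodes).  \code{penalty = 0} lets the curve interpolate the per-node
#' quantiles; a very large penalty recovers the straight-line fit.
#'
#' @inheritParams fit_quantile
#' @param penalty Non-negative roughness penalty.
#' @param max_nodes If there are more distinct ages than this, nodes are
#'   placed on an equally spaced grid instead (default 201).
#' @return List with \code{nodes}, fitted \code{values} at the nodes,
#'   \code{loss} (pinball part only), \code{penalty} and \code{tau};
#'   prediction interpolates linearly between nodes.
#' @export
fit_smoothed_additive_quantile <- function(data, tau, penalty = 1,
                                           max_nodes = 201) {
  if (tau <= 0 || tau >= 1) stop_pn("tau must lie strictly inside (0, 1)")
  if (penalty < 0) stop_pn("penalty must be non-negative")
  y <- data$score
  age <- data$age
  w <- if ("weight" %in% names(data)) data$weight else rep(1, length(y))
  keep <- !is.na(y) & !is.na(age)
  y <- y[keep]; age <- age[keep]; w <- w[keep]
  ua <- sort(unique(age))
  if (length(ua) > max_nodes) {
    nodes <- seq(min(age), max(age), length.out = max_nodes)
    j <- pmin(
      pmax(round((age - nodes[1]) / diff(nodes[1:2])) + 1, 1),
      max_nodes
    )
  } else {
    nodes <- ua
    j <- match(age, ua)
  }
  m <- length(nodes)
  if (m < 2) stop_pn("need at least two distinct ages")
  # observations attach to single nodes, so every incidence cross-product
  # is a per-node aggregate (never form the incidence matrix)
  node_sum <- function(x) {
    out <- numeric(m)
    s <- rowsum(x, j)
    out[as.integer(rownames(s))] <- s
    out
  }
  # second-difference (slope-change) operator
  if (m >= 3) {
    D <- matrix(0, m - 2, m)
    for (i in seq_len(m - 2)) {
      h1 <- nodes[i + 1] - nodes[i]
      h2 <- nodes[i + 2] - nodes[i + 1]
      D[i, i] <- 1 / h1
      D[i, i + 1] <- -(1 / h1 + 1 / h2)
      D[i, i + 2] <- 1 / h2
    }
  } else {
    D <- matrix(0, 0, m)
  }
  # initialize at per-node weighted quantiles
  theta <- vapply(seq_len(m), function(k) {
    sel <- j == k
    if (any(sel)) weighted_quantile_pinball(y[sel], w[sel], tau) else NA_real_
  }, numeric(1))
  theta <- stats::approx(nodes[!is.na(theta)], theta[!is.na(theta)],
    xout = nodes, rule = 2
  )$y
  obj <- function(th) {
    sum(w * .pinball(y - th[j], tau)) + penalty * sum(abs(D %*% th))
  }
  eps <- 1e-3
  sw <- (2 * tau - 1) * node_sum(w)
  best <- theta
  best_obj <- obj(theta)
  for (it in seq_len(600)) {
    r <- y - theta[j]
    a <- w / (eps + abs(r))
    d <- drop(D %*% theta)
    b <- penalty / (eps + abs(d))
    H <- 2 * crossprod(D, D * b)
    diag(H) <- diag(H) + node_sum(a) + 1e-10
    rhs <- node_sum(a * y) + sw
    new_theta <- tryCatch(drop(solve(H, rhs)), error = function(e) NULL)
    if (is.null(new_theta)) break
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    o <- obj(theta)
    if (is.finite(o) && o < best_obj) {
      best <- theta
      best_obj <- o
    }
    if (delta < 1e-10 * max(1, max(abs(theta)))) {
      if (eps <= 1e-11) break
      eps <- eps / 10
    }
  }
  theta <- best
  # the straight line has zero roughness penalty and is always feasible;
  # keep whichever attains the lower exact objective (guards the MM path
  # against ill-conditioning at extreme penalties)
  lin <- fit_quantile(
    data.frame(age = age, score = y, weight = w),
    smoother_spec("linear"), tau
  )
  lin_vals <- drop(eval_basis(lin$basis, nodes) %*% lin$coef)
  if (obj(lin_vals) < obj(theta)) theta <- lin_vals
  list(
    nodes = nodes, values = theta,
    loss = sum(w * .pinball(y - theta[j], tau)),
    penalty = penalty, tau = tau
  )
}

#' Fit a set of quantile-regression centile curves sharing one basis
#'
#' @inheritParams fit_quantile
#' @param basis Either a \code{\link{smoother_spec}} (\code{"linear"},
#'   \code{"polynomial"} with df 2-4, \code{"fractional_polynomial"}) or the
#'   string \code{"smoothed"} for the penalized additive fit.
#' @param taus Quantile levels; default the nine reporting percentiles
#'   5, 10, 20, 25, 50, 75, 80, 90, 95 (as probabilities).
#' @param penalty Roughness penalty when \code{basis = "smoothed"}.
#' @param weighted Use the analytic weights (if present)?
#' @return A \code{quantile_model_set}: shared frozen basis, one coefficient
#'   row (or node-value row) and achieved pinball loss per tau.
#' @export
fit_quantile_set <- function(data, basis,
                             taus = c(
                               0.05, 0.10, 0.20, 0.25, 0.50,
                               0.75, 0.80, 0.90, 0.95
                             ),
                             penalty = 1, weighted = TRUE) {
  if (!weighted) data$weight <- NULL
  smoothed <- identical(basis, "smoothed")
  fits <- lapply(taus, function(tt) {
    if (smoothed) {
      fit_smoothed_additive_quantile(data, tt, penalty = penalty)
    } else {
      fit_quantile(data, basis, tt)
    }
  })
  out <- list(
    taus = taus,
    loss = vapply(fits, `[[`, numeric(1), "loss"),
    weighted = weighted,
    age_range = c(floor(min(data$age, na.rm = TRUE)), ceiling(max(data$age, na.rm = TRUE))),
    n = sum(!is.na(data$score) & !is.na(data$age)),
    converged = TRUE
  )
  if (smoothed) {
    out$basis <- list(kind = "smoothed", penalty = penalty)
    out$nodes <- fits[[1]]$nodes
    out$values <- do.call(rbind, lapply(fits, `[[`, "values"))
  } else {
    out$basis <- fits[[1]]$basis
    out$coef <- do.call(rbind, lapply(fits, `[[`, "coef"))
  }
  structure(out, class = "quantile_model_set")
}

#' @export
print.quantile_model_set <- function(x, ...) {
  cat(
    "Quantile regression centile set (basis: ", x$basis$kind, "), n = ",
    x$n, ", taus: ", paste(x$taus, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Monotone rearrangement of centile curves
#'
#' Sorts fitted values across percentile levels at every grid age, removing
#' quantile crossings; curves that are already monotone pass through
#' unchanged.  Rearrangement never increases the total pinball loss.
#'
#' @param curves Numeric matrix: rows = percentile levels (in increasing
#'   nominal order), columns = grid ages.
#' @return Matrix of the same shape, non-decreasing down each column.
#' @export
rearrange_noncrossing <- function(curves) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  apply(curves, 2, sort)
}

# Shared prediction interface: fitted centile score at (age, p).
# Only the fitted taus are available for a quantile_model_set.

#' Fitted centile score at given ages
#'
#' Generic shared by the two modelling approaches (and by oracle wrappers),
#' so validation treats any model as an age -> percentile-curve map.
#'
#' @param object A fitted model.
#' @param age Ages within the fitted range.
#' @param p Probability level(s).
#' @param ... Method-specific arguments (e.g. \code{floor0}).
#' @return Numeric vector of scores.
#' @export
predict_centile <- function(object, age, p, ...) UseMethod("predict_centile")

#' @export
predict_centile.centile_model <- function(object, age, p, ...) {
  centile(object, age, p, ...)
}

#' @export
predict_centile.quantile_model_set <- function(object, age, p, floor0 = TRUE, ...) {
  n <- max(length(age), length(p))
  age <- rep_len(age, n)
  p <- rep_len(p, n)
  out <- numeric(n)
  for (tt in unique(p)) {
    i <- which(abs(object$taus - tt) < 1e-9)
    if (length(i) != 1) {
      stop_pn("percentile ", 100 * tt, " was not fitted in this model set")
    }
    sel <- p == tt
    if (identical(object$basis$kind, "smoothed")) {
      out[sel] <- stats::approx(object$nodes, object$values[i, ],
        xout = age[sel], rule = 2
      )$y
    } else {
      X <- eval_basis(object$basis, age[sel])
      out[sel] <- drop(X %*% as.numeric(object$coef[i, ]))
    }
  }
  if (floor0) pmax(out, 0) else out
}

#' Wrap an arbitrary centile function as a model
#'
#' Useful for oracle comparisons: wraps \code{f(age, p)} so it can be passed
#' wherever a fitted model is expected.
#'
#' @param f Function of (age, p) returning scores.
#' @param age_range Ages the wrapper claims to cover.
#' @return A \code{centile_fn} object supporting
#'   \code{\link{predict_centile}}.
#' @export
centile_fn <- function(f, age_range = c(45, 85)) {
  structure(list(f = f, age_range = age_range, converged = TRUE),
    class = "centile_fn"
  )
}

#' @export
predict_centile.centile_fn <- function(object, age, p, ...) {
  n <- max(length(age), length(p))
  object$f(rep_len(age, n), rep_len(p, n))
}
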