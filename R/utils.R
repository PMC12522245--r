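# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
stop_pn <- function(...) stop(..., call. = FALSE)

# Vectorized safeguarded bisection for strictly increasing scalar maps.
# Solves f(x) = target[i] for each target; f must be vectorized.
# Brackets are expanded geometrically from (lower, upper) until they
# enclose every target, then bisected to machine-level width.
solve_monotone <- function(f, target, lower, upper, iter = 200L) {
  n <- length(target)
  lo <- rep_len(lower, n)
  hi <- rep_len(upper, n)
  # expand brackets where needed
  for (k in 1:60) {
    flo <- f(lo)
    bad <- flo > target
    if (!any(bad)) break
    lo[bad] <- lo[bad] - 2^k * pmax(1, abs(lo[bad]))
  }
  for (k in 1:60) {
    fhi <- f(hi)
    bad <- fhi < target
    if (!any(bad)) break
    hi[bad] <- hi[bad] + 2^k * pmax(1, abs(hi[bad]))
  }
  for (k in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    below <- fm < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-15 * max(1, max(abs(hi)))) break
  }
  0.5 * (lo + hi)
}

# Weighted mean / SD with the Sum(w x)/Sum(w) convention.
wmean <- function(x, w) sum(w * x) / sum(w)

wsd <- function(x, w) {
  m <- wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# Weighted tau-quantile: the minimizer of the weighted pinball loss.
# Returns the smallest y with cumulative weight >= tau * total weight.
weighted_quantile_pinball <- function(y, w, tau) {
  o <- order(y)
  y <- y[o]
  w <- w[o]
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  i <- which(cw >= tau * tot - 1e-12 * tot)[1]
  y[i]
}

# Derive a per-use 32-bit sub-seed from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

# Run an expression under a local RNG state with the given seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
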