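# Design-matrix bases for age effects, shared by the distributional and
# quantile-regression models.  A smoother spec is fitted once on training
# ages (fixing knots / boundary knots / FP shift), after which the frozen
# basis can be evaluated at arbitrary ages in range — this is what makes
# serialized models reproducible bit-for-bit.

.fp_powers_allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial basis expansion
#'
#' Builds the conventional FP basis: one column per power p, equal to
#' \code{age^p}, with \code{p = 0} meaning \code{log(age)}; a repeated power
#' contributes \code{age^p * log(age)} (FP convention for degree-2 models
#' with tied powers).  Ages must be positive (apply a documented shift
#' first if not); powers come from the conventional set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} with degree at most 2.
#'
#' @param ages Positive numeric vector.
#' @param powers Numeric vector (length 1 or 2) of FP powers.
#' @param scale Divisor applied to age before exponentiation (default 10;
#'   keeps columns well conditioned for ages 45-85).
#' @return Numeric matrix with one column per power (no intercept).
#' @export
expand_fractional_polynomial <- function(ages, powers, scale = 10) {
  if (any(ages <= 0)) stop_pn("fractional polynomials need positive ages")
  if (length(powers) < 1 || length(powers) > 2) {
    stop_pn("fractional-polynomial degree is capped at 2")
  }
  if (!all(powers %in% .fp_powers_allowed)) {
    stop_pn(
      "FP powers must come from {", paste(.fp_powers_allowed, collapse = ", "), "}"
    )
  }
  a <- ages / scale
  col <- function(p) if (p == 0) log(a) else a^p
  out <- matrix(col(powers[1]), ncol = 1)
  if (length(powers) == 2) {
    second <- if (powers[2] == powers[1]) col(powers[1]) * log(a) else col(powers[2])
    out <- cbind(out, second)
  }
  colnames(out) <- paste0("fp", seq_along(powers))
  out
}

#' Describe an age smoother
#'
#' @param kind One of \code{"constant"}, \code{"linear"},
#'   \code{"cubic_spline"} (natural cubic regression spline),
#'   \code{"polynomial_spline"} (cubic B-spline), \code{"polynomial"}
#'   (raw polynomial of given order), or \code{"fractional_polynomial"}.
#' @param df Basis dimension excluding the intercept (spline kinds;
#'   default 3); polynomial order for \code{"polynomial"}.
#' @param powers FP powers (see
#'   \code{\link{expand_fractional_polynomial}}), default \code{c(1, 0)}.
#' @return A \code{smoother_spec} object.
#' @export
smoother_spec <- function(kind = c(
                            "cubic_spline", "polynomial_spline", "polynomial",
                            "fractional_polynomial", "linear", "constant"
                          ),
                          df = NULL, powers = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("cubic_spline", "polynomial_spline")) {
    if (is.null(df)) df <- 3
    if (df < 1) stop_pn("spline df must be positive")
  }
  if (kind == "polynomial") {
    if (is.null(df)) df <- 2
    if (df < 1) stop_pn("polynomial order must be at least 1")
  }
  if (kind == "fractional_polynomial" && is.null(powers)) powers <- c(1, 0)
  structure(list(kind = kind, df = df, powers = powers),
    class = "smoother_spec"
  )
}

# Fit the basis on training ages: freezes knots etc.  Returns a frozen
# basis description with the training design matrix attached.
fit_basis <- function(spec, age) {
  if (!inherits(spec, "smoother_spec")) spec <- do.call(smoother_spec, as.list(spec))
  info <- list(kind = spec$kind, df = spec$df, powers = spec$powers)
  if (spec$kind == "cubic_spline") {
    b <- splines::ns(age, df = spec$df)
    info$knots <- as.numeric(attr(b, "knots"))
    info$boundary <- as.numeric(attr(b, "Boundary.knots"))
  } else if (spec$kind == "polynomial_spline") {
    b <- splines::bs(age, df = spec$df, degree = 3)
    info$knots <- as.numeric(attr(b, "knots"))
    info$boundary <- as.numeric(attr(b, "Boundary.knots"))
    info$degree <- 3
  }
  info
}

# Evaluate a frozen basis at new ages; returns the design matrix with
# intercept as the first column.
eval_basis <- function(info, age) {
  x <- switch(info$kind,
    constant = NULL,
    linear = matrix((age - 65) / 10, ncol = 1),
    polynomial = outer((age - 65) / 10, seq_len(info$df), `^`),
    cubic_spline = unclass(splines::ns(age,
      knots = info$knots, Boundary.knots = info$boundary
    )),
    polynomial_spline = unclass(splines::bs(age,
      knots = info$knots, Boundary.knots = info$boundary, degree = info$degree
    )),
    fractional_polynomial = expand_fractional_polynomial(age, info$powers),
    stop_pn("unknown smoother kind '", info$kind, "'")
  )
  cbind(intercept = rep(1, length(age)), x)
}
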