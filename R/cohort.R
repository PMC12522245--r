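# Synthetic reference cohort with known ground truth, plus the eligibility
# filter and descriptive analyses applied to any cohort (synthetic or real).
#
# The generator emulates the structure of a large population-based aging
# cohort: ages uniform on 45-85, ~47% female, interview dates spread over a
# calendar year, positive survey weights (inflation weights for description,
# analytic weights for modelling) with mean 1, and PASE totals drawn from a
# sex-specific four-parameter distribution whose location declines linearly
# with age (the true 50th centile falls ~100 points from 45 to 85) with
# scale narrowing with age and heavier spread below than above the median.
# A subpopulation carrying mobility/disability exclusion flags has the same
# shape shifted down.  Scores are censored at 0 (the instrument cannot go
# negative), so the generator's true centile is max(0, family quantile) —
# available in closed form for every age, sex and probability.

.sex_truth <- function(family, mu45, mu_slope, sigma45, sigma85, nu, tau) {
  list(
    family = family, mu45 = mu45, mu_slope = mu_slope,
    sigma45 = sigma45, sigma85 = sigma85, nu = nu, tau = tau
  )
}

# Mean of the standardized (mu = 0, sigma = 1) family member, by quadrature.
.family_zmean <- function(family, nu, tau) {
  stats::integrate(
    function(z) z * dist_pdf(family, z, list(mu = 0, sigma = 1, nu = nu, tau = tau)),
    -Inf, Inf,
    rel.tol = 1e-10
  )$value
}

#' Specification of the synthetic cohort generator
#'
#' Defaults describe the study conditions the pipeline targets: n of 51,338
#' before filtering, 47% female, a ~22.6% excluded (gait aid / ADL-IADL
#' assistance) subpopulation with lower scores, ~6% of records with missing
#' eligibility or PASE information, and sex-specific score distributions —
#' SHASHo2 for males, SEP4 for females, both with location falling 2.5
#' points/year of age and scale narrowing with age.  The location intercepts
#' are calibrated at construction time (by quadrature on the generating
#' family) so the included population's expected score matches the
#' mean anchors of 172.57 (males) and 147.39 (females).
#'
#' @param n Number of subjects to generate (before any filtering).
#' @param female_fraction Probability a subject is female.
#' @param male,female Per-sex ground truth: list with \code{family},
#'   \code{mu45} (location at age 45; \code{NULL} = calibrate to the mean
#'   anchor), \code{mu_slope} (points/year), \code{sigma45}, \code{sigma85}
#'   (scale at the range ends; log-linear in between), \code{nu},
#'   \code{tau}.
#' @param mean_anchor Named vector \code{c(male=, female=)}: target expected
#'   score of the included population (uniform over ages 45-85), used only
#'   when the corresponding \code{mu45} is \code{NULL}.
#' @param excluded_fraction Fraction of subjects carrying at least one
#'   exclusion flag.
#' @param excluded_shift Location shift (<= 0) applied to excluded
#'   subjects' scores.
#' @param missing_fraction Fraction of otherwise eligible (non-excluded)
#'   subjects with missing eligibility flags or missing PASE data; the
#'   default makes the missing share about 5.9% of the whole cohort.
#' @param year Calendar year over which interview dates are spread.
#' @param seed Integer seed making generation deterministic.
#' @return A \code{generator_spec} object.
#' @export
generator_spec <- function(n = 51338,
                           female_fraction = 0.47,
                           male = NULL, female = NULL,
                           mean_anchor = c(male = 172.57, female = 147.39),
                           excluded_fraction = 0.226,
                           excluded_shift = -45,
                           missing_fraction = 0.076,
                           year = 2014,
                           seed = 1) {
  if (n < 1) stop_pn("n must be at least 1")
  if (female_fraction <= 0 || female_fraction >= 1) {
    stop_pn("female_fraction must lie strictly inside (0, 1)")
  }
  if (excluded_fraction < 0 || excluded_fraction >= 1) {
    stop_pn("excluded_fraction must lie in [0, 1)")
  }
  if (excluded_shift > 0) stop_pn("excluded_shift must be <= 0")
  if (is.null(male)) {
    male <- .sex_truth("SHASHo2", NULL, -2.5, 75, 48, -0.1, 1.05)
  }
  if (is.null(female)) {
    female <- .sex_truth("SEP4", NULL, -2.5, 70, 42, 1.35, 2.4)
  }
  for (sx in c("male", "female")) {
    tr <- get(sx)
    if (is.null(tr$mu45)) {
      # E[score] = mean_a mu(a) + zmean * mean_a sigma(a); solve for mu45.
      zm <- .family_zmean(tr$family, tr$nu, tr$tau)
      ages <- seq(45, 85, length.out = 401)
      sig <- exp(seq(log(tr$sigma45), log(tr$sigma85), length.out = 401))
      tr$mu45 <- mean_anchor[[sx]] - mean(tr$mu_slope * (ages - 45)) -
        zm * mean(sig)
      assign(sx, tr)
    }
    chk <- true_params(
      structure(list(male = male, female = female), class = "generator_spec"),
      sx, c(45, 65, 85)
    )
    if (any(!is.finite(unlist(chk)))) {
      stop_pn("ground-truth parameter curves must be finite on [45, 85]")
    }
  }
  structure(
    list(
      n = as.integer(n), female_fraction = female_fraction,
      male = male, female = female,
      excluded_fraction = excluded_fraction,
      excluded_shift = excluded_shift,
      missing_fraction = missing_fraction,
      year = year, seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' Ground-truth distribution parameters at given ages
#'
#' @param spec A \code{generator_spec}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param age Numeric vector of ages in [45, 85].
#' @return List with vectors \code{mu}, \code{sigma}, \code{nu}, \code{tau}.
#' @export
true_params <- function(spec, sex, age) {
  tr <- spec[[match.arg(sex, c("male", "female"))]]
  frac <- (age - 45) / 40
  list(
    mu = tr$mu45 + tr$mu_slope * (age - 45),
    sigma = exp(log(tr$sigma45) + frac * (log(tr$sigma85) - log(tr$sigma45))),
    nu = rep_len(tr$nu, length(age)),
    tau = rep_len(tr$tau, length(age))
  )
}

#' Ground-truth centile of the generator
#'
#' Closed-form true p-quantile of the (0-censored) score distribution at a
#' given age and sex: \code{max(0, Q_family(p; theta(age)))}.
#'
#' @inheritParams true_params
#' @param p Probability in (0, 1), scalar or vector.
#' @return Numeric vector of true centile scores.
#' @export
true_centile <- function(spec, sex, age, p) {
  sex <- match.arg(sex, c("male", "female"))
  tr <- spec[[sex]]
  n <- max(length(age), length(p))
  pm <- true_params(spec, sex, rep_len(age, n))
  pmax(0, dist_quantile(tr$family, rep_len(p, n), pm))
}

#' Generate a synthetic cohort
#'
#' @param spec A \code{generator_spec}.
#' @return Data frame of subject records: \code{id}, \code{age}, \code{sex},
#'   \code{interview_date}, \code{uses_gait_aid},
#'   \code{needs_adl_iadl_assist}, \code{inflation_weight},
#'   \code{analytic_weight}, \code{pase_total}.  Deterministic given
#'   \code{spec$seed}.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    stop_pn("spec must be a generator_spec (see generator_spec())")
  }
  n <- spec$n
  with_seed(spec$seed, {
    sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
    age <- stats::runif(n, 45, 85)
    day0 <- as.Date(sprintf("%d-01-01", spec$year))
    ndays <- as.integer(as.Date(sprintf("%d-12-31", spec$year)) - day0) + 1L
    interview_date <- day0 + (sample.int(ndays, n, replace = TRUE) - 1L)
    excl <- stats::runif(n) < spec$excluded_fraction
    # excluded subjects carry a gait-aid flag, an ADL/IADL flag, or both
    which_flag <- sample.int(3L, n, replace = TRUE)
    uses_gait_aid <- excl & which_flag != 2L
    needs_adl <- excl & which_flag != 1L
    inflation_weight <- stats::rgamma(n, shape = 20, rate = 20)
    analytic_weight <- stats::rgamma(n, shape = 20, rate = 20)
    score <- numeric(n)
    for (sx in c("male", "female")) {
      idx <- sex == sx
      pm <- true_params(spec, sx, age[idx])
      score[idx] <- dist_sample(spec[[sx]]$family, sum(idx), pm)
    }
    score[excl] <- score[excl] + spec$excluded_shift
    score <- pmax(0, score)
    # route a slice of non-excluded records to missingness: half lose an
    # eligibility flag, half lose their PASE data
    uses_gait_aid <- as.logical(uses_gait_aid)
    needs_adl <- as.logical(needs_adl)
    mis <- !excl & stats::runif(n) < spec$missing_fraction
    mis_kind <- stats::runif(n) < 0.5
    needs_adl[mis & mis_kind] <- NA
    uses_gait_aid[mis & mis_kind & stats::runif(n) < 0.3] <- NA
    score[mis & !mis_kind] <- NA
    data.frame(
      id = sprintf("S%06d", seq_len(n)),
      age = age,
      sex = sex,
      interview_date = interview_date,
      uses_gait_aid = uses_gait_aid,
      needs_adl_iadl_assist = needs_adl,
      inflation_weight = inflation_weight,
      analytic_weight = analytic_weight,
      pase_total = score,
      stringsAsFactors = FALSE
    )
  })
}

#' Partition a cohort by the normative-sample eligibility rules
#'
#' A subject enters the reference ("healthy") sample only if they report no
#' gait-aid use and no assistance with ADL/IADL activities, with both flags
#' observed and complete PASE data.  Subjects with either flag TRUE are
#' excluded; subjects with missing flags or missing PASE data are dropped
#' (missingness is routed, never guessed).
#'
#' @param records Cohort data frame (see \code{\link{generate_cohort}}).
#' @return List of three disjoint data frames covering the input:
#'   \code{included}, \code{excluded}, \code{missing_dropped}.
#' @export
apply_exclusions <- function(records) {
  gait <- records$uses_gait_aid
  adl <- records$needs_adl_iadl_assist
  has_pase <- !is.na(records$pase_total)
  excl <- (!is.na(gait) & gait) | (!is.na(adl) & adl)
  miss <- !excl & (is.na(gait) | is.na(adl) | !has_pase)
  incl <- !excl & !miss
  list(
    included = records[incl, , drop = FALSE],
    excluded = records[excl, , drop = FALSE],
    missing_dropped = records[miss, , drop = FALSE]
  )
}

#' Map an interview date to its season
#'
#' Winter = January-March, Spring = April-June, Summer = July-September,
#' Fall = October-December.
#'
#' @param date A \code{Date} vector (or string coercible to one).
#' @return Character vector in \code{c("winter","spring","summer","fall")}.
#' @export
assign_season <- function(date) {
  d <- as.Date(date)
  if (anyNA(d)) stop_pn("invalid interview date")
  month <- as.integer(format(d, "%m"))
  c(
    "winter", "winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "fall", "fall", "fall"
  )[month]
}

#' Survey-weighted descriptive statistics
#'
#' Weighted means and SDs for numeric variables (weighted mean
#' \eqn{\sum w x / \sum w}; SD via \eqn{\sum w (x - \bar x)^2 / \sum w}) and
#' weighted proportions for character/factor/logical variables.
#'
#' @param records Data frame.
#' @param weight_field Name of the (strictly positive) weight column;
#'   inflation weights are the convention for population description.
#' @param variables Columns to describe; defaults to every column except
#'   identifiers, dates and weights.
#' @return Long data frame: \code{variable}, \code{level} (NA for numeric),
#'   \code{statistic} (\code{"mean"}, \code{"sd"} or \code{"proportion"}),
#'   \code{value}, \code{n}.
#' @export
weighted_descriptives <- function(records, weight_field = "inflation_weight",
                                  variables = NULL) {
  w <- records[[weight_field]]
  if (is.null(w)) stop_pn("no weight column '", weight_field, "'")
  if (any(is.na(w)) || any(w <= 0)) stop_pn("weights must be strictly positive")
  if (sum(w) <= 0) stop_pn("total weight must be positive")
  if (is.null(variables)) {
    skip <- c("id", "interview_date", "inflation_weight", "analytic_weight")
    variables <- setdiff(names(records), skip)
  }
  rows <- list()
  for (v in variables) {
    x <- records[[v]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        statistic = c("mean", "sd"),
        value = c(wmean(x[ok], w[ok]), wsd(x[ok], w[ok])),
        n = sum(ok)
      )
    } else {
      x <- as.character(x)
      for (lev in sort(unique(x[ok]))) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lev, statistic = "proportion",
          value = sum(w[ok][x[ok] == lev]) / sum(w[ok]),
          n = sum(ok)
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare included vs excluded scores within 10-year age bands
#'
#' Two-sample t-tests (Welch by default) of the PASE total between the
#' included and excluded partitions within age bands 45-54, 55-64, 65-74
#' and 75+.
#'
#' @param included,excluded Data frames with \code{age} and
#'   \code{pase_total}.
#' @param var_equal Assume equal variances (classical t) instead of Welch?
#' @return Data frame with one row per band: group sizes and means, mean
#'   difference (included - excluded), \code{t}, \code{df}, \code{p_value};
#'   bands with fewer than 2 subjects in either group are flagged
#'   \code{skipped} and carry NA statistics.
#' @export
compare_included_excluded <- function(included, excluded, var_equal = FALSE) {
  cut_band <- function(age) {
    ifelse(age < 55, "45-54",
      ifelse(age < 65, "55-64", ifelse(age < 75, "65-74", "75+"))
    )
  }
  bands <- c("45-54", "55-64", "65-74", "75+")
  bi <- cut_band(included$age)
  be <- cut_band(excluded$age)
  out <- lapply(bands, function(b) {
    xi <- included$pase_total[bi == b & !is.na(included$pase_total)]
    xe <- excluded$pase_total[be == b & !is.na(excluded$pase_total)]
    if (length(xi) < 2 || length(xe) < 2) {
      return(data.frame(
        band = b, n_included = length(xi), n_excluded = length(xe),
        mean_included = NA_real_, mean_excluded = NA_real_,
        mean_diff = NA_real_, t = NA_real_, df = NA_real_,
        p_value = NA_real_, skipped = TRUE
      ))
    }
    tt <- stats::t.test(xi, xe, var.equal = var_equal)
    data.frame(
      band = b, n_included = length(xi), n_excluded = length(xe),
      mean_included = mean(xi), mean_excluded = mean(xe),
      mean_diff = mean(xi) - mean(xe),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, skipped = FALSE
    )
  })
  do.call(rbind, out)
}

#' Read / write a cohort CSV
#'
#' @param path File path.
#' @return \code{read_cohort_csv} returns the cohort data frame with typed
#'   columns; \code{write_cohort_csv} returns \code{path} invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("interview_date" %in% names(df)) {
    df$interview_date <- as.Date(df$interview_date)
  }
  for (cn in c("uses_gait_aid", "needs_adl_iadl_assist")) {
    if (cn %in% names(df)) df[[cn]] <- as.logical(df[[cn]])
  }
  df
}

#' @rdname read_cohort_csv
#' @param records Cohort data frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
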