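# Model comparison by repeated age-stratified cross-validation.
#
# A 70/30 split is drawn within every year-of-age stratum, candidate models
# are fitted on the training part, and the holdout coverage below the
# fitted 5th and 50th centiles and above the 95th is measured with analytic
# weights.  The procedure repeats under derived sub-seeds; the selection
# rule operationalizes "greater attention to the 5th percentile"
# lexicographically: closest mean below-P5 coverage to 0.05 wins, with ties
# (within 0.002) broken by P50 closeness, then P95, then fewer failed
# repetitions.

#' Age-stratified train/test split
#'
#' Within every year-of-age stratum (\code{floor(age)}),
#' \code{round(train_fraction * n)} records (round half up) go to the
#' training set.  Strata with a single record are flagged and sent whole to
#' training.
#'
#' @param data Data frame with an \code{age} column.
#' @param train_fraction Training share, default 0.70.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with \code{train}, \code{test} (disjoint, union = input) and
#'   \code{flagged_strata} (integer ages of degenerate strata).
#' @export
stratified_split <- function(data, train_fraction = 0.70, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_pn("train_fraction must lie strictly inside (0, 1)")
  }
  stratum <- floor(data$age)
  if (anyNA(stratum)) stop_pn("ages must be non-missing")
  idx_train <- logical(nrow(data))
  flagged <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(stratum))) {
      rows <- which(stratum == s)
      ns <- length(rows)
      if (ns < 2) {
        idx_train[rows] <- TRUE
        flagged <- c(flagged, s)
        next
      }
      k <- floor(train_fraction * ns + 0.5) # round half up
      k <- min(max(k, 1), ns - 1)
      idx_train[rows[sample.int(ns, k)]] <- TRUE
    }
  })
  list(
    train = data[idx_train, , drop = FALSE],
    test = data[!idx_train, , drop = FALSE],
    flagged_strata = flagged
  )
}

#' Holdout coverage at the designated centiles
#'
#' Weighted fraction of holdout subjects scoring below the model's fitted
#' 5th and 50th centiles at their own age, and above the fitted 95th.
#'
#' @param model Any object supporting \code{\link{predict_centile}}.
#' @param test Data frame with \code{age}, \code{score} and optionally
#'   \code{weight}.
#' @param weighted Weight subjects by their analytic weights?
#' @return Named numeric vector \code{c(below_P5, below_P50, above_P95)}.
#' @export
holdout_coverage <- function(model, test, weighted = TRUE) {
  w <- if (weighted && "weight" %in% names(test)) test$weight else rep(1, nrow(test))
  ok <- !is.na(test$score) & !is.na(test$age)
  age <- test$age[ok]
  y <- test$score[ok]
  w <- w[ok]
  tw <- sum(w)
  p5 <- predict_centile(model, age, 0.05)
  p50 <- predict_centile(model, age, 0.50)
  p95 <- predict_centile(model, age, 0.95)
  c(
    below_P5 = sum(w[y < p5]) / tw,
    below_P50 = sum(w[y < p50]) / tw,
    above_P95 = sum(w[y > p95]) / tw
  )
}

# Fit one model spec (either approach) on a training set.
.fit_spec <- function(spec, train) {
  if (identical(spec$approach, "gamlss")) {
    fit_distributional_model(
      train, spec$family,
      smoothers = if (is.null(spec$smoothers)) .default_smoothers() else spec$smoothers,
      controls = if (is.null(spec$controls)) fit_controls() else spec$controls
    )
  } else if (identical(spec$approach, "quantreg")) {
    fit_quantile_set(
      train,
      basis = spec$basis,
      taus = if (is.null(spec$taus)) c(0.05, 0.5, 0.95) else spec$taus,
      penalty = if (is.null(spec$penalty)) 1 else spec$penalty,
      weighted = !isFALSE(spec$weighted)
    )
  } else {
    stop_pn("model spec approach must be 'gamlss' or 'quantreg'")
  }
}

#' Describe a candidate model for cross-validation
#'
#' @param id Short label for reports.
#' @param approach \code{"gamlss"} (distributional) or \code{"quantreg"}.
#' @param family Family name (gamlss approach).
#' @param smoothers,controls Passed to
#'   \code{\link{fit_distributional_model}}.
#' @param basis,taus,penalty,weighted Passed to
#'   \code{\link{fit_quantile_set}}.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(id, approach = c("gamlss", "quantreg"), family = NULL,
                       smoothers = NULL, controls = NULL, basis = NULL,
                       taus = NULL, penalty = NULL, weighted = TRUE) {
  approach <- match.arg(approach)
  structure(
    list(
      id = id, approach = approach, family = family, smoothers = smoothers,
      controls = controls, basis = basis, taus = taus, penalty = penalty,
      weighted = weighted
    ),
    class = "model_spec"
  )
}

#' Repeated split/fit/evaluate cross-validation
#'
#' For each repetition: draw an age-stratified 70/30 split (sub-seed derived
#' from the master seed), fit every candidate spec on the training part, and
#' record holdout coverage.  A spec failing to fit in a repetition is
#' recorded as a failure for that repetition only.
#'
#' @param model_specs List of \code{\link{model_spec}}s.
#' @param data Data frame with \code{age}, \code{score}, optional
#'   \code{weight}.
#' @param reps Number of repetitions (the reference procedure uses 100).
#' @param seed Master seed; per-rep seeds are derived from it.
#' @param train_fraction Training share per stratum.
#' @param weighted Weighted holdout coverage?
#' @return A \code{coverage_report}: data frame \code{summary} (one row per
#'   spec: means and SDs of the three coverages, failure count) and
#'   \code{per_rep} (long format).
#' @export
cross_validate <- function(model_specs, data, reps = 100, seed = 1,
                           train_fraction = 0.70, weighted = TRUE) {
  if (length(model_specs) < 1) stop_pn("need at least one model spec")
  if (reps < 1) stop_pn("reps must be at least 1")
  if (inherits(model_specs[[1]], "model_spec") == FALSE &&
    !is.null(model_specs$id)) {
    model_specs <- list(model_specs)
  }
  per_rep <- list()
  for (r in seq_len(reps)) {
    sp <- stratified_split(data, train_fraction, seed = derive_seed(seed, r))
    for (ms in model_specs) {
      fit <- tryCatch(.fit_spec(ms, sp$train), error = function(e) NULL)
      failed <- is.null(fit) || !isTRUE(fit$converged)
      cov <- if (failed) {
        c(below_P5 = NA_real_, below_P50 = NA_real_, above_P95 = NA_real_)
      } else {
        holdout_coverage(fit, sp$test, weighted = weighted)
      }
      per_rep[[length(per_rep) + 1]] <- data.frame(
        model = ms$id, rep = r, failed = failed,
        below_P5 = cov[["below_P5"]], below_P50 = cov[["below_P50"]],
        above_P95 = cov[["above_P95"]]
      )
    }
  }
  per_rep <- do.call(rbind, per_rep)
  ids <- vapply(model_specs, `[[`, "", "id")
  summary <- do.call(rbind, lapply(ids, function(id) {
    d <- per_rep[per_rep$model == id & !per_rep$failed, , drop = FALSE]
    data.frame(
      model = id, reps = reps, failures = sum(per_rep$model == id & per_rep$failed),
      mean_below_P5 = mean(d$below_P5), sd_below_P5 = stats::sd(d$below_P5),
      mean_below_P50 = mean(d$below_P50), sd_below_P50 = stats::sd(d$below_P50),
      mean_above_P95 = mean(d$above_P95), sd_above_P95 = stats::sd(d$above_P95)
    )
  }))
  structure(
    list(summary = summary, per_rep = per_rep, seed = seed, reps = reps),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Cross-validation coverage report (", x$reps, " reps, seed ", x$seed,
    ")\n",
    sep = ""
  )
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select the best model from a coverage report
#'
#' Lexicographic rule prioritizing the 5th percentile: minimize
#' \code{|mean below_P5 - 0.05|}; candidates within \code{tie_tol} (default
#' 0.002) of the best are tie-broken by \code{|mean below_P50 - 0.50|}, then
#' \code{|mean above_P95 - 0.05|}, then fewer failed repetitions.
#'
#' @param report A \code{coverage_report} (or its \code{summary} data
#'   frame).
#' @param tie_tol Absolute P5-coverage difference treated as a tie.
#' @return The chosen model id (character), with the summary row as
#'   attribute \code{"summary"}.
#' @export
select_model <- function(report, tie_tol = 0.002) {
  s <- if (inherits(report, "coverage_report")) report$summary else report
  s <- s[is.finite(s$mean_below_P5), , drop = FALSE]
  if (nrow(s) == 0) stop_pn("no successful coverage reports to select from")
  d5 <- abs(s$mean_below_P5 - 0.05)
  cand <- which(d5 <= min(d5) + tie_tol)
  s2 <- s[cand, , drop = FALSE]
  ord <- order(
    abs(s2$mean_below_P50 - 0.50),
    abs(s2$mean_above_P95 - 0.05),
    s2$failures,
    seq_len(nrow(s2))
  )
  chosen <- s2[ord[1], , drop = FALSE]
  structure(chosen$model, summary = chosen)
}

#' Write a coverage report to CSV files
#'
#' @param report A \code{coverage_report}.
#' @param summary_path,per_rep_path Output CSVs; the master seed is recorded
#'   in a comment header line.
#' @return Invisibly, the two paths.
#' @export
write_coverage_report <- function(report, summary_path, per_rep_path) {
  for (pp in c(summary_path, per_rep_path)) {
    writeLines(sprintf("# master_seed=%d reps=%d", report$seed, report$reps), pp)
  }
  suppressWarnings({
    utils::write.table(report$summary, summary_path,
      sep = ",", row.names = FALSE,
      append = TRUE
    )
    utils::write.table(report$per_rep, per_rep_path,
      sep = ",", row.names = FALSE,
      append = TRUE
    )
  })
  invisible(c(summary_path, per_rep_path))
}
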