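# Deliverables: norm tables, percentile charts, score -> percentile lookup,
# and the end-to-end pipeline (score -> filter -> stratify -> fit both
# approaches -> GAIC rank -> cross-validate -> select -> tables/charts)
# with a reproducibility manifest.

.norm_percentiles <- c(5, 10, 20, 25, 50, 75, 80, 90, 95)

#' Build a norm table from a fitted model
#'
#' Evaluates the model's centiles on an integer age grid, floors scores at
#' 0, and enforces monotonicity across percentiles at every age by monotone
#' rearrangement.
#'
#' @param model Fitted model supporting \code{\link{predict_centile}} with a
#'   \code{converged} flag and \code{age_range}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param season \code{"all"} (default) or one of winter/spring/summer/fall.
#' @param ages Integer age grid (default 45:85).
#' @param percentiles Percentile levels (default 5, 10, 20, 25, 50, 75, 80,
#'   90, 95).
#' @param provenance Optional list recorded with the table (model id, seed,
#'   config hash).
#' @return A \code{norm_table}: ages x percentiles score matrix plus
#'   metadata.
#' @export
build_norm_table <- function(model, sex, season = "all", ages = 45:85,
                             percentiles = .norm_percentiles,
                             provenance = list()) {
  sex <- match.arg(sex, c("male", "female"))
  season <- match.arg(season, c("all", "winter", "spring", "summer", "fall"))
  if (!isTRUE(model$converged)) stop_pn("model did not converge")
  if (length(percentiles) < 1) stop_pn("need at least one percentile")
  if (!is.null(model$age_range) &&
    (min(ages) < model$age_range[1] - 1e-9 ||
      max(ages) > model$age_range[2] + 1e-9)) {
    stop_pn("model does not cover the requested age grid")
  }
  vals <- sapply(
    percentiles,
    function(q) pmax(0, predict_centile(model, ages, q / 100))
  )
  vals <- matrix(vals, nrow = length(ages))
  # monotone rearrangement across the percentile axis at each age
  vals <- t(rearrange_noncrossing(t(vals)))
  dimnames(vals) <- list(age = ages, percentile = percentiles)
  structure(
    list(
      sex = sex, season = season, ages = as.integer(ages),
      percentiles = percentiles, values = vals, provenance = provenance
    ),
    class = "norm_table"
  )
}

#' @export
print.norm_table <- function(x, digits = 0, ...) {
  cat(
    "PASE norm table: sex = ", x$sex, ", season = ", x$season, ", ages ",
    min(x$ages), "-", max(x$ages), "\n",
    sep = ""
  )
  show <- x$ages %in% seq(45, 85, by = 10)
  print(round(x$values[show, , drop = FALSE], digits))
  invisible(x)
}

#' Convert a norm table to/from long-format data
#'
#' Machine-readable form keeps full precision; the display convention rounds
#' scores to integers.
#'
#' @param table A \code{norm_table}.
#' @return Data frame with columns sex, season, age, percentile, score.
#' @export
norm_table_long <- function(table) {
  data.frame(
    sex = table$sex, season = table$season,
    age = rep(table$ages, times = length(table$percentiles)),
    percentile = rep(table$percentiles, each = length(table$ages)),
    score = as.vector(table$values)
  )
}

#' @rdname norm_table_long
#' @param path Output CSV path.
#' @export
write_norm_table <- function(table, path) {
  utils::write.csv(norm_table_long(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname norm_table_long
#' @export
read_norm_table <- function(path) {
  d <- utils::read.csv(path)
  ages <- sort(unique(d$age))
  pct <- sort(unique(d$percentile))
  vals <- matrix(NA_real_, length(ages), length(pct),
    dimnames = list(age = ages, percentile = pct)
  )
  vals[cbind(match(d$age, ages), match(d$percentile, pct))] <- d$score
  structure(
    list(
      sex = d$sex[1], season = d$season[1], ages = as.integer(ages),
      percentiles = pct, values = vals, provenance = list()
    ),
    class = "norm_table"
  )
}

#' Place a score on the normative percentile scale
#'
#' With a fitted distributional model the exact percentile is
#' \code{100 * F(score; theta(age))}.  With only a norm table the percentile
#' is bracketed between the neighbouring table rows (linear interpolation at
#' the nearest grid age); scores outside the tabulated range are reported as
#' \code{"<5"} or \code{">95"}.
#'
#' @param object A \code{centile_model} or \code{norm_table}.
#' @param age Age in the covered range.
#' @param score Non-negative PASE score.
#' @return List with \code{percentile} (numeric, NA when outside a table's
#'   range), \code{bracket} (table lookup only) and \code{statement}.
#' @export
lookup_percentile <- function(object, age, score) {
  if (score < 0) stop_pn("score must be non-negative")
  if (inherits(object, "centile_model")) {
    rng <- object$age_range
    if (age < rng[1] - 1e-9 || age > rng[2] + 1e-9) {
      stop_pn("age outside the fitted range")
    }
    pars <- predict_params(object, age)
    pct <- 100 * dist_cdf(object$family, score, pars)
    return(list(
      percentile = pct, bracket = NULL,
      statement = sprintf(
        "score %.5g at age %.5g is at the %.1f percentile", score, age, pct
      )
    ))
  }
  if (!inherits(object, "norm_table")) {
    stop_pn("object must be a centile_model or norm_table")
  }
  if (age < min(object$ages) || age > max(object$ages)) {
    stop_pn("age outside the table grid")
  }
  row <- object$values[which.min(abs(object$ages - age)), ]
  pct <- object$percentiles
  if (score < row[1]) {
    return(list(
      percentile = NA_real_, bracket = c(NA, pct[1]),
      statement = sprintf("<%g", pct[1])
    ))
  }
  if (score > row[length(row)]) {
    return(list(
      percentile = NA_real_, bracket = c(pct[length(pct)], NA),
      statement = sprintf(">%g", pct[length(pct)])
    ))
  }
  hi <- which(row >= score)[1]
  if (row[hi] == score || hi == 1) {
    p <- pct[hi]
    bracket <- c(pct[hi], pct[hi])
  } else {
    lo <- hi - 1
    frac <- (score - row[lo]) / (row[hi] - row[lo])
    p <- pct[lo] + frac * (pct[hi] - pct[lo])
    bracket <- c(pct[lo], pct[hi])
  }
  list(
    percentile = unname(p), bracket = unname(bracket),
    statement = sprintf(
      "score %.5g at age %.5g falls between the %g and %g percentiles (~%.1f)",
      score, age, bracket[1], bracket[2], p
    )
  )
}

#' Render a norm chart (SVG)
#'
#' Draws one line per percentile against age, labelled at the right margin.
#' Rendering is deterministic: the same table yields a byte-identical file.
#'
#' @param table A \code{norm_table}.
#' @param path Output SVG path.
#' @return \code{path}, invisibly.
#' @export
render_norm_chart <- function(table, path) {
  if (length(table$percentiles) < 1) stop_pn("nothing to draw: no percentiles")
  grDevices::svg(path, width = 8, height = 5.5)
  on.exit(grDevices::dev.off(), add = TRUE)
  vals <- table$values
  graphics::matplot(table$ages, vals,
    type = "l", lty = 1, lwd = 1.6,
    col = grDevices::hcl.colors(ncol(vals), "Zissou 1"),
    xlab = "Age (years)", ylab = "PASE total score",
    main = sprintf(
      "PASE percentiles, %s%s", table$sex,
      if (table$season == "all") "" else paste0(", ", table$season)
    ),
    xlim = c(min(table$ages), max(table$ages) + 3)
  )
  graphics::text(
    x = max(table$ages) + 1.5, y = vals[nrow(vals), ],
    labels = paste0("P", table$percentiles), cex = 0.7, adj = 0
  )
  invisible(path)
}

# -- end-to-end pipeline ------------------------------------------------------

#' Default pipeline configuration
#'
#' @param n Synthetic cohort size (ignored when \code{cohort_csv} given).
#' @param seed Master seed; every random stage derives its seed from it.
#' @param cohort_csv Optional path to a cohort CSV (columns as produced by
#'   \code{\link{generate_cohort}}); when \code{NULL} a synthetic cohort is
#'   generated.
#' @param families Named list of candidate family vectors per sex.
#' @param k GAIC penalty for family ranking.
#' @param cv_reps Cross-validation repetitions (the reference procedure uses
#'   100).
#' @param season_mode Also produce per-season tables?
#' @param quantreg_bases Quantile-regression candidates to cross-validate
#'   alongside the best distributional model; default the six reference
#'   candidates (linear, polynomial order 2-4, smoothed, fractional
#'   polynomial).
#' @return Configuration list for \code{\link{run_pipeline}}.
#' @export
pipeline_config <- function(n = 51338, seed = 1, cohort_csv = NULL,
                            families = list(
                              male = c("SHASH", "SEP2", "SEP1", "SHASHo", "SHASHo2"),
                              female = c("SEP4", "JSU", "JSUo", "ST1", "ST5")
                            ),
                            k = 2, cv_reps = 100, season_mode = FALSE,
                            quantreg_bases = c(
                              "linear", "poly2", "poly3", "poly4",
                              "smoothed", "fractional_polynomial"
                            )) {
  list(
    n = n, seed = seed, cohort_csv = cohort_csv, families = families,
    k = k, cv_reps = cv_reps, season_mode = season_mode,
    quantreg_bases = quantreg_bases
  )
}

.qr_spec_from_name <- function(nm) {
  switch(nm,
    linear = model_spec("qr_linear", "quantreg", basis = smoother_spec("linear")),
    poly2 = model_spec("qr_poly2", "quantreg", basis = smoother_spec("polynomial", df = 2)),
    poly3 = model_spec("qr_poly3", "quantreg", basis = smoother_spec("polynomial", df = 3)),
    poly4 = model_spec("qr_poly4", "quantreg", basis = smoother_spec("polynomial", df = 4)),
    smoothed = model_spec("qr_smoothed", "quantreg", basis = "smoothed", penalty = 25),
    fractional_polynomial = model_spec("qr_fp", "quantreg",
      basis = smoother_spec("fractional_polynomial", powers = c(1, 0))
    ),
    stop_pn("unknown quantile-regression basis '", nm, "'")
  )
}

#' Run the whole normative-value pipeline
#'
#' Stages: obtain cohort (read or simulate) -> score items if needed ->
#' eligibility filter -> sex stratification -> rank distribution families by
#' GAIC -> cross-validate the best distributional model against the
#' quantile-regression candidates -> select by 5th-percentile coverage ->
#' fit the selected model on the full stratum -> norm tables, charts,
#' serialized models, coverage reports and a JSON manifest (with config
#' hash, seeds and artifact checksums).  Any stage failure halts with the
#' stage name; partial outputs are kept under a \code{failed/} prefix.
#'
#' @param config See \code{\link{pipeline_config}}; a path to a YAML file is
#'   also accepted.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "pase_norms_out") {
  if (is.character(config)) config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pasenorms")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[order(names(config))]
  )
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(manifest$config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  stage <- "setup"
  artifacts <- character(0)
  fail <- function(e) {
    failed_dir <- file.path(out_dir, "failed")
    dir.create(failed_dir, showWarnings = FALSE)
    for (a in artifacts) {
      file.copy(a, file.path(failed_dir, basename(a)), overwrite = TRUE)
    }
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(failed_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    stop_pn("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  }
  tryCatch(
    {
      stage <- "cohort"
      if (!is.null(config$cohort_csv)) {
        cohort <- read_cohort_csv(config$cohort_csv)
        manifest$cohort_source <- config$cohort_csv
      } else {
        gspec <- generator_spec(n = config$n, seed = derive_seed(config$seed, 1))
        cohort <- generate_cohort(gspec)
        manifest$cohort_source <- "synthetic"
      }
      if (!"pase_total" %in% names(cohort)) {
        stage <- "score"
        cohort$pase_total <- score_items_table(cohort)$pase_total
      }
      stage <- "filter"
      parts <- apply_exclusions(cohort)
      included <- parts$included
      included$season <- assign_season(included$interview_date)
      manifest$counts <- list(
        total = nrow(cohort), included = nrow(included),
        excluded = nrow(parts$excluded),
        missing_dropped = nrow(parts$missing_dropped)
      )

      manifest$strata <- list()
      for (sx in c("male", "female")) {
        sdat <- included[included$sex == sx, , drop = FALSE]
        dd <- data.frame(
          age = sdat$age, score = sdat$pase_total,
          weight = sdat$analytic_weight, season = sdat$season
        )
        stage <- paste0("rank_families_", sx)
        rk <- rank_families(dd, config$families[[sx]], k = config$k)
        best_family <- rk$table$family[1]

        stage <- paste0("cross_validate_", sx)
        specs <- c(
          list(model_spec(paste0("gamlss_", best_family), "gamlss",
            family = best_family
          )),
          lapply(config$quantreg_bases, .qr_spec_from_name)
        )
        cvrep <- cross_validate(specs, dd,
          reps = config$cv_reps,
          seed = derive_seed(config$seed, 2)
        )
        chosen <- select_model(cvrep)
        cv_paths <- file.path(out_dir, paste0(
          "cv_", sx, c("_summary.csv", "_per_rep.csv")
        ))
        write_coverage_report(cvrep, cv_paths[1], cv_paths[2])
        artifacts <- c(artifacts, cv_paths)

        stage <- paste0("final_fit_", sx)
        chosen_spec <- specs[[match(as.character(chosen), vapply(specs, `[[`, "", "id"))]]
        if (chosen_spec$approach == "quantreg") {
          # the final model must carry every reporting percentile
          chosen_spec$taus <- .norm_percentiles / 100
        }
        final <- .fit_spec(chosen_spec, dd)
        model_path <- file.path(out_dir, paste0("model_", sx, ".json"))
        serialize_model(final, model_path)
        artifacts <- c(artifacts, model_path)

        stage <- paste0("norms_", sx)
        prov <- list(
          model = as.character(chosen), seed = config$seed,
          config_hash = manifest$config_hash
        )
        tbl <- build_norm_table(final, sx, provenance = prov)
        tp <- file.path(out_dir, paste0("norms_", sx, ".csv"))
        cp <- file.path(out_dir, paste0("chart_", sx, ".svg"))
        write_norm_table(tbl, tp)
        render_norm_chart(tbl, cp)
        artifacts <- c(artifacts, tp, cp)

        season_tables <- list()
        if (isTRUE(config$season_mode)) {
          stage <- paste0("norms_season_", sx)
          for (sn in c("winter", "spring", "summer", "fall")) {
            dds <- dd[dd$season == sn, , drop = FALSE]
            fs <- .fit_spec(chosen_spec, dds)
            ts <- build_norm_table(fs, sx, season = sn, provenance = prov)
            tps <- file.path(out_dir, paste0("norms_", sx, "_", sn, ".csv"))
            write_norm_table(ts, tps)
            artifacts <- c(artifacts, tps)
            season_tables[[sn]] <- tps
          }
        }
        manifest$strata[[sx]] <- list(
          n = nrow(dd),
          gaic_ranking = rk$table,
          cv_summary = cvrep$summary,
          selected_model = as.character(chosen),
          season_tables = season_tables
        )
      }
      stage <- "manifest"
      manifest$artifacts <- lapply(
        stats::setNames(artifacts, basename(artifacts)),
        function(a) unname(tools::md5sum(a))
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    },
    error = fail
  )
  invisible(manifest)
}
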