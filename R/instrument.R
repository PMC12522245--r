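# PASE instrument scoring.
#
# The PASE (Physical Activity Scale for the Elderly) is a 7-day-recall
# questionnaire.  Leisure activities record a frequency category
# (0 never, 1 seldom = 1-2 d/wk, 2 sometimes = 3-4 d/wk, 3 often = 5-7 d/wk)
# and, when frequency > 0, a duration category (1 = <1 h, 2 = 1-2 h,
# 3 = 2-4 h, 4 = >4 h).  Household activities are yes/no.  Paid/volunteer
# work records hours per week and whether it involves standing or walking.
# The total score is a weighted sum: for leisure items the activity weight
# times average hours/day, for household items the weight itself, and for
# work the weight times hours/day — but only when the work involves standing
# or walking.  Sitting/sedentary items never contribute to the total.
#
# The questionnaire's published activity weights and the category midpoints
# are configuration, not code: they ship as documented defaults (from the
# PASE administration manual) in a versioned YAML file so the scoring engine
# is testable under any weight set.

.pase_leisure <- c(
  "walking", "light_sport", "moderate_sport", "strenuous_sport",
  "muscle_strength"
)
.pase_household <- c(
  "light_housework", "heavy_housework", "home_repair", "lawn_work",
  "gardening", "caring_for_others"
)

#' Default PASE scoring configuration
#'
#' Activity weights follow the PASE administration manual: walking 20,
#' light/moderate/strenuous sport 21/23/23, muscle-strength exercise 30,
#' light housework 25, heavy housework 25, home repair 30, lawn work 36,
#' gardening 20, caring for another person 35, and work involving standing
#' or walking 21 (applied to hours/day).  Frequency-category midpoints are
#' 0/1.5/3.5/6 days per week and duration midpoints 0.5/1.5/3/5 hours per
#' day.
#'
#' @return A \code{scoring_config} object (a validated list with elements
#'   \code{weights}, \code{freq_midpoints}, \code{dur_midpoints}).
#' @export
default_scoring_config <- function() {
  scoring_config(
    weights = c(
      walking = 20, light_sport = 21, moderate_sport = 23,
      strenuous_sport = 23, muscle_strength = 30,
      light_housework = 25, heavy_housework = 25, home_repair = 30,
      lawn_work = 36, gardening = 20, caring_for_others = 35,
      work = 21
    ),
    freq_midpoints = c("0" = 0, "1" = 1.5, "2" = 3.5, "3" = 6),
    dur_midpoints = c("1" = 0.5, "2" = 1.5, "3" = 3, "4" = 5)
  )
}

#' Construct and validate a PASE scoring configuration
#'
#' @param weights Named numeric vector, activity id to positive weight;
#'   must include a \code{work} entry for the occupational item.
#' @param freq_midpoints Named numeric vector mapping frequency categories
#'   \code{"0".."3"} to days/week; category 0 must map to 0 and the others
#'   must be strictly positive and non-decreasing.
#' @param dur_midpoints Named numeric vector mapping duration categories
#'   \code{"1".."4"} to hours/day; strictly positive.
#' @return A \code{scoring_config} object.
#' @export
scoring_config <- function(weights, freq_midpoints, dur_midpoints) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop_pn("weights must be a named vector of activity weights")
  }
  if (any(weights <= 0)) {
    stop_pn(
      "activity weights must be positive; offending: ",
      paste(names(weights)[weights <= 0], collapse = ", ")
    )
  }
  if (!identical(sort(names(freq_midpoints)), c("0", "1", "2", "3"))) {
    stop_pn("freq_midpoints must be named '0'..'3'")
  }
  if (!identical(sort(names(dur_midpoints)), c("1", "2", "3", "4"))) {
    stop_pn("dur_midpoints must be named '1'..'4'")
  }
  if (freq_midpoints[["0"]] != 0 || any(freq_midpoints[c("1", "2", "3")] <= 0)) {
    stop_pn("freq_midpoints: category 0 must be 0, others strictly positive")
  }
  if (any(dur_midpoints <= 0)) {
    stop_pn("dur_midpoints must be strictly positive")
  }
  structure(
    list(
      weights = weights,
      freq_midpoints = freq_midpoints[c("0", "1", "2", "3")],
      dur_midpoints = dur_midpoints[c("1", "2", "3", "4")]
    ),
    class = "scoring_config"
  )
}

#' Read / write a scoring configuration (YAML)
#'
#' @param path File path.
#' @return \code{read_scoring_config} returns a \code{scoring_config};
#'   \code{write_scoring_config} returns \code{path} invisibly.
#' @export
read_scoring_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scoring_config(
    weights = unlist(raw$weights),
    freq_midpoints = unlist(raw$freq_midpoints),
    dur_midpoints = unlist(raw$dur_midpoints)
  )
}

#' @rdname read_scoring_config
#' @param config A \code{scoring_config}.
#' @export
write_scoring_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), as.list), path)
  invisible(path)
}

#' Average daily hours for a leisure item
#'
#' Converts a (frequency, duration) category pair to hours/day:
#' \code{(freq_midpoint_days / 7) * dur_midpoint_hours}; zero when the
#' frequency category is 0 ("never").
#'
#' @param frequency Integer frequency category in 0..3.
#' @param duration Integer duration category in 1..4 (ignored, and may be
#'   \code{NA}, when \code{frequency} is 0).
#' @param config A \code{scoring_config}.
#' @return Hours per day (numeric scalar or vector).
#' @export
avg_daily_hours <- function(frequency, duration, config = default_scoring_config()) {
  if (any(!frequency %in% 0:3, na.rm = TRUE) || anyNA(frequency)) {
    bad <- unique(frequency[!(frequency %in% 0:3)])
    stop_pn("unknown frequency category: ", paste(bad, collapse = ", "))
  }
  out <- numeric(length(frequency))
  act <- frequency > 0
  if (any(act)) {
    d <- duration[act]
    if (anyNA(d) || any(!d %in% 1:4)) {
      bad <- unique(d[is.na(d) | !(d %in% 1:4)])
      stop_pn("unknown duration category: ", paste(bad, collapse = ", "))
    }
    out[act] <- config$freq_midpoints[as.character(frequency[act])] / 7 *
      config$dur_midpoints[as.character(d)]
  }
  out
}

#' Construct a single participant's PASE item responses
#'
#' @param leisure Data frame with columns \code{activity} (character id),
#'   \code{freq} (0..3 or NA = missing response), \code{dur} (1..4, required
#'   iff \code{freq > 0}).
#' @param household Data frame with columns \code{activity} and \code{yes}
#'   (logical, NA = missing response).
#' @param work_hours Hours/week of paid or volunteer work, in [0, 168].
#' @param work_standing Logical: does the work involve standing or walking?
#'   (Sitting-level work does not contribute to the total.)
#' @return A \code{pase_items} object.
#' @export
pase_items <- function(leisure = NULL, household = NULL,
                       work_hours = 0, work_standing = FALSE) {
  if (is.null(leisure)) {
    leisure <- data.frame(
      activity = character(), freq = integer(), dur = integer()
    )
  }
  if (is.null(household)) {
    household <- data.frame(activity = character(), yes = logical())
  }
  ok <- is.na(leisure$freq) | leisure$freq %in% 0:3
  if (!all(ok)) {
    stop_pn(
      "invalid frequency category for: ",
      paste(leisure$activity[!ok], collapse = ", ")
    )
  }
  need_dur <- !is.na(leisure$freq) & leisure$freq > 0
  bad_dur <- need_dur & !is.na(leisure$dur) & !leisure$dur %in% 1:4
  if (any(bad_dur)) {
    stop_pn(
      "invalid duration category for: ",
      paste(leisure$activity[bad_dur], collapse = ", ")
    )
  }
  stray_dur <- !need_dur & !is.na(leisure$dur)
  if (any(stray_dur)) {
    stop_pn("duration present without activity frequency for: ",
      paste(leisure$activity[stray_dur], collapse = ", "))
  }
  if (!is.na(work_hours) && (work_hours < 0 || work_hours > 168)) {
    stop_pn("work_hours must lie in [0, 168]")
  }
  structure(
    list(
      leisure = leisure, household = household,
      work_hours = work_hours, work_standing = work_standing
    ),
    class = "pase_items"
  )
}

#' Compute a PASE total score
#'
#' \code{total = sum(leisure weight x avg daily hours) +
#' sum(household weight x yes) + work weight x (hours/week / 7) x
#' (work involves standing or walking)}.
#'
#' @param items A \code{pase_items} object.
#' @param config A \code{scoring_config} covering every activity in
#'   \code{items}.
#' @param missing Policy for missing item responses: \code{"undefined"}
#'   (default — any missing response makes the whole score undefined,
#'   returned as \code{NA}) or \code{"partial"} (score the observed items
#'   only, without imputation).
#' @return Non-negative numeric score, or \code{NA} under the default
#'   missing policy when any response is missing.
#' @export
score_pase <- function(items, config = default_scoring_config(),
                       missing = c("undefined", "partial")) {
  missing <- match.arg(missing)
  if (!inherits(items, "pase_items")) stop_pn("items must be a pase_items object")
  acts <- c(items$leisure$activity, items$household$activity)
  known <- c(acts %in% names(config$weights))
  if (!all(known)) {
    stop_pn(
      "no scoring weight for activity: ",
      paste(unique(acts[!known]), collapse = ", ")
    )
  }
  miss <- c(
    is.na(items$leisure$freq),
    !is.na(items$leisure$freq) & items$leisure$freq > 0 & is.na(items$leisure$dur),
    is.na(items$household$yes),
    is.na(items$work_hours),
    items$work_hours > 0 && is.na(items$work_standing)
  )
  if (any(miss) && missing == "undefined") {
    return(NA_real_)
  }

  total <- 0
  li <- items$leisure[!is.na(items$leisure$freq), , drop = FALSE]
  li <- li[li$freq == 0 | !is.na(li$dur), , drop = FALSE]
  if (nrow(li)) {
    hrs <- avg_daily_hours(li$freq, li$dur, config)
    total <- total + sum(config$weights[li$activity] * hrs)
  }
  hh <- items$household[!is.na(items$household$yes), , drop = FALSE]
  if (nrow(hh)) {
    total <- total + sum(config$weights[hh$activity] * as.numeric(hh$yes))
  }
  if (!is.na(items$work_hours) && items$work_hours > 0 &&
    isTRUE(items$work_standing)) {
    total <- total + config$weights[["work"]] * items$work_hours / 7
  }
  unname(total)
}

#' Score an item-response table (one row per subject)
#'
#' Expects columns \code{<activity>_freq} / \code{<activity>_dur} for the
#' five leisure activities (walking, light_sport, moderate_sport,
#' strenuous_sport, muscle_strength), logical or 0/1 columns named after
#' the six household activities (light_housework, heavy_housework,
#' home_repair, lawn_work, gardening, caring_for_others), and
#' \code{work_hours} / \code{work_standing}.  Sedentary columns
#' (\code{sitting_freq}, \code{sitting_dur}, \code{work_sitting}) are
#' accepted and ignored.
#'
#' @param data Data frame of item responses; an \code{id} column is carried
#'   through if present.
#' @inheritParams score_pase
#' @return Data frame with column \code{pase_total} (and \code{id} if
#'   supplied).
#' @export
score_items_table <- function(data, config = default_scoring_config(),
                              missing = c("undefined", "partial")) {
  missing <- match.arg(missing)
  scores <- vapply(seq_len(nrow(data)), function(i) {
    row <- data[i, , drop = FALSE]
    leis <- data.frame(
      activity = .pase_leisure,
      freq = vapply(
        paste0(.pase_leisure, "_freq"),
        function(cn) if (cn %in% names(row)) as.integer(row[[cn]]) else NA_integer_,
        integer(1)
      ),
      dur = vapply(
        paste0(.pase_leisure, "_dur"),
        function(cn) if (cn %in% names(row)) as.integer(row[[cn]]) else NA_integer_,
        integer(1)
      )
    )
    # a duration is only meaningful when the activity was performed
    leis$dur[is.na(leis$freq) | leis$freq == 0] <- NA_integer_
    hh <- data.frame(
      activity = .pase_household,
      yes = vapply(
        .pase_household,
        function(cn) if (cn %in% names(row)) as.logical(row[[cn]]) else NA,
        logical(1)
      )
    )
    it <- pase_items(
      leisure = leis, household = hh,
      work_hours = if ("work_hours" %in% names(row)) row[["work_hours"]] else 0,
      work_standing = if ("work_standing" %in% names(row)) {
        as.logical(row[["work_standing"]])
      } else {
        FALSE
      }
    )
    score_pase(it, config, missing)
  }, numeric(1))
  out <- data.frame(pase_total = scores)
  if ("id" %in% names(data)) out <- cbind(id = data$id, out)
  out
}
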