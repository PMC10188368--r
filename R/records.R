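#' Interval layout used throughout the package
#'
#' The analysis window runs from 7 months' gestation to the end of day 9 of
#' life, split into 10 intervals: the stillbirth interval (`STB`), the pooled
#' first two days of life (`D0-1`, pooled because day-0 versus day-1 recording
#' is inconsistent across surveys), and single days 2 through 9. Intervals are
#' half-open on age: day *k* covers \[k, k+1) days; censoring at day 10 means
#' survival through the end of day 9.
#'
#' @return Character vector of the 10 interval labels, in analysis order.
#' @export
interval_labels <- function() {
  c("STB", "D0-1", paste0("D", 2:9))
}

MANDATORY_COLUMNS <- c(
  "survey_id", "record_id", "gestation_months", "conception_offset_months",
  "outcome"
)
OPTIONAL_COLUMNS <- c(
  "child_alive", "age_at_death_days", "current_age_months", "weight"
)
OUTCOME_LEVELS <- c("stillbirth", "livebirth", "ongoing")

#' Eligibility and censoring rules for pregnancy records
#'
#' Encodes which pregnancies enter the analysis: terminations before
#' `min_gestation_months` are excluded (the survey proxy for the 28-week
#' stillbirth definition), conceptions must fall inside a window of months
#' before the interview, livebirths in the interview month are assumed to have
#' survived the first week, and follow-up is censored at `censor_day`.
#'
#' @param min_gestation_months Minimum gestation, in months, for a pregnancy to
#'   count (default 7).
#' @param conception_window_months Closed interval of months before the
#'   interview within which conception must fall (default `c(7, 66)`).
#' @param interview_month_rule If `TRUE` (default), livebirths occurring in the
#'   month of the interview are treated as more than one week old, i.e. as
#'   surviving past day 9.
#' @param censor_day Day of life at which follow-up is censored (default 10;
#'   days 7-9 are retained only so the heaping index can be computed).
#' @return An object of class `eligibility_rules`.
#' @export
eligibility_rules <- function(min_gestation_months = 7,
                              conception_window_months = c(7, 66),
                              interview_month_rule = TRUE,
                              censor_day = 10) {
  stopifnot(
    length(min_gestation_months) == 1, min_gestation_months >= 0,
    length(conception_window_months) == 2,
    conception_window_months[1] <= conception_window_months[2],
    is.logical(interview_month_rule), length(censor_day) == 1, censor_day >= 1
  )
  if (conception_window_months[1] < min_gestation_months) {
    stop("conception window lower bound must be >= min_gestation_months")
  }
  structure(
    list(
      min_gestation_months = as.integer(min_gestation_months),
      conception_window_months = as.numeric(conception_window_months),
      interview_month_rule = isTRUE(interview_month_rule),
      censor_day = as.integer(censor_day)
    ),
    class = "eligibility_rules"
  )
}

coerce_logical_column <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out[is.na(x) | v == ""] <- NA
  bad <- !is.na(x) & v != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

#' Read a per-pregnancy table from delimited text
#'
#' Reads the documented delimited-text layout: one row per pregnancy of at
#' least seven months' gestation, UTF-8, mandatory header. Comma is the default
#' delimiter; tab is accepted (auto-detected from the header when `sep` is
#' `NULL`). Mandatory columns are `survey_id`, `record_id`, `gestation_months`,
#' `conception_offset_months`, and `outcome` (one of `stillbirth`, `livebirth`,
#' `ongoing`). `child_alive` is required for livebirths; `age_at_death_days`
#' must be present exactly for dead livebirths; `current_age_months` describes
#' surviving children and ongoing pregnancies; `weight` is a positive sampling
#' weight defaulting to 1. Any further columns are carried through unmodified
#' as covariates.
#'
#' @param file Path to a delimited text file, or a connection.
#' @param sep Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A data frame of class `pregnancy_records`, one row per input row,
#'   input order preserved.
#' @export
read_pregnancy_table <- function(file, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(
    file,
    header = TRUE, sep = sep, quote = "\"", stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = c("NA", ""), encoding = "UTF-8",
    colClasses = NA
  )
  as_pregnancy_records(df)
}

#' Validate and classify a data frame as pregnancy records
#'
#' Applies the type coercions and record-level invariants of the documented
#' layout (see [read_pregnancy_table()]). Rows violating an invariant are
#' reported together, by row number and `record_id`, in a single error.
#'
#' @param df A data frame with the documented columns.
#' @return `df` with canonical column types and class `pregnancy_records`.
#' @export
as_pregnancy_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  for (col in setdiff(OPTIONAL_COLUMNS, names(df))) {
    df[[col]] <- switch(col,
      child_alive = rep(NA, n),
      weight = rep(1, n),
      rep(NA_real_, n)
    )
  }

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) == 0) return(invisible())
    ids <- df$record_id[rows]
    msg <- sprintf("row %d (record_id=%s): %s", rows, ids, what)
    problems <<- c(problems, msg)
  }

  for (col in c("gestation_months", "conception_offset_months",
                "age_at_death_days", "current_age_months", "weight")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(as.character(v)))
      note(which(!is.na(v) & is.na(coerced)), paste0("non-numeric ", col))
      df[[col]] <- coerced
    }
  }
  ca <- coerce_logical_column(df$child_alive)
  note(attr(ca, "bad"), "unparseable child_alive")
  attr(ca, "bad") <- NULL
  df$child_alive <- ca
  df$outcome <- tolower(trimws(as.character(df$outcome)))
  df$survey_id <- as.character(df$survey_id)
  df$record_id <- as.character(df$record_id)

  note(which(!df$outcome %in% OUTCOME_LEVELS),
       "outcome not one of stillbirth/livebirth/ongoing")
  note(which(is.na(df$gestation_months) | df$gestation_months < 0),
       "gestation_months missing or negative")
  note(which(is.na(df$conception_offset_months)),
       "conception_offset_months missing")
  note(which(!is.na(df$age_at_death_days) & df$age_at_death_days < 0),
       "negative age_at_death_days")
  note(which(is.na(df$weight) | df$weight <= 0),
       "sampling weight missing or non-positive")
  is_lb <- df$outcome == "livebirth"
  note(which(is_lb & is.na(df$child_alive)),
       "child_alive missing for a livebirth")
  dead <- is_lb & !is.na(df$child_alive) & !df$child_alive
  note(which(!is.na(df$age_at_death_days) & !dead),
       "age_at_death_days present but the record is not a dead livebirth")
  note(which(dead & is.na(df$age_at_death_days)),
       "age_at_death_days missing for a dead livebirth")

  if (length(problems) > 0) {
    shown <- utils::head(problems, 20)
    more <- length(problems) - length(shown)
    stop(
      "invalid pregnancy record(s):\n  ",
      paste(shown, collapse = "\n  "),
      if (more > 0) sprintf("\n  ... and %d more", more)
    )
  }
  class(df) <- c("pregnancy_records", "data.frame")
  df
}

#' Apply eligibility rules to pregnancy records
#'
#' Drops pregnancies terminated before the minimum gestation and pregnancies
#' conceived outside the conception window, tallying exclusions by reason.
#' Ongoing pregnancies of sufficient gestation are retained (they are later
#' censored in the stillbirth interval). The operation is idempotent: applying
#' it to an already-filtered set excludes nothing.
#'
#' @param records A `pregnancy_records` data frame.
#' @param rules An [eligibility_rules()] object.
#' @return A list with elements `records` (the retained rows, order preserved)
#'   and `exclusions` (named integer tally by reason, summing to the number of
#'   dropped rows).
#' @export
apply_eligibility <- function(records, rules = eligibility_rules()) {
  stopifnot(inherits(records, "pregnancy_records"),
            inherits(rules, "eligibility_rules"))
  short <- records$gestation_months < rules$min_gestation_months
  off <- records$conception_offset_months
  outside <- !short &
    (off < rules$conception_window_months[1] |
       off > rules$conception_window_months[2])
  keep <- !short & !outside
  exclusions <- c(
    "gestation<7" = sum(short),
    "outside window" = sum(outside)
  )
  names(exclusions)[1] <- sprintf("gestation<%d", rules$min_gestation_months)
  out <- records[keep, , drop = FALSE]
  class(out) <- c("pregnancy_records", "data.frame")
  list(records = out, exclusions = exclusions)
}

#' Construct an interval count table directly
#'
#' Builds the deaths / entrants / censored accounting over the 10 analysis
#' intervals from a death vector, a total cohort size, and optional censoring.
#' Entrants follow the flow-conservation recursion
#' `n[j+1] = n[j] - d[j] - c[j]`, and all survivors of day 9 are censored at
#' day 10 (interval 10 closes the table).
#'
#' @param deaths Numeric vector of 10 (possibly weighted) death counts in
#'   interval order (`STB`, `D0-1`, days 2..9).
#' @param total Total (possibly weighted) number of pregnancies entering the
#'   stillbirth interval.
#' @param censored Optional numeric vector of 10 censored counts. Censoring in
#'   interval 10 is recomputed from the flow so the table always closes; if
#'   omitted, all interim censoring is zero.
#' @param survey_id Optional survey identifier carried in the table.
#' @return An object of class `interval_counts`: a data frame with columns
#'   `interval`, `label`, `deaths`, `entrants`, `censored`, plus attributes
#'   `total_pregnancies` and `effective_weight_d01`.
#' @export
interval_counts <- function(deaths, total, censored = NULL,
                            survey_id = NA_character_) {
  stopifnot(length(deaths) == 10, all(deaths >= 0), length(total) == 1)
  if (is.null(censored)) censored <- numeric(10)
  stopifnot(length(censored) == 10, all(censored[1:9] >= 0))
  n <- numeric(10)
  n[1] <- total
  for (j in 1:9) n[j + 1] <- n[j] - deaths[j] - censored[j]
  censored[10] <- n[10] - deaths[10]
  out <- structure(
    data.frame(
      interval = 1:10,
      label = interval_labels(),
      deaths = as.numeric(deaths),
      entrants = n,
      censored = as.numeric(censored),
      stringsAsFactors = FALSE
    ),
    total_pregnancies = as.numeric(total),
    effective_weight_d01 = 1,
    survey_id = survey_id,
    class = c("interval_counts", "data.frame")
  )
  validate_interval_counts(out)
  out
}

validate_interval_counts <- function(x, tol = 1e-8) {
  stopifnot(inherits(x, "interval_counts"), nrow(x) == 10)
  d <- x$deaths; n <- x$entrants; cc <- x$censored
  if (any(d < -tol) || any(cc < -tol) || any(n < -tol)) {
    stop("interval counts must be nonnegative")
  }
  if (any(d > n + tol)) stop("deaths exceed entrants in some interval")
  if (abs(n[1] - attr(x, "total_pregnancies")) > tol) {
    stop("entrants in interval 1 must equal total_pregnancies")
  }
  flow <- n[1:9] - d[1:9] - cc[1:9] - n[2:10]
  if (any(abs(flow) > tol * pmax(1, n[1]))) {
    stop("flow conservation violated: n[j+1] != n[j] - d[j] - c[j]")
  }
  if (abs(n[10] - d[10] - cc[10]) > tol * pmax(1, n[1])) {
    stop("interval 10 does not close: censoring must absorb survivors")
  }
  invisible(x)
}

#' Restructure pregnancy records into interval-censored counts
#'
#' Tabulates eligibility-filtered records onto the 10 analysis intervals:
#' stillbirths die in interval 1; ongoing pregnancies are censored in interval
#' 1; deaths on days 0-1 fall in interval 2 and deaths on day k (k = 2..9) in
#' interval k+1; surviving children, livebirths in the interview month (when
#' the rule is active), and deaths at 10 or more days are censored at day 10.
#' With `use_weights = TRUE` all counts are sampling-weight sums (frequency
#' weights); with all weights equal to 1 the two modes coincide.
#'
#' @param records A `pregnancy_records` data frame, already passed through
#'   [apply_eligibility()].
#' @param use_weights Logical; sum sampling weights instead of counting rows.
#' @param rules An [eligibility_rules()] object (governs the interview-month
#'   rule and the censoring day).
#' @return An [interval_counts()] object.
#' @export
build_interval_counts <- function(records, use_weights = TRUE,
                                  rules = eligibility_rules()) {
  stopifnot(inherits(records, "pregnancy_records"))
  w <- if (use_weights) records$weight else rep(1, nrow(records))
  d <- numeric(10)
  cens <- numeric(10)
  survivors <- 0

  ongoing <- records$outcome == "ongoing"
  sb <- records$outcome == "stillbirth"
  lb <- records$outcome == "livebirth"
  alive <- lb & !is.na(records$child_alive) & records$child_alive
  dead <- lb & !is.na(records$child_alive) & !records$child_alive

  if (any(dead & is.na(records$age_at_death_days))) {
    bad <- records$record_id[dead & is.na(records$age_at_death_days)]
    stop("age_at_death_days missing for dead child(ren): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }

  d[1] <- sum(w[sb])
  cens[1] <- sum(w[ongoing])
  survivors <- survivors + sum(w[alive])

  age <- records$age_at_death_days
  # day k of life maps to interval k+1; days 0 and 1 are pooled in interval 2
  death_interval <- ifelse(age <= 1, 2, age + 1)
  for (j in 2:10) {
    d[j] <- sum(w[dead & death_interval == j])
  }
  survivors <- survivors + sum(w[dead & age >= rules$censor_day])

  total <- sum(w)
  out <- interval_counts(
    deaths = d, total = total, censored = cens,
    survey_id = if (length(unique(records$survey_id)) == 1) {
      records$survey_id[1]
    } else {
      NA_character_
    }
  )
  # closure check: survivors must equal the censoring absorbed at day 10
  stopifnot(abs(out$censored[10] - survivors) < 1e-6 * max(1, total))
  out
}

#' @export
print.interval_counts <- function(x, ...) {
  cat("Interval-censored pregnancy cohort")
  sid <- attr(x, "survey_id")
  if (!is.na(sid)) cat(" [", sid, "]", sep = "")
  cat(": ", format(attr(x, "total_pregnancies")), " pregnancies\n", sep = "")
  w <- attr(x, "effective_weight_d01")
  if (!is.null(w) && w != 1) {
    cat("  D0-1 deaths carry effective weight", format(w, digits = 4), "\n")
  }
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Write an interval count table to CSV or JSON
#'
#' @param x An `interval_counts` object.
#' @param file Output path.
#' @param format `"csv"` (one row per interval) or `"json"`.
#' @return `file`, invisibly.
#' @export
write_interval_counts <- function(x, file, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_interval_counts(x)
  if (format == "csv") {
    utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  } else {
    payload <- list(
      survey_id = attr(x, "survey_id"),
      total_pregnancies = attr(x, "total_pregnancies"),
      effective_weight_d01 = attr(x, "effective_weight_d01"),
      intervals = as.data.frame(x)
    )
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(file)
}

#' Read an interval count table written by [write_interval_counts()]
#'
#' @param file Path to a CSV or JSON interval table.
#' @return An `interval_counts` object.
#' @export
read_interval_counts <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(file, simplifyVector = TRUE)
    df <- payload$intervals
    out <- interval_counts(
      deaths = df$deaths, total = payload$total_pregnancies,
      censored = df$censored,
      survey_id = if (is.null(payload$survey_id)) NA_character_
                  else payload$survey_id
    )
    attr(out, "effective_weight_d01") <- payload$effective_weight_d01
    out
  } else {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    interval_counts(deaths = df$deaths, total = df$entrants[1],
                    censored = df$censored)
  }
}
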