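#' Day-7 age-heaping index
#'
#' Five times the number of deaths reported on day 7 divided by the sum of all
#' deaths on days 5-9. A value of 1 means day 7 carries exactly its uniform
#' share; values well above 1 indicate heaping of reported ages at death onto
#' day 7.
#'
#' @param deaths Numeric vector of 5 nonnegative death counts for days 5, 6,
#'   7, 8, 9 (in that order).
#' @return The heaping index, or `NA_real_` (undefined) when no deaths were
#'   reported on days 5-9.
#' @examples
#' heaping_index(c(2, 2, 2, 2, 2)) # 1: uniform
#' heaping_index(c(0, 0, 5, 0, 0)) # 5: fully heaped
#' @export
heaping_index <- function(deaths) {
  stopifnot(is.numeric(deaths), length(deaths) == 5)
  if (any(is.na(deaths)) || any(deaths < 0)) {
    stop("deaths on days 5-9 must be nonnegative")
  }
  s <- sum(deaths)
  if (s == 0) return(NA_real_)
  5 * deaths[3] / s
}

#' Reference plausibility bands for the data-quality indicators
#'
#' Default reference bands, derived from vital registration, historical, and
#' prospective pregnancy-outcome data, against which survey-specific indicator
#' values are classified. Band intervals are lower-inclusive and
#' upper-exclusive, contiguous, and cover the whole nonnegative axis. The
#' D0-1/D2-6 ratio has a one-sided rule only: at least 2.4 is plausible,
#' anything lower indicates under-reporting of very early neonatal deaths.
#'
#' @return An object of class `reference_bands`: a named list (metrics
#'   `heaping`, `sb_d01`, `sb_week`, `d01_d26`) of data frames with columns
#'   `lower`, `upper`, `band`.
#' @export
reference_bands <- function() {
  band_df <- function(breaks, bands) {
    data.frame(
      lower = breaks, upper = c(breaks[-1], Inf), band = bands,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      heaping = band_df(
        c(0, 0.6, 0.8, 1.3, 1.5),
        c("improbable", "probable", "plausible", "probable", "improbable")
      ),
      sb_d01 = band_df(
        c(0, 1.0, 1.7, 3.0, 4.0),
        c("improbable", "probable", "plausible", "probable", "improbable")
      ),
      sb_week = band_df(
        c(0, 0.5, 1.0, 1.9, 2.4),
        c("improbable", "probable", "plausible", "probable", "improbable")
      ),
      d01_d26 = band_df(c(0, 2.4), c("under-reported", "plausible"))
    ),
    class = "reference_bands"
  )
}

validate_reference_bands <- function(bands) {
  stopifnot(inherits(bands, "reference_bands") || is.list(bands))
  for (metric in names(bands)) {
    b <- bands[[metric]]
    stopifnot(all(c("lower", "upper", "band") %in% names(b)))
    if (b$lower[1] != 0 || !is.infinite(b$upper[nrow(b)])) {
      stop("bands for ", metric, " must cover [0, Inf)")
    }
    if (nrow(b) > 1 && any(b$lower[-1] != b$upper[-nrow(b)])) {
      stop("bands for ", metric, " must be contiguous and non-overlapping")
    }
  }
  invisible(bands)
}

#' Read a plausibility-band table from a JSON or YAML config file
#'
#' The file holds one entry per metric with fields `breaks` (ascending lower
#' bounds, starting at 0) and `bands` (one label per break); the last band
#' extends to infinity. Metrics not present fall back to the defaults.
#'
#' @param file Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A `reference_bands` object.
#' @export
read_bands_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  bands <- reference_bands()
  for (metric in names(cfg)) {
    if (!metric %in% names(bands)) {
      stop("unknown metric in bands config: ", metric)
    }
    breaks <- as.numeric(cfg[[metric]]$breaks)
    labels <- as.character(cfg[[metric]]$bands)
    stopifnot(length(breaks) == length(labels), breaks[1] == 0,
              !is.unsorted(breaks, strictly = TRUE))
    bands[[metric]] <- data.frame(
      lower = breaks, upper = c(breaks[-1], Inf), band = labels,
      stringsAsFactors = FALSE
    )
  }
  validate_reference_bands(bands)
  bands
}

#' Classify an indicator value against its plausibility bands
#'
#' Returns the unique band whose lower-inclusive, upper-exclusive interval
#' contains the value. Undefined (NA) values are "unclassifiable". The result
#' carries a `side` attribute ("low"/"high") locating non-plausible values
#' relative to the plausible range.
#'
#' @param metric One of `"heaping"`, `"sb_d01"`, `"sb_week"`, `"d01_d26"` (or
#'   any metric present in `bands`).
#' @param value Nonnegative indicator value, or `NA`.
#' @param bands A [reference_bands()] object.
#' @return The band label (character scalar).
#' @export
classify_metric <- function(metric, value, bands = reference_bands()) {
  if (!metric %in% names(bands)) stop("unknown metric: ", metric)
  if (is.na(value)) return(structure("unclassifiable", side = NA_character_))
  if (value < 0) stop("indicator values must be nonnegative")
  b <- bands[[metric]]
  row <- which(value >= b$lower & value < b$upper)
  stopifnot(length(row) == 1)
  plausible_at <- which(b$band == "plausible")
  side <- if (length(plausible_at) == 0 || b$band[row] == "plausible") {
    NA_character_
  } else if (row < min(plausible_at)) "low" else "high"
  structure(b$band[row], side = side)
}

#' Compute the four data-quality indicators from an interval table
#'
#' From weighted interval counts, computes the stillbirth-to-D0-1 ratio, the
#' stillbirth-to-first-week (days 0-6) ratio, the D0-1-to-D2-6 ratio, and the
#' day-7 heaping index (days 5-9 sit in intervals 6-10). Each indicator is
#' undefined (NA) exactly when its denominator is zero.
#'
#' @param counts An [interval_counts()] object.
#' @return An object of class `quality_metrics`: list with elements `values`
#'   (the four indicators) and `counts` (the component death counts).
#' @export
ratio_metrics <- function(counts) {
  validate_interval_counts(counts)
  d <- counts$deaths
  stb <- d[1]
  d01 <- d[2]
  d26 <- sum(d[3:7])   # days 2-6
  week <- d01 + d26    # days 0-6
  d59 <- d[6:10]       # days 5-9
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      values = list(
        heaping = if (sum(d59) == 0) NA_real_ else heaping_index(d59),
        sb_d01 = ratio(stb, d01),
        sb_week = ratio(stb, week),
        d01_d26 = ratio(d01, d26)
      ),
      counts = list(
        stillbirths = stb, d01 = d01, d26 = d26, first_week = week,
        day5 = d[6], day6 = d[7], day7 = d[8], day8 = d[9], day9 = d[10]
      )
    ),
    class = "quality_metrics"
  )
}

#' Full data-quality report with bands and adjustment triggers
#'
#' Computes all four indicators, classifies each against the reference bands,
#' and evaluates the two adjustment triggers: the stillbirth constraint fires
#' when the stillbirth-to-D0-1 ratio is strictly below `constraint_constant`,
#' and D0-1 weighting fires when the D0-1-to-D2-6 ratio is strictly below
#' `weight_constant`. Undefined ratios leave the corresponding trigger off and
#' are flagged.
#'
#' @param counts An [interval_counts()] object.
#' @param bands A [reference_bands()] object.
#' @param constraint_constant Reference stillbirth-to-D0-1 ratio (default
#'   1.89, the corpus median behind the adjustment rule).
#' @param weight_constant Reference D0-1-to-D2-6 ratio (default 2.4).
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(counts, bands = reference_bands(),
                           constraint_constant = 1.89,
                           weight_constant = 2.4) {
  validate_reference_bands(bands)
  m <- ratio_metrics(counts)
  v <- m$values
  classification <- lapply(names(v), function(metric) {
    classify_metric(metric, v[[metric]], bands)
  })
  names(classification) <- names(v)
  structure(
    list(
      metrics = v,
      counts = m$counts,
      bands = vapply(classification, as.character, character(1)),
      band_sides = vapply(classification, attr, character(1), "side"),
      triggers = list(
        sb_constraint = !is.na(v$sb_d01) && v$sb_d01 < constraint_constant,
        d01_weight = !is.na(v$d01_d26) && v$d01_d26 < weight_constant
      ),
      undefined = names(v)[vapply(v, is.na, logical(1))],
      constants = list(constraint_constant = constraint_constant,
                       weight_constant = weight_constant),
      survey_id = attr(counts, "survey_id")
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Data-quality report")
  if (!is.na(x$survey_id)) cat(" [", x$survey_id, "]", sep = "")
  cat("\n")
  metric_names <- c(
    heaping = "Heaping index (day 7)",
    sb_d01 = "Stillbirths / D0-1",
    sb_week = "Stillbirths / first week",
    d01_d26 = "D0-1 / D2-6"
  )
  for (metric in names(x$metrics)) {
    v <- x$metrics[[metric]]
    side <- x$band_sides[[metric]]
    cat(sprintf(
      "  %-26s %s  [%s%s]\n", metric_names[[metric]],
      if (is.na(v)) "undefined" else formatC(v, digits = 3, format = "fg"),
      x$bands[[metric]],
      if (!is.na(side)) paste0(", ", side) else ""
    ))
  }
  cat(sprintf(
    "  Triggers: stillbirth constraint (ratio < %.2f): %s; D0-1 weighting (ratio < %.2f): %s\n",
    x$constants$constraint_constant, x$triggers$sb_constraint,
    x$constants$weight_constant, x$triggers$d01_weight
  ))
  invisible(x)
}

quality_report_payload <- function(x) {
  list(
    survey_id = x$survey_id,
    metrics = x$metrics,
    bands = as.list(x$bands),
    band_sides = as.list(x$band_sides),
    triggers = x$triggers,
    counts = x$counts,
    constants = x$constants
  )
}

#' Write a quality report as JSON or CSV
#'
#' @param x A `quality_report` object.
#' @param file Output path.
#' @param format `"json"` (full report) or `"csv"` (one row per metric).
#' @return `file`, invisibly.
#' @export
write_quality_report <- function(x, file, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(quality_report_payload(x), file, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    df <- data.frame(
      metric = names(x$metrics),
      value = vapply(x$metrics, function(v) as.numeric(v), numeric(1)),
      band = unname(x$bands),
      side = unname(x$band_sides),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, file, row.names = FALSE, na = "")
  }
  invisible(file)
}
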