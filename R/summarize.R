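#' Summarize quality metrics and adjusted rates across surveys
#'
#' Aggregates per-survey adjustment outputs the way a multi-survey report
#' does: median, interquartile range, and range of each quality indicator and
#' each model's rates; counts and percentages of surveys per plausibility
#' band; pairwise Pearson correlations between the indicators; and per-model
#' median relative differences from model 1 (the median of the per-survey
#' relative differences, not the difference of medians). Quantiles use the
#' median-unbiased definition (`stats::quantile(type = 8)`) throughout.
#'
#' @param x A list of `perinatal_adjust` objects, a directory containing
#'   per-survey JSON outputs from [write_adjust_output()], or a character
#'   vector of such JSON paths.
#' @param bands A [reference_bands()] object used for the band tallies.
#' @return An object of class `perinatal_summary`: list with `n_surveys`,
#'   `metrics` (summary stats per indicator), `band_counts`, `correlations`,
#'   `rates` (summary stats per model and rate), `relative_diff` (per-model
#'   medians and IQRs), and `per_survey` (the underlying tidy table).
#' @export
summarize_surveys <- function(x, bands = reference_bands()) {
  surveys <- collect_survey_outputs(x)
  if (length(surveys) == 0) stop("no survey outputs to summarize")

  per_survey <- do.call(rbind, lapply(seq_along(surveys), function(i) {
    df <- as.data.frame(surveys[[i]])
    df$.survey <- i
    df
  }))
  metric_cols <- c("heaping", "sb_d01", "sb_week", "d01_d26")
  # quality indicators repeat across a survey's model rows; survey-level
  # summaries use one row per survey
  survey_level <- per_survey[!duplicated(per_survey$.survey), , drop = FALSE]

  qtl <- function(v, p) stats::quantile(v, p, na.rm = TRUE, names = FALSE,
                                        type = 8)
  summarize_vec <- function(v) {
    v_ok <- v[!is.na(v)]
    data.frame(
      n = length(v_ok),
      median = if (length(v_ok)) qtl(v, 0.5) else NA_real_,
      q1 = if (length(v_ok)) qtl(v, 0.25) else NA_real_,
      q3 = if (length(v_ok)) qtl(v, 0.75) else NA_real_,
      min = if (length(v_ok)) min(v_ok) else NA_real_,
      max = if (length(v_ok)) max(v_ok) else NA_real_,
      mean = if (length(v_ok)) mean(v_ok) else NA_real_,
      sd = if (length(v_ok) > 1) stats::sd(v_ok) else NA_real_
    )
  }

  metrics <- do.call(rbind, lapply(metric_cols, function(mc) {
    cbind(data.frame(metric = mc, stringsAsFactors = FALSE),
          summarize_vec(survey_level[[mc]]))
  }))

  band_counts <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- survey_level[[mc]]
    lab <- vapply(v, function(val) {
      as.character(classify_metric(mc, val, bands))
    }, character(1))
    classifiable <- lab != "unclassifiable"
    tab <- table(factor(lab[classifiable],
                        levels = unique(bands[[mc]]$band)))
    data.frame(
      metric = mc, band = names(tab), count = as.integer(tab),
      percent = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab) else
        rep(NA_real_, length(tab)),
      stringsAsFactors = FALSE
    )
  }))

  correlations <- stats::cor(survey_level[metric_cols],
                             use = "pairwise.complete.obs",
                             method = "pearson")

  rate_rows <- per_survey[!is.na(per_survey$model), , drop = FALSE]
  rates <- NULL
  relative_diff <- NULL
  if (nrow(rate_rows) > 0) {
    rates <- do.call(rbind, lapply(split(rate_rows, rate_rows$model),
                                   function(block) {
      do.call(rbind, lapply(c("sbr", "enmr", "pmr"), function(rn) {
        cbind(data.frame(model = block$model[1], rate = rn,
                         stringsAsFactors = FALSE),
              summarize_vec(block[[rn]]))
      }))
    }))
    rel_cols <- c("rel_sbr", "rel_enmr", "rel_pmr")
    relative_diff <- do.call(rbind, lapply(split(rate_rows, rate_rows$model),
                                           function(block) {
      do.call(rbind, lapply(seq_along(rel_cols), function(k) {
        cbind(data.frame(model = block$model[1],
                         rate = c("sbr", "enmr", "pmr")[k],
                         stringsAsFactors = FALSE),
              summarize_vec(block[[rel_cols[k]]]))
      }))
    }))
    rownames(rates) <- rownames(relative_diff) <- NULL
  }

  structure(
    list(
      n_surveys = length(surveys),
      metrics = metrics,
      band_counts = band_counts,
      correlations = correlations,
      rates = rates,
      relative_diff = relative_diff,
      per_survey = per_survey
    ),
    class = "perinatal_summary"
  )
}

# normalize adjust outputs (in-memory objects or JSON files) to a common
# per-survey representation: one data frame row per survey x model, with the
# quality metrics repeated
collect_survey_outputs <- function(x) {
  if (inherits(x, "perinatal_adjust")) x <- list(x)
  if (is.character(x)) {
    files <- x
    if (length(x) == 1 && dir.exists(x)) {
      files <- list.files(x, pattern = "\\.json$", full.names = TRUE)
    }
    if (length(files) == 0) stop("no JSON survey outputs found")
    return(lapply(files, read_adjust_output))
  }
  stopifnot(is.list(x))
  lapply(x, function(obj) {
    stopifnot(inherits(obj, "perinatal_adjust"))
    adjust_tidy_rows(
      survey_id = obj$survey_id,
      metrics = obj$quality$metrics,
      models = lapply(names(obj$fits), function(key) {
        r <- rates_from_lifetable(obj$fits[[key]]$lifetable)
        rel <- obj$relative_diff[obj$relative_diff$model == key,
                                 c("sbr", "enmr", "pmr")]
        list(model = key, rates = list(sbr = r$sbr, enmr = r$enmr,
                                       pmr = r$pmr),
             relative_diff_vs_model1 = as.list(rel))
      })
    )
  })
}

adjust_tidy_rows <- function(survey_id, metrics, models) {
  base <- data.frame(
    survey_id = if (is.null(survey_id) || is.na(survey_id)) NA_character_
                else survey_id,
    heaping = null_na(metrics$heaping),
    sb_d01 = null_na(metrics$sb_d01),
    sb_week = null_na(metrics$sb_week),
    d01_d26 = null_na(metrics$d01_d26),
    stringsAsFactors = FALSE
  )
  if (length(models) == 0) {
    base$model <- NA_character_
    base$sbr <- base$enmr <- base$pmr <- NA_real_
    base$rel_sbr <- base$rel_enmr <- base$rel_pmr <- NA_real_
    return(base)
  }
  do.call(rbind, lapply(models, function(m) {
    row <- base
    row$model <- m$model
    row$sbr <- null_na(m$rates$sbr)
    row$enmr <- null_na(m$rates$enmr)
    row$pmr <- null_na(m$rates$pmr)
    rel <- m$relative_diff_vs_model1
    row$rel_sbr <- null_na(rel$sbr)
    row$rel_enmr <- null_na(rel$enmr)
    row$rel_pmr <- null_na(rel$pmr)
    row
  }))
}

null_na <- function(v) {
  if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
}

#' Read one per-survey JSON output back into the tidy summary form
#'
#' @param file A JSON file written by [write_adjust_output()].
#' @return A data frame, one row per model, carrying the quality metrics.
#' @export
read_adjust_output <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = FALSE)
  adjust_tidy_rows(
    survey_id = payload$survey_id,
    metrics = payload$quality$metrics,
    models = unname(payload$models)
  )
}

#' @export
print.perinatal_summary <- function(x, ...) {
  cat("Multi-survey summary over", x$n_surveys, "survey(s)\n\n")
  cat("Quality indicators (median-unbiased quantiles):\n")
  df <- x$metrics
  num <- c("median", "q1", "q3", "min", "max", "mean", "sd")
  df[num] <- round(df[num], 2)
  print(df, row.names = FALSE)
  cat("\nPlausibility-band tallies:\n")
  print(x$band_counts, row.names = FALSE)
  if (!is.null(x$rates)) {
    cat("\nRates per 1000 by model:\n")
    df <- x$rates
    df[num] <- round(df[num], 1)
    print(df[, c("model", "rate", "n", "median", "q1", "q3", "min", "max")],
          row.names = FALSE)
    cat("\nRelative differences from model 1 (%, median of per-survey values):\n")
    df <- x$relative_diff
    df[num] <- round(df[num], 1)
    print(df[df$model != "model1", c("model", "rate", "median", "q1", "q3")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a multi-survey summary as JSON or CSV
#'
#' @param x A `perinatal_summary` object.
#' @param file Output path.
#' @param format `"json"` (full summary) or `"csv"` (the per-metric table).
#' @return `file`, invisibly.
#' @export
write_summary <- function(x, file, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      n_surveys = x$n_surveys,
      metrics = x$metrics,
      band_counts = x$band_counts,
      correlations = as.data.frame(as.table(x$correlations)),
      rates = x$rates,
      relative_diff = x$relative_diff
    )
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(x$metrics, file, row.names = FALSE, na = "")
  }
  invisible(file)
}
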