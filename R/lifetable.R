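#' Real-cohort life table over the 10 analysis intervals
#'
#' Computes conditional risks of death, cumulative survival, and cumulative
#' death probability from 7 months' gestation through the end of day 9. In
#' this design censoring occurs only at interval boundaries (ongoing
#' pregnancies leave at the stillbirth interval, everyone else at day 10), so
#' the default conditional risk is `q_j = d_j / n_j`. The actuarial
#' half-interval correction `q_j = d_j / (n_j - c_j/2)` is available behind
#' `interior_censoring` for data where censoring can fall inside an interval.
#'
#' @param counts An [interval_counts()] object.
#' @param interior_censoring Use the actuarial half-interval exposure
#'   correction (default `FALSE`).
#' @return An object of class `life_table`: data frame with per-interval
#'   columns `interval`, `label`, `entrants`, `deaths`, `censored`, `q`
#'   (conditional risk), `S` (cumulative survival), `F` (cumulative death
#'   probability), and attribute `source = "observed"`.
#' @export
compute_life_table <- function(counts, interior_censoring = FALSE) {
  validate_interval_counts(counts)
  d <- counts$deaths
  n <- counts$entrants
  cc <- counts$censored
  if (n[1] <= 0) stop("life table undefined: no pregnancies at risk")
  if (any(n == 0 & d > 0)) stop("deaths in an interval with no entrants")
  exposure <- if (interior_censoring) n - cc / 2 else n
  q <- ifelse(exposure > 0, d / exposure, 0)
  if (any(q < 0 | q > 1)) {
    stop("conditional risks outside [0, 1]; check counts (or the ",
         "half-interval correction with heavy interval censoring)")
  }
  S <- cumprod(1 - q)
  new_life_table(counts, q, source = "observed")
}

new_life_table <- function(counts, q, source) {
  S <- cumprod(1 - q)
  structure(
    data.frame(
      interval = 1:10,
      label = interval_labels(),
      entrants = counts$entrants,
      deaths = counts$deaths,
      censored = counts$censored,
      q = q,
      S = S,
      F = 1 - S,
      stringsAsFactors = FALSE
    ),
    source = source,
    survey_id = attr(counts, "survey_id"),
    class = c("life_table", "data.frame")
  )
}

#' @export
print.life_table <- function(x, digits = 5, ...) {
  cat("Life table (", attr(x, "source"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$q <- signif(df$q, digits)
  df$S <- signif(df$S, digits)
  df$F <- signif(df$F, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

cloglog <- function(q) log(-log(1 - q))
inv_cloglog <- function(gamma) 1 - exp(-exp(gamma))

#' Binomial interval log-likelihood of a set of conditional risks
#'
#' @param q Conditional risks per interval.
#' @param counts An `interval_counts` object.
#' @return The log-likelihood (terms with zero counts contribute zero).
#' @keywords internal
interval_loglik <- function(q, counts) {
  d <- counts$deaths
  n <- counts$entrants
  term <- function(count, p) ifelse(count > 0, count * log(p), 0)
  sum(term(d, q) + term(n - d, 1 - q))
}

#' Saturated piecewise-exponential (cloglog) fit
#'
#' Fits the interval-censored piecewise-exponential model with one coefficient
#' per interval on the complementary log-log scale,
#' `log(-log(1 - q_j)) = gamma_j`. The saturated binomial likelihood separates
#' over intervals, so the maximizer is available in closed form,
#' `q_j = d_j / n_j` — the model is exactly equivalent to the real-cohort life
#' table. Intervals with zero deaths get a `-Inf` coefficient sentinel
#' (`q_j = 0`) and are flagged.
#'
#' @param counts An [interval_counts()] object.
#' @param interior_censoring Passed to [compute_life_table()].
#' @return An object of class `pwe_fit`: list with `gamma` (length-10
#'   coefficient vector), `lifetable` (fitted [compute_life_table()] output
#'   with source `"model1"`), `loglik`, and `zero_intervals`.
#' @export
fit_piecewise_exponential <- function(counts, interior_censoring = FALSE) {
  lt <- compute_life_table(counts, interior_censoring = interior_censoring)
  q <- lt$q
  gamma <- ifelse(q > 0, cloglog(q), -Inf)
  fitted_lt <- new_life_table(counts, q, source = "model1")
  structure(
    list(
      gamma = stats::setNames(gamma, interval_labels()),
      lifetable = fitted_lt,
      loglik = interval_loglik(q, counts),
      zero_intervals = interval_labels()[q == 0]
    ),
    class = "pwe_fit"
  )
}

#' @export
print.pwe_fit <- function(x, ...) {
  cat("Piecewise-exponential (cloglog) fit, saturated: one coefficient per",
      "interval\n")
  print(signif(x$gamma, 5))
  cat("log-likelihood:", format(x$loglik), "\n")
  if (length(x$zero_intervals) > 0) {
    cat("zero-death intervals (q = 0 sentinel):",
        paste(x$zero_intervals, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.pwe_fit <- function(object, ...) object$gamma

#' @export
logLik.pwe_fit <- function(object, ...) {
  structure(object$loglik, df = sum(is.finite(object$gamma)),
            class = "logLik")
}

#' Stillbirth, early neonatal, and perinatal mortality rates
#'
#' Converts a life table into the three headline rates per 1000: the
#' stillbirth rate `1000 * q_1` (per 1000 births), the early neonatal
#' mortality rate over days 0-6 among livebirths
#' `1000 * (1 - prod(1 - q_j), j = 2..7)` (per 1000 livebirths), and the
#' perinatal mortality rate combining both (per 1000 births). Days 7-9 are
#' outside the perinatal window; they enter the analysis only through the
#' heaping index and the day-7 smoothing.
#'
#' @param lt A `life_table` object.
#' @return An object of class `mortality_rates`: list with `sbr`, `enmr`,
#'   `pmr`, and `model` (the life table's source label).
#' @export
rates_from_lifetable <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  q <- lt$q
  q_en <- 1 - prod(1 - q[2:7])
  structure(
    list(
      sbr = 1000 * q[1],
      enmr = 1000 * q_en,
      pmr = 1000 * (1 - (1 - q[1]) * (1 - q_en)),
      model = attr(lt, "source")
    ),
    class = "mortality_rates"
  )
}

#' @export
print.mortality_rates <- function(x, ...) {
  cat(sprintf(
    "Mortality rates (%s): stillbirth %.1f/1000 births, early neonatal %.1f/1000 livebirths, perinatal %.1f/1000 births\n",
    x$model, x$sbr, x$enmr, x$pmr
  ))
  invisible(x)
}

#' @export
as.data.frame.mortality_rates <- function(x, ...) {
  data.frame(model = x$model, sbr = x$sbr, enmr = x$enmr, pmr = x$pmr,
             stringsAsFactors = FALSE)
}

#' Write a life table as CSV or JSON
#'
#' @param x A `life_table` object.
#' @param file Output path.
#' @param format `"csv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_life_table <- function(x, file, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  } else {
    payload <- list(
      survey_id = attr(x, "survey_id"),
      source = attr(x, "source"),
      intervals = as.data.frame(x)
    )
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(file)
}
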