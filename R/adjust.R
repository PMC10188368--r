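#' Fit the observed and adjusted perinatal mortality models to one survey
#'
#' The central fitting function of the package. Takes a survey's pregnancy
#' data, computes the data-quality report, and fits the requested subset of
#' the four models:
#'
#' * **model 1** — observed piecewise-exponential (saturated cloglog) fit,
#'   equivalent to the real-cohort life table;
#' * **model 2** — Gompertz-Makeham fit with the stillbirth constraint
#'   `gamma1 = gamma2 + log(1.89)` on the raw table (adjusts stillbirth
#'   omission and transference);
#' * **model 3** — Gompertz-Makeham fit without the constraint on the
#'   D0-1-weighted table (adjusts under-reporting of very early neonatal
#'   deaths);
#' * **model 4** — both: the table is weighted first, the stillbirth trigger
#'   is re-evaluated on the weighted table, and the constraint applied if it
#'   still fires.
#'
#' Each adjustment applies only when its quality trigger fires; on a table
#' with both triggers false all four models agree (up to the smoothing of
#' days 2-9). A failure in one model is captured per model and leaves the
#' others intact.
#'
#' @param x The survey data: a `pregnancy_records` data frame, a path to a
#'   delimited pregnancy table, or an [interval_counts()] object (taken as
#'   already eligibility-filtered).
#' @param models Integer subset of `1:4` (default all). Model 1 is always
#'   added: the relative differences are defined against it.
#' @param bands [reference_bands()] used for classification.
#' @param config An [adjust_config()] object; its `model` field is ignored
#'   here (the `models` argument governs).
#' @param use_weights Sum sampling weights when tabulating records (default
#'   `TRUE`).
#' @param rules [eligibility_rules()] applied when `x` holds records.
#' @return An object of class `perinatal_adjust` with components `quality`,
#'   `fits` (named list of [fit_gm()] results), `rates` (data frame of
#'   per-model rates per 1000), `relative_diff` (percent differences vs model
#'   1), `errors` (per-model error messages), `counts`, `exclusions`, and
#'   `config`.
#' @seealso [summary.perinatal_adjust()], [write_adjust_output()],
#'   [summarize_surveys()]
#' @export
adjust_survey <- function(x, models = 1:4, bands = reference_bands(),
                          config = adjust_config(), use_weights = TRUE,
                          rules = eligibility_rules()) {
  stopifnot(all(models %in% 1:4))
  models <- sort(unique(c(1L, as.integer(models))))
  exclusions <- NULL
  if (is.character(x) && length(x) == 1) {
    x <- read_pregnancy_table(x)
  }
  if (inherits(x, "pregnancy_records")) {
    elig <- apply_eligibility(x, rules)
    exclusions <- elig$exclusions
    counts <- build_interval_counts(elig$records, use_weights = use_weights,
                                    rules = rules)
  } else if (inherits(x, "interval_counts")) {
    counts <- x
  } else {
    stop("x must be pregnancy records, a file path, or interval counts")
  }

  quality <- quality_report(
    counts, bands,
    constraint_constant = config$constraint_constant,
    weight_constant = config$weight_constant
  )

  # the weighted table is shared by models 3 and 4
  weighted <- NULL
  weighted_quality <- NULL
  get_weighted <- function() {
    if (is.null(weighted)) {
      if (isTRUE(quality$triggers$d01_weight)) {
        wres <- apply_d01_weighting(counts, config$weight_constant,
                                    balance = config$balance)
        weighted <<- wres$counts
      } else {
        weighted <<- counts
      }
      weighted_quality <<- quality_report(
        weighted, bands,
        constraint_constant = config$constraint_constant,
        weight_constant = config$weight_constant
      )
    }
    weighted
  }

  fits <- list()
  errors <- list()
  for (m in models) {
    key <- paste0("model", m)
    res <- tryCatch({
      cfg <- config
      cfg$model <- m
      switch(as.character(m),
        "1" = fit_gm(counts, cfg, quality),
        "2" = fit_gm(counts, cfg, quality),
        "3" = {
          tab <- get_weighted()
          fit_gm(tab, cfg, weighted_quality)
        },
        "4" = {
          tab <- get_weighted()
          # trigger re-evaluated on the weighted table
          fit_gm(tab, cfg, weighted_quality)
        }
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      fits[[key]] <- res
    }
  }

  rates <- do.call(rbind, lapply(names(fits), function(key) {
    as.data.frame(rates_from_lifetable(fits[[key]]$lifetable))
  }))
  relative_diff <- NULL
  if (!is.null(rates) && "model1" %in% rates$model) {
    base <- rates[rates$model == "model1", c("sbr", "enmr", "pmr")]
    relative_diff <- rates
    for (col in c("sbr", "enmr", "pmr")) {
      relative_diff[[col]] <- 100 * (rates[[col]] - base[[col]]) / base[[col]]
    }
  }

  structure(
    list(
      quality = quality,
      fits = fits,
      rates = rates,
      relative_diff = relative_diff,
      errors = errors,
      counts = counts,
      weighted_counts = weighted,
      exclusions = exclusions,
      config = config,
      survey_id = attr(counts, "survey_id")
    ),
    class = "perinatal_adjust"
  )
}

#' @export
print.perinatal_adjust <- function(x, ...) {
  cat("Perinatal mortality adjustment")
  if (!is.na(x$survey_id)) cat(" [", x$survey_id, "]", sep = "")
  cat(": ", format(attr(x$counts, "total_pregnancies")),
      " pregnancies\n", sep = "")
  tr <- x$quality$triggers
  cat(sprintf("Triggers: stillbirth constraint %s, D0-1 weighting %s\n",
              if (tr$sb_constraint) "ON" else "off",
              if (tr$d01_weight) "ON" else "off"))
  if (!is.null(x$rates)) {
    df <- x$rates
    df[c("sbr", "enmr", "pmr")] <- round(df[c("sbr", "enmr", "pmr")], 1)
    cat("Rates per 1000 (sbr, enmr per 1000 livebirths, pmr):\n")
    print(df, row.names = FALSE)
  }
  if (!is.null(x$relative_diff) && nrow(x$relative_diff) > 1) {
    df <- x$relative_diff
    df[c("sbr", "enmr", "pmr")] <- round(df[c("sbr", "enmr", "pmr")], 1)
    cat("Relative differences vs model 1 (%):\n")
    print(df[df$model != "model1", ], row.names = FALSE)
  }
  if (length(x$errors) > 0) {
    cat("Model errors:\n")
    for (key in names(x$errors)) cat("  ", key, ": ", x$errors[[key]], "\n",
                                     sep = "")
  }
  invisible(x)
}

#' @export
summary.perinatal_adjust <- function(object, ...) {
  structure(list(adjust = object), class = "summary.perinatal_adjust")
}

#' @export
print.summary.perinatal_adjust <- function(x, ...) {
  a <- x$adjust
  print(a)
  cat("\n")
  print(a$quality)
  for (key in names(a$fits)) {
    cat("\n")
    print(a$fits[[key]])
  }
  invisible(x)
}

#' @export
coef.perinatal_adjust <- function(object, ...) {
  keys <- names(object$fits)
  out <- vapply(keys, function(key) object$fits[[key]]$coefficients,
                numeric(5))
  rownames(out) <- c("gamma1", "gamma2", "gamma0", "alpha", "beta")
  out
}

#' @export
plot.perinatal_adjust <- function(x, ...) {
  if (is.null(x$rates)) stop("no fitted models to plot")
  m <- t(as.matrix(x$rates[, c("sbr", "enmr", "pmr")]))
  colnames(m) <- x$rates$model
  graphics::barplot(
    m, beside = TRUE,
    legend.text = c("stillbirth", "early neonatal", "perinatal"),
    args.legend = list(x = "topleft", bty = "n"),
    ylab = "rate per 1000", ...
  )
  invisible(x)
}

#' Serialize a fitted adjustment to JSON
#'
#' Writes the per-survey output consumed by [summarize_surveys()]: quality
#' metrics with bands and triggers, per-model rates, relative differences,
#' model coefficients, log-likelihoods, and convergence flags.
#'
#' @param x A `perinatal_adjust` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_adjust_output <- function(x, file) {
  stopifnot(inherits(x, "perinatal_adjust"))
  models <- lapply(names(x$fits), function(key) {
    fit <- x$fits[[key]]
    rates <- rates_from_lifetable(fit$lifetable)
    rel <- NULL
    if (!is.null(x$relative_diff)) {
      row <- x$relative_diff[x$relative_diff$model == key, ]
      if (nrow(row) == 1) rel <- as.list(row[c("sbr", "enmr", "pmr")])
    }
    list(
      model = key,
      rates = list(sbr = rates$sbr, enmr = rates$enmr, pmr = rates$pmr),
      relative_diff_vs_model1 = rel,
      coefficients = as.list(fit$coefficients),
      constraint_active = fit$constraint_active,
      d01_weight = fit$d01_weight,
      loglik = fit$loglik,
      fitted_heaping = fit$fitted_heaping,
      converged = fit$convergence$converged,
      flags = as.list(fit$flags)
    )
  })
  names(models) <- names(x$fits)
  payload <- list(
    survey_id = x$survey_id,
    total_pregnancies = attr(x$counts, "total_pregnancies"),
    quality = quality_report_payload(x$quality),
    models = models,
    errors = x$errors,
    exclusions = as.list(x$exclusions)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}
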