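#' Configuration for the adjustment models
#'
#' @param model Which adjustment model to fit: 1 = observed piecewise
#'   exponential; 2 = Gompertz-Makeham with the stillbirth constraint;
#'   3 = Gompertz-Makeham on the D0-1-weighted table; 4 = both.
#' @param constraint_constant Reference stillbirth-to-D0-1 ratio enforced by
#'   the model-2/4 constraint (default 1.89).
#' @param weight_constant Reference D0-1-to-D2-6 ratio targeted by the
#'   model-3/4 weighting (default 2.4).
#' @param tol Optimizer convergence tolerance on the relative log-likelihood
#'   change (default 1e-8).
#' @param max_iterations Maximum optimizer iterations per start (default 500).
#' @param restarts Number of deterministic starting points (default 3).
#' @param balance How D0-1 upweighting preserves flow conservation:
#'   `"reduce-downstream"` (default; later entrants shrink) or
#'   `"inflate-cohort"` (the extra weighted deaths are added to the cohort).
#' @param interior_censoring Passed through to the life-table computations.
#' @return An object of class `adjust_config`.
#' @export
adjust_config <- function(model = 4,
                          constraint_constant = 1.89,
                          weight_constant = 2.4,
                          tol = 1e-8,
                          max_iterations = 500,
                          restarts = 3,
                          balance = c("reduce-downstream", "inflate-cohort"),
                          interior_censoring = FALSE) {
  balance <- match.arg(balance)
  stopifnot(
    length(model) == 1, model %in% 1:4,
    constraint_constant > 0, weight_constant > 0, tol > 0,
    max_iterations >= 1, restarts >= 1
  )
  structure(
    list(
      model = as.integer(model),
      constraint_constant = constraint_constant,
      weight_constant = weight_constant,
      tol = tol,
      max_iterations = as.integer(max_iterations),
      restarts = as.integer(restarts),
      balance = balance,
      interior_censoring = isTRUE(interior_censoring)
    ),
    class = "adjust_config"
  )
}

#' Read an adjustment configuration from JSON or YAML
#'
#' Fields mirror the arguments of [adjust_config()]; absent fields keep their
#' defaults.
#'
#' @param file Path to a `.json`, `.yaml`, or `.yml` file.
#' @return An `adjust_config` object.
#' @export
read_adjust_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  known <- names(formals(adjust_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown adjustment config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(adjust_config, cfg)
}

#' Upweight deaths on days 0-1 toward the reference D2-6 ratio
#'
#' When the observed ratio r of D0-1 deaths to deaths on days 2-6 falls below
#' the reference constant, D0-1 deaths are multiplied by `weight_constant / r`
#' so the weighted table attains the reference ratio exactly; tables at or
#' above the reference are returned unchanged with weight 1. Flow conservation
#' is preserved by shrinking later entrants (the extra deaths come out of the
#' day-10 survivors), or, behind `balance = "inflate-cohort"`, by enlarging the
#' cohort so downstream intervals are untouched.
#'
#' @param counts An [interval_counts()] object.
#' @param weight_constant Reference D0-1-to-D2-6 ratio (default 2.4).
#' @param balance See [adjust_config()].
#' @return A list with `counts` (the possibly reweighted table, carrying the
#'   weight in its `effective_weight_d01` attribute), `weight`, `ratio`, and
#'   `degenerate` (`TRUE` when D0-1 deaths are zero so no weight is defined).
#' @export
apply_d01_weighting <- function(counts, weight_constant = 2.4,
                                balance = c("reduce-downstream",
                                            "inflate-cohort")) {
  balance <- match.arg(balance)
  validate_interval_counts(counts)
  d <- counts$deaths
  d26 <- sum(d[3:7])
  if (d26 == 0) {
    stop("D0-1 weighting undefined: no deaths on days 2-6")
  }
  r <- d[2] / d26
  if (d[2] == 0) {
    return(list(counts = counts, weight = NA_real_, ratio = 0,
                degenerate = TRUE))
  }
  if (r >= weight_constant) {
    return(list(counts = counts, weight = 1, ratio = r, degenerate = FALSE))
  }
  w <- weight_constant / r
  extra <- d[2] * (w - 1)
  new_d <- d
  new_d[2] <- d[2] * w
  if (balance == "reduce-downstream") {
    out <- tryCatch(
      interval_counts(new_d, total = attr(counts, "total_pregnancies"),
                      censored = counts$censored,
                      survey_id = attr(counts, "survey_id")),
      error = function(e) {
        stop("D0-1 weighting infeasible: not enough day-10 survivors to ",
             "absorb the weighted deaths (", conditionMessage(e), ")")
      }
    )
  } else {
    # the extra weighted deaths are treated as additional pregnancies that all
    # died on days 0-1, leaving every later interval untouched
    # the extras enter as pregnancies that survive the stillbirth interval and
    # die on days 0-1, so every interval from day 2 onward is untouched
    out <- interval_counts(new_d, total = attr(counts, "total_pregnancies") +
                             extra, censored = counts$censored,
                           survey_id = attr(counts, "survey_id"))
  }
  attr(out, "effective_weight_d01") <- w
  list(counts = out, weight = w, ratio = r, degenerate = FALSE)
}

gm_day_midpoints <- function() seq(2.5, 9.5, by = 1)

# negative log-likelihood of the smooth hazard part (intervals 3..10):
# h_j = gamma0 + exp(alpha + beta * x_j), q_j = 1 - exp(-h_j)
gm_tail_negll <- function(par, d, n, x) {
  h <- par[1] + exp(par[2] + par[3] * x)
  if (any(!is.finite(h)) || any(h <= 0)) return(1e12)
  q <- -expm1(-h)
  ll <- sum(ifelse(d > 0, d * log(q), 0) + (n - d) * (-h))
  if (!is.finite(ll)) return(1e12)
  -ll
}

# The Makeham floor gamma0 trades off against the Gompertz term along a flat
# ridge, so a single quasi-Newton run can stall in a side basin. The fit
# therefore profiles the likelihood over a gamma0 grid (inner 2-parameter
# fits for alpha, beta from a log-linear start) and polishes the best
# profile point with a full 3-parameter run; deterministic throughout.
gm_tail_fit <- function(counts, config) {
  d <- counts$deaths[3:10]
  n <- counts$entrants[3:10]
  x <- gm_day_midpoints()
  if (sum(d) == 0) {
    return(list(par = c(gamma0 = 0, alpha = -Inf, beta = 0), q = rep(0, 8),
                converged = TRUE, zero_tail = TRUE, trace = NULL))
  }
  # observed per-day cumulative hazards, floored for empty days
  q_obs <- pmin(d / pmax(n, 1), 0.99)
  h_obs <- pmax(-log(1 - q_obs), 0.25 / pmax(n, 1))
  ctrl <- list(maxit = config$max_iterations,
               factr = config$tol / .Machine$double.eps)

  inner_fit <- function(g0) {
    resid <- pmax(h_obs - g0, min(h_obs) * 1e-4)
    start <- stats::lm.fit(cbind(1, x), log(resid))$coefficients
    fit <- tryCatch(
      stats::optim(
        c(start[1], start[2]),
        function(ab) gm_tail_negll(c(g0, ab), d, n, x),
        method = "L-BFGS-B", lower = c(-40, -10), upper = c(5, 10),
        control = ctrl
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    list(par = c(g0, fit$par), value = fit$value,
         convergence = fit$convergence)
  }

  g0_grid <- unique(c(0, seq(0, max(h_obs), length.out =
                               max(11, 7 * config$restarts))))
  profile <- Filter(Negate(is.null), lapply(g0_grid, inner_fit))
  if (length(profile) == 0) {
    stop("Gompertz-Makeham tail fit failed at every profile point")
  }
  values <- vapply(profile, function(p) p$value, numeric(1))
  best <- profile[[which.min(values)]]

  polish <- tryCatch(
    stats::optim(
      best$par, gm_tail_negll, d = d, n = n, x = x,
      method = "L-BFGS-B", lower = c(0, -40, -10), upper = c(1, 5, 10),
      control = ctrl
    ),
    error = function(e) NULL
  )
  trace <- list(
    profile = data.frame(gamma0 = vapply(profile, function(p) p$par[1],
                                         numeric(1)),
                         loglik = -values),
    polish = if (!is.null(polish)) list(value = -polish$value,
                                        convergence = polish$convergence)
  )
  if (!is.null(polish) && polish$convergence == 0 &&
      polish$value <= best$value) {
    par <- polish$par
    converged <- TRUE
  } else {
    par <- best$par
    converged <- best$convergence == 0
  }
  if (!converged) {
    stop("Gompertz-Makeham tail fit did not converge; best log-likelihood ",
         format(-min(values)), " over ", length(profile), " profile points")
  }
  names(par) <- c("gamma0", "alpha", "beta")
  h <- par[1] + exp(par[2] + par[3] * x)
  list(par = par, q = -expm1(-h), converged = converged, zero_tail = FALSE,
       trace = trace)
}

#' Fit the modified Gompertz-Makeham adjustment model
#'
#' Maximizes the interval-censored cloglog likelihood with linear predictor
#' `gamma_1` for the stillbirth interval, `gamma_2` for days 0-1, and a smooth
#' hazard `h_j = gamma_0 + exp(alpha + beta * x_j)` (Makeham constant plus
#' Gompertz log-linear decline on the day midpoints x = 2.5 .. 9.5) for single
#' days 2-9. The smooth tail redistributes deaths heaped on day 7.
#'
#' For models 2 and 4, when the quality report's stillbirth trigger fires, the
#' constraint `gamma_1 = gamma_2 + log(constraint_constant)` is enforced
#' exactly by substitution. The observed stillbirth count is then treated as
#' unreliable (it is what the adjustment replaces), so the stillbirth interval
#' is excluded from estimation and `gamma_2` is fitted from the neonatal data;
#' the reported log-likelihood is still evaluated over the full table at the
#' fitted parameters. When the constraint is requested but the trigger is
#' false, it is skipped (and recorded).
#'
#' Models 3 and 4 expect `counts` to be the weighted table from
#' [apply_d01_weighting()]; model 1 delegates to
#' [fit_piecewise_exponential()].
#'
#' @param counts An [interval_counts()] object (weighted for models 3/4).
#' @param config An [adjust_config()] object; `config$model` selects the
#'   model.
#' @param quality A [quality_report()] for `counts`; computed on the fly when
#'   `NULL`. Models 2/4 read the stillbirth trigger from it.
#' @return An object of class `gm_fit` with components `coefficients`
#'   (`gamma1`, `gamma2`, `gamma0`, `alpha`, `beta`), `constraint_requested`,
#'   `constraint_active`, `d01_weight`, `loglik`, `lifetable` (fitted),
#'   `expected_deaths`, `fitted_heaping`, `convergence`, and `flags`.
#' @export
fit_gm <- function(counts, config = adjust_config(), quality = NULL) {
  validate_interval_counts(counts)
  if (config$model == 1) {
    pwe <- fit_piecewise_exponential(
      counts, interior_censoring = config$interior_censoring)
    return(pwe_as_gm_fit(pwe, counts, config))
  }
  if (is.null(quality)) {
    quality <- quality_report(
      counts,
      constraint_constant = config$constraint_constant,
      weight_constant = config$weight_constant
    )
  }
  d <- counts$deaths
  n <- counts$entrants
  if (n[1] <= 0) stop("no pregnancies at risk")

  constraint_requested <- config$model %in% c(2L, 4L)
  constraint_active <- constraint_requested && isTRUE(quality$triggers$sb_constraint)
  flags <- character(0)
  if (constraint_requested && !constraint_active) {
    flags <- c(flags, "constraint requested but trigger false; skipped")
  }

  q2 <- d[2] / n[2]
  gamma2 <- if (q2 > 0) cloglog(q2) else -Inf
  if (q2 == 0) flags <- c(flags, "zero D0-1 deaths: gamma2 = -Inf sentinel")
  if (constraint_active) {
    if (q2 == 0) {
      stop("stillbirth constraint undefined: no deaths on days 0-1")
    }
    gamma1 <- gamma2 + log(config$constraint_constant)
    q1 <- inv_cloglog(gamma1)
  } else {
    q1 <- d[1] / n[1]
    gamma1 <- if (q1 > 0) cloglog(q1) else -Inf
    if (q1 == 0) flags <- c(flags, "zero stillbirths: gamma1 = -Inf sentinel")
  }

  tail <- gm_tail_fit(counts, config)
  if (tail$zero_tail) flags <- c(flags, "no deaths on days 2-9: flat zero tail")

  q <- c(q1, q2, tail$q)
  lt <- new_life_table(counts, q, source = paste0("model", config$model))
  ed <- expected_deaths(q, counts)
  fit <- structure(
    list(
      coefficients = c(gamma1 = unname(gamma1), gamma2 = unname(gamma2),
                       tail$par),
      constraint_requested = constraint_requested,
      constraint_active = constraint_active,
      d01_weight = attr(counts, "effective_weight_d01"),
      loglik = interval_loglik(q, counts),
      lifetable = lt,
      expected_deaths = ed,
      fitted_heaping = if (sum(ed[6:10]) > 0) heaping_index(ed[6:10])
                       else NA_real_,
      convergence = list(converged = tail$converged, trace = tail$trace),
      flags = flags,
      model = config$model,
      config = config
    ),
    class = "gm_fit"
  )
  fit
}

# model 1 wrapped in the common fit container
pwe_as_gm_fit <- function(pwe, counts, config) {
  q <- pwe$lifetable$q
  ed <- expected_deaths(q, counts)
  structure(
    list(
      coefficients = c(gamma1 = unname(pwe$gamma[1]),
                       gamma2 = unname(pwe$gamma[2]),
                       gamma0 = NA_real_, alpha = NA_real_, beta = NA_real_),
      gamma = pwe$gamma,
      constraint_requested = FALSE,
      constraint_active = FALSE,
      d01_weight = attr(counts, "effective_weight_d01"),
      loglik = pwe$loglik,
      lifetable = pwe$lifetable,
      expected_deaths = ed,
      fitted_heaping = if (sum(ed[6:10]) > 0) heaping_index(ed[6:10])
                       else NA_real_,
      convergence = list(converged = TRUE, trace = NULL),
      flags = if (length(pwe$zero_intervals) > 0) {
        paste("zero-death intervals:",
              paste(pwe$zero_intervals, collapse = ", "))
      } else character(0),
      model = 1L,
      config = config
    ),
    class = "gm_fit"
  )
}

# expected deaths under fitted risks, propagating the fitted cohort through
# the observed interim censoring; day-10 censoring absorbs the remainder
expected_deaths <- function(q, counts) {
  n_hat <- numeric(10)
  d_hat <- numeric(10)
  n_hat[1] <- counts$entrants[1]
  for (j in 1:10) {
    d_hat[j] <- q[j] * n_hat[j]
    if (j < 10) n_hat[j + 1] <- max(n_hat[j] - d_hat[j] - counts$censored[j], 0)
  }
  stats::setNames(d_hat, interval_labels())
}

#' Fitted stillbirth-to-D0-1 hazard ratio of a Gompertz-Makeham fit
#'
#' The ratio of the fitted cumulative hazards of the stillbirth interval and
#' the pooled days 0-1, `exp(gamma1 - gamma2)`. Under an active constraint
#' this equals the reference constant exactly, by construction.
#'
#' @param fit A `gm_fit` object.
#' @return A numeric scalar.
#' @export
fitted_sb_ratio <- function(fit) {
  stopifnot(inherits(fit, "gm_fit"))
  unname(exp(fit$coefficients[["gamma1"]] - fit$coefficients[["gamma2"]]))
}

#' @export
print.gm_fit <- function(x, ...) {
  cat("Modified Gompertz-Makeham fit (model ", x$model, ")\n", sep = "")
  print(signif(x$coefficients, 5))
  if (x$constraint_requested) {
    cat("stillbirth constraint:",
        if (x$constraint_active) "active (gamma1 = gamma2 + log C)"
        else "requested but not triggered", "\n")
  }
  if (!is.null(x$d01_weight) && x$d01_weight != 1) {
    cat("D0-1 effective weight:", format(x$d01_weight, digits = 4), "\n")
  }
  cat("log-likelihood:", format(x$loglik), "\n")
  cat("fitted day-7 heaping index:",
      if (is.na(x$fitted_heaping)) "undefined"
      else format(x$fitted_heaping, digits = 3), "\n")
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.gm_fit <- function(object, ...) object$coefficients

#' @export
logLik.gm_fit <- function(object, ...) {
  df <- if (object$model == 1) sum(is.finite(object$gamma)) else {
    if (object$constraint_active) 4 else 5
  }
  structure(object$loglik, df = df, class = "logLik")
}

#' @export
fitted.gm_fit <- function(object, ...) object$lifetable

#' @export
residuals.gm_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  lt <- object$lifetable
  d <- lt$deaths
  n <- lt$entrants
  d_hat <- n * lt$q
  if (type == "response") {
    return(stats::setNames(d - d_hat, interval_labels()))
  }
  term <- function(obs, exp) ifelse(obs > 0, obs * log(obs / exp), 0)
  dev <- 2 * (term(d, pmax(d_hat, 1e-300)) +
                term(n - d, pmax(n - d_hat, 1e-300)))
  stats::setNames(sign(d - d_hat) * sqrt(pmax(dev, 0)), interval_labels())
}
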