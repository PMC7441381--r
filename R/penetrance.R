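#' Fit a Cox proportional-hazards model on the age scale
#'
#' Cox partial-likelihood fit with age as the time-scale: time-to-event is
#' the age at diagnosis for cases and the age at last follow-up for
#' censored individuals, with all subjects at risk from birth unless an
#' `entry` age is supplied (left truncation). Ties are handled by the
#' Breslow method by default (ages recorded in whole years produce heavy
#' ties); the Breslow estimator provides the baseline cumulative hazard.
#'
#' @param time positive event/censoring ages.
#' @param event 0/1 event indicator (at least one event required).
#' @param covariates data frame of numeric covariates (e.g. `carrier`,
#'   `z`, sex coded 0/1, PCs).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param entry optional entry ages for left-truncated risk sets.
#' @return an object of class `cox_penetrance_fit`: list with the
#'   underlying `coxph` fit, `coefficients`, `vcov`, the Breslow baseline
#'   cumulative hazard (`basehaz`, a step function data frame for the
#'   covariate-zero profile), `covariate_means` and `n_events`.
#' @export
fit_cox <- function(time, event, covariates, ties = c("breslow", "efron"),
                    entry = NULL) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates),
            nrow(covariates) %in% c(0L, length(time)),
            length(event) == length(time))
  if (any(time <= 0)) stop("event/censoring times must be positive")
  if (sum(event) < 1) stop("no events; Cox model not estimable")
  if (anyNA(time) || anyNA(event) || anyNA(covariates))
    stop("missing values in survival data")
  null_model <- ncol(covariates) == 0L
  dat <- data.frame(.time = time, .event = as.integer(event))
  if (!null_model) dat <- cbind(dat, covariates)
  monotone <- FALSE
  if (is.null(entry)) {
    fml <- if (null_model) survival::Surv(.time, .event) ~ 1
           else survival::Surv(.time, .event) ~ .
  } else {
    dat$.entry <- entry
    fml <- if (null_model) survival::Surv(.entry, .time, .event) ~ 1
           else survival::Surv(.entry, .time, .event) ~ . - .entry
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties, x = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  bh <- survival::basehaz(fit, centered = FALSE)
  cm <- if (null_model) setNames(numeric(0), character(0))
        else colMeans(fit$x)
  structure(list(coxph = fit, coefficients = coef(fit),
                 vcov = if (null_model) NULL else vcov(fit),
                 basehaz = bh,
                 covariate_means = cm,
                 n_events = sum(event), ties = ties,
                 max_time = max(time), monotone_likelihood = monotone),
            class = "cox_penetrance_fit")
}

#' @export
print.cox_penetrance_fit <- function(x, ...) {
  cat(sprintf("Cox fit (age time-scale, %s ties): %d events%s\n", x$ties,
              x$n_events,
              if (x$monotone_likelihood) " [monotone likelihood]" else ""))
  print(exp(x$coefficients))
  invisible(x)
}

#' Baseline cumulative hazard at a set of ages
#'
#' Breslow step-function baseline cumulative hazard of a
#' [fit_cox()] model, evaluated for the covariate-zero profile.
#'
#' @param fit a [fit_cox()] result.
#' @param t ages at which to evaluate.
#' @return numeric vector `H0(t)`.
#' @export
baseline_cumhaz <- function(fit, t) {
  stopifnot(inherits(fit, "cox_penetrance_fit"))
  sf <- stats::stepfun(fit$basehaz$time, c(0, fit$basehaz$hazard))
  sf(t)
}

#' Cumulative incidence (penetrance) at an age for a covariate profile
#'
#' `F(t) = 1 - S(t)` with `S(t) = exp(-H0(t) * exp(x'beta))`, evaluated by
#' [survival::survfit()] on the fitted model; the 95% interval uses the
#' log(-log S) transform. Unspecified covariates are held at their means.
#'
#' @param fit a [fit_cox()] result.
#' @param profile named list/vector of covariate values (e.g.
#'   `list(carrier = 1, z = 1.3)`); omitted covariates take their sample
#'   means.
#' @param t horizon age (default 75); a horizon beyond the observed
#'   follow-up triggers an extrapolation warning and uses the last
#'   estimate.
#' @return data frame with `t`, `F`, `ci_low`, `ci_high`.
#' @export
cumulative_incidence_at <- function(fit, profile = list(), t = 75) {
  stopifnot(inherits(fit, "cox_penetrance_fit"), length(t) == 1L, t >= 0)
  nd <- as.list(fit$covariate_means)
  for (nm in names(profile)) {
    if (!nm %in% names(nd))
      stop("unknown covariate in profile: ", nm)
    nd[[nm]] <- profile[[nm]]
  }
  if (t > fit$max_time)
    warning(sprintf(
      "horizon %.1f exceeds observed follow-up %.1f; using last estimate",
      t, fit$max_time))
  if (t < min(fit$basehaz$time[fit$basehaz$hazard > 0]))
    return(data.frame(t = t, F = 0, ci_low = 0, ci_high = 0))
  sf <- if (length(nd) == 0L)
    survival::survfit(fit$coxph, conf.type = "log-log")
  else
    survival::survfit(fit$coxph, newdata = as.data.frame(nd),
                      conf.type = "log-log")
  sm <- summary(sf, times = min(t, fit$max_time), extend = TRUE)
  data.frame(t = t, F = 1 - sm$surv[1],
             ci_low = 1 - sm$upper[1], ci_high = 1 - sm$lower[1])
}

#' Penetrance curve across score percentiles
#'
#' Cumulative incidence by age `t` for carriers and noncarriers at every
#' score percentile, other covariates at their means.
#'
#' @param fit a [fit_cox()] result whose covariates include `carrier` and
#'   `z` (names configurable).
#' @param z_map numeric vector of length 100 mapping percentile to score
#'   value in SD units (e.g. the `z_map` attribute of
#'   [percentile_or_curve()], or percentile bin means).
#' @param t horizon age.
#' @param carrier_var,z_var covariate names for carrier status and score.
#' @return data frame of class `penetrance_curve`: `percentile`,
#'   `carrier`, `F`, `ci_low`, `ci_high`.
#' @export
penetrance_curve <- function(fit, z_map, t = 75,
                             carrier_var = "carrier", z_var = "z") {
  stopifnot(inherits(fit, "cox_penetrance_fit"), length(z_map) == 100L)
  stopifnot(all(c(carrier_var, z_var) %in% names(fit$covariate_means)))
  grid <- expand.grid(percentile = 1:100, carrier = c(0L, 1L))
  nd <- as.data.frame(lapply(fit$covariate_means, rep, nrow(grid)))
  nd[[carrier_var]] <- grid$carrier
  nd[[z_var]] <- z_map[grid$percentile]
  if (t > fit$max_time)
    warning(sprintf(
      "horizon %.1f exceeds observed follow-up %.1f; using last estimate",
      t, fit$max_time))
  sf <- survival::survfit(fit$coxph, newdata = nd, conf.type = "log-log")
  sm <- summary(sf, times = min(t, fit$max_time), extend = TRUE)
  out <- data.frame(percentile = grid$percentile, carrier = grid$carrier,
                    F = 1 - as.numeric(sm$surv),
                    ci_low = 1 - as.numeric(sm$upper),
                    ci_high = 1 - as.numeric(sm$lower))
  class(out) <- c("penetrance_curve", "data.frame")
  out
}
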