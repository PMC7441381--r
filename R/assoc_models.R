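#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()],
#' coefficient tolerance 1e-8, at most 100 iterations) with explicit
#' convergence and separation status. Wald confidence intervals are
#' `exp(beta +/- z_{0.975} * SE)`.
#'
#' @param outcome binary 0/1 vector with both classes present.
#' @param predictors data frame of predictors (factors allowed); the model
#'   is `outcome ~ .`.
#' @return an object of class `logistic_fit`: list with `coefficients`
#'   (log-odds scale), `vcov`, `loglik`, `n`, `converged`, `separation`
#'   and the underlying `glm` object.
#' @export
fit_logistic <- function(outcome, predictors) {
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(outcome))
  if (anyNA(outcome) || anyNA(predictors))
    stop("missing values in outcome or predictors")
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; model not estimable")
  dat <- cbind(data.frame(.y = y), predictors)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sep <- sep || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  structure(list(coefficients = coef(fit), vcov = vcov(fit),
                 loglik = as.numeric(logLik(fit)), n = length(y),
                 converged = fit$converged, separation = sep, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n=%d, loglik=%.2f, converged=%s%s\n", x$n,
              x$loglik, x$converged,
              if (x$separation) " [separation detected]" else ""))
  print(or_table(x))
  invisible(x)
}

#' Odds-ratio table from a logistic fit
#'
#' @param fit a [fit_logistic()] result.
#' @param conf_level confidence level for Wald intervals.
#' @return data frame with `term`, `or`, `ci_low`, `ci_high`, `p` for every
#'   non-intercept coefficient.
#' @export
or_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  keep <- names(b) != "(Intercept)"
  data.frame(term = names(b)[keep],
             or = exp(b[keep]),
             ci_low = exp(b[keep] - zc * se[keep]),
             ci_high = exp(b[keep] + zc * se[keep]),
             p = 2 * pnorm(-abs(b[keep] / se[keep])),
             row.names = NULL)
}

#' Stratify score percentiles into low / intermediate / high
#'
#' Low is the lowest quintile (percentile <= 20), intermediate the middle
#' three quintiles (21-80), high the top quintile (>= 81).
#'
#' @param percentiles integer percentiles in `1:100`.
#' @return factor with ordered levels `low`, `intermediate`, `high`.
#' @export
stratify_scores <- function(percentiles) {
  stopifnot(all(percentiles >= 1 & percentiles <= 100))
  factor(ifelse(percentiles <= 20, "low",
                ifelse(percentiles <= 80, "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Six-level carrier-by-score-stratum odds ratios
#'
#' Single logistic fit with a six-level indicator (2 carrier states x 3
#' score strata) plus covariates; noncarriers with intermediate score are
#' the reference (odds ratio fixed at 1 with a degenerate interval).
#' Levels with no observations are reported as not estimable.
#'
#' @param outcome binary disease vector.
#' @param carrier 0/1 carrier status.
#' @param stratum score stratum from [stratify_scores()].
#' @param covariates optional data frame of adjustment covariates.
#' @return data frame with one row per level: `carrier`, `stratum`, `n`,
#'   `n_cases`, `estimable`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
six_level_or <- function(outcome, carrier, stratum, covariates = NULL) {
  stopifnot(length(outcome) == length(carrier),
            length(outcome) == length(stratum))
  lvl <- paste(ifelse(carrier == 1, "carrier", "noncarrier"),
               as.character(stratum), sep = ".")
  all_levels <- as.vector(outer(c("noncarrier", "carrier"),
                                c("low", "intermediate", "high"),
                                paste, sep = "."))
  group <- factor(lvl, levels = c("noncarrier.intermediate",
                                  setdiff(all_levels,
                                          "noncarrier.intermediate")))
  present <- levels(group)[tabulate(group, nbins = nlevels(group)) > 0]
  dat <- data.frame(group = droplevels(group))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- fit_logistic(outcome, dat)
  tab <- or_table(fit)
  zc <- qnorm(0.975)
  out <- do.call(rbind, lapply(all_levels, function(lv) {
    parts <- strsplit(lv, ".", fixed = TRUE)[[1]]
    n_lv <- sum(lvl == lv)
    row <- data.frame(carrier = as.integer(parts[1] == "carrier"),
                      stratum = parts[2], n = n_lv,
                      n_cases = sum(outcome[lvl == lv]),
                      estimable = TRUE, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_)
    if (lv == "noncarrier.intermediate") {
      row$or <- 1; row$ci_low <- 1; row$ci_high <- 1
    } else if (n_lv == 0 || !(lv %in% present)) {
      row$estimable <- FALSE
    } else {
      tr <- tab[tab$term == paste0("group", lv), ]
      row$or <- tr$or; row$ci_low <- tr$ci_low; row$ci_high <- tr$ci_high
      row$p <- tr$p
    }
    row
  }))
  out$stratum <- factor(out$stratum, levels = c("low", "intermediate", "high"))
  attr(out, "fit") <- fit
  out
}

#' Odds ratio per score SD, separately in carriers and noncarriers
#'
#' Two independent logistic fits of disease on the standardized score plus
#' covariates, restricted to each carrier stratum. A stratum with fewer
#' than 10 events carries a warning.
#'
#' @param outcome binary disease vector.
#' @param z standardized (corrected) score.
#' @param carrier 0/1 carrier status.
#' @param covariates optional data frame of adjustment covariates.
#' @return data frame with one row per stratum: `stratum`, `n`, `n_events`,
#'   `or_per_sd`, `ci_low`, `ci_high`, `p`.
#' @export
or_per_sd_by_stratum <- function(outcome, z, carrier, covariates = NULL) {
  stopifnot(length(outcome) == length(z), length(outcome) == length(carrier))
  if (sum(carrier == 1) == 0 || sum(carrier == 0) == 0)
    stop("both carrier strata must be non-empty")
  res <- lapply(c(noncarrier = 0, carrier = 1), function(cs) {
    idx <- carrier == cs
    nev <- sum(outcome[idx])
    if (nev < 10)
      warning(sprintf("stratum carrier=%d has only %d events", cs, nev))
    dat <- data.frame(z = z[idx])
    if (!is.null(covariates)) dat <- cbind(dat, covariates[idx, , drop = FALSE])
    fit <- fit_logistic(outcome[idx], dat)
    tr <- or_table(fit); tr <- tr[tr$term == "z", ]
    data.frame(n = sum(idx), n_events = nev, or_per_sd = tr$or,
               ci_low = tr$ci_low, ci_high = tr$ci_high, p = tr$p)
  })
  out <- cbind(stratum = names(res), do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Wald test for score-by-carrier interaction
#'
#' Logistic fit with main effects, covariates and the score-by-carrier
#' product term; returns the two-sided Wald p-value on the product
#' coefficient.
#'
#' @inheritParams or_per_sd_by_stratum
#' @return list with `p_interaction`, `estimate` (log odds-ratio
#'   difference per SD), `se`, and the full `fit`.
#' @export
interaction_test <- function(outcome, z, carrier, covariates = NULL) {
  dat <- data.frame(z = z, carrier = carrier, zxcarrier = z * carrier)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- fit_logistic(outcome, dat)
  est <- fit$coefficients["zxcarrier"]
  se <- sqrt(fit$vcov["zxcarrier", "zxcarrier"])
  list(p_interaction = as.numeric(2 * pnorm(-abs(est / se))),
       estimate = as.numeric(est), se = as.numeric(se), fit = fit)
}

#' Predicted odds-ratio curve across score percentiles
#'
#' Fits disease on carrier status and standardized score (optionally their
#' product) plus covariates, then predicts the odds ratio at every
#' percentile for carriers and noncarriers, referenced to noncarriers at
#' the median percentile with covariates held at their means. The score
#' value for percentile `p` is the empirical mean of `z` within the
#' percentile bin (empty bins are interpolated, with a warning).
#' Confidence intervals use the delta method on the coefficient
#' covariance.
#'
#' @inheritParams or_per_sd_by_stratum
#' @param percentiles integer percentiles per individual (default: from
#'   [percentile_map()] applied to `z`).
#' @param interaction include the score-by-carrier product term (default
#'   `FALSE`: additive model).
#' @param ref_percentile reference percentile (default 50).
#' @return data frame of class `percentile_or_curve`: `percentile`,
#'   `carrier`, `or`, `ci_low`, `ci_high`; the underlying fit is in
#'   attribute `fit`.
#' @export
percentile_or_curve <- function(outcome, z, carrier, covariates = NULL,
                                percentiles = percentile_map(z),
                                interaction = FALSE, ref_percentile = 50L) {
  stopifnot(length(outcome) == length(z), length(z) == length(percentiles))
  dat <- data.frame(carrier = carrier, z = z)
  if (interaction) dat$zxcarrier <- z * carrier
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- fit_logistic(outcome, dat)
  if (!fit$converged) stop("percentile curve requires a converged fit")

  zbar <- tapply(z, factor(percentiles, levels = 1:100), mean)
  if (anyNA(zbar)) {
    warning(sprintf("%d empty percentile bins interpolated", sum(is.na(zbar))))
    ok <- which(!is.na(zbar))
    zbar <- approx(ok, zbar[ok], xout = 1:100, rule = 2)$y
  }
  z_ref <- zbar[ref_percentile]

  b <- fit$coefficients
  V <- fit$vcov
  terms <- c("carrier", "z", if (interaction) "zxcarrier")
  bb <- b[terms]
  VV <- V[terms, terms, drop = FALSE]
  zc <- qnorm(0.975)
  grid <- expand.grid(percentile = 1:100, carrier = c(0L, 1L))
  grad <- cbind(grid$carrier, zbar[grid$percentile] - z_ref)
  if (interaction) grad <- cbind(grad, grid$carrier * zbar[grid$percentile])
  delta <- drop(grad %*% bb)
  sds <- sqrt(rowSums((grad %*% VV) * grad))
  out <- data.frame(percentile = grid$percentile, carrier = grid$carrier,
                    or = exp(delta), ci_low = exp(delta - zc * sds),
                    ci_high = exp(delta + zc * sds))
  attr(out, "fit") <- fit
  attr(out, "z_map") <- zbar
  class(out) <- c("percentile_or_curve", "data.frame")
  out
}

#' Likelihood-ratio test of score linearity
#'
#' Compares a logistic model with the corrected score as a single linear
#' term against a cubic polynomial model (adds square and cube),
#' `LRT = 2 * (loglik_cubic - loglik_linear)` on 2 degrees of freedom.
#'
#' @param outcome binary disease vector.
#' @param score corrected polygenic score.
#' @param covariates optional data frame of adjustment covariates.
#' @return list with `statistic`, `df`, `p`, and both fits.
#' @export
linearity_lrt <- function(outcome, score, covariates = NULL) {
  d1 <- data.frame(score = score)
  d2 <- data.frame(score = score, score2 = score^2, score3 = score^3)
  if (!is.null(covariates)) {
    d1 <- cbind(d1, covariates); d2 <- cbind(d2, covariates)
  }
  f1 <- fit_logistic(outcome, d1)
  f2 <- fit_logistic(outcome, d2)
  if (!f1$converged || !f2$converged)
    stop("linearity test requires both models to converge")
  stat <- max(0, 2 * (f2$loglik - f1$loglik))
  list(statistic = stat, df = 2L, p = pchisq(stat, df = 2, lower.tail = FALSE),
       fit_linear = f1, fit_cubic = f2)
}

#' Observed-versus-expected calibration table
#'
#' Hosmer-Lemeshow-style comparison of mean predicted probability and
#' observed event fraction in percentile bins (default 20 bins of 5
#' percentiles each).
#'
#' @param predicted fitted probabilities.
#' @param percentiles integer score percentiles per individual.
#' @param outcome binary disease vector.
#' @param n_bins number of percentile bins (must divide 100).
#' @return data frame with `bin`, `percentile_low`, `percentile_high`,
#'   `n`, `expected` (mean predicted), `observed` (event fraction).
#' @export
calibration_table <- function(predicted, percentiles, outcome, n_bins = 20L) {
  stopifnot(length(predicted) == length(percentiles),
            length(predicted) == length(outcome), 100 %% n_bins == 0)
  width <- 100 %/% n_bins
  bin <- ceiling(percentiles / width)
  out <- data.frame(bin = seq_len(n_bins),
                    percentile_low = (seq_len(n_bins) - 1L) * width + 1L,
                    percentile_high = seq_len(n_bins) * width)
  agg <- function(x) vapply(seq_len(n_bins), function(b) {
    i <- bin == b
    if (any(i)) mean(x[i]) else NA_real_
  }, 1)
  out$n <- vapply(seq_len(n_bins), function(b) sum(bin == b), 1L)
  out$expected <- agg(predicted)
  out$observed <- agg(as.numeric(outcome))
  out
}
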