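#' Define a retrospective power scenario
#'
#' Describes a case-control study for retrospective power analysis of the
#' polygenic-score-by-carrier interaction test. The study size, case total,
#' carrier count and the noncarrier score effect are held at their observed
#' values; the carrier score effect is the quantity varied by
#' [interaction_power()] and [detectable_or_bounds()]. Simulated phenotypes
#' are assigned by conditional-Bernoulli sampling so that every replicate
#' reproduces the observed case total exactly.
#'
#' The carrier-status association with disease is part of the observed
#' design because it sets the case fraction among carriers, which drives
#' the information available for the carrier score slope. It can be given
#' directly as `carrier_disease_or`, or derived from the observed carrier
#' case count via the unadjusted 2x2 odds ratio.
#'
#' @param n_individuals total study size.
#' @param n_cases observed number of cases (held fixed in every replicate).
#' @param n_carriers observed number of monogenic variant carriers.
#' @param noncarrier_or_per_sd observed odds ratio per SD of the score in
#'   noncarriers (the null value for the carrier effect).
#' @param n_carrier_cases observed carrier count among cases; used to derive
#'   `carrier_disease_or` when that is not supplied.
#' @param carrier_disease_or odds ratio of disease for carrier status in the
#'   generating model (default: unadjusted 2x2 OR from `n_carrier_cases`,
#'   or 1 when neither is given).
#' @param alpha two-sided test level.
#' @param target_power power at which detectable bounds are located.
#' @param n_reps Monte-Carlo replicates per evaluated carrier effect size.
#' @param carrier_score `"normal"` draws carrier scores standard normal like
#'   noncarriers; `"supplied"` recycles `carrier_score_values`.
#' @param carrier_score_values numeric vector of carrier scores (SD units)
#'   used when `carrier_score = "supplied"`.
#' @return an object of class `power_scenario`.
#' @seealso [cad_power_scenario()], [bc_power_scenario()]
#' @export
power_scenario <- function(n_individuals, n_cases, n_carriers,
                           noncarrier_or_per_sd,
                           n_carrier_cases = NULL,
                           carrier_disease_or = NULL,
                           alpha = 0.05, target_power = 0.80,
                           n_reps = 500L,
                           carrier_score = c("normal", "supplied"),
                           carrier_score_values = NULL) {
  carrier_score <- match.arg(carrier_score)
  stopifnot(n_individuals > 0, n_cases > 0, n_cases < n_individuals,
            n_carriers >= 1, noncarrier_or_per_sd > 0,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            n_reps >= 1)
  if (is.null(carrier_disease_or)) {
    if (!is.null(n_carrier_cases)) {
      a <- n_carrier_cases
      b <- n_carriers - a
      cc <- n_cases - a
      d <- (n_individuals - n_cases) - b
      stopifnot(a >= 0, b >= 0, cc > 0, d > 0)
      carrier_disease_or <- if (b == 0) Inf else (a * d) / (b * cc)
    } else {
      carrier_disease_or <- 1
    }
  }
  if (carrier_score == "supplied" && is.null(carrier_score_values))
    stop("carrier_score_values required when carrier_score = \"supplied\"")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_cases = as.integer(n_cases),
    n_carriers = as.integer(n_carriers),
    noncarrier_or_per_sd = noncarrier_or_per_sd,
    carrier_disease_or = carrier_disease_or,
    alpha = alpha, target_power = target_power,
    n_reps = as.integer(n_reps),
    carrier_score = carrier_score,
    carrier_score_values = carrier_score_values),
    class = "power_scenario")
}

#' @export
print.power_scenario <- function(x, ...) {
  cat(sprintf(
    "Retrospective power scenario: n=%d, cases=%d (fixed), carriers=%d\n",
    x$n_individuals, x$n_cases, x$n_carriers))
  cat(sprintf(
    "  noncarrier OR/SD %.3f (null), carrier-disease OR %.3f, alpha %.3f, target power %.2f, %d reps\n",
    x$noncarrier_or_per_sd, x$carrier_disease_or, x$alpha, x$target_power,
    x$n_reps))
  invisible(x)
}

#' Coronary artery disease case-control power scenario
#'
#' The published coronary artery disease case-control design: 12,852
#' participants with 6,432 cases, 56 familial hypercholesterolemia variant
#' carriers (43 among cases), and a noncarrier odds ratio per SD of 1.74.
#'
#' @param n_reps replicates per grid point.
#' @return a [power_scenario()].
#' @export
cad_power_scenario <- function(n_reps = 500L) {
  power_scenario(n_individuals = 12852L, n_cases = 6432L, n_carriers = 56L,
                 noncarrier_or_per_sd = 1.74, n_carrier_cases = 43L,
                 n_reps = n_reps)
}

#' Breast cancer case-control power scenario
#'
#' The published breast cancer case-control design: 19,264 women with 1,920
#' cases, 845 BRCA1/2 variant carriers (174 among cases), and a noncarrier
#' odds ratio per SD of 1.57.
#'
#' @inheritParams cad_power_scenario
#' @return a [power_scenario()].
#' @export
bc_power_scenario <- function(n_reps = 500L) {
  power_scenario(n_individuals = 19264L, n_cases = 1920L, n_carriers = 845L,
                 noncarrier_or_per_sd = 1.57, n_carrier_cases = 174L,
                 n_reps = n_reps)
}

# Solve the model intercept so that the expected case count equals n_cases.
.calibrate_intercept <- function(eta, n_cases) {
  f <- function(a) sum(plogis(a + eta)) - n_cases
  r <- tryCatch(uniroot(f, lower = -45, upper = 45, tol = 1e-9),
                error = function(e) NULL)
  if (is.null(r))
    stop("intercept calibration failed: expected case count cannot reach n_cases")
  r$root
}

# Minimal logistic IRLS result for the interaction model; returns the Wald
# z statistic for the product term or NA when the fit is unusable.
.interaction_wald_z <- function(z, carrier, y) {
  X <- cbind(1, z, carrier, z * carrier)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  control = glm.control(epsilon = 1e-8,
                                                        maxit = 100)))
  if (!fit$converged) return(NA_real_)
  b <- fit$coefficients
  if (anyNA(b) || max(abs(b)) > 15) return(NA_real_)
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))),
                error = function(e) NULL)
  if (is.null(V)) return(NA_real_)
  se <- sqrt(V[4, 4])
  if (!is.finite(se) || se > 50) return(NA_real_)
  b[4] / se
}

#' Estimate interaction-test power at one carrier effect size
#'
#' Monte-Carlo power of the two-sided Wald test for the score-by-carrier
#' product term. Each replicate draws scores, computes case probabilities
#' from a logistic model with stratum-specific score effects and the
#' scenario's carrier-disease odds ratio, calibrates the intercept so the
#' expected case count matches the observed total, assigns phenotypes by
#' exact conditional-Bernoulli sampling with the case total fixed, and fits
#' the interaction model.
#'
#' @param scenario a [power_scenario()].
#' @param carrier_or odds ratio per SD of the score in carriers under the
#'   alternative being evaluated.
#' @param n_reps replicates (default: from the scenario).
#' @param seed integer master seed; per-replicate seeds are derived from it.
#' @return an object of class `power_estimate`: list with `power`, its
#'   Monte-Carlo standard error `mc_se`, replicate counts, and the number of
#'   replicates dropped for failed (separated/non-converged) fits.
#' @export
interaction_power <- function(scenario, carrier_or,
                              n_reps = scenario$n_reps, seed = 1L) {
  stopifnot(inherits(scenario, "power_scenario"), carrier_or > 0)
  n <- scenario$n_individuals
  m <- scenario$n_cases
  ncar <- scenario$n_carriers
  b_nc <- log(scenario$noncarrier_or_per_sd)
  b_c <- log(carrier_or)
  g <- log(scenario$carrier_disease_or)
  zcrit <- qnorm(1 - scenario$alpha / 2)
  carrier <- c(rep(1, ncar), rep(0, n - ncar))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  n_reject <- 0L; n_used <- 0L; n_failed <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    z <- rnorm(n)
    if (scenario$carrier_score == "supplied")
      z[seq_len(ncar)] <- rep_len(sample(scenario$carrier_score_values), ncar)
    eta <- g * carrier + ifelse(carrier == 1, b_c, b_nc) * z
    a <- .calibrate_intercept(eta, m)
    p <- plogis(a + eta)
    y <- rcond_bernoulli(p, m, ndraws = 1L)[1L, ]
    wz <- .interaction_wald_z(z, carrier, y)
    if (is.na(wz)) { n_failed <- n_failed + 1L; next }
    n_used <- n_used + 1L
    if (abs(wz) > zcrit) n_reject <- n_reject + 1L
  }
  if (n_used == 0L) stop("all replicates failed to fit")
  pw <- n_reject / n_used
  structure(list(power = pw,
                 mc_se = sqrt(pw * (1 - pw) / n_used),
                 carrier_or = carrier_or,
                 n_reps = n_reps, n_used = n_used, n_failed = n_failed,
                 alpha = scenario$alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power %.3f (MC SE %.3f) at carrier OR/SD %.3f [%d/%d reps used]\n",
              x$power, x$mc_se, x$carrier_or, x$n_used, x$n_reps))
  invisible(x)
}

#' Deterministic normal-approximation power for the interaction test
#'
#' Expected-information approximation used to seed the bisection bracket in
#' [detectable_or_bounds()]: the 4x4 Fisher information of the interaction
#' model is averaged over a deterministic normal score grid, the intercept
#' is calibrated to the scenario case fraction, and power is the normal
#' upper-tail mass of the Wald statistic.
#'
#' @inheritParams interaction_power
#' @param grid_size number of deterministic score quantiles.
#' @return approximate power (numeric scalar).
#' @export
approx_interaction_power <- function(scenario, carrier_or, grid_size = 2001L) {
  stopifnot(inherits(scenario, "power_scenario"), carrier_or > 0)
  zq <- qnorm(ppoints(grid_size))
  b_nc <- log(scenario$noncarrier_or_per_sd)
  b_c <- log(carrier_or)
  g <- log(scenario$carrier_disease_or)
  n <- scenario$n_individuals; ncar <- scenario$n_carriers
  f <- function(a) {
    (n - ncar) * mean(plogis(a + b_nc * zq)) +
      ncar * mean(plogis(a + g + b_c * zq)) - scenario$n_cases
  }
  a <- uniroot(f, lower = -45, upper = 45, tol = 1e-9)$root
  info_block <- function(offset, slope, weight, car) {
    mu <- plogis(a + offset + slope * zq)
    w <- mu * (1 - mu)
    X <- cbind(1, zq, car, car * zq)
    weight * crossprod(X * sqrt(w)) / length(zq)
  }
  I <- info_block(0, b_nc, n - ncar, car = 0) +
    info_block(g, b_c, ncar, car = 1)
  V <- chol2inv(chol(I))
  se <- sqrt(V[4, 4])
  delta <- abs(b_c - b_nc)
  zcrit <- qnorm(1 - scenario$alpha / 2)
  pnorm(delta / se - zcrit) + pnorm(-delta / se - zcrit)
}

#' Detectable carrier odds-ratio bounds at target power
#'
#' Locates, on each side of the noncarrier null, the carrier odds ratio per
#' SD at which the interaction test attains the scenario's target power, by
#' monotone bisection on the log odds-ratio distance from the null. The
#' initial bracket comes from the deterministic information approximation
#' ([approx_interaction_power()]) and is expanded if it does not straddle
#' the target. Bisection stops when the bracket is narrower than `tol_or`
#' on the OR scale, or narrower than the Monte-Carlo positional uncertainty
#' of the power crossing (at which point further bisection fits noise); the
#' returned bound linearly interpolates the crossing within the final
#' bracket.
#'
#' @inheritParams interaction_power
#' @param side `"both"`, `"lower"` or `"upper"`.
#' @param tol_or absolute bracket-width stopping tolerance on the OR scale.
#' @param max_iter maximum bisection steps per side.
#' @param verbose print each power evaluation.
#' @return an object of class `detectable_or_bounds`: data frame with one
#'   row per side (`side`, `or`, `power_at_bound`, `mc_se`, `n_evals`),
#'   with the full evaluation log in attribute `"evaluations"`.
#' @export
detectable_or_bounds <- function(scenario, side = c("both", "lower", "upper"),
                                 seed = 1L, n_reps = scenario$n_reps,
                                 tol_or = 0.01, max_iter = 12L,
                                 verbose = FALSE) {
  side <- match.arg(side)
  sides <- if (side == "both") c("lower", "upper") else side
  null_log <- log(scenario$noncarrier_or_per_sd)
  target <- scenario$target_power

  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval_seeds <- sample.int(.Machine$integer.max - 1L, 64L)
  eval_i <- 0L
  log_rows <- list()

  eval_power <- function(s, delta) {
    eval_i <<- eval_i + 1L
    or <- exp(null_log + ifelse(s == "upper", 1, -1) * delta)
    pe <- interaction_power(scenario, or, n_reps = n_reps,
                            seed = eval_seeds[eval_i])
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(side = s, carrier_or = or, power = pe$power,
                 mc_se = pe$mc_se, n_used = pe$n_used)
    if (verbose)
      cat(sprintf("  [%s] OR %.4f -> power %.3f (se %.3f)\n",
                  s, or, pe$power, pe$mc_se))
    pe
  }

  res <- lapply(sides, function(s) {
    # bracket seeded by the deterministic approximation
    d0 <- tryCatch(uniroot(function(d) {
      or <- exp(null_log + ifelse(s == "upper", 1, -1) * d)
      approx_interaction_power(scenario, or) - target
    }, lower = 1e-4, upper = log(100), tol = 1e-5)$root,
    error = function(e) NA_real_)
    if (is.na(d0))
      return(data.frame(side = s, or = NA_real_, power_at_bound = NA_real_,
                        mc_se = NA_real_, n_evals = 0L))
    d_lo <- 0.55 * d0; d_hi <- 1.35 * d0
    p_lo <- eval_power(s, d_lo)
    for (k in 1:6) {
      if (p_lo$power < target) break
      d_hi <- d_lo; d_lo <- d_lo / 1.6
      p_lo <- eval_power(s, d_lo)
    }
    p_hi <- eval_power(s, d_hi)
    open <- FALSE
    for (k in 1:6) {
      if (p_hi$power >= target) break
      d_lo <- d_hi; p_lo <- p_hi
      d_hi <- d_hi * 1.6
      if (d_hi > log(200)) { open <- TRUE; break }
      p_hi <- eval_power(s, d_hi)
    }
    if (open || p_lo$power >= target || p_hi$power < target) {
      warning(sprintf("target power not bracketed on the %s side", s))
      return(data.frame(side = s, or = NA_real_, power_at_bound = NA_real_,
                        mc_se = NA_real_, n_evals = eval_i))
    }
    sgn <- ifelse(s == "upper", 1, -1)
    for (it in seq_len(max_iter)) {
      width_or <- abs(exp(null_log + sgn * d_hi) - exp(null_log + sgn * d_lo))
      slope <- abs(p_hi$power - p_lo$power) / (d_hi - d_lo)
      pos_se <- if (slope > 0) p_lo$mc_se / slope else Inf
      if (width_or < tol_or || (d_hi - d_lo) < pos_se) break
      d_mid <- (d_lo + d_hi) / 2
      p_mid <- eval_power(s, d_mid)
      if (p_mid$power < target) { d_lo <- d_mid; p_lo <- p_mid }
      else { d_hi <- d_mid; p_hi <- p_mid }
    }
    # linear interpolation of the crossing inside the final bracket
    frac <- if (p_hi$power > p_lo$power)
      (target - p_lo$power) / (p_hi$power - p_lo$power) else 0.5
    frac <- min(max(frac, 0), 1)
    d_star <- d_lo + frac * (d_hi - d_lo)
    pw_se <- sqrt(mean(c(p_lo$mc_se, p_hi$mc_se)^2))
    data.frame(side = s, or = exp(null_log + sgn * d_star),
               power_at_bound = target,
               mc_se = pw_se, n_evals = eval_i)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "evaluations") <- do.call(rbind, log_rows)
  attr(out, "scenario") <- scenario
  class(out) <- c("detectable_or_bounds", "data.frame")
  out
}

#' @export
print.detectable_or_bounds <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Detectable carrier OR/SD bounds at %.0f%% power (null OR/SD %.2f):\n",
    100 * sc$target_power, sc$noncarrier_or_per_sd))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: %s\n", x$side[i],
                ifelse(is.na(x$or[i]), "open (not reached)",
                       sprintf("%.3f", x$or[i]))))
  invisible(x)
}
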