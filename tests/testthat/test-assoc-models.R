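# Expand a 2x2 exposure-by-disease table into individual rows.
expand_2x2 <- function(a, b, c_, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c_ + d)))
}

test_that("the unadjusted 2x2 odds ratio matches the closed form", {
  # carrier counts from the coronary case-control design: 43 of 6432 cases,
  # 13 of 6420 controls
  dat <- expand_2x2(43, 13, 6432 - 43, 6420 - 13)
  fit <- fit_logistic(dat$y, data.frame(x = dat$x))
  expect_equal(unname(fit$coefficients["x"]),
               log((43 * 6407) / (13 * 6389)), tolerance = 1e-6)
  tab <- or_table(fit)
  expect_equal(tab$or, (43 * 6407) / (13 * 6389), tolerance = 1e-5)
})

test_that("glm coefficients maximize the likelihood (direct search oracle)", {
  set.seed(71)
  n <- 20
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  fit <- fit_logistic(y, data.frame(x = x))
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log1p(exp(b[1] + b[2] * x)))
  # coarse grid bracket followed by direct optimization, independent of IRLS
  grid <- expand.grid(b0 = seq(-3, 3, 0.25), b1 = seq(-3, 3, 0.25))
  start <- unlist(grid[which.min(apply(grid, 1, nll)), ])
  opt <- optim(start, nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), unname(opt$par), tolerance = 1e-5)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
})

test_that("independent predictors give near-zero slopes and sane errors", {
  set.seed(72)
  y <- rbinom(500, 1, 0.3)
  fit <- fit_logistic(y, data.frame(a = rnorm(500), b = rnorm(500)))
  expect_lt(max(abs(fit$coefficients[-1])), 0.3)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "single class")
  expect_error(fit_logistic(c(y[1:9], NA), data.frame(x = rnorm(10))),
               "missing")
})

test_that("Wald intervals are symmetric on the log scale", {
  co <- test_cohort()
  ph <- co$phenotypes
  fit <- fit_logistic(ph$disease, data.frame(carrier = ph$carrier,
                                             z = ph$true_z))
  tab <- or_table(fit)
  expect_lt(max(abs((log(tab$ci_high) - log(tab$or)) -
                      (log(tab$or) - log(tab$ci_low)))), 1e-9)
})

test_that("score strata use the 20/80 quintile boundaries", {
  expect_identical(as.character(stratify_scores(c(20, 21, 80, 81))),
                   c("low", "intermediate", "intermediate", "high"))
  expect_identical(as.character(stratify_scores(c(1, 25, 50, 75, 99))),
                   c("low", "intermediate", "intermediate", "intermediate",
                     "high"))
  pct <- percentile_map(rnorm(5000))
  tabs <- table(stratify_scores(pct)) / 5000
  expect_equal(as.numeric(tabs), c(0.2, 0.6, 0.2), tolerance = 0.03)
  expect_error(stratify_scores(c(0, 50)), "percentiles")
})

test_that("six-level odds ratios order as expected under joint effects", {
  co <- cached_cohort("assoc", function() {
    cfg <- sim_config(n_individuals = 8000L, n_score_variants = 60L,
                      carrier_frequency = 0.05, baseline_prevalence = 0.1,
                      beta_carrier = log(3), beta_prs_per_sd = log(1.7),
                      seed = 78L)
    assign_disease_cross_sectional(generate_population(cfg))
  })
  ph <- co$phenotypes
  pcs <- as.matrix(ph[, grep("^pc", names(ph))])
  ss <- score_set(co$dosages, co$weights, pcs)
  strata <- stratify_scores(ss$percentile)
  covs <- data.frame(age = ph$age_enroll, male = as.numeric(ph$sex == "male"))
  res <- six_level_or(ph$disease, ph$carrier, strata, covs)
  expect_equal(nrow(res), 6L)
  ref <- res[res$carrier == 0 & res$stratum == "intermediate", ]
  expect_equal(ref$or, 1)
  expect_equal(c(ref$ci_low, ref$ci_high), c(1, 1))
  # score gradient within noncarriers
  nc <- res[res$carrier == 0, ]
  expect_lt(nc$or[nc$stratum == "low"], nc$or[nc$stratum == "high"])
  # carriers sit above noncarriers within every estimable stratum
  est <- res$estimable
  for (s in c("low", "intermediate", "high")) {
    rows <- res[res$stratum == s & est, ]
    if (nrow(rows) == 2)
      expect_lt(rows$or[rows$carrier == 0], rows$or[rows$carrier == 1])
  }
})

test_that("six-level fit reports empty carrier levels as not estimable", {
  set.seed(73)
  n <- 600
  y <- rbinom(n, 1, 0.3)
  strata <- stratify_scores(percentile_map(rnorm(n)))
  res <- six_level_or(y, rep(0L, n), strata)
  expect_true(all(!res$estimable[res$carrier == 1]))
  expect_equal(sum(res$estimable), 3L)
})

test_that("null six-level fits keep all odds ratios near one", {
  set.seed(74)
  n <- 4000
  y <- rbinom(n, 1, 0.3)
  carrier <- rbinom(n, 1, 0.05)
  strata <- stratify_scores(percentile_map(rnorm(n)))
  res <- six_level_or(y, carrier, strata)
  est <- res[res$estimable & !(res$carrier == 0 &
                                 res$stratum == "intermediate"), ]
  # all five contrasts stay within sampling error of the null; allow one
  # 95% interval to miss
  se <- (log(est$ci_high) - log(est$ci_low)) / (2 * qnorm(0.975))
  expect_true(all(abs(log(est$or)) / se < 3.5))
  expect_gte(sum(est$ci_low <= 1 & est$ci_high >= 1), 4L)
})

test_that("stratified per-SD fits equal the saturated interaction model", {
  set.seed(75)
  n <- 3000
  carrier <- rbinom(n, 1, 0.3)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * z + 0.7 * carrier + 0.3 * z * carrier))
  strat <- suppressWarnings(or_per_sd_by_stratum(y, z, carrier))
  it <- interaction_test(y, z, carrier)
  b <- it$fit$coefficients
  expect_equal(log(strat$or_per_sd[strat$stratum == "noncarrier"]),
               unname(b["z"]), tolerance = 1e-6)
  expect_equal(log(strat$or_per_sd[strat$stratum == "carrier"]),
               unname(b["z"] + b["zxcarrier"]), tolerance = 1e-6)
})

test_that("permuted scores give per-SD odds ratios near one", {
  co <- test_cohort()
  ph <- co$phenotypes
  set.seed(76)
  z_perm <- sample(ph$true_z)
  res <- suppressWarnings(or_per_sd_by_stratum(ph$disease, z_perm,
                                               ph$carrier))
  expect_true(all(res$ci_low <= 1 & res$ci_high >= 1))
})

test_that("the interaction coefficient is the difference of stratum log-ORs", {
  # covariate-free saturated case with binary score
  counts <- expand.grid(y = 0:1, z = 0:1, carrier = 0:1)
  counts$n <- c(50, 10, 40, 20, 30, 12, 20, 18)
  dat <- counts[rep(seq_len(nrow(counts)), counts$n), ]
  it <- interaction_test(dat$y, dat$z, dat$carrier)
  or_in <- function(cc) {
    t <- table(dat$z[dat$carrier == cc], dat$y[dat$carrier == cc])
    log((t["1", "1"] * t["0", "0"]) / (t["0", "1"] * t["1", "0"]))
  }
  expect_equal(it$estimate, or_in(1) - or_in(0), tolerance = 1e-6)
})

test_that("percentile OR curve is referenced, additive and delta-consistent", {
  co <- test_cohort()
  ph <- co$phenotypes
  z <- standardize_scores(ph$true_z)
  curve <- percentile_or_curve(ph$disease, z, ph$carrier)
  expect_equal(nrow(curve), 200L)
  expect_equal(curve$or[curve$percentile == 50 & curve$carrier == 0], 1,
               tolerance = 1e-12)
  # additive model: carrier-to-noncarrier ratio constant over percentiles
  ratio <- curve$or[curve$carrier == 1] / curve$or[curve$carrier == 0]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  # monotone when the score coefficient is positive
  fit <- attr(curve, "fit")
  expect_gt(fit$coefficients["z"], 0)
  nc <- curve$or[curve$carrier == 0]
  expect_true(all(diff(nc) > -1e-12))
  # delta-method wiring: reconstruct one point from coefficients and z map
  zmap <- attr(curve, "z_map")
  b <- fit$coefficients
  or90 <- exp(b["carrier"] + b["z"] * (zmap[90] - zmap[50]))
  expect_equal(curve$or[curve$percentile == 90 & curve$carrier == 1],
               unname(or90), tolerance = 1e-10)
  # CI symmetry on the log scale
  ok <- curve$or > 0
  expect_lt(max(abs((log(curve$ci_high[ok]) - log(curve$or[ok])) -
                      (log(curve$or[ok]) - log(curve$ci_low[ok])))), 1e-9)
})

test_that("linearity LRT is nonnegative, calibrated and consistent", {
  set.seed(77)
  n <- 1500
  rej <- 0L
  for (r in 1:120) {
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * s))
    lrt <- linearity_lrt(y, s)
    expect_gte(lrt$statistic, 0)
    if (lrt$p < 0.05) rej <- rej + 1L
  }
  # two-sided 3.5 SE band around the nominal 5% level
  expect_lt(abs(rej / 120 - 0.05), 3.5 * sqrt(0.05 * 0.95 / 120))
  # strong curvature is detected
  s <- rnorm(4000)
  y2 <- rbinom(4000, 1, plogis(-1 + 0.4 * s + 0.5 * s^2))
  expect_lt(linearity_lrt(y2, s)$p, 1e-6)
})

test_that("calibration bins conserve counts and track a calibrated model", {
  co <- test_cohort()
  ph <- co$phenotypes
  z <- standardize_scores(ph$true_z)
  fit <- fit_logistic(ph$disease, data.frame(z = z, carrier = ph$carrier))
  pct <- percentile_map(z)
  cal <- calibration_table(fit$glm$fitted.values, pct, ph$disease)
  expect_equal(nrow(cal), 20L)
  expect_equal(sum(cal$n), nrow(ph))
  # a correctly specified model is calibrated within binomial error per bin
  band <- 4 * sqrt(cal$expected * (1 - cal$expected) / cal$n)
  expect_true(all(abs(cal$observed - cal$expected) < band + 0.01))
  # constant-probability model: identical expectation in every bin
  cal0 <- calibration_table(rep(0.3, nrow(ph)), pct, ph$disease)
  expect_equal(diff(range(cal0$expected)), 0)
})
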