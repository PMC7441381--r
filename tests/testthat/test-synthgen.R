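test_that("identical config and seed give a bit-identical cohort", {
  cfg <- sim_config(n_individuals = 400L, n_score_variants = 30L, seed = 5L)
  a <- assign_onset_ages(assign_disease_cross_sectional(
    generate_population(cfg)))
  b <- assign_onset_ages(assign_disease_cross_sectional(
    generate_population(cfg)))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$weights, b$weights)
  expect_identical(a$annotations, b$annotations)
})

test_that("dosages are hard calls in {0,1,2} and IDs align", {
  co <- test_cohort()
  expect_true(all(co$dosages %in% 0:2))
  expect_identical(rownames(co$dosages), co$phenotypes$individual_id)
  expect_identical(rownames(co$rare_dosages), co$phenotypes$individual_id)
  expect_false(anyDuplicated(co$phenotypes$individual_id) > 0)
})

test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(carrier_frequency = 1.2), "probabilities")
  expect_error(sim_config(n_ancestry_components = 0), "n_ancestry_components")
  expect_error(sim_config(hazard_shape = -1), "Weibull")
})

test_that("carrier counts follow the binomial sampling bound", {
  cfg <- sim_config(n_individuals = 50000L, n_score_variants = 5L,
                    carrier_frequency = 0.005, seed = 21L)
  co <- generate_population(cfg)
  n_car <- sum(co$phenotypes$carrier)
  expect_lt(abs(n_car - 250), 3 * sqrt(50000 * 0.005 * 0.995))
  # never two pathogenic variants in one individual
  path_cols <- grep("^rv0(0\\d|1[0-2])$", colnames(co$rare_dosages))
  expect_lte(max(rowSums(co$rare_dosages[, 1:12])), 1)
})

test_that("vanishing divergence removes between-component score shifts", {
  cfg <- sim_config(n_individuals = 8000L, n_score_variants = 80L,
                    n_ancestry_components = 2L, fst = 1e-4, seed = 22L)
  co <- generate_population(cfg)
  comp <- max.col(co$truth$ancestry)
  raw <- co$truth$raw_score
  d <- abs(mean(raw[comp == 1]) - mean(raw[comp == 2])) / sd(raw)
  expect_lt(d, 0.1)
})

test_that("ancestry correction removes the confounding the generator builds", {
  cfg <- sim_config(n_individuals = 8000L, n_score_variants = 80L,
                    n_ancestry_components = 2L, fst = 0.2, seed = 25L)
  co <- generate_population(cfg)
  raw <- co$truth$raw_score
  pc <- as.matrix(co$phenotypes[, "pc1", drop = FALSE])
  corrected <- ancestry_correct(raw, pc)
  expect_lt(abs(cor(corrected, pc[, 1])), 1e-10)
  comp <- max.col(co$truth$ancestry)
  raw_gap <- abs(mean(raw[comp == 1]) - mean(raw[comp == 2]))
  cor_gap <- abs(mean(corrected[comp == 1]) - mean(corrected[comp == 2]))
  expect_gt(raw_gap / sd(raw), 0.2)  # the confounding is real
  expect_lt(cor_gap, 0.05 * raw_gap)
})

test_that("null effects reproduce the target prevalence", {
  cfg <- sim_config(n_individuals = 20000L, n_score_variants = 5L,
                    beta_carrier = 0, beta_prs_per_sd = 0, beta_age = 0,
                    beta_sex_male = 0, baseline_prevalence = 0.07,
                    seed = 24L)
  co <- assign_disease_cross_sectional(generate_population(cfg))
  prev <- mean(co$phenotypes$disease)
  expect_lt(abs(prev - 0.07), 3 * sqrt(0.07 * 0.93 / 20000))
})

test_that("zero prevalence yields no cases and downstream fits refuse", {
  cfg <- sim_config(n_individuals = 300L, n_score_variants = 5L,
                    baseline_prevalence = 0, seed = 25L)
  co <- assign_disease_cross_sectional(generate_population(cfg))
  expect_equal(sum(co$phenotypes$disease), 0)
  expect_error(fit_logistic(co$phenotypes$disease,
                            data.frame(z = co$phenotypes$true_z)),
               "single class")
})

test_that("constant-hazard onset ages match the exponential closed form", {
  lambda <- 0.01
  cfg <- sim_config(n_individuals = 40000L, n_score_variants = 5L,
                    beta_carrier = 0, beta_prs_per_sd = 0, beta_sex_male = 0,
                    hazard_shape = 1, hazard_scale = 1 / lambda,
                    censoring_age_range = c(200, 201), seed = 26L)
  co <- assign_onset_ages(generate_population(cfg))
  emp <- mean(co$phenotypes$onset_age <= 75)
  expect_equal(emp, 1 - exp(-lambda * 75), tolerance = 0.01)
})

test_that("a strong carrier effect advances onset; zero censoring kills events", {
  cfg <- sim_config(n_individuals = 20000L, n_score_variants = 5L,
                    carrier_frequency = 0.05, beta_carrier = log(8),
                    seed = 27L)
  co <- assign_onset_ages(generate_population(cfg))
  ph <- co$phenotypes
  expect_lt(median(ph$onset_age[ph$carrier == 1]),
            median(ph$onset_age[ph$carrier == 0]))
  cfg0 <- sim_config(n_individuals = 500L, n_score_variants = 5L,
                     censoring_age_range = c(0, 0), seed = 28L)
  co0 <- assign_onset_ages(generate_population(cfg0))
  expect_equal(sum(co0$phenotypes$event), 0)
})

test_that("case-control sampling respects strata and errors on shortfall", {
  co <- test_cohort()
  n_cases_avail <- sum(co$phenotypes$disease)
  cc <- sample_case_control(co, 100, 200, seed = 3L)
  expect_equal(sum(cc$phenotypes$disease), 100)
  expect_equal(sum(1 - cc$phenotypes$disease), 200)
  expect_equal(nrow(cc$dosages), 300)
  cc0 <- sample_case_control(co, 0, 150, seed = 3L)
  expect_true(all(cc0$phenotypes$disease == 0))
  expect_error(sample_case_control(co, n_cases_avail + 1, 10, seed = 3L),
               "available")
})

test_that("case-control carrier OR approximates the population OR when rare", {
  cfg <- sim_config(n_individuals = 150000L, n_score_variants = 5L,
                    carrier_frequency = 0.02, beta_carrier = log(3),
                    beta_prs_per_sd = 0, beta_age = 0, beta_sex_male = 0,
                    baseline_prevalence = 0.01, seed = 29L)
  co <- assign_disease_cross_sectional(generate_population(cfg))
  cc <- sample_case_control(co, 1200, 1200, seed = 4L)
  ph <- cc$phenotypes
  tab <- table(ph$carrier, ph$disease)
  or_cc <- (tab["1", "1"] * tab["0", "0"]) / (tab["0", "1"] * tab["1", "0"])
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_cc) - log(3)), 3 * se)
})

test_that("annotation generator honours proportions and frequency bounds", {
  syn_only <- c(synonymous = 1, missense = 0, nonsense = 0, frameshift = 0,
                canonical_splice = 0, other = 0)
  ann <- generate_variant_annotations(50, consequence_probs = syn_only,
                                      seed = 31L)
  expect_equal(nrow(candidate_filter(ann)), 0)
  ann2 <- generate_variant_annotations(200, seed = 32L)
  af <- as.matrix(ann2[, grep("^af_", names(ann2))])
  expect_true(all(af >= 0 & af <= 1))
  expect_setequal(unique(ann2$classification) %in%
                    c("P", "LP", "VUS", "LB", "B"), TRUE)
})

test_that("filter survivors on a toy table equal the hand count", {
  ann <- generate_variant_annotations(100, seed = 33L)
  kept <- region_quality_filter(candidate_filter(ann))
  af <- as.matrix(ann[, grep("^af_", names(ann))])
  by_hand <- ann$consequence != "synonymous" &
    apply(af <= 0.005, 1, all) &
    !ann$low_complexity & !ann$segdup & ann$rf_pass
  expect_equal(nrow(kept), sum(by_hand))
  expect_identical(kept$variant_id, ann$variant_id[by_hand])
})
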