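#' Configuration for the synthetic cohort generator
#'
#' Bundles the generating parameters for [generate_population()] and the
#' phenotype generators. Ancestry structure follows a Balding-Nichols
#' model: ancestral allele frequencies are drawn uniform on (0.05, 0.95)
#' and each ancestry component receives its own frequencies from a Beta
#' distribution with divergence parameter `fst`; individuals are admixed
#' with Dirichlet(1) proportions, which are exported (minus one redundant
#' column) as principal-component surrogates carrying the confounding the
#' ancestry correction must remove.
#'
#' @param n_individuals cohort size.
#' @param n_score_variants number of common score variants.
#' @param n_ancestry_components number of ancestry components (>= 1).
#' @param fst Balding-Nichols divergence parameter, in (0, 1).
#' @param carrier_frequency probability of carrying one rare pathogenic
#'   variant (at most one per individual).
#' @param beta_carrier log odds ratio of disease for carrier status.
#' @param beta_prs_per_sd log odds ratio per SD of the true score.
#' @param baseline_prevalence target marginal disease prevalence for the
#'   cross-sectional generator.
#' @param age_range enrollment age range, years (uniform, rounded to whole
#'   years).
#' @param sex_fraction_female probability of female sex.
#' @param beta_age log odds of disease per year of age (cross-sectional).
#' @param beta_sex_male log odds ratio of disease for male sex.
#' @param hazard_shape,hazard_scale Weibull baseline parameters for onset
#'   ages (shape > 1 gives rates rising with age, as for adult-onset
#'   disease; the default baseline gives roughly 10% cumulative incidence
#'   by age 75).
#' @param censoring_age_range censoring age range, years (uniform).
#' @param seed integer seed recorded in all outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000L,
                       n_score_variants = 200L,
                       n_ancestry_components = 3L,
                       fst = 0.05,
                       carrier_frequency = 0.005,
                       beta_carrier = log(3),
                       beta_prs_per_sd = log(1.6),
                       baseline_prevalence = 0.05,
                       age_range = c(40, 69),
                       sex_fraction_female = 0.54,
                       beta_age = log(1.05),
                       beta_sex_male = log(1.7),
                       hazard_shape = 4,
                       hazard_scale = 135,
                       censoring_age_range = c(55, 80),
                       seed = 1L) {
  probs <- c(carrier_frequency = carrier_frequency,
             baseline_prevalence = baseline_prevalence,
             sex_fraction_female = sex_fraction_female)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (!(fst > 0 && fst < 1)) stop("`fst` must lie strictly in (0, 1)")
  if (n_ancestry_components < 1L) stop("`n_ancestry_components` must be >= 1")
  stopifnot(n_individuals >= 1, n_score_variants >= 1,
            length(age_range) == 2, age_range[1] <= age_range[2],
            length(censoring_age_range) == 2,
            censoring_age_range[1] <= censoring_age_range[2])
  if (hazard_shape <= 0 || hazard_scale <= 0)
    stop("Weibull `hazard_shape` and `hazard_scale` must be positive")
  structure(as.list(environment())[c(
    "n_individuals", "n_score_variants", "n_ancestry_components", "fst",
    "carrier_frequency", "beta_carrier", "beta_prs_per_sd",
    "baseline_prevalence", "age_range", "sex_fraction_female", "beta_age",
    "beta_sex_male", "hazard_shape", "hazard_scale", "censoring_age_range",
    "seed")], class = "sim_config")
}

# Gene footprints used for synthetic weights/annotations/regions (toy
# coordinates, one chromosome per gene).
.condition_genes <- function() {
  data.frame(
    gene = c("LDLR", "APOB", "PCSK9", "BRCA1", "BRCA2",
             "MLH1", "MSH2", "MSH6", "PMS2"),
    condition = c("FH", "FH", "FH", "HBOC", "HBOC",
                  "Lynch", "Lynch", "Lynch", "Lynch"),
    chromosome = c("19", "2", "1", "17", "13", "3", "2", "2", "7"),
    start = c(11200000L, 21224300L, 55505200L, 43044295L, 32315474L,
              37034840L, 47630206L, 47783145L, 5973239L),
    end = c(11244500L, 21266945L, 55530525L, 43125483L, 32400266L,
            37107380L, 47710367L, 47810101L, 6009106L),
    stringsAsFactors = FALSE)
}

#' Default condition-to-gene map
#'
#' Familial hypercholesterolemia (LDLR, APOB, PCSK9), hereditary breast and
#' ovarian cancer (BRCA1, BRCA2) and Lynch syndrome (MLH1, MSH2, MSH6,
#' PMS2).
#'
#' @return named list of gene symbol vectors.
#' @export
condition_gene_map <- function() {
  g <- .condition_genes()
  split(g$gene, g$condition)[c("FH", "HBOC", "Lynch")]
}

#' Generate a synthetic cohort
#'
#' Simulates genotypes, score weights, rare pathogenic carrier variants and
#' baseline covariates with known ground truth. Common-variant dosages are
#' Binomial(2, p) draws at individual-specific frequencies mixing the
#' Balding-Nichols component frequencies by each individual's admixture
#' proportions; score weights are normal; carrier status is Bernoulli and
#' each carrier holds exactly one rare pathogenic variant in the genes of
#' `condition` (never two, matching clinical observation in these genes).
#' Rare decoy variants that fail the downstream frequency, consequence or
#' region filters are included so that the variant screen is exercised
#' end to end.
#'
#' @param config a [sim_config()].
#' @param condition condition whose genes carry the pathogenic variants.
#' @return an object of class `synthetic_cohort`: list with `phenotypes`
#'   (data frame), `dosages` (individuals x score variants matrix),
#'   `rare_dosages` (individuals x rare variants), `weights`,
#'   `annotations`, `regions` (gene footprints) and `truth` (generating
#'   parameters, including the config and seed).
#' @export
generate_population <- function(config = sim_config(),
                                condition = c("FH", "HBOC", "Lynch")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  set.seed(config$seed)
  n <- config$n_individuals
  nv <- config$n_score_variants
  K <- config$n_ancestry_components

  ids <- sprintf("I%06d", seq_len(n))

  # admixture proportions (Dirichlet(1,...,1))
  A <- matrix(rexp(n * K), n, K)
  A <- A / rowSums(A)

  # Balding-Nichols component frequencies
  p0 <- runif(nv, 0.05, 0.95)
  shape_scale <- (1 - config$fst) / config$fst
  P_comp <- matrix(stats::rbeta(nv * K,
                                rep(p0 * shape_scale, K),
                                rep((1 - p0) * shape_scale, K)), nv, K)
  P_ind <- A %*% t(P_comp)           # n x nv individual-level frequencies
  dos <- matrix(rbinom(n * nv, 2L, P_ind), n, nv)
  variant_ids <- sprintf("sv%04d", seq_len(nv))
  dimnames(dos) <- list(ids, variant_ids)

  # weights: variants placed genome-wide; a handful land inside the 1-Mb
  # flanks of the condition genes so flanking exclusion has work to do
  genes <- .condition_genes()
  cond_genes <- genes[genes$condition == condition, , drop = FALSE]
  chroms <- as.character(sample(1:22, nv, replace = TRUE))
  pos <- sample.int(2.4e8, nv, replace = TRUE)
  n_flank <- max(2L, round(0.05 * nv))
  flank_idx <- sample.int(nv, n_flank)
  gpick <- sample.int(nrow(cond_genes), n_flank, replace = TRUE)
  chroms[flank_idx] <- cond_genes$chromosome[gpick]
  pos[flank_idx] <- round(runif(n_flank,
                                cond_genes$start[gpick] - 9e5,
                                cond_genes$end[gpick] + 9e5))
  weights <- data.frame(variant_id = variant_ids,
                        chromosome = chroms,
                        position = pos,
                        effect_allele = "A",
                        other_allele = "G",
                        weight = rnorm(nv, 0, 0.1),
                        stringsAsFactors = FALSE)

  raw <- as.numeric(dos %*% weights$weight)
  true_z <- as.numeric(scale(raw))

  # carriers: Bernoulli, one pathogenic variant each
  carrier <- rbinom(n, 1L, config$carrier_frequency)
  n_path <- 12L
  path_ids <- sprintf("rv%03d", seq_len(n_path))
  path_gene <- sample(cond_genes$gene, n_path, replace = TRUE)
  assigned <- sample.int(n_path, sum(carrier), replace = TRUE)

  n_decoy <- 12L
  decoy_ids <- sprintf("rv%03d", n_path + seq_len(n_decoy))
  rare <- matrix(0L, n, n_path + n_decoy,
                 dimnames = list(ids, c(path_ids, decoy_ids)))
  rare[cbind(which(carrier == 1L), assigned)] <- 1L
  # decoys get their own sparse genotypes (never qualifying)
  rare[, n_path + seq_len(n_decoy)] <-
    matrix(rbinom(n * n_decoy, 1L, 0.01), n, n_decoy)

  annotations <- .cohort_annotations(path_ids, path_gene, decoy_ids,
                                     cond_genes$gene)

  phen <- data.frame(
    individual_id = ids,
    age_enroll = round(runif(n, config$age_range[1], config$age_range[2])),
    sex = ifelse(runif(n) < config$sex_fraction_female, "female", "male"),
    carrier = carrier,
    true_z = true_z,
    stringsAsFactors = FALSE)
  if (K >= 2L) {
    pcs <- A[, seq_len(K - 1L), drop = FALSE]
    colnames(pcs) <- paste0("pc", seq_len(K - 1L))
    phen <- cbind(phen, pcs)
  }

  structure(list(
    phenotypes = phen,
    dosages = dos,
    rare_dosages = rare,
    weights = weights,
    annotations = annotations,
    regions = cond_genes[, c("chromosome", "start", "end", "gene")],
    truth = list(config = config, condition = condition, raw_score = raw,
                 ancestry = A, seed = config$seed)),
    class = "synthetic_cohort")
}

# Annotation table in which exactly the pathogenic variant set survives the
# frequency, consequence, region and classification filters; decoys fail
# one rule each in rotation.
.cohort_annotations <- function(path_ids, path_gene, decoy_ids, gene_pool) {
  subpops <- c("afr", "amr", "eas", "nfe", "sas")
  n_p <- length(path_ids); n_d <- length(decoy_ids)
  mk_af <- function(n) matrix(runif(n * length(subpops), 0, 0.004), n,
                              length(subpops),
                              dimnames = list(NULL, paste0("af_", subpops)))
  path <- data.frame(variant_id = path_ids, gene = path_gene,
                     consequence = sample(c("nonsense", "frameshift",
                                            "missense", "canonical_splice"),
                                          n_p, replace = TRUE),
                     stringsAsFactors = FALSE)
  path <- cbind(path, mk_af(n_p))
  path$low_complexity <- FALSE; path$segdup <- FALSE; path$rf_pass <- TRUE
  path$classification <- sample(c("P", "LP"), n_p, replace = TRUE)

  decoy <- data.frame(variant_id = decoy_ids,
                      gene = sample(gene_pool, n_d, replace = TRUE),
                      consequence = "missense",
                      stringsAsFactors = FALSE)
  decoy <- cbind(decoy, mk_af(n_d))
  decoy$low_complexity <- FALSE; decoy$segdup <- FALSE; decoy$rf_pass <- TRUE
  decoy$classification <- "VUS"
  fail <- rep_len(c("synonymous", "common", "low_complexity", "segdup",
                    "rf", "vus"), n_d)
  for (i in seq_len(n_d)) {
    switch(fail[i],
           synonymous = { decoy$consequence[i] <- "synonymous"
                          decoy$classification[i] <- "B" },
           common = { decoy[i, "af_nfe"] <- runif(1, 0.01, 0.1)
                      decoy$classification[i] <- "LB" },
           low_complexity = decoy$low_complexity[i] <- TRUE,
           segdup = decoy$segdup[i] <- TRUE,
           rf = decoy$rf_pass[i] <- FALSE,
           vus = decoy$classification[i] <- "VUS")
  }
  out <- rbind(path, decoy)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d individuals, %d score variants, %d rare variants (%s), seed %d\n",
    nrow(x$phenotypes), ncol(x$dosages), ncol(x$rare_dosages),
    x$truth$condition, x$truth$seed))
  if ("disease" %in% names(x$phenotypes))
    cat(sprintf("  prevalent disease: %d (%.2f%%)\n",
                sum(x$phenotypes$disease),
                100 * mean(x$phenotypes$disease)))
  invisible(x)
}

#' Assign cross-sectional (prevalent) disease status
#'
#' Draws disease status from a logistic model in carrier status, true score,
#' age and sex, with the intercept solved numerically so the realized
#' marginal prevalence matches `baseline_prevalence` in expectation.
#' Degenerate prevalences 0 and 1 short-circuit to all-control/all-case
#' cohorts.
#'
#' @param cohort a [generate_population()] result.
#' @param config generating parameters; defaults to the cohort's own.
#' @return the cohort with a `disease` column added to `phenotypes`.
#' @export
assign_disease_cross_sectional <- function(cohort,
                                           config = cohort$truth$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ph <- cohort$phenotypes
  n <- nrow(ph)
  if (config$baseline_prevalence %in% c(0, 1)) {
    ph$disease <- rep(as.integer(config$baseline_prevalence), n)
  } else {
    eta <- config$beta_carrier * ph$carrier +
      config$beta_prs_per_sd * ph$true_z +
      config$beta_age * (ph$age_enroll - mean(ph$age_enroll)) +
      config$beta_sex_male * (ph$sex == "male")
    a <- .calibrate_intercept(eta, n * config$baseline_prevalence)
    ph$disease <- rbinom(n, 1L, plogis(a + eta))
  }
  cohort$phenotypes <- ph
  cohort$truth$prevalence_model <- list(
    beta_carrier = config$beta_carrier,
    beta_prs_per_sd = config$beta_prs_per_sd,
    baseline_prevalence = config$baseline_prevalence)
  cohort
}

#' Assign onset and censoring ages from a Weibull hazards model
#'
#' Onset ages follow a Weibull proportional-hazards model with linear
#' predictor `beta_carrier * carrier + beta_prs_per_sd * true_z +
#' beta_sex_male * male`; censoring ages are drawn independently and
#' uniformly on `censoring_age_range`. The observed time is the earlier of
#' onset and censoring; `prevalent` flags events whose onset precedes the
#' enrollment age.
#'
#' @inheritParams assign_disease_cross_sectional
#' @return the cohort with `onset_age`, `censor_age`, `age_dx_or_censor`,
#'   `event` and `prevalent` columns added to `phenotypes`.
#' @export
assign_onset_ages <- function(cohort, config = cohort$truth$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (config$hazard_shape <= 0 || config$hazard_scale <= 0)
    stop("Weibull `hazard_shape` and `hazard_scale` must be positive")
  ph <- cohort$phenotypes
  n <- nrow(ph)
  lp <- config$beta_carrier * ph$carrier +
    config$beta_prs_per_sd * ph$true_z +
    config$beta_sex_male * (ph$sex == "male")
  u <- runif(n)
  onset <- config$hazard_scale * (-log(u) * exp(-lp))^(1 / config$hazard_shape)
  censor <- runif(n, config$censoring_age_range[1],
                  config$censoring_age_range[2])
  ph$onset_age <- onset
  ph$censor_age <- censor
  ph$event <- as.integer(onset <= censor)
  ph$age_dx_or_censor <- pmin(onset, censor)
  ph$prevalent <- as.integer(ph$event == 1L & onset <= ph$age_enroll)
  cohort$phenotypes <- ph
  cohort$truth$onset_model <- list(
    hazard_shape = config$hazard_shape, hazard_scale = config$hazard_scale,
    beta_carrier = config$beta_carrier,
    beta_prs_per_sd = config$beta_prs_per_sd,
    beta_sex_male = config$beta_sex_male)
  cohort
}

#' Sample a case-control study from a cohort
#'
#' Uniform subsampling without replacement within each disease stratum,
#' emulating case-control ascertainment from a population cohort.
#'
#' @param cohort a cohort with a `disease` column (see
#'   [assign_disease_cross_sectional()]).
#' @param n_cases,n_controls stratum sample sizes.
#' @param seed integer seed for the subsampling (recorded in `truth`).
#' @return a `synthetic_cohort` restricted to the sampled rows.
#' @export
sample_case_control <- function(cohort, n_cases, n_controls, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ph <- cohort$phenotypes
  if (!"disease" %in% names(ph))
    stop("cohort has no `disease` column; run assign_disease_cross_sectional() first")
  cases <- which(ph$disease == 1L)
  controls <- which(ph$disease == 0L)
  if (n_cases > length(cases))
    stop(sprintf("requested %d cases but only %d available",
                 n_cases, length(cases)))
  if (n_controls > length(controls))
    stop(sprintf("requested %d controls but only %d available",
                 n_controls, length(controls)))
  set.seed(as.integer(seed))
  keep <- sort(c(if (n_cases > 0) sample(cases, n_cases),
                 if (n_controls > 0) sample(controls, n_controls)))
  cohort$phenotypes <- ph[keep, , drop = FALSE]
  cohort$dosages <- cohort$dosages[keep, , drop = FALSE]
  cohort$rare_dosages <- cohort$rare_dosages[keep, , drop = FALSE]
  cohort$truth$case_control <- list(n_cases = n_cases,
                                    n_controls = n_controls, seed = seed)
  cohort
}

#' Generate a toy variant annotation table
#'
#' Builds an annotation table with configurable consequence, flag and
#' pathogenicity-class proportions and per-subpopulation allele
#' frequencies, for exercising the variant filters.
#'
#' @param n_variants number of variants.
#' @param consequence_probs named proportions over consequence classes.
#' @param class_probs named proportions over pathogenicity classes
#'   (P/LP/VUS/LB/B).
#' @param p_common probability a variant is common (frequency above 0.005)
#'   in at least one subpopulation.
#' @param p_low_complexity,p_segdup,p_rf_fail region/quality flag rates.
#' @param genes gene symbols sampled for the variants.
#' @param subpops subpopulation labels for the frequency columns.
#' @param seed optional integer seed.
#' @return data frame with columns `variant_id`, `gene`, `consequence`,
#'   `af_<subpop>` frequency columns, `low_complexity`, `segdup`,
#'   `rf_pass`, `classification`.
#' @export
generate_variant_annotations <- function(n_variants = 100L,
                                         consequence_probs = c(
                                           synonymous = 0.25, missense = 0.40,
                                           nonsense = 0.10, frameshift = 0.10,
                                           canonical_splice = 0.05,
                                           other = 0.10),
                                         class_probs = c(P = 0.05, LP = 0.05,
                                                         VUS = 0.30, LB = 0.30,
                                                         B = 0.30),
                                         p_common = 0.20,
                                         p_low_complexity = 0.05,
                                         p_segdup = 0.05,
                                         p_rf_fail = 0.05,
                                         genes = .condition_genes()$gene,
                                         subpops = c("afr", "amr", "eas",
                                                     "nfe", "sas"),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(n_variants >= 1, abs(sum(consequence_probs) - 1) < 1e-8,
            abs(sum(class_probs) - 1) < 1e-8)
  af <- matrix(runif(n_variants * length(subpops), 0, 0.004),
               n_variants, length(subpops),
               dimnames = list(NULL, paste0("af_", subpops)))
  common <- runif(n_variants) < p_common
  for (i in which(common)) {
    k <- sample.int(length(subpops), sample(1:2, 1))
    af[i, k] <- runif(length(k), 0.006, 0.2)
  }
  out <- data.frame(
    variant_id = sprintf("tv%04d", seq_len(n_variants)),
    gene = sample(genes, n_variants, replace = TRUE),
    consequence = sample(names(consequence_probs), n_variants,
                         replace = TRUE, prob = consequence_probs),
    stringsAsFactors = FALSE)
  out <- cbind(out, af)
  out$low_complexity <- runif(n_variants) < p_low_complexity
  out$segdup <- runif(n_variants) < p_segdup
  out$rf_pass <- runif(n_variants) >= p_rf_fail
  out$classification <- sample(names(class_probs), n_variants,
                               replace = TRUE, prob = class_probs)
  out
}
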