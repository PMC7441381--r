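#' Pipeline configuration
#'
#' Collects the analysis defaults — four ancestry PCs, quintile strata at
#' percentiles 20/80, subpopulation allele-frequency threshold 0.005
#' (mode "any"), a 1-Mb flanking window for score surgery, two-sided
#' alpha 0.05, 80% target power, and a 75-year penetrance horizon — plus
#' either a synthetic-cohort configuration or paths to input files.
#'
#' @param sim a [sim_config()] for synthetic mode, or `NULL` for file mode.
#' @param paths named list of input paths for file mode (`phenotypes`,
#'   `dosages`, `rare_dosages`, `weights`, `annotations`, `regions`).
#' @param gene_map condition-to-gene map.
#' @param af_threshold,af_mode candidate filter settings.
#' @param window flanking-exclusion window in base pairs.
#' @param alpha two-sided test level.
#' @param t_horizon penetrance horizon in years.
#' @param condition condition analyzed (must be a name of `gene_map`).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            gene_map = condition_gene_map(),
                            af_threshold = 0.005,
                            af_mode = c("any", "each"),
                            window = 1e6, alpha = 0.05, t_horizon = 75,
                            condition = "FH", seed = 1L) {
  af_mode <- match.arg(af_mode)
  if (is.null(sim) && is.null(paths))
    stop("either `sim` or `paths` must be given")
  stopifnot(condition %in% names(gene_map))
  structure(list(sim = sim, paths = paths, gene_map = gene_map,
                 af_threshold = af_threshold, af_mode = af_mode,
                 window = window, alpha = alpha, t_horizon = t_horizon,
                 condition = condition, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full monogenic-by-polygenic analysis pipeline
#'
#' End-to-end driver: obtain a cohort (synthetic, or read from files),
#' compute and ancestry-correct polygenic scores, screen variants and call
#' carrier status, fit the stratified, per-SD and interaction logistic
#' models, the percentile odds-ratio curve, the linearity test and the
#' calibration table, and (when onset ages are available) the Cox
#' penetrance curve to the horizon age. Deterministic given the
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, results are written as
#'   CSV plus a JSON run log with versions, seed and filter counts.
#' @return invisibly, a named list bundle with the cohort/inputs, score
#'   set, carrier table, model results and the run log.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(package_version = as.character(utils::packageVersion("polypen")),
              r_version = R.version.string, seed = config$seed)

  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- config$seed
    cohort <- generate_population(cfg, condition = config$condition)
    cohort <- assign_disease_cross_sectional(cohort)
    cohort <- assign_onset_ages(cohort)
    ph <- cohort$phenotypes
    dosages <- cohort$dosages
    rare <- cohort$rare_dosages
    weights <- cohort$weights
    annotations <- cohort$annotations
  } else {
    p <- config$paths
    ph <- read_phenotypes(p$phenotypes)
    dosages <- read_dosage_matrix(p$dosages)
    rare <- if (!is.null(p$rare_dosages)) read_dosage_matrix(p$rare_dosages)
            else dosages
    weights <- read_score_weights(p$weights)
    annotations <- read_annotations(p$annotations)
    cohort <- NULL
  }
  n_in <- nrow(ph)
  log$n_individuals <- n_in

  pc_cols <- grep("^pc", names(ph), value = TRUE)
  pc <- as.matrix(ph[, pc_cols, drop = FALSE])
  scores <- score_set(dosages, weights, pc)
  log$n_scored <- nrow(scores)

  cand <- candidate_filter(annotations, config$af_threshold, config$af_mode)
  clean <- region_quality_filter(cand)
  log$filter_counts <- c(n_annotated = nrow(annotations),
                         attr(cand, "drop_counts"),
                         attr(clean, "drop_counts"),
                         n_qualifying = sum(clean$classification %in%
                                              c("P", "LP")))
  carriers_all <- determine_carrier_status(clean, rare, config$gene_map)
  carriers <- carriers_all[carriers_all$condition == config$condition, ]
  log$n_carriers <- sum(carriers$carrier)

  stopifnot(identical(carriers$individual_id, scores$individual_id),
            identical(ph$individual_id, scores$individual_id))
  z <- scores$z
  carrier <- carriers$carrier
  covars <- data.frame(age = ph$age_enroll,
                       male = as.numeric(ph$sex == "male"))
  covars <- cbind(covars, as.data.frame(pc))
  outcome <- ph$disease

  strata <- stratify_scores(scores$percentile)
  res <- list(
    six_level = six_level_or(outcome, carrier, strata, covars),
    or_per_sd = or_per_sd_by_stratum(outcome, z, carrier, covars),
    interaction = interaction_test(outcome, z, carrier, covars),
    or_curve = percentile_or_curve(outcome, z, carrier, covars,
                                   percentiles = scores$percentile),
    linearity = linearity_lrt(outcome, scores$corrected, covars))
  fitted_p <- attr(res$or_curve, "fit")$glm$fitted.values
  res$calibration <- calibration_table(fitted_p, scores$percentile, outcome)

  if ("age_dx_or_censor" %in% names(ph)) {
    cox_cov <- data.frame(carrier = carrier, z = z,
                          male = as.numeric(ph$sex == "male"))
    cox_cov <- cbind(cox_cov, as.data.frame(pc))
    cx <- fit_cox(ph$age_dx_or_censor, ph$event, cox_cov)
    res$cox <- cx
    res$penetrance <- penetrance_curve(cx, attr(res$or_curve, "z_map"),
                                       t = config$t_horizon)
  }

  bundle <- list(config = config, cohort = cohort, phenotypes = ph,
                 scores = scores, carriers = carriers, results = res,
                 log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) write.table(x, file.path(out_dir, f), sep = ",",
                                     quote = FALSE, row.names = FALSE)
    wr(scores, "scores.csv")
    wr(carriers, "carriers.csv")
    wr(res$six_level, "six_level_or.csv")
    wr(res$or_per_sd, "or_per_sd.csv")
    wr(as.data.frame(res$or_curve), "percentile_or_curve.csv")
    wr(res$calibration, "calibration.csv")
    if (!is.null(res$penetrance))
      wr(as.data.frame(res$penetrance), "penetrance_curve.csv")
    log$p_interaction <- res$interaction$p_interaction
    log$linearity_p <- res$linearity$p
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}
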