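.allowed_consequences <- c("synonymous", "missense", "nonsense",
                           "frameshift", "canonical_splice", "other")

#' Frequency and consequence candidate filter
#'
#' Drops synonymous variants and variants whose allele frequency exceeds
#' `af_threshold` (strictly greater) in at least one subpopulation
#' (`mode = "any"`) or in every subpopulation (`mode = "each"`).
#' Frequency columns are those named `af_*`.
#'
#' @param annotations variant annotation data frame (see
#'   [generate_variant_annotations()] / [read_annotations()]).
#' @param af_threshold subpopulation allele-frequency threshold.
#' @param mode `"any"` (exclude if common in at least one subpopulation;
#'   default) or `"each"` (exclude only if common in all).
#' @return the surviving rows, with per-rule drop counts in attribute
#'   `drop_counts` (`n_synonymous`, `n_frequency`; a variant failing both
#'   rules is counted under both).
#' @export
candidate_filter <- function(annotations, af_threshold = 0.005,
                             mode = c("any", "each")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(annotations), "consequence" %in% names(annotations))
  bad <- setdiff(unique(annotations$consequence), .allowed_consequences)
  if (length(bad) > 0)
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.allowed_consequences, collapse = ", "))
  af_cols <- grep("^af_", names(annotations), value = TRUE)
  if (length(af_cols) == 0) stop("no `af_*` subpopulation frequency columns")
  af <- as.matrix(annotations[, af_cols, drop = FALSE])
  syn <- annotations$consequence == "synonymous"
  over <- af > af_threshold
  freq <- if (mode == "any") apply(over, 1, any) else apply(over, 1, all)
  keep <- !(syn | freq)
  structure(annotations[keep, , drop = FALSE],
            drop_counts = c(n_synonymous = sum(syn), n_frequency = sum(freq)))
}

#' Region and quality filter
#'
#' Drops variants in low-complexity regions or segmental duplications and
#' variants failing the variant-quality random-forest flag. Idempotent.
#'
#' @inheritParams candidate_filter
#' @return the surviving rows with drop counts in attribute `drop_counts`.
#' @export
region_quality_filter <- function(annotations) {
  need <- c("low_complexity", "segdup", "rf_pass")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0)
    stop("missing region/quality flag column(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(annotations[, need]))
    stop("region/quality flags contain NA")
  keep <- !annotations$low_complexity & !annotations$segdup &
    annotations$rf_pass
  structure(annotations[keep, , drop = FALSE],
            drop_counts = c(n_low_complexity = sum(annotations$low_complexity),
                            n_segdup = sum(annotations$segdup),
                            n_rf_fail = sum(!annotations$rf_pass)))
}

#' Call monogenic carrier status from qualifying variants
#'
#' A carrier holds a dosage of at least `dosage_threshold` at one or more
#' pathogenic/likely pathogenic variant in the genes of a condition.
#' Individuals with two or more qualifying variants for one condition are
#' a data-quality violation (none are expected in these genes): handled by
#' `multiple = "error"` or `"keep_first"` (retain the first qualifying
#' variant with a warning).
#'
#' @param annotations filtered annotation table; only rows with
#'   `classification` in `P`/`LP` qualify.
#' @param dosages individuals x variants matrix covering the qualifying
#'   variant IDs.
#' @param gene_map named list mapping condition to gene symbols
#'   (default [condition_gene_map()]).
#' @param dosage_threshold minimum dosage counting as carrying one allele
#'   (below 1 to tolerate imputed dosages).
#' @param multiple `"error"` or `"keep_first"`.
#' @return data frame with one row per individual per condition:
#'   `individual_id`, `condition`, `carrier`, `variant_id`, `gene`.
#' @export
determine_carrier_status <- function(annotations, dosages,
                                     gene_map = condition_gene_map(),
                                     dosage_threshold = 0.9,
                                     multiple = c("error", "keep_first")) {
  multiple <- match.arg(multiple)
  stopifnot(is.data.frame(annotations), is.matrix(dosages))
  if (!"classification" %in% names(annotations))
    stop("annotations must carry a `classification` column")
  plp <- annotations[annotations$classification %in% c("P", "LP"), ,
                     drop = FALSE]
  unmapped <- setdiff(unique(plp$gene), unlist(gene_map))
  if (length(unmapped) > 0)
    stop("pathogenic variants in gene(s) absent from the condition map: ",
         paste(unmapped, collapse = ", "))
  ids <- rownames(dosages)
  out <- lapply(names(gene_map), function(cond) {
    vv <- plp[plp$gene %in% gene_map[[cond]], , drop = FALSE]
    res <- data.frame(individual_id = ids, condition = cond,
                      carrier = 0L, variant_id = NA_character_,
                      gene = NA_character_, stringsAsFactors = FALSE)
    vpresent <- intersect(vv$variant_id, colnames(dosages))
    if (length(vpresent) > 0) {
      D <- dosages[, vpresent, drop = FALSE] >= dosage_threshold
      nqual <- rowSums(D)
      if (any(nqual > 1)) {
        offenders <- ids[nqual > 1]
        if (multiple == "error")
          stop(sprintf(
            "%d individual(s) with more than one qualifying %s variant (e.g. %s)",
            length(offenders), cond, offenders[1]))
        warning(sprintf(
          "%d individual(s) with more than one qualifying %s variant; keeping the first",
          length(offenders), cond))
      }
      hit <- nqual >= 1
      first <- apply(D[hit, , drop = FALSE], 1, which.max)
      res$carrier[hit] <- 1L
      res$variant_id[hit] <- vpresent[first]
      res$gene[hit] <- vv$gene[match(vpresent[first], vv$variant_id)]
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize carrier prevalence
#'
#' Carrier count and percentage, overall or within groups (e.g. case
#' status), from a carrier-status table.
#'
#' @param carriers data frame with `carrier` (0/1) and optionally the
#'   grouping column.
#' @param by optional name of a grouping column.
#' @return data frame with `n`, `n_carriers`, `percent` per group.
#' @export
carrier_prevalence <- function(carriers, by = NULL) {
  stopifnot("carrier" %in% names(carriers))
  if (is.null(by)) {
    data.frame(n = nrow(carriers), n_carriers = sum(carriers$carrier),
               percent = 100 * mean(carriers$carrier))
  } else {
    stopifnot(by %in% names(carriers))
    sp <- split(carriers$carrier, carriers[[by]])
    out <- data.frame(group = names(sp),
                      n = vapply(sp, length, 1L),
                      n_carriers = vapply(sp, function(x) sum(x), 1L),
                      percent = vapply(sp, function(x) 100 * mean(x), 1))
    names(out)[1] <- by
    rownames(out) <- NULL
    out
  }
}

#' Per-gene carrier association with disease
#'
#' One adjusted logistic regression per gene of carrier status against
#' disease. Genes with no carriers are reported as not estimable; fits
#' with detected separation fall back to a Firth-type penalized fit,
#' labelled in the output.
#'
#' @param gene_flags logical/0-1 matrix or data frame, individuals x genes,
#'   flagging carriers of qualifying variants in each gene.
#' @param outcome binary disease vector.
#' @param covariates optional data frame of adjustment covariates.
#' @return data frame with one row per gene: `gene`, `n_carriers`,
#'   `estimable`, `or`, `ci_low`, `ci_high`, `p`, `method`
#'   (`"wald"`/`"firth"`).
#' @export
per_gene_association <- function(gene_flags, outcome, covariates = NULL) {
  gene_flags <- as.matrix(gene_flags)
  stopifnot(nrow(gene_flags) == length(outcome))
  res <- lapply(colnames(gene_flags), function(g) {
    flag <- as.numeric(gene_flags[, g])
    nc <- sum(flag)
    if (nc == 0)
      return(data.frame(gene = g, n_carriers = 0L, estimable = FALSE,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, method = NA_character_))
    dat <- data.frame(carrier = flag)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    fit <- fit_logistic(outcome, dat)
    method <- "wald"
    if (fit$separation || !fit$converged) {
      X <- model.matrix(~ ., dat)
      ff <- .firth_logistic(X, outcome)
      est <- ff$coefficients["carrier"]
      se <- sqrt(ff$vcov["carrier", "carrier"])
      method <- "firth"
    } else {
      est <- fit$coefficients["carrier"]
      se <- sqrt(fit$vcov["carrier", "carrier"])
    }
    zc <- qnorm(0.975)
    data.frame(gene = g, n_carriers = as.integer(nc), estimable = TRUE,
               or = exp(est), ci_low = exp(est - zc * se),
               ci_high = exp(est + zc * se),
               p = 2 * pnorm(-abs(est / se)), method = method)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Firth-type penalized logistic regression (Jeffreys prior) by modified
# scoring: score U* = X'(y - p + h (1/2 - p)) with h the leverages of the
# weighted design. Keeps estimates finite under separation.
.firth_logistic <- function(X, y, maxit = 200L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    sw <- sqrt(w)
    q <- qr(X * sw)
    h <- rowSums(qr.Q(q)[, seq_len(q$rank), drop = FALSE]^2)
    U <- crossprod(X, y - p + h * (0.5 - p))
    I <- crossprod(X * sw)
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  V <- solve(crossprod(X * sqrt(w)))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(drop(beta), colnames(X)), vcov = V,
       iterations = it)
}
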