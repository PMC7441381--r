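#' Compute raw polygenic scores from dosages and weights
#'
#' Weighted sum of effect-allele dosages, `raw_i = sum_v w_v * d_iv`.
#' Weight variants are matched to dosage columns by variant ID. When the
#' dosage matrix carries a `variant_info` attribute (as returned by
#' [read_dosage_matrix()] for VCF input), effect-allele orientation is
#' resolved: a dosage stored for the alternate allele is flipped to
#' `2 - d` when the weight's effect allele is the reference allele, and a
#' variant whose effect allele matches neither allele is counted
#' unresolvable. Missing dosages are imputed with the variant's mean
#' dosage over non-missing individuals (twice the effect-allele
#' frequency), or with zero under `missing_policy = "zero"`.
#'
#' @param dosages numeric matrix, individuals x variants, entries in
#'   `[0, 2]` with `NA` for missing; column names are variant IDs.
#' @param weights data frame of score weights (see [read_score_weights()]).
#' @param missing_policy `"impute_mean"` (default) or `"zero"`.
#' @return named numeric vector of raw scores with attributes `n_matched`,
#'   `n_unresolved` (weight variants absent or allele-unresolvable),
#'   `n_flipped` and `n_imputed`. Errors when more than half of the weight
#'   variants are unresolvable.
#' @export
compute_raw_scores <- function(dosages, weights,
                               missing_policy = c("impute_mean", "zero")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(dosages), is.data.frame(weights),
            all(c("variant_id", "weight") %in% names(weights)))
  idx <- match(weights$variant_id, colnames(dosages))
  vinfo <- attr(dosages, "variant_info")
  flip <- rep(FALSE, nrow(weights))
  unresolved <- is.na(idx)
  if (!is.null(vinfo) && "effect_allele" %in% names(weights)) {
    m <- match(weights$variant_id, vinfo$variant_id)
    has <- !is.na(m) & !unresolved
    ea <- weights$effect_allele[has]
    flip[has] <- ea == vinfo$ref[m[has]]
    bad <- has & !(weights$effect_allele == vinfo$alt[m] |
                     weights$effect_allele == vinfo$ref[m])
    bad[is.na(bad)] <- FALSE
    unresolved <- unresolved | bad
  }
  n_unresolved <- sum(unresolved)
  if (n_unresolved > 0.5 * nrow(weights))
    stop(sprintf("%d of %d weight variants unresolvable in the dosage matrix",
                 n_unresolved, nrow(weights)))
  use <- !unresolved
  D <- dosages[, idx[use], drop = FALSE]
  if (any(flip[use])) D[, flip[use]] <- 2 - D[, flip[use], drop = FALSE]
  n_imputed <- sum(is.na(D))
  if (n_imputed > 0) {
    fill <- if (missing_policy == "impute_mean")
      colMeans(D, na.rm = TRUE) else rep(0, ncol(D))
    fill[is.nan(fill)] <- 0
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- fill[na_idx[, 2]]
  }
  raw <- as.numeric(D %*% weights$weight[use])
  names(raw) <- rownames(dosages)
  structure(raw, n_matched = sum(use), n_unresolved = n_unresolved,
            n_flipped = sum(flip[use]), n_imputed = n_imputed)
}

#' Ancestry-correct scores by principal-component residualization
#'
#' Ordinary least squares of the raw score on an intercept and the leading
#' ancestry principal components; the residuals are the ancestry-corrected
#' score, exactly orthogonal to every PC and invariant to adding a
#' constant to the raw scores.
#'
#' @param raw numeric vector of raw scores.
#' @param pc numeric matrix or data frame of ancestry covariates (one
#'   column per component).
#' @return numeric vector of corrected scores (residuals) with the fitted
#'   coefficients in attribute `coefficients`.
#' @export
ancestry_correct <- function(raw, pc) {
  pc <- as.matrix(pc)
  stopifnot(is.numeric(raw), nrow(pc) == length(raw))
  if (length(raw) < ncol(pc) + 2L)
    stop("need at least K + 2 individuals to fit the ancestry model")
  if (is.null(colnames(pc))) colnames(pc) <- paste0("pc", seq_len(ncol(pc)))
  X <- cbind("(Intercept)" = 1, pc)
  fit <- lm.fit(X, raw)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):ncol(X)]]
    stop("ancestry design is rank deficient; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(as.numeric(fit$residuals), names = names(raw),
            coefficients = fit$coefficients)
}

#' Map scores to integer percentiles against a reference distribution
#'
#' Percentile = `ceiling(100 * r / n_ref)` clamped to `[1, 100]`, where `r`
#' is the mean rank of the value within the reference distribution (ties
#' receive their average rank; values outside the reference clamp to 1 or
#' 100).
#'
#' @param x numeric scores to map.
#' @param reference reference distribution (default: `x` itself).
#' @return integer vector of percentiles in `1:100`.
#' @export
percentile_map <- function(x, reference = x) {
  stopifnot(is.numeric(x), is.numeric(reference), length(reference) >= 1L)
  sr <- sort(reference)
  n_le <- findInterval(x, sr)
  n_lt <- findInterval(x, sr, left.open = TRUE)
  r <- n_lt + (n_le - n_lt + 1) / 2
  as.integer(pmin(100L, pmax(1L, ceiling(100 * r / length(sr)))))
}

#' Standardize scores against a reference distribution
#'
#' `z = (x - mean(reference)) / sd(reference)`, using the sample
#' (denominator `n - 1`) standard deviation.
#'
#' @inheritParams percentile_map
#' @return numeric vector of z scores.
#' @export
standardize_scores <- function(x, reference = x) {
  stopifnot(is.numeric(x), is.numeric(reference))
  s <- sd(reference)
  if (!is.finite(s) || s == 0)
    stop("reference distribution has zero or undefined standard deviation")
  (x - mean(reference)) / s
}

#' Remove score variants flanking a set of gene regions
#'
#' Drops every weight variant on the same chromosome as a gene whose
#' position falls within `window` base pairs of the gene footprint,
#' i.e. inside `[start - window, end + window]` with inclusive bounds.
#' Chromosome names are normalized by stripping a `"chr"` prefix (with a
#' warning when the two inputs use different dialects).
#'
#' @param weights score weight data frame with `chromosome` and `position`.
#' @param regions data frame of gene footprints with `chromosome`, `start`,
#'   `end` (1-based inclusive; see [read_regions()] for BED input).
#' @param window flank size in base pairs (default 1 Mb).
#' @return the pruned weights with attributes `n_removed` and
#'   `removed_ids`.
#' @export
exclude_flanking_variants <- function(weights, regions, window = 1e6) {
  stopifnot(all(c("chromosome", "position") %in% names(weights)))
  if (nrow(regions) == 0L)
    return(structure(weights, n_removed = 0L, removed_ids = character(0)))
  stopifnot(all(c("chromosome", "start", "end") %in% names(regions)))
  wc <- sub("^chr", "", as.character(weights$chromosome))
  rc <- sub("^chr", "", as.character(regions$chromosome))
  if (xor(any(grepl("^chr", weights$chromosome)),
          any(grepl("^chr", regions$chromosome))))
    warning("chromosome-name dialects differ (\"chr1\" vs \"1\"); normalized")
  drop <- rep(FALSE, nrow(weights))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (wc == rc[i] &
                      weights$position >= regions$start[i] - window &
                      weights$position <= regions$end[i] + window)
  }
  structure(weights[!drop, , drop = FALSE],
            n_removed = sum(drop),
            removed_ids = weights$variant_id[drop])
}

#' Residualize a score on a secondary score and ancestry components
#'
#' OLS of the primary score on the secondary score plus the ancestry PCs;
#' the residuals are a version of the primary score purged of the signal
#' captured by the secondary score (e.g. removing an LDL-cholesterol score
#' from a coronary disease score).
#'
#' @param primary,secondary aligned numeric score vectors.
#' @param pc ancestry covariate matrix as in [ancestry_correct()].
#' @return numeric residual vector with fitted coefficients in attribute
#'   `coefficients`.
#' @export
residualize_on_secondary_score <- function(primary, secondary, pc) {
  pc <- as.matrix(pc)
  stopifnot(length(primary) == length(secondary),
            nrow(pc) == length(primary))
  if (is.null(colnames(pc))) colnames(pc) <- paste0("pc", seq_len(ncol(pc)))
  X <- cbind("(Intercept)" = 1, secondary = secondary, pc)
  fit <- lm.fit(X, primary)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(as.numeric(fit$residuals), names = names(primary),
            coefficients = fit$coefficients)
}

#' Build a full score set (raw, corrected, z, percentile)
#'
#' Convenience wrapper chaining [compute_raw_scores()],
#' [ancestry_correct()], [standardize_scores()] and [percentile_map()].
#' The reference distribution for standardization and percentiles is the
#' corrected-score distribution of the scored individuals themselves.
#'
#' @inheritParams compute_raw_scores
#' @param pc ancestry covariates for [ancestry_correct()].
#' @return data frame with `individual_id`, `raw`, `corrected`, `z`,
#'   `percentile`.
#' @export
score_set <- function(dosages, weights, pc,
                      missing_policy = c("impute_mean", "zero")) {
  raw <- compute_raw_scores(dosages, weights, missing_policy)
  corrected <- ancestry_correct(as.numeric(raw), pc)
  data.frame(individual_id = rownames(dosages),
             raw = as.numeric(raw),
             corrected = as.numeric(corrected),
             z = standardize_scores(as.numeric(corrected)),
             percentile = percentile_map(as.numeric(corrected)),
             stringsAsFactors = FALSE)
}
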