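#' Read an individuals-by-variants dosage matrix
#'
#' Reads effect-allele dosages either from a tab-delimited table (first
#' column individual ID, remaining columns one variant each) or from a VCF
#' (using the `DS` dosage FORMAT field when present, otherwise counting
#' alternate alleles in `GT`; requires the vcfR package). Dosages must lie
#' in `[0, 2]`; missing entries are `NA`. For VCF input the returned
#' matrix carries a `variant_info` attribute (variant ID, chromosome,
#' position, ref, alt) recording that dosages count the alternate allele,
#' which [compute_raw_scores()] uses to resolve effect-allele orientation.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return numeric matrix, individuals x variants.
#' @export
read_dosage_matrix <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 1L) stop("empty dosage table: ", path)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                                as.numeric))),
                   arr.ind = TRUE)
      stop(sprintf("non-numeric dosage at data line %d of %s",
                   if (length(bad)) bad[1, 1] else NA_integer_, path))
    }
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    vid <- ifelse(is.na(fx$ID) | fx$ID == ".",
                  paste(fx$CHROM, fx$POS, fx$REF, fx$ALT, sep = ":"), fx$ID)
    fmt <- if (nrow(v@gt) > 0)
      unique(unlist(strsplit(v@gt[, "FORMAT"], ":"))) else character(0)
    if ("DS" %in% fmt) {
      d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      d <- apply(gt, c(1, 2), function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
      })
    }
    m <- t(d)
    colnames(m) <- vid
    attr(m, "variant_info") <- data.frame(
      variant_id = vid, chromosome = fx$CHROM,
      position = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
      stringsAsFactors = FALSE)
  }
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosages outside [0, 2] in ", path)
  m
}

#' Write a dosage matrix as tab-delimited text
#'
#' @param dosages individuals x variants matrix.
#' @param path output path.
#' @export
write_dosage_tsv <- function(dosages, path) {
  tab <- data.frame(individual_id = rownames(dosages), dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score weight file
#'
#' Whitespace- or tab-delimited file with a header; columns are matched
#' case-insensitively to `variant_id`/`id`, `chromosome`/`chrom`,
#' `position`/`pos`, `effect_allele`, optional `other_allele`, and
#' `weight`/`effect_weight`. Duplicate variant IDs are rejected.
#'
#' @param path file path.
#' @return data frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, (`other_allele`), `weight`.
#' @export
read_score_weights <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  lower <- tolower(names(tab))
  pick <- function(...) {
    i <- which(lower %in% c(...))
    if (length(i) == 0) NA_integer_ else i[1]
  }
  cols <- c(variant_id = pick("variant_id", "id", "snp", "rsid"),
            chromosome = pick("chromosome", "chrom", "chr"),
            position = pick("position", "pos", "bp"),
            effect_allele = pick("effect_allele", "ea", "a1"),
            weight = pick("weight", "effect_weight", "beta"))
  if (anyNA(cols))
    stop("weight file missing required column(s): ",
         paste(names(cols)[is.na(cols)], collapse = ", "))
  out <- data.frame(variant_id = as.character(tab[[cols["variant_id"]]]),
                    chromosome = as.character(tab[[cols["chromosome"]]]),
                    position = as.integer(tab[[cols["position"]]]),
                    effect_allele = as.character(tab[[cols["effect_allele"]]]),
                    weight = as.numeric(tab[[cols["weight"]]]),
                    stringsAsFactors = FALSE)
  oa <- pick("other_allele", "oa", "a2")
  if (!is.na(oa)) out$other_allele <- as.character(tab[[oa]])
  if (anyDuplicated(out$variant_id))
    stop("duplicate variant IDs in weight file: ",
         paste(head(out$variant_id[duplicated(out$variant_id)]),
               collapse = ", "))
  if (any(out$position <= 0, na.rm = TRUE)) stop("non-positive positions")
  if (any(!is.finite(out$weight))) stop("non-finite weights")
  out
}

#' Read a phenotype table
#'
#' CSV or TSV (by extension) with at least `individual_id`; validates ID
#' uniqueness, positive `age_dx_or_censor` and the implication
#' `prevalent => disease` when those columns are present.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(tab))
    stop("phenotype table must have an `individual_id` column")
  if (anyDuplicated(tab$individual_id))
    stop("duplicate individual IDs in phenotype table")
  if ("age_dx_or_censor" %in% names(tab) &&
      any(tab$age_dx_or_censor <= 0, na.rm = TRUE))
    stop("`age_dx_or_censor` must be positive")
  # prevalent means diagnosed before enrollment: under the time-to-event
  # definition that implies an event; in a cross-sectional table it implies
  # disease status
  if ("prevalent" %in% names(tab)) {
    against <- if ("event" %in% names(tab)) "event"
               else if ("disease" %in% names(tab)) "disease" else NULL
    if (!is.null(against) &&
        any(tab$prevalent == 1 & tab[[against]] == 0, na.rm = TRUE))
      stop(sprintf("`prevalent` implies `%s`", against))
  }
  tab
}

#' Read a variant annotation table
#'
#' Tab-delimited with header; requires `variant_id`, `gene`,
#' `consequence`, `classification`, at least one `af_*` frequency column,
#' and logical region/quality flags.
#'
#' @param path file path.
#' @return data frame suitable for [candidate_filter()].
#' @export
read_annotations <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "consequence", "classification",
            "low_complexity", "segdup", "rf_pass")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  af_cols <- grep("^af_", names(tab), value = TRUE)
  if (length(af_cols) == 0) stop("no `af_*` frequency columns")
  af <- as.matrix(tab[, af_cols, drop = FALSE])
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies outside [0, 1]")
  for (fl in c("low_complexity", "segdup", "rf_pass"))
    tab[[fl]] <- as.logical(tab[[fl]])
  tab
}

#' Read gene regions from a BED file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' 1-based inclusive convention used internally (start + 1). Column 4, if
#' present, is taken as the gene symbol.
#'
#' @param path BED file path.
#' @return data frame with `chromosome`, `start`, `end` (1-based
#'   inclusive), `gene`.
#' @export
read_regions <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns")
  out <- data.frame(chromosome = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L,
                    end = as.integer(tab[[3]]),
                    gene = if (ncol(tab) >= 4L) as.character(tab[[4]])
                           else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed BED interval (start > end)")
  out
}

#' Write gene regions as BED
#'
#' Converts the internal 1-based inclusive intervals back to 0-based
#' half-open BED.
#'
#' @param regions data frame with `chromosome`, `start`, `end`, `gene`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  write.table(data.frame(regions$chromosome, regions$start - 1L,
                         regions$end, regions$gene),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes phenotype CSV, dosage TSVs (common score variants and rare
#' variants), score weight TSV, annotation TSV, and a BED of gene
#' footprints into a directory.
#'
#' @param cohort a [generate_population()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"),
             dosages = file.path(dir, "dosages.tsv"),
             rare_dosages = file.path(dir, "rare_dosages.tsv"),
             weights = file.path(dir, "weights.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             regions = file.path(dir, "regions.bed"))
  write.table(cohort$phenotypes, paths["phenotypes"], sep = ",",
              quote = FALSE, row.names = FALSE)
  write_dosage_tsv(cohort$dosages, paths["dosages"])
  write_dosage_tsv(cohort$rare_dosages, paths["rare_dosages"])
  write.table(cohort$weights, paths["weights"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_regions_bed(cohort$regions, paths["regions"])
  invisible(paths)
}
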