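toy_weights <- function(w = c(0.1, -0.2, 0.3)) {
  data.frame(variant_id = c("v1", "v2", "v3"),
             chromosome = "1", position = c(100L, 200L, 300L),
             effect_allele = "A", weight = w, stringsAsFactors = FALSE)
}

toy_dosages <- function(x = rbind(c(0, 1, 2), c(2, 0, 1))) {
  dimnames(x) <- list(c("s1", "s2"), c("v1", "v2", "v3"))
  x
}

test_that("raw scores are the weighted dosage sums", {
  raw <- compute_raw_scores(toy_dosages(), toy_weights())
  expect_equal(as.numeric(raw), c(0.4, 0.5), tolerance = 1e-12)
  zero <- compute_raw_scores(toy_dosages(), toy_weights(c(0, 0, 0)))
  expect_equal(as.numeric(zero), c(0, 0))
})

test_that("missing dosages are mean-imputed (or zeroed on request)", {
  d <- rbind(c(0, 1, 2), c(2, 0, 1), c(NA, 1, 0))
  dimnames(d) <- list(c("s1", "s2", "s3"), c("v1", "v2", "v3"))
  raw <- compute_raw_scores(d, toy_weights())
  # v1 non-missing mean dosage is 1.0, so the missing entry adds 1.0 * 0.1
  expect_equal(as.numeric(raw[3]), 1.0 * 0.1 + 1 * (-0.2) + 0 * 0.3,
               tolerance = 1e-12)
  expect_equal(attr(raw, "n_imputed"), 1L)
  raw0 <- compute_raw_scores(d, toy_weights(), missing_policy = "zero")
  expect_equal(as.numeric(raw0[3]), -0.2, tolerance = 1e-12)
})

test_that("effect-allele orientation flips alternate-counted dosages", {
  d <- toy_dosages()
  attr(d, "variant_info") <- data.frame(
    variant_id = c("v1", "v2", "v3"), chromosome = "1",
    position = c(100L, 200L, 300L), ref = c("A", "C", "T"),
    alt = c("G", "A", "C"), stringsAsFactors = FALSE)
  # weights count allele A: v1 has A as ref -> flip; v2 has A as alt -> keep;
  # v3 has neither -> unresolved (dropped with a count)
  raw <- compute_raw_scores(d, toy_weights())
  expect_equal(attr(raw, "n_flipped"), 1L)
  expect_equal(attr(raw, "n_unresolved"), 1L)
  expect_equal(as.numeric(raw), c((2 - 0) * 0.1 + 1 * (-0.2),
                                  (2 - 2) * 0.1 + 0 * (-0.2)),
               tolerance = 1e-12)
  # more than half unresolvable is an error
  w_bad <- toy_weights(); w_bad$variant_id <- c("x1", "x2", "v3")
  attr(d, "variant_info")$alt <- c("G", "A", "C")
  expect_error(compute_raw_scores(d, w_bad), "unresolvable")
})

test_that("ancestry correction reproduces the closed-form OLS solution", {
  set.seed(51)
  pc <- cbind(pc1 = rnorm(5), pc2 = rnorm(5))
  raw <- c(1.2, -0.3, 0.5, 2.0, -1.1)
  corrected <- ancestry_correct(raw, pc)
  X <- cbind(1, pc)
  beta_hat <- solve(t(X) %*% X, t(X) %*% raw)  # normal equations by hand
  expect_equal(as.numeric(corrected), as.numeric(raw - X %*% beta_hat),
               tolerance = 1e-10)
  expect_lt(max(abs(cor(corrected, pc))), 1e-10)
})

test_that("orthogonal PCs reduce correction to centering", {
  raw <- c(3, 5, 7, 9)
  pc <- matrix(c(1, -1, -1, 1), ncol = 1)  # orthogonal to centered raw
  corrected <- ancestry_correct(raw, pc)
  expect_equal(as.numeric(corrected), raw - mean(raw), tolerance = 1e-10)
})

test_that("correction is invariant to shifting raw scores by a constant", {
  set.seed(52)
  pc <- matrix(rnorm(40), ncol = 2)
  raw <- rnorm(20)
  a <- ancestry_correct(raw, pc)
  b <- ancestry_correct(raw + 17.3, pc)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
  expect_equal(percentile_map(a), percentile_map(b))
  expect_equal(as.numeric(standardize_scores(a)),
               as.numeric(standardize_scores(b)), tolerance = 1e-10)
})

test_that("rank-deficient ancestry designs fail naming the columns", {
  pc <- cbind(pc1 = 1:6, pc2 = (1:6) * 2)
  expect_error(ancestry_correct(rnorm(6), pc), "pc2")
  expect_error(ancestry_correct(rnorm(3), matrix(rnorm(6), ncol = 2)),
               "K \\+ 2")
})

test_that("percentiles follow mean ranks with clamping", {
  set.seed(53)
  ref <- rnorm(100)
  expect_setequal(percentile_map(ref), 1:100)
  expect_equal(percentile_map(min(ref) - 5, ref), 1L)
  expect_equal(percentile_map(max(ref) + 5, ref), 100L)
  ref2 <- 1:1000
  expect_equal(percentile_map(500, ref2), 50L)
  # ties get mean ranks: value 1 has mean rank 1.5 -> ceil(150/4) = 38
  expect_equal(percentile_map(c(1, 1, 2, 2), c(1, 1, 2, 2)),
               c(38L, 38L, 88L, 88L))
})

test_that("standardization uses the sample SD and rejects degenerate refs", {
  expect_error(standardize_scores(c(2, 2, 2)), "zero")
  set.seed(54)
  x <- rnorm(200)
  z <- standardize_scores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize_scores(c(0, 2)), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
})

test_that("flanking exclusion uses inclusive footprint-edge distances", {
  w <- data.frame(variant_id = paste0("v", 1:4), chromosome = "1",
                  position = c(4L, 5L, 26L, 100L), effect_allele = "A",
                  weight = 0.1, stringsAsFactors = FALSE)
  gene <- data.frame(chromosome = "1", start = 10L, end = 20L, gene = "G1")
  pruned <- exclude_flanking_variants(w, gene, window = 5)
  expect_equal(attr(pruned, "n_removed"), 1L)
  expect_identical(attr(pruned, "removed_ids"), "v2")
  expect_identical(pruned$variant_id, c("v1", "v3", "v4"))
  # exactly at start - window is removed (inclusive bound)
  w2 <- w; w2$position <- 5L
  expect_equal(attr(exclude_flanking_variants(w2, gene, window = 5),
                    "n_removed"), 4L)
  # empty region set is the identity
  empty <- exclude_flanking_variants(w, gene[0, ])
  expect_identical(empty$variant_id, w$variant_id)
  expect_equal(attr(empty, "n_removed"), 0L)
})

test_that("flanking exclusion normalizes chromosome dialects and only removes", {
  w <- data.frame(variant_id = c("v1", "v2"), chromosome = c("chr1", "chr2"),
                  position = c(50L, 50L), effect_allele = "A", weight = 1,
                  stringsAsFactors = FALSE)
  gene <- data.frame(chromosome = "1", start = 40L, end = 60L, gene = "G")
  expect_warning(pruned <- exclude_flanking_variants(w, gene, window = 5),
                 "dialect")
  expect_identical(pruned$variant_id, "v2")
  expect_true(all(pruned$variant_id %in% w$variant_id))
})

test_that("secondary-score residualization leaves orthogonal residuals", {
  set.seed(55)
  pc <- matrix(rnorm(600), ncol = 3)
  secondary <- rnorm(200)
  primary <- 0.8 * secondary + rnorm(200, 0, 0.5)
  r <- residualize_on_secondary_score(primary, secondary, pc)
  expect_lt(abs(cor(r, secondary)), 1e-10)
  expect_lt(max(abs(cor(r, pc))), 1e-10)
  # identical secondary absorbs everything
  r0 <- residualize_on_secondary_score(primary, primary, pc)
  expect_lt(max(abs(r0)), 1e-10)
  # independent secondary: residuals are essentially the centered primary
  indep <- rnorm(200)
  r1 <- residualize_on_secondary_score(primary, indep, pc)
  fit <- lm.fit(cbind(1, indep, pc), primary)
  expect_equal(as.numeric(r1), as.numeric(fit$residuals), tolerance = 1e-10)
  expect_gt(cor(r1, primary - mean(primary)), 0.95)
})

test_that("score_set chains the engine into a consistent table", {
  co <- test_cohort()
  pcs <- as.matrix(co$phenotypes[, grep("^pc", names(co$phenotypes))])
  ss <- score_set(co$dosages, co$weights, pcs)
  expect_identical(ss$individual_id, co$phenotypes$individual_id)
  expect_true(all(ss$percentile >= 1 & ss$percentile <= 100))
  expect_equal(mean(ss$z), 0, tolerance = 1e-10)
  expect_equal(sd(ss$z), 1, tolerance = 1e-10)
  expect_equal(ss$raw, co$truth$raw_score, tolerance = 1e-10)
})
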