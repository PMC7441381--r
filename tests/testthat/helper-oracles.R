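# Brute-force enumeration of the conditional Bernoulli law: all size-m
# subsets with probability proportional to prod(p[s]) * prod(1 - p[-s]).
enum_cond_bernoulli <- function(p, m) {
  n <- length(p)
  subs <- utils::combn(n, m)
  w <- apply(subs, 2, function(s) prod(p[s]) * prod(1 - p[seq_len(n)[-s]]))
  list(subsets = subs, prob = w / sum(w))
}

# Key a drawn 0/1 vector to its subset index in the enumeration.
subset_key <- function(y) paste(which(y == 1), collapse = ",")

enum_keys <- function(enum) {
  apply(enum$subsets, 2, paste, collapse = ",")
}

# Small cohorts reused across tests (built once per test run).
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, maker) {
  if (is.null(.cohort_cache[[name]])) .cohort_cache[[name]] <- maker()
  .cohort_cache[[name]]
}

test_cohort <- function() {
  cached_cohort("base", function() {
    cfg <- sim_config(n_individuals = 6000L, n_score_variants = 60L,
                      fst = 0.1, carrier_frequency = 0.01,
                      baseline_prevalence = 0.1, seed = 42L)
    co <- generate_population(cfg)
    co <- assign_disease_cross_sectional(co)
    assign_onset_ages(co)
  })
}
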