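#' Sample from the conditional Bernoulli distribution
#'
#' Draws binary vectors `y` distributed as independent Bernoulli(`p[i]`)
#' conditioned on `sum(y) == n_cases`, the law with
#' `P(y) proportional to prod(r[i]^y[i])` for odds `r[i] = p[i]/(1-p[i])`.
#' This is the sampling primitive behind retrospective power analysis with
#' the observed case total held fixed: each simulated phenotype vector has
#' exactly the study's number of cases while respecting heterogeneous
#' per-individual case probabilities.
#'
#' Two exact samplers are provided. `"dp"` fills the backward
#' Poisson-binomial recursion (an `O(n * n_cases)` table) and samples each
#' individual sequentially from the exact conditional inclusion probability.
#' `"reject"` exponentially tilts `p` so the expected sum equals `n_cases`
#' (tilting multiplies every odds by one constant, which leaves the
#' conditional law unchanged) and then accepts independent Bernoulli draws
#' whose sum hits `n_cases`; acceptance is of order `1/sd(sum)`, making it
#' the faster choice at biobank scale. `"auto"` uses the table when it is
#' small and rejection otherwise.
#'
#' Entries with `p` equal to 0 or 1 are treated as forced assignments and
#' removed before sampling.
#'
#' @param p numeric vector of per-individual case probabilities in `[0, 1]`.
#' @param n_cases integer, the fixed number of cases (`sum(y)`).
#' @param ndraws number of independent draws.
#' @param method `"auto"`, `"dp"` or `"reject"`.
#' @param max_tries maximum rejection attempts per draw before failing over.
#' @return integer matrix with `ndraws` rows and `length(p)` columns; every
#'   row sums to `n_cases`.
#' @examples
#' y <- rcond_bernoulli(c(0.9, 0.5, 0.1), 1, ndraws = 5, method = "dp")
#' rowSums(y)
#' @export
rcond_bernoulli <- function(p, n_cases, ndraws = 1L,
                            method = c("auto", "dp", "reject"),
                            max_tries = 1e6L) {
  method <- match.arg(method)
  stopifnot(is.numeric(p), length(p) >= 1L, ndraws >= 1L)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must be probabilities in [0, 1] without NA")
  n <- length(p)
  n_cases <- as.integer(n_cases)
  if (n_cases < 0L || n_cases > n)
    stop("`n_cases` must lie in [0, length(p)]")

  forced1 <- which(p == 1)
  forced0 <- which(p == 0)
  free <- which(p > 0 & p < 1)
  m <- n_cases - length(forced1)
  if (m < 0L || m > length(free))
    stop(sprintf(
      "conditioning event has probability zero: %d forced cases, %d forced controls, %d free slots for %d requested cases",
      length(forced1), length(forced0), length(free), n_cases))

  out <- matrix(0L, nrow = ndraws, ncol = n)
  out[, forced1] <- 1L

  if (length(free) > 0L && m > 0L && m < length(free)) {
    pf <- p[free]
    if (method == "auto") {
      method <- if ((length(free) + 1) * (min(m, length(free) - m) + 1) <= 2^24)
        "dp" else "reject"
    }
    yf <- switch(method,
      dp = {
        # complement trick keeps the table narrow when m > n/2
        if (m > length(free) - m) {
          1L - .cb_dp_sample(1 - pf, length(free) - m, as.integer(ndraws))
        } else {
          .cb_dp_sample(pf, m, as.integer(ndraws))
        }
      },
      reject = {
        # tilt only when E[sum] is off target; a well-calibrated p already
        # gives O(1/sd) acceptance and tilting would be a no-op
        off <- abs(sum(pf) - m)
        pt <- if (off < 0.25 * sqrt(sum(pf * (1 - pf)) + 1))
          pf else .tilt_to_mean(pf, m)
        .cb_reject_sample(pt, m, as.integer(ndraws), as.integer(max_tries))$y
      })
    out[, free] <- yf
  } else if (length(free) > 0L && m == length(free)) {
    out[, free] <- 1L
  }
  out
}

# Exponential tilt: find c on the log-odds scale so that
# sum(plogis(logit(p) + c)) == m.
.tilt_to_mean <- function(p, m) {
  lo <- log(p) - log1p(-p)
  f <- function(c) sum(plogis(lo + c)) - m
  c_star <- uniroot(f, lower = -45, upper = 45, tol = 1e-10)$root
  plogis(lo + c_star)
}

#' Exact conditional inclusion probabilities
#'
#' Computes `P(y[i] = 1 | sum(y) = n_cases)` for independent
#' Bernoulli(`p[i]`) components by forward/backward Poisson-binomial
#' recursions: `pi_i = p_i * P(sum of the others = n_cases - 1) /
#' P(sum = n_cases)`.
#'
#' @inheritParams rcond_bernoulli
#' @return numeric vector of inclusion probabilities summing to `n_cases`.
#' @export
cond_bernoulli_inclusion <- function(p, n_cases) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must be probabilities in [0, 1] without NA")
  n <- length(p)
  m <- as.integer(n_cases)
  if (m < 0L || m > n) stop("`n_cases` must lie in [0, length(p)]")

  # backward tail distributions: B[[i]][j+1] = P(sum of y_i..y_n == j)
  B <- vector("list", n + 1L)
  B[[n + 1L]] <- 1
  for (i in n:1) {
    prev <- B[[i + 1L]]
    cur <- c(prev * (1 - p[i]), 0) + c(0, prev * p[i])
    B[[i]] <- cur[seq_len(min(length(cur), m + 1L))]
  }
  denom <- if (length(B[[1L]]) >= m + 1L) B[[1L]][m + 1L] else 0
  if (denom <= 0) stop("conditioning event has probability zero")

  fw <- 1  # forward: P(sum of y_1..y_{i-1} == j)
  incl <- numeric(n)
  for (i in seq_len(n)) {
    if (m >= 1L) {
      tail_i <- B[[i + 1L]]
      # P(sum of others == m - 1) = sum_j fw[j] * tail_i[m - 1 - j]
      jmax <- min(length(fw) - 1L, m - 1L)
      js <- 0:jmax
      needed <- m - 1L - js
      ok <- needed < length(tail_i)
      s <- sum(fw[js[ok] + 1L] * tail_i[needed[ok] + 1L])
      incl[i] <- p[i] * s / denom
    }
    fw <- c(fw * (1 - p[i]), 0) + c(0, fw * p[i])
    fw <- fw[seq_len(min(length(fw), m + 1L))]
  }
  incl
}
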