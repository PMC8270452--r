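# Exact and Monte-Carlo multinomial goodness-of-fit p-values for a single
# day's (n_F, n_C, n_U) count vector. The ordering statistic is the null
# probability of the observed composition: the p-value sums the null
# probability of every outcome no more probable than the observed one
# (ties included), the standard exact multinomial test.

# Shared preprocessing: validate, apply the zero-null convention, drop
# empty categories. Returns NULL when the p-value is decided already.
prep_multinomial <- function(counts, probs) {
  if (length(counts) != length(probs)) {
    stop_pw("counts and probs must have the same length")
  }
  counts <- as.integer(round(counts))
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_pw("counts must be non-negative integers")
  }
  probs <- check_simplex(probs, "null probabilities")
  n <- sum(counts)
  if (n < 1) stop_pw("total count must be >= 1")
  # A positive count in a category the null rules out is impossible under
  # the null: p-value 0 by convention.
  if (any(probs == 0 & counts > 0)) {
    return(list(decided = 0))
  }
  keep <- probs > 0
  list(decided = NULL, counts = counts[keep], probs = probs[keep], n = n)
}

# log null probability of a composition, with a factorial lookup table lf
# (lf[i] = lfactorial(i - 1)).
log_prob_obs <- function(counts, lp, lf, n) {
  lf[n + 1] - sum(lf[counts + 1]) + sum(counts * lp)
}

#' Exact multinomial goodness-of-fit p-value
#'
#' Enumerates every composition of the day's total `n` over the (up to
#' three) categories with positive null probability and sums the null
#' probabilities of all outcomes at most as probable as the observed one.
#' Feasible for `n` up to `cap` (about `(n+1)(n+2)/2` compositions); above
#' the cap use [mc_multinomial_pvalue()].
#'
#' @param counts Observed count vector (length <= 3 after removing
#'   categories with null probability zero).
#' @param probs Null probability vector on the simplex, same length.
#' @param cap Largest total count enumerated exactly (default 2000).
#' @return The exact p-value in `[0, 1]`. A positive count in a category
#'   with null probability zero returns 0 (impossible outcome).
#' @examples
#' exact_multinomial_pvalue(c(3, 0, 0), c(0.5, 0.3, 0.2))
#' @export
exact_multinomial_pvalue <- function(counts, probs, cap = 2000) {
  pp <- prep_multinomial(counts, probs)
  if (!is.null(pp$decided)) return(pp$decided)
  counts <- pp$counts; probs <- pp$probs; n <- pp$n
  k <- length(counts)
  if (k == 1) return(1)
  if (k > 3) stop_pw("exact enumeration supports at most 3 categories")
  if (n > cap) {
    stop_pw("n = ", n, " exceeds the enumeration cap (", cap,
            "); use mc_multinomial_pvalue()")
  }
  lf <- lfactorial(0:n)
  lp <- log(probs)
  if (k == 2) {
    a <- 0:n
    lpx <- lf[n + 1] - lf[a + 1] - lf[n - a + 1] + a * lp[1] +
      (n - a) * lp[2]
  } else {
    a <- rep.int(0:n, (n:0) + 1L)
    b <- sequence((n:0) + 1L) - 1L
    cc <- n - a - b
    lpx <- lf[n + 1] - lf[a + 1] - lf[b + 1] - lf[cc + 1] +
      a * lp[1] + b * lp[2] + cc * lp[3]
  }
  lobs <- log_prob_obs(counts, lp, lf, n)
  min(1, sum(exp(lpx[lpx <= lobs + 1e-9])))
}

#' Monte-Carlo multinomial goodness-of-fit p-value
#'
#' Simulates `n_sim` count vectors from the null and applies the
#' add-one-rank estimator `(1 + #\{P(sim) <= P(obs)\}) / (1 + n_sim)`, which
#' is a valid p-value for any `n_sim`. Intended for totals beyond the exact
#' enumeration cap.
#'
#' @inheritParams exact_multinomial_pvalue
#' @param n_sim Number of simulated tables (>= 1000; default 10000).
#' @param seed Optional integer seed; given the seed the p-value is
#'   reproducible.
#' @return The Monte-Carlo p-value in `(0, 1]`.
#' @export
mc_multinomial_pvalue <- function(counts, probs, n_sim = 10000, seed = NULL) {
  if (n_sim < 1000) stop_pw("n_sim must be >= 1000")
  pp <- prep_multinomial(counts, probs)
  if (!is.null(pp$decided)) return(pp$decided)
  counts <- pp$counts; probs <- pp$probs; n <- pp$n
  if (length(counts) == 1) return(1)
  draw <- function() stats::rmultinom(n_sim, n, probs)
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  lf <- lfactorial(0:n)
  lp <- log(probs)
  lpx <- lf[n + 1] - colSums(matrix(lf[x + 1], nrow = length(probs))) +
    colSums(x * lp)
  lobs <- log_prob_obs(counts, lp, lf, n)
  (1 + sum(lpx <= lobs + 1e-9)) / (1 + n_sim)
}

# Dispatcher used by the day-level tests: exact when feasible, else MC.
multinomial_pvalue_auto <- function(counts, probs, exact_cap = 2000,
                                    n_sim = 10000, seed = NULL) {
  n <- sum(counts)
  if (n <= exact_cap) {
    list(p = exact_multinomial_pvalue(counts, probs, cap = exact_cap),
         method = "exact")
  } else {
    list(p = mc_multinomial_pvalue(counts, probs, n_sim = n_sim, seed = seed),
         method = "monte_carlo")
  }
}
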