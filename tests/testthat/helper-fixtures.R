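# Shared fixture builders for the test suite.

# Daily polarity series from a counts matrix (rows = days, cols = F, C, U).
make_series <- function(counts, start = "2018-01-01", interactions = NULL) {
  counts <- matrix(counts, ncol = 3)
  daily_polarity(seq(as.Date(start), by = "day", length.out = nrow(counts)),
                 counts[, 1], counts[, 2], counts[, 3],
                 interactions = interactions)
}

# Post-record data frame from parallel vectors.
make_posts <- function(ids, days, labels, retweets = 0, likes = 0,
                       start = "2018-01-01") {
  n <- length(ids)
  data.frame(
    post_id = as.character(ids),
    timestamp = as.POSIXct(as.Date(start), tz = "UTC") +
      (rep_len(days, n) - 1) * 86400 + seq_len(n),
    label = rep_len(labels, n),
    n_retweets = as.integer(rep_len(retweets, n)),
    n_likes = as.integer(rep_len(likes, n)),
    stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the exact multinomial p-value:
# enumerate all compositions with dmultinom and sum those no more probable
# than the observed outcome.
oracle_multinomial_pvalue <- function(counts, probs) {
  n <- sum(counts)
  grid <- expand.grid(a = 0:n, b = 0:n)
  grid <- grid[grid$a + grid$b <= n, ]
  pr <- apply(grid, 1, function(r) {
    stats::dmultinom(c(r[1], r[2], n - r[1] - r[2]), prob = probs)
  })
  pobs <- stats::dmultinom(counts, prob = probs)
  sum(pr[pr <= pobs * (1 + 1e-9)])
}

# Clopper-Pearson interval by direct tail inversion with uniroot (oracle
# independent of stats::binom.test).
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- (1 - level) / 2
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}
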