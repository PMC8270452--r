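# Day-level disorientation tests: basic multinomial (yearly null), running
# multinomial (trailing-window null) and running-variance (chi-square).

# Common result-frame constructor. `statistic` is the log null probability
# of the observed composition for the multinomial tests and the chi-square
# statistic for the variance test.
new_daily_test_result <- function(date, volume, statistic, p_value, method,
                                  direction, skipped, skip_reason, null_info) {
  out <- data.frame(date = date, volume = volume, statistic = statistic,
                    p_value = p_value, method = method, direction = direction,
                    skipped = skipped, skip_reason = skip_reason,
                    stringsAsFactors = FALSE)
  attr(out, "null_info") <- null_info
  class(out) <- c("daily_test_result", "data.frame")
  out
}

#' Basic daily multinomial test against the yearly null
#'
#' For every day with enough volume, tests whether the day's
#' (favourable, contrary, undecided) counts could be a multinomial sample
#' whose parameter vector is the pooled yearly polarity proportion —
#' i.e. whether the day's opinion mix deviates beyond sampling noise from
#' the whole-period average. Exact enumeration is used up to `exact_cap`
#' posts per day, seeded Monte Carlo above.
#'
#' @param series A [daily_polarity()] series with positive total volume.
#' @param min_volume Smallest daily volume tested (default 1); days below it
#'   are marked skipped.
#' @param exact_cap,n_sim See [exact_multinomial_pvalue()] and
#'   [mc_multinomial_pvalue()].
#' @param seed Optional base seed; day `t` uses a sub-seed derived from it
#'   so results do not depend on evaluation order.
#' @return A `daily_test_result` data frame (one row per day) with columns
#'   `date, volume, statistic, p_value, method, direction, skipped,
#'   skip_reason`; the null proportions are attached as the `"null_info"`
#'   attribute.
#' @seealso [running_daily_test()], [running_variance_test()],
#'   [rejection_summary()]
#' @export
basic_daily_test <- function(series, min_volume = 1, exact_cap = 2000,
                             n_sim = 10000, seed = NULL) {
  counts <- as.matrix(series[, c("n_F", "n_C", "n_U")])
  total <- colSums(counts)
  if (sum(total) == 0) stop_pw("series has zero total volume")
  null_probs <- total / sum(total)
  n_days <- nrow(series)
  p <- stat <- rep(NA_real_, n_days)
  method <- rep(NA_character_, n_days)
  skipped <- series$volume < min_volume
  reason <- ifelse(skipped, "low_volume", NA_character_)
  for (t in which(!skipped)) {
    res <- multinomial_pvalue_auto(
      counts[t, ], null_probs, exact_cap = exact_cap, n_sim = n_sim,
      seed = if (is.null(seed)) NULL else derive_seed(seed, t))
    p[t] <- res$p
    method[t] <- res$method
    stat[t] <- obs_log_prob(counts[t, ], null_probs)
  }
  new_daily_test_result(series$date, series$volume, stat, p, method,
                        NA_character_, skipped, reason,
                        list(type = "yearly", probs = null_probs))
}

# log null probability of an observed composition (reporting statistic).
obs_log_prob <- function(counts, probs) {
  keep <- probs > 0
  if (any(counts[!keep] > 0)) return(-Inf)
  stats::dmultinom(counts[keep], prob = probs[keep], log = TRUE)
}

#' Running-window daily multinomial test
#'
#' Tests each day's polarity counts against a "running" null built from the
#' `window` preceding days: by default the unweighted mean of their daily
#' proportion vectors (`null_type = "pooled"` pools their counts instead).
#' The first `window` days and days with fewer than `min_history` non-empty
#' preceding days in the window are skipped. A category absent from the
#' running null but observed on the tested day yields p = 0 (impossible
#' under the null).
#'
#' @inheritParams basic_daily_test
#' @param window Length of the trailing window in days (default 15, >= 2);
#'   the tested day itself is excluded.
#' @param min_history Minimum number of non-empty (volume > 0) days required
#'   inside the window (default 5).
#' @param null_type `"mean"` (default, average of daily proportion vectors)
#'   or `"pooled"` (proportions of the pooled window counts).
#' @return A `daily_test_result` data frame; see [basic_daily_test()].
#' @export
running_daily_test <- function(series, window = 15, min_history = 5,
                               min_volume = 1,
                               null_type = c("mean", "pooled"),
                               exact_cap = 2000, n_sim = 10000, seed = NULL) {
  null_type <- match.arg(null_type)
  if (window < 2) stop_pw("window must be >= 2")
  counts <- as.matrix(series[, c("n_F", "n_C", "n_U")])
  props <- polarity_proportions(series)
  n_days <- nrow(series)
  p <- stat <- rep(NA_real_, n_days)
  method <- reason <- rep(NA_character_, n_days)
  skipped <- rep(TRUE, n_days)
  for (t in seq_len(n_days)) {
    if (t <= window) { reason[t] <- "warmup"; next }
    prev <- (t - window):(t - 1)
    nonempty <- prev[series$volume[prev] > 0]
    if (length(nonempty) < min_history) {
      reason[t] <- "insufficient_history"; next
    }
    if (series$volume[t] < min_volume) { reason[t] <- "low_volume"; next }
    null_probs <- if (null_type == "mean") {
      colMeans(props[nonempty, , drop = FALSE])
    } else {
      cs <- colSums(counts[nonempty, , drop = FALSE])
      cs / sum(cs)
    }
    res <- multinomial_pvalue_auto(
      counts[t, ], null_probs, exact_cap = exact_cap, n_sim = n_sim,
      seed = if (is.null(seed)) NULL else derive_seed(seed, t))
    skipped[t] <- FALSE
    p[t] <- res$p
    method[t] <- res$method
    stat[t] <- obs_log_prob(counts[t, ], null_probs)
  }
  new_daily_test_result(series$date, series$volume, stat, p, method,
                        NA_character_, skipped, reason,
                        list(type = "running", window = window,
                             null_type = null_type))
}

#' Chi-square p-values for a running variance against a reference variance
#'
#' Workhorse behind [running_variance_test()], usable on any numeric series:
#' for each position the sample variance of the trailing `window` observed
#' values is compared with the reference variance `sigma0_sq` via
#' \eqn{T = (w-1) s_w^2 / \sigma_0^2 \sim \chi^2_{w-1}}, two-sided
#' (`p = 2 min(F(T), 1 - F(T))`, capped at 1).
#'
#' @param x Numeric vector (daily favourable proportions); `NA` entries are
#'   skipped and do not enter any window.
#' @param window Window length (>= 3).
#' @param sigma0_sq Reference variance; defaults to the sample variance
#'   (divisor N-1) of the non-missing values of `x`. Must be positive.
#' @return A data frame `statistic, p_value, direction, skipped,
#'   skip_reason` aligned with `x`; direction is `"high"` or `"low"`
#'   according to the sign of `s_w^2 - sigma0_sq`.
#' @export
running_variance_pvalues <- function(x, window = 15, sigma0_sq = NULL) {
  if (window < 3) stop_pw("window must be >= 3")
  obs <- which(!is.na(x))
  if (is.null(sigma0_sq)) sigma0_sq <- stats::var(x[obs])
  if (!is.finite(sigma0_sq) || sigma0_sq <= 0) {
    stop_pw("reference variance must be positive")
  }
  n <- length(x)
  stat <- p <- rep(NA_real_, n)
  direction <- reason <- rep(NA_character_, n)
  skipped <- rep(TRUE, n)
  reason[is.na(x)] <- "no_data"
  df <- window - 1
  for (i in seq_along(obs)) {
    t <- obs[i]
    if (i < window) { reason[t] <- "warmup"; next }
    win <- x[obs[(i - window + 1):i]]
    s2 <- stats::var(win)
    stat[t] <- df * s2 / sigma0_sq
    lo <- stats::pchisq(stat[t], df)
    p[t] <- min(1, 2 * min(lo, 1 - lo))
    direction[t] <- if (s2 >= sigma0_sq) "high" else "low"
    skipped[t] <- FALSE
  }
  data.frame(statistic = stat, p_value = p, direction = direction,
             skipped = skipped, skip_reason = reason,
             stringsAsFactors = FALSE)
}

#' Running-variance test on the favourable proportion
#'
#' Computes the trailing `window`-day sample variance of the daily
#' favourable proportion and tests, per day, whether it equals the yearly
#' variance of that proportion, using the standard chi-square variance test
#' (two-sided). Significantly high variance flags short-term instability;
#' significantly low variance flags opinion "freezing".
#'
#' @inheritParams basic_daily_test
#' @param window Trailing window length in non-empty days (default 15).
#' @param sigma0_sq Yearly reference variance; defaults to the sample
#'   variance of the favourable proportion over all non-empty days.
#' @return A `daily_test_result` data frame; `statistic` holds
#'   \eqn{(w-1)s_w^2/\sigma_0^2} and `direction` the side of the deviation.
#' @export
running_variance_test <- function(series, window = 15, sigma0_sq = NULL) {
  p_f <- polarity_proportions(series)[, "F"]
  core <- running_variance_pvalues(p_f, window = window,
                                   sigma0_sq = sigma0_sq)
  new_daily_test_result(series$date, series$volume, core$statistic,
                        core$p_value, ifelse(core$skipped, NA_character_,
                                             "chi2_variance"),
                        core$direction, core$skipped, core$skip_reason,
                        list(type = "variance", window = window,
                             sigma0_sq = sigma0_sq %||%
                               stats::var(p_f, na.rm = TRUE)))
}

#' Rejection-day summary at multiple significance levels
#'
#' Counts, for each significance level, the tested (non-skipped) days whose
#' p-value falls at or below the level, next to the count expected under the
#' null (`alpha` times the number of tested days) — the paper-style
#' "observed vs expected rejection days" comparison that replaces a
#' multiplicity correction.
#'
#' @param results A `daily_test_result` data frame.
#' @param alphas Significance levels (default `c(0.10, 0.05, 0.01)`).
#' @return A `test_summary` data frame with columns `alpha, rejected_days,
#'   expected_days, tested_days`.
#' @export
rejection_summary <- function(results, alphas = c(0.10, 0.05, 0.01)) {
  tested <- !results$skipped
  n_tested <- sum(tested)
  pv <- results$p_value[tested]
  out <- data.frame(
    alpha = alphas,
    rejected_days = vapply(alphas, function(a) sum(pv <= a), integer(1)),
    expected_days = alphas * n_tested,
    tested_days = n_tested)
  class(out) <- c("test_summary", "data.frame")
  out
}

#' @export
print.test_summary <- function(x, ...) {
  cat(sprintf("Rejection-day summary (%d tested days)\n", x$tested_days[1]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  alpha = %4.2f: %3d rejected vs %.2f expected\n",
                x$alpha[i], x$rejected_days[i], x$expected_days[i]))
  }
  invisible(x)
}

#' Window-length sensitivity analysis for the running tests
#'
#' Re-runs the running multinomial and/or running-variance test for each
#' window length and tabulates the rejection-day summaries, to check how
#' robust the flagged days are to the (somewhat arbitrary) choice of the
#' stable-opinion horizon.
#'
#' @inheritParams running_daily_test
#' @param windows Integer vector of window lengths (each >= 2; the variance
#'   test additionally requires >= 3).
#' @param alphas Significance levels for the summaries.
#' @param tests Character subset of `c("running", "variance")`.
#' @param ... Passed on to [running_daily_test()].
#' @return A data frame with columns `window, test, alpha, rejected_days,
#'   expected_days, tested_days` (zero rows for an empty `windows`).
#' @export
window_sensitivity <- function(series, windows, alphas = c(0.10, 0.05, 0.01),
                               tests = c("running", "variance"), ...) {
  tests <- match.arg(tests, several.ok = TRUE)
  rows <- list()
  for (w in windows) {
    for (test in tests) {
      res <- if (test == "running") {
        running_daily_test(series, window = w, ...)
      } else {
        running_variance_test(series, window = w)
      }
      s <- rejection_summary(res, alphas)
      rows[[length(rows) + 1]] <- cbind(window = w, test = test,
                                        as.data.frame(s))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(window = integer(0), test = character(0),
                      alpha = numeric(0), rejected_days = integer(0),
                      expected_days = numeric(0), tested_days = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
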