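# Synthetic opinion-stream generator. The default scenario emulates the
# statistical structure of a year of vaccine-debate posts: a baseline
# polarity mix of roughly 70% favourable / 16% contrary / 14% undecided,
# negative-binomial daily volumes with three dominant spikes, short
# event-driven shifts of the favourable share around those spikes, and a
# slow parabolic trend in the favourable share (rising until late spring,
# then declining by 7-8 points by year end).

#' Scenario configuration for the synthetic opinion stream
#'
#' Full parametrisation of a simulated labelled-post stream. The truth
#' trajectory is built as baseline composed with the long-term trend
#' (a quadratic on the logit of the favourable share over normalised time
#' `s in [0, 1]`, contrary:undecided ratio held fixed) and with short
#' additive events on the favourable share (the complement rescaled
#' proportionally). Daily volumes are negative binomial with optional
#' multiplicative spikes; interactions add a heavy-tailed (lognormal)
#' like/retweet multiplier.
#'
#' @param n_days Number of days (default 365).
#' @param start_date First calendar day (default `"2018-01-01"`).
#' @param baseline Baseline polarity probabilities `(F, C, U)` on the
#'   simplex (default `c(0.70, 0.164, 0.136)`).
#' @param volume_mean,volume_dispersion Negative-binomial daily volume mean
#'   (default 200) and dispersion `size` (default 5; smaller = burstier).
#' @param spikes List of `c(day, multiplier)` volume spikes. The default
#'   (`NULL`) places three dominant peaks in late June, early August and
#'   early September for full-year scenarios, and none for shorter ones.
#' @param events List of `c(start_day, duration_days, delta)` short
#'   perturbations adding `delta` to the favourable share. The default
#'   (`NULL`) mimics the moderate peak-day shifts around the three spikes
#'   for full-year scenarios, and is empty for shorter ones.
#' @param trend Quadratic coefficients `c(a, b, c)` of the logit-scale
#'   long-term trend `a + b s + c s^2`; the default rises to a vertex about
#'   40% through the period and ends about 7.5 points below the peak.
#'   `c(0, 0, 0)` disables the trend.
#' @param ooc_fraction Fraction of generated posts that are out-of-context
#'   (default 0.578) — these never enter polarity counts.
#' @param duplicate_rate Fraction of post records duplicated verbatim to
#'   exercise deduplication (default 0.02).
#' @param interaction_meanlog,interaction_sdlog Lognormal parameters of the
#'   per-day likes+retweets multiplier (defaults 1 and 1).
#' @param seed Default integer seed for generation.
#' @return A validated `scenario_config` list.
#' @seealso [generate_series()], [generate_posts()],
#'   [calibration_experiment()]
#' @export
scenario_config <- function(n_days = 365,
                            start_date = "2018-01-01",
                            baseline = c(F = 0.70, C = 0.164, U = 0.136),
                            volume_mean = 200,
                            volume_dispersion = 5,
                            spikes = NULL,
                            events = NULL,
                            trend = c(-0.094, 0.910, -1.066),
                            ooc_fraction = 0.578,
                            duplicate_rate = 0.02,
                            interaction_meanlog = 1,
                            interaction_sdlog = 1,
                            seed = 1L) {
  if (n_days < 1) stop_pw("n_days must be >= 1")
  # The standard-year defaults (three dominant peaks with moderate
  # favourable-share shifts) only make sense for a full-year series;
  # shorter scenarios default to no spikes and no events.
  if (is.null(spikes)) {
    spikes <- if (n_days >= 365) {
      list(c(173, 30), c(216, 60), c(248, 45))
    } else {
      list()
    }
  }
  if (is.null(events)) {
    events <- if (n_days >= 365) {
      list(c(173, 3, 0.017), c(216, 5, 0.077), c(248, 3, 0.036))
    } else {
      list()
    }
  }
  baseline <- check_simplex(baseline, "baseline")
  if (volume_mean <= 0) stop_pw("volume_mean must be > 0")
  if (volume_dispersion <= 0) stop_pw("volume_dispersion must be > 0")
  if (length(trend) != 3 || any(!is.finite(trend))) {
    stop_pw("trend must be three finite quadratic coefficients")
  }
  for (sp in spikes) {
    if (length(sp) != 2 || sp[1] < 1 || sp[1] > n_days || sp[2] <= 0) {
      stop_pw("each spike must be c(day, multiplier) within the period")
    }
  }
  for (ev in events) {
    if (length(ev) != 3 || ev[1] < 1 || ev[1] > n_days || ev[2] < 1) {
      stop_pw("each event must be c(start_day, duration_days, delta)")
    }
  }
  if (ooc_fraction < 0 || ooc_fraction >= 1) {
    stop_pw("ooc_fraction must be in [0, 1)")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop_pw("duplicate_rate must be in [0, 1)")
  }
  cfg <- list(n_days = as.integer(n_days),
              start_date = as.Date(start_date),
              baseline = stats::setNames(baseline, POLARITY_LEVELS),
              volume_mean = volume_mean,
              volume_dispersion = volume_dispersion,
              spikes = spikes, events = events, trend = trend,
              ooc_fraction = ooc_fraction,
              duplicate_rate = duplicate_rate,
              interaction_meanlog = interaction_meanlog,
              interaction_sdlog = interaction_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' A null scenario: no events, no spikes, no trend
#'
#' Convenience wrapper around [scenario_config()] with all perturbations
#' switched off — the configuration used for type-I-error (calibration)
#' experiments.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
null_scenario <- function(...) {
  scenario_config(spikes = list(), events = list(), trend = c(0, 0, 0), ...)
}

# Deterministic truth trajectory p(t), n_days x 3, plus event-day flags and
# the days clipped to stay inside the simplex.
truth_trajectory <- function(config) {
  n <- config$n_days
  base <- config$baseline
  s <- if (n > 1) (0:(n - 1)) / (n - 1) else 0
  dlt <- config$trend[1] + config$trend[2] * s + config$trend[3] * s^2
  p_f <- stats::plogis(stats::qlogis(base[1]) + dlt)
  cu_ratio <- base[2] / (base[2] + base[3])
  p <- cbind(F = p_f, C = (1 - p_f) * cu_ratio,
             U = (1 - p_f) * (1 - cu_ratio))
  event_day <- rep(FALSE, n)
  clipped <- integer(0)
  eps <- 1e-6
  for (ev in config$events) {
    idx <- seq(ev[1], min(n, ev[1] + ev[2] - 1))
    event_day[idx] <- TRUE
    p_new <- p[idx, 1] + ev[3]
    bad <- p_new < eps | p_new > 1 - eps
    if (any(bad)) {
      clipped <- c(clipped, idx[bad])
      p_new <- pmin(pmax(p_new, eps), 1 - eps)
    }
    scale <- (1 - p_new) / (1 - p[idx, 1])
    p[idx, 1] <- p_new
    p[idx, 2] <- p[idx, 2] * scale
    p[idx, 3] <- p[idx, 3] * scale
  }
  list(p = p, event_day = event_day, clipped_days = unique(clipped))
}

#' Generate a synthetic daily polarity series with its ground truth
#'
#' Draws, for each day, a negative-binomial volume (spike multipliers
#' applied), multinomial polarity counts from the day's true probability
#' vector, and a heavy-tailed interaction total. Fully reproducible from
#' `(config, seed)`; the truth trajectory depends on the config only, never
#' on the seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A list with `series` (a [daily_polarity()]) and `truth` (a
#'   `synthetic_truth` list: `p` — the n_days x 3 true probability matrix,
#'   `event_day` flags, `trend`, `clipped_days`, `seed`).
#' @export
generate_series <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  tr <- truth_trajectory(config)
  if (length(tr$clipped_days) > 0) {
    warning("truth probabilities clipped to the simplex on day(s) ",
            paste(tr$clipped_days, collapse = ", "))
  }
  n <- config$n_days
  draws <- withr::with_seed(seed, {
    vol <- stats::rnbinom(n, mu = config$volume_mean,
                          size = config$volume_dispersion)
    for (sp in config$spikes) {
      vol[sp[1]] <- as.integer(round(max(vol[sp[1]], 1) * sp[2]))
    }
    counts <- t(vapply(seq_len(n), function(t) {
      if (vol[t] == 0) return(c(0L, 0L, 0L))
      drop(stats::rmultinom(1, vol[t], tr$p[t, ]))
    }, integer(3)))
    extra <- round(vol * stats::rlnorm(n, config$interaction_meanlog,
                                       config$interaction_sdlog))
    list(vol = vol, counts = counts, extra = extra)
  })
  dates <- seq(config$start_date, by = "day", length.out = n)
  series <- daily_polarity(dates, draws$counts[, 1], draws$counts[, 2],
                           draws$counts[, 3],
                           interactions = draws$vol + draws$extra)
  truth <- structure(list(p = tr$p, event_day = tr$event_day,
                          trend = config$trend,
                          clipped_days = tr$clipped_days,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(series = series, truth = truth)
}

#' Generate individual synthetic post records
#'
#' Expands the daily series of [generate_series()] (same config and seed,
#' hence identical counts) into per-post records: unique ids, timestamps
#' within the day, labels, and per-post likes/retweets that sum to the
#' day's interaction total. Out-of-context posts and verbatim duplicate
#' records are interleaved at the configured rates so that deduplication
#' and OOC filtering can be exercised; aggregating the deduplicated records
#' reproduces the series exactly.
#'
#' @inheritParams generate_series
#' @return A list with `posts` (a post-record data frame as from
#'   [read_posts()]), `series` and `truth` (as [generate_series()]).
#' @export
generate_posts <- function(config, seed = config$seed) {
  gs <- generate_series(config, seed)
  series <- gs$series
  n_days <- nrow(series)
  posts <- withr::with_seed(derive_seed(seed, 999983L), {
    day_frames <- vector("list", n_days)
    next_id <- 1L
    f <- config$ooc_fraction
    for (t in seq_len(n_days)) {
      v <- series$volume[t]
      n_ooc <- stats::rpois(1, v * f / (1 - f))
      n_tot <- v + n_ooc
      if (n_tot == 0) next
      labels <- c(rep(POLARITY_LEVELS,
                      times = unlist(series[t, c("n_F", "n_C", "n_U")])),
                  rep("OOC", n_ooc))
      labels <- sample(labels)
      extra <- series$interactions[t] - v
      likes <- retweets <- integer(n_tot)
      if (v > 0 && extra > 0) {
        lk_total <- stats::rbinom(1, extra, 0.5)
        polarity_idx <- which(labels != "OOC")
        likes[polarity_idx] <- drop(stats::rmultinom(1, lk_total,
                                                     rep(1, v)))
        retweets[polarity_idx] <- drop(stats::rmultinom(1, extra - lk_total,
                                                        rep(1, v)))
      }
      secs <- sort(stats::runif(n_tot, 0, 86399))
      day_frames[[t]] <- data.frame(
        post_id = sprintf("t%09d", next_id:(next_id + n_tot - 1L)),
        timestamp = as.POSIXct(series$date[t], tz = "UTC") + secs,
        label = labels, n_retweets = retweets, n_likes = likes,
        stringsAsFactors = FALSE)
      next_id <- next_id + n_tot
    }
    out <- do.call(rbind, day_frames)
    if (config$duplicate_rate > 0 && nrow(out) > 0) {
      k <- stats::rbinom(1, nrow(out), config$duplicate_rate)
      if (k > 0) {
        dup <- out[sample.int(nrow(out), k), , drop = FALSE]
        out <- rbind(out, dup)
        out <- out[order(out$timestamp, out$post_id), , drop = FALSE]
      }
    }
    rownames(out) <- NULL
    out
  })
  list(posts = posts, series = series, truth = gs$truth)
}

#' Simulate a multi-rater annotation matrix
#'
#' Draws latent true labels from `true_label_probs` and, for each rater, an
#' assigned label from the rater's confusion-matrix row for the item's true
#' label. Used as the fixture generator for the agreement statistics.
#'
#' @param n_items Number of annotated items.
#' @param n_raters Raters per item (>= 2).
#' @param true_label_probs Length-4 probability vector over F/C/U/OOC.
#' @param confusion A single row-stochastic 4 x 4 confusion matrix
#'   (rows = true label, columns = assigned label) shared by all raters, or
#'   a list of `n_raters` such matrices.
#' @param seed Integer seed.
#' @return An items x 4 count matrix (class `annotation_matrix`) with
#'   attributes `n_raters` and `truth` (the latent labels).
#' @export
generate_annotations <- function(n_items, n_raters, true_label_probs,
                                 confusion, seed = 1L) {
  if (n_raters < 2) stop_pw("need at least 2 raters")
  true_label_probs <- check_simplex(true_label_probs, "true_label_probs")
  if (is.matrix(confusion)) confusion <- rep(list(confusion), n_raters)
  if (length(confusion) != n_raters) {
    stop_pw("confusion must be one matrix or a list of n_raters matrices")
  }
  k <- length(LABEL_LEVELS)
  for (cm in confusion) {
    if (!is.matrix(cm) || any(dim(cm) != k) || any(cm < 0) ||
        any(abs(rowSums(cm) - 1) > 1e-8)) {
      stop_pw("confusion matrices must be row-stochastic ", k, " x ", k)
    }
  }
  withr::with_seed(seed, {
    truth <- sample.int(k, n_items, replace = TRUE, prob = true_label_probs)
    counts <- matrix(0L, n_items, k,
                     dimnames = list(NULL, LABEL_LEVELS))
    for (r in seq_len(n_raters)) {
      cm <- confusion[[r]]
      # Inverse-CDF draw, vectorised over items.
      cum <- t(apply(cm, 1, cumsum))[truth, , drop = FALSE]
      u <- stats::runif(n_items)
      lab <- rowSums(u > cum) + 1L
      counts[cbind(seq_len(n_items), lab)] <-
        counts[cbind(seq_len(n_items), lab)] + 1L
    }
    structure(counts, n_raters = as.integer(n_raters),
              truth = LABEL_LEVELS[truth], class = "annotation_matrix")
  })
}

#' Type-I-error / power calibration experiment
#'
#' Generates `n_replicates` independent series from `config`, runs the named
#' day-level test on each, and tabulates the mean number of rejection days
#' and the rejection fraction per significance level, with Monte-Carlo
#' standard errors. With a null configuration (no events, no trend) this
#' measures test calibration — e.g. about 18.25 expected rejection days in
#' a 365-day year at the 5% level.
#'
#' @param config A [scenario_config()]; use [null_scenario()] for type-I
#'   runs.
#' @param test One of `"basic"`, `"running"`, `"variance"`.
#' @param n_replicates Number of independent replicate series (default 200).
#' @param alphas Significance levels (default `c(0.10, 0.05, 0.01)`).
#' @param window Window for the running tests (default 15).
#' @param seed Base seed; replicate `r` uses a sub-seed derived from it.
#' @param ... Further arguments to the test function.
#' @return A data frame `alpha, mean_rejected, se_rejected,
#'   rejection_fraction, se_fraction, mean_tested, expected_days`.
#' @export
calibration_experiment <- function(config,
                                   test = c("basic", "running", "variance"),
                                   n_replicates = 200,
                                   alphas = c(0.10, 0.05, 0.01),
                                   window = 15, seed = 1L, ...) {
  test <- match.arg(test)
  rej <- matrix(NA_real_, n_replicates, length(alphas))
  tested <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    s_r <- derive_seed(seed, r)
    gs <- generate_series(config, seed = s_r)
    res <- switch(test,
      basic = basic_daily_test(gs$series, seed = s_r, ...),
      running = running_daily_test(gs$series, window = window, seed = s_r,
                                   ...),
      variance = running_variance_test(gs$series, window = window, ...))
    summ <- rejection_summary(res, alphas)
    rej[r, ] <- summ$rejected_days
    tested[r] <- summ$tested_days[1]
  }
  frac <- sweep(rej, 1, pmax(tested, 1), "/")
  data.frame(
    alpha = alphas,
    mean_rejected = colMeans(rej),
    se_rejected = apply(rej, 2, stats::sd) / sqrt(n_replicates),
    rejection_fraction = colMeans(frac),
    se_fraction = apply(frac, 2, stats::sd) / sqrt(n_replicates),
    mean_tested = mean(tested),
    expected_days = alphas * mean(tested))
}
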