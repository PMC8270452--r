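#' Read labelled post records from a delimited text file
#'
#' Reads a CSV with columns `post_id,timestamp,label,n_retweets,n_likes`
#' (ISO-8601 timestamps, labels in F/C/U/OOC) into a validated data frame of
#' post records. Records with a malformed timestamp, an unknown label, an
#' empty id, or negative interaction counts are rejected individually; the
#' number rejected is reported via [message()] and attached as the
#' `"n_rejected"` attribute.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `post_id` (character), `timestamp`
#'   (POSIXct, UTC), `label` (character, one of `"F"`, `"C"`, `"U"`,
#'   `"OOC"`), `n_retweets` and `n_likes` (integer).
#' @seealso [deduplicate()], [aggregate_daily()]
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) stop_pw("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("post_id", "timestamp", "label", "n_retweets", "n_likes")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop_pw("missing column(s): ", paste(missing, collapse = ", "))
  }
  ts <- parse_timestamp(raw$timestamp)
  rt <- suppressWarnings(as.integer(raw$n_retweets))
  lk <- suppressWarnings(as.integer(raw$n_likes))
  ok <- !is.na(ts) & raw$label %in% LABEL_LEVELS & nzchar(raw$post_id) &
    !is.na(rt) & rt >= 0 & !is.na(lk) & lk >= 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected, " malformed record(s) rejected")
  }
  out <- data.frame(post_id = raw$post_id[ok], timestamp = ts[ok],
                    label = raw$label[ok], n_retweets = rt[ok],
                    n_likes = lk[ok], stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rejected
  out
}

# Parse ISO-8601 timestamps ("2018-01-01T12:00:00", with T or space, optional
# fractional seconds / trailing Z) as UTC. Bare dates parse to midnight.
parse_timestamp <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x))
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  ts
}

#' Deduplicate a stream of post records
#'
#' Keeps the first occurrence (in input order) of each `post_id` and, by
#' default, drops out-of-context (OOC) records so that the result is the
#' polarity stream proper.
#'
#' @param records Data frame of post records (see [read_posts()]).
#' @param keep_ooc Keep OOC records? Default `FALSE`: OOC posts take no part
#'   in polarity counts nor interaction totals.
#' @return The filtered data frame; attribute `"n_duplicates"` holds the
#'   number of duplicate records removed.
#' @export
deduplicate <- function(records, keep_ooc = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    attr(records, "n_duplicates") <- 0L
    return(records)
  }
  dup <- duplicated(records$post_id)
  out <- records[!dup, , drop = FALSE]
  if (!keep_ooc) out <- out[out$label != "OOC", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Construct a daily polarity series
#'
#' Low-level constructor for the date-indexed series of daily
#' favourable/contrary/undecided counts that every disorientation test
#' consumes. Dates must be consecutive calendar days; days with no posts are
#' carried as explicit zeros.
#'
#' @param date `Date` vector, strictly increasing, no gaps.
#' @param n_F,n_C,n_U Non-negative integer daily counts per category.
#' @param interactions Per-day total of posts + likes + retweets; must be at
#'   least the daily volume. Defaults to the volume (no extra interactions).
#' @return A `daily_polarity` data frame with columns `date, n_F, n_C, n_U,
#'   volume, interactions`.
#' @export
daily_polarity <- function(date, n_F, n_C, n_U, interactions = NULL) {
  date <- as.Date(date)
  n <- length(date)
  if (n == 0) stop_pw("empty series")
  if (n > 1 && !all(diff(as.integer(date)) == 1)) {
    stop_pw("dates must be consecutive calendar days")
  }
  counts <- cbind(n_F = as.integer(n_F), n_C = as.integer(n_C),
                  n_U = as.integer(n_U))
  if (nrow(counts) != n) stop_pw("count lengths must match dates")
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_pw("counts must be non-negative integers")
  }
  volume <- as.integer(rowSums(counts))
  if (is.null(interactions)) interactions <- volume
  interactions <- as.integer(round(interactions))
  if (any(interactions < volume)) {
    stop_pw("interactions must be >= daily volume")
  }
  out <- data.frame(date = date, counts, volume = volume,
                    interactions = interactions)
  class(out) <- c("daily_polarity", "data.frame")
  out
}

#' @export
print.daily_polarity <- function(x, ...) {
  cat(sprintf("Daily polarity series: %d days (%s to %s), %d posts\n",
              nrow(x), format(min(x$date)), format(max(x$date)),
              sum(x$volume)))
  NextMethod()
}

#' Aggregate deduplicated post records to a daily polarity series
#'
#' Assigns each post to one calendar day (UTC, with an optional fixed offset)
#' and tallies per-day polarity counts, volume and interaction totals
#' (posts + likes + retweets of the posts created that day). Days inside the
#' range with no posts get zero counts; posts outside the range are excluded
#' and counted in the `"n_out_of_range"` attribute.
#'
#' @param records Deduplicated post records ([deduplicate()]). OOC records,
#'   if still present, are ignored.
#' @param start,end First and last calendar day of the series (`Date` or
#'   string).
#' @param tz_offset_hours Hours added to the UTC timestamp before taking the
#'   calendar day (day-boundary convention; default 0 = UTC midnight).
#' @return A [daily_polarity()] series covering `start..end`.
#' @export
aggregate_daily <- function(records, start, end, tz_offset_hours = 0) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop_pw("invalid date range")
  }
  records <- records[records$label %in% POLARITY_LEVELS, , drop = FALSE]
  days <- seq(start, end, by = "day")
  day <- as.Date(records$timestamp + tz_offset_hours * 3600, tz = "UTC")
  in_range <- day >= start & day <= end
  n_out <- sum(!in_range)
  if (n_out > 0) message(n_out, " record(s) outside the date range excluded")
  records <- records[in_range, , drop = FALSE]
  day <- day[in_range]
  idx <- as.integer(day - start) + 1L
  tab <- function(lab) {
    tabulate(idx[records$label == lab], nbins = length(days))
  }
  n_F <- tab("F"); n_C <- tab("C"); n_U <- tab("U")
  extra <- tabulate(rep(idx, records$n_likes + records$n_retweets),
                    nbins = length(days))
  out <- daily_polarity(days, n_F, n_C, n_U,
                        interactions = n_F + n_C + n_U + extra)
  attr(out, "n_out_of_range") <- n_out
  out
}

#' Extract the daily proportion matrix from a series
#'
#' @param series A [daily_polarity()] series.
#' @return Numeric matrix with columns `F`, `C`, `U`; rows for zero-volume
#'   days are `NA` (proportions undefined).
#' @export
polarity_proportions <- function(series) {
  counts <- as.matrix(series[, c("n_F", "n_C", "n_U")])
  p <- counts / series$volume
  p[series$volume == 0, ] <- NA_real_
  colnames(p) <- POLARITY_LEVELS
  p
}

#' Pooled polarity proportions with bootstrap confidence intervals
#'
#' Pools the counts over the whole period and reports the overall
#' favourable/contrary/undecided proportions, the hesitant proportion
#' (contrary + undecided), and nonparametric bootstrap percentile intervals.
#' The default bootstrap resamples individual posts (multinomially from the
#' pooled counts); `ci_method = "day_block"` resamples whole days with
#' replacement instead, respecting day-level clustering.
#'
#' @param series A [daily_polarity()] series with positive total volume.
#' @param ci_method `"bootstrap"` (post-level, default) or `"day_block"`.
#' @param ci_level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `polarity_summary` list with elements `proportions` (named
#'   F/C/U), `ci` (2 x 3 matrix), `p_hesitant`, `ci_hesitant`, `n`.
#' @export
polarity_summary <- function(series, ci_method = c("bootstrap", "day_block"),
                             ci_level = 0.95, n_boot = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  counts <- as.matrix(series[, c("n_F", "n_C", "n_U")])
  pooled <- colSums(counts)
  n <- sum(pooled)
  if (n == 0) stop_pw("zero total volume: no proportions to summarise")
  p <- pooled / n
  boot_fun <- function() {
    if (ci_method == "bootstrap") {
      bs <- stats::rmultinom(n_boot, n, p)      # resample posts
      t(bs) / n
    } else {
      reps <- matrix(0, n_boot, 3)              # resample days
      for (b in seq_len(n_boot)) {
        i <- sample.int(nrow(counts), replace = TRUE)
        cs <- colSums(counts[i, , drop = FALSE])
        reps[b, ] <- cs / sum(cs)
      }
      reps
    }
  }
  reps <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  alpha <- (1 - ci_level) / 2
  ci <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  hes <- reps[, 2] + reps[, 3]
  out <- list(
    proportions = stats::setNames(as.numeric(p), POLARITY_LEVELS),
    ci = structure(ci, dimnames = list(c("lower", "upper"), POLARITY_LEVELS)),
    p_hesitant = as.numeric(p[2] + p[3]),
    ci_hesitant = stats::quantile(hes, probs = c(alpha, 1 - alpha),
                                  names = FALSE),
    n = as.integer(n), ci_level = ci_level, ci_method = ci_method)
  class(out) <- "polarity_summary"
  out
}

#' @export
print.polarity_summary <- function(x, ...) {
  cat(sprintf("Pooled polarity proportions (n = %d posts)\n", x$n))
  for (j in seq_along(x$proportions)) {
    cat(sprintf("  %s = %5.1f%%  (%d%% CI: %.1f-%.1f)\n",
                names(x$proportions)[j], 100 * x$proportions[j],
                round(100 * x$ci_level), 100 * x$ci[1, j], 100 * x$ci[2, j]))
  }
  cat(sprintf("  hesitant (C + U) = %.1f%%  (CI: %.1f-%.1f)\n",
              100 * x$p_hesitant, 100 * x$ci_hesitant[1],
              100 * x$ci_hesitant[2]))
  invisible(x)
}

#' Write / read a daily polarity series as CSV
#'
#' @param series A [daily_polarity()] series.
#' @param path Output (input) CSV path with columns
#'   `date,n_F,n_C,n_U,volume,interactions`.
#' @return `write_daily_series()` returns `path` invisibly;
#'   `read_daily_series()` returns the validated series.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path) {
  if (!file.exists(path)) stop_pw("daily series file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_polarity(as.Date(df$date), df$n_F, df$n_C, df$n_U,
                 interactions = df$interactions)
}
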