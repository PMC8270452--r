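# Discrete beta-kernel smoothing of daily polarity proportions. The kernel's
# support is the observed day grid itself, so no weight ever falls outside
# the observation window and the usual boundary bias of symmetric kernels
# cannot arise: at the edges the beta shape parameters place the kernel mode
# exactly on the edge.

#' Discrete beta-kernel weights at one evaluation point
#'
#' Weights over the day grid `0..T` for smoothing at day index `x` with
#' bandwidth `h`: the beta density with shape parameters
#' `x/(Th) + 1` and `(T - x)/(Th) + 1` evaluated at `j/T` for `j = 0..T`,
#' normalised to sum to one. All weight lies inside the grid; as `h -> 0`
#' the weights concentrate on `j = x`.
#'
#' @param x Evaluation day index in `[0, T]`.
#' @param h Bandwidth, > 0 (dimensionless, on the unit-interval scale of the
#'   rescaled grid).
#' @param T Last day index (grid is `0..T`, `T >= 1`).
#' @return Numeric weight vector of length `T + 1`, non-negative, summing
#'   to 1.
#' @export
beta_kernel_weights <- function(x, h, T) {
  if (h <= 0) stop_pw("bandwidth h must be > 0")
  if (T < 1) stop_pw("grid must have at least two days (T >= 1)")
  if (x < 0 || x > T) stop_pw("x must lie in [0, T]")
  w <- stats::dbeta((0:T) / T, x / (T * h) + 1, (T - x) / (T * h) + 1)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) {
    stop_pw("bandwidth too small for this grid: all kernel weights underflow")
  }
  w / s
}

# Full (T+1) x (T+1) weight matrix; row i smooths at day index i-1.
beta_kernel_matrix <- function(n, h) {
  T <- n - 1
  t(vapply(0:T, function(x) beta_kernel_weights(x, h, T), numeric(n)))
}

# Smooth a numeric matrix (days x categories, NA rows = undefined days) with
# a given weight matrix, renormalising weights over the observed days.
apply_kernel <- function(W, y) {
  y <- as.matrix(y)
  obs <- stats::complete.cases(y)
  if (!any(obs)) stop_pw("no observed days to smooth")
  Wo <- W[, obs, drop = FALSE]
  rs <- rowSums(Wo)
  if (any(rs <= 0)) {
    stop_pw("some days receive zero total weight; increase the bandwidth")
  }
  (Wo / rs) %*% y[obs, , drop = FALSE]
}

#' Smooth a daily polarity series with the discrete beta kernel
#'
#' Smooths each polarity proportion independently as the beta-kernel
#' weighted mean of the observed daily proportions. Days with zero volume
#' have undefined proportions: they are excluded from every weighted mean
#' (weights renormalised over observed days) but still receive a smoothed
#' value. Because the same weights apply to each category, the three
#' smoothed proportions sum to one automatically when every day is
#' observed; `renormalize = TRUE` forces the sum to one otherwise.
#'
#' @param series A [daily_polarity()] series (or a numeric matrix of daily
#'   proportions with `NA` rows for undefined days).
#' @param h Bandwidth, > 0; see [cv_bandwidth()] for data-driven selection.
#' @param renormalize Rescale the three smoothed proportions to sum to one
#'   per day (default `FALSE`).
#' @return A `smoothed_series` data frame with the raw and smoothed
#'   proportions per category; bandwidth and renormalisation flag are
#'   attached as attributes.
#' @export
smooth_series <- function(series, h, renormalize = FALSE) {
  if (inherits(series, "daily_polarity")) {
    y <- polarity_proportions(series)
    dates <- series$date
  } else {
    y <- as.matrix(series)
    dates <- seq_len(nrow(y))
  }
  if (nrow(y) < 2) stop_pw("need at least two days to smooth")
  W <- beta_kernel_matrix(nrow(y), h)
  sm <- apply_kernel(W, y)
  if (renormalize && ncol(sm) > 1) sm <- sm / rowSums(sm)
  cats <- colnames(y)
  if (is.null(cats) || !all(nzchar(cats))) cats <- seq_len(ncol(y))
  out <- data.frame(date = dates, raw = y, smooth = sm)
  names(out) <- c("date", paste0("raw_", cats), paste0("smooth_", cats))
  attr(out, "h") <- h
  attr(out, "renormalized") <- renormalize
  class(out) <- c("smoothed_series", "data.frame")
  out
}

#' Leave-one-out cross-validated bandwidth for the beta-kernel smoother
#'
#' For each candidate bandwidth, predicts every observed day from all the
#' others (its own weight set to zero, remaining weights renormalised) and
#' accumulates the squared prediction error over all categories; returns
#' the bandwidth minimising that error, breaking ties toward the largest
#' (smoothest) candidate. Bandwidths so small that some day receives no
#' weight from the others are treated as infeasible.
#'
#' @param series A [daily_polarity()] series or numeric matrix/vector of
#'   daily values (`NA` = missing day).
#' @param h_grid Positive candidate bandwidths.
#' @return The selected bandwidth; the per-candidate LOO errors are
#'   attached as the `"cv_errors"` attribute.
#' @export
cv_bandwidth <- function(series, h_grid) {
  if (length(h_grid) == 0 || any(h_grid <= 0)) {
    stop_pw("h_grid must be a non-empty vector of positive bandwidths")
  }
  y <- if (inherits(series, "daily_polarity")) {
    polarity_proportions(series)
  } else {
    as.matrix(series)
  }
  obs <- stats::complete.cases(y)
  if (sum(obs) < 3) stop_pw("need at least three observed days")
  h_grid <- sort(h_grid)
  errs <- vapply(h_grid, function(h) {
    W <- beta_kernel_matrix(nrow(y), h)
    diag(W) <- 0
    pred <- tryCatch(apply_kernel(W, y), error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    sum((pred[obs, , drop = FALSE] - y[obs, , drop = FALSE])^2)
  }, numeric(1))
  if (all(!is.finite(errs))) {
    stop_pw("no feasible bandwidth in h_grid; enlarge the candidates")
  }
  best <- max(which(errs <= min(errs)))   # ties -> larger h
  structure(h_grid[best], cv_errors = stats::setNames(errs, h_grid))
}
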