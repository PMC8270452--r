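# Stepwise polynomial trend fitting for the long-term disorientation
# analysis: OLS fits of increasing degree on a centred/scaled day index,
# with the degree chosen where one more degree stops buying a material
# R-squared gain.

#' Stepwise polynomial trend fit
#'
#' Fits ordinary least squares polynomials of degree 0 to `max_degree` of
#' the (smoothed) daily values on the centred and scaled day index, records
#' the coefficient of determination per degree, and selects the smallest
#' degree `d >= 1` for which raising the degree to `d + 1` improves
#' R-squared by less than `delta_r2` — the "negligible gain" stopping rule.
#' For a year of smoothed polarity proportions shaped like the motivating
#' application, this typically selects the parabola.
#'
#' @param y Numeric vector of daily values (e.g. a smoothed favourable
#'   proportion); `NA`s are dropped.
#' @param x Day index (default `seq_along(y)`).
#' @param max_degree Largest degree considered (default 5).
#' @param delta_r2 Minimum R-squared gain counted as material (default
#'   0.01).
#' @return A `trend_fit` list: `selected_degree`, `coefficients` (in the
#'   centred/scaled basis, ascending powers), `coefficients_raw` (same
#'   polynomial in the raw day index), `r2_by_degree`, `center`, `scale`,
#'   `model` (the selected `lm`), `fitted` (aligned with `x`), `n`.
#'   A constant input returns degree 0 with R-squared defined as 1.
#' @examples
#' x <- 1:100
#' fit <- fit_polynomial_trend(0.7 + 0.001 * (x - 50) - 2e-5 * (x - 50)^2)
#' fit$selected_degree  # 2
#' @export
fit_polynomial_trend <- function(y, x = seq_along(y), max_degree = 5,
                                 delta_r2 = 0.01) {
  keep <- !is.na(y)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < max_degree + 2) {
    stop_pw("need at least max_degree + 2 = ", max_degree + 2, " points")
  }
  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  sst <- sum((y - mean(y))^2)
  degrees <- 0:max_degree
  if (sst < 1e-24) {                      # constant input: exact fit at d = 0
    fit0 <- stats::lm(y ~ 1)
    out <- list(selected_degree = 0L,
                coefficients = stats::coef(fit0),
                coefficients_raw = stats::coef(fit0),
                r2_by_degree = stats::setNames(rep(1, length(degrees)),
                                               degrees),
                center = m, scale = s, model = fit0,
                fitted = rep(mean(y), n), n = n, delta_r2 = delta_r2)
    class(out) <- "trend_fit"
    return(out)
  }
  fits <- lapply(degrees, function(d) {
    if (d == 0) stats::lm(y ~ 1) else stats::lm(y ~ poly(z, d, raw = TRUE))
  })
  r2 <- vapply(fits, function(f) 1 - sum(stats::resid(f)^2) / sst,
               numeric(1))
  r2 <- pmin(pmax(cummax(r2), 0), 1)      # guard rounding: R2 in [0,1], monotone
  selected <- max_degree
  if (max_degree >= 2) {
    for (d in 1:(max_degree - 1)) {
      if (r2[d + 2] - r2[d + 1] < delta_r2) { selected <- d; break }
    }
  }
  model <- fits[[selected + 1]]
  cz <- stats::coef(model)
  names(cz) <- paste0("z^", 0:selected)
  out <- list(selected_degree = as.integer(selected),
              coefficients = cz,
              coefficients_raw = rebase_polynomial(unname(cz), m, s),
              r2_by_degree = stats::setNames(r2, degrees),
              center = m, scale = s, model = model,
              fitted = stats::fitted(model), n = n, delta_r2 = delta_r2)
  class(out) <- "trend_fit"
  out
}

# Re-express sum_j c_j ((x - m)/s)^j as coefficients of powers of x.
rebase_polynomial <- function(coefs, m, s) {
  d <- length(coefs) - 1
  out <- numeric(d + 1)
  base <- c(-m / s, 1 / s)                # the polynomial (x - m)/s
  pow <- 1                                 # ((x - m)/s)^0
  for (j in 0:d) {
    out[seq_along(pow)] <- out[seq_along(pow)] + coefs[j + 1] * pow
    if (j < d) pow <- stats::convolve(pow, rev(base), type = "open")
  }
  names(out) <- paste0("x^", 0:d)
  out
}

#' Evaluate a trend fit at day indices
#'
#' @param object A `trend_fit`.
#' @param x Day indices at which to evaluate the selected polynomial.
#' @param ... Unused.
#' @return Numeric vector of trend values.
#' @export
predict.trend_fit <- function(object, x, ...) {
  z <- (x - object$center) / object$scale
  drop(outer(z, 0:object$selected_degree, `^`) %*% object$coefficients)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Stepwise polynomial trend: degree %d selected (n = %d)\n",
              x$selected_degree, x$n))
  r2 <- x$r2_by_degree
  cat("  R-squared by degree:",
      paste(sprintf("%s: %.4f", names(r2), r2), collapse = ", "), "\n")
  cat("  coefficients (raw day index):\n")
  print(signif(x$coefficients_raw, 6))
  invisible(x)
}
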