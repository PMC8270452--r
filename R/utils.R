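# Internal helpers shared across modules.

# Labels of the three polarity categories, in canonical order.
POLARITY_LEVELS <- c("F", "C", "U")
# All four post categories (OOC = out of context, dropped before analysis).
LABEL_LEVELS <- c("F", "C", "U", "OOC")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pw <- function(...) stop(..., call. = FALSE)

# Validate a probability vector on the simplex (within tolerance) and
# renormalise away rounding error.
check_simplex <- function(p, name = "probs", tol = 1e-8) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stop_pw(name, " must be a non-negative numeric vector")
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop_pw(name, " must sum to 1 (got ", format(s), ")")
  }
  p / s
}

# Derive a stream of reproducible sub-seeds from one base seed, staying
# within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483587)
}
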