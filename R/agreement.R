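#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for a fixed number of raters per item:
#' \deqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)} with per-item agreement
#' \eqn{P_i = (\sum_j n_{ij}^2 - n)/(n(n-1))} (n raters per item) and chance
#' agreement \eqn{\bar P_e = \sum_j p_j^2} from the marginal category
#' proportions.
#'
#' @param counts Items x categories matrix of non-negative integers; entry
#'   (i, j) is the number of raters assigning category j to item i. Every
#'   row must sum to the same number of raters (>= 2).
#' @return The kappa value in `[-1, 1]`. If all mass falls in one category
#'   (`P_e = 1`) the statistic degenerates: perfect agreement returns 1,
#'   anything else is an error.
#' @examples
#' m <- rbind(c(2, 0, 0, 0), c(1, 1, 0, 0))  # (F,F) and (F,C), 2 raters
#' fleiss_kappa(m)                            # -1/3
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop_pw("need at least one item")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_pw("counts must be non-negative integers")
  }
  n_raters <- unique(rowSums(counts))
  if (length(n_raters) != 1) {
    stop_pw("every item must be rated by the same number of raters")
  }
  if (n_raters < 2) stop_pw("need at least 2 raters per item")
  p_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    if (p_bar >= 1 - 1e-12) return(1)
    stop_pw("degenerate marginal distribution: chance agreement is 1")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Raw pairwise agreement with an exact binomial interval
#'
#' Fraction of annotation pairs whose two labels agree, with a
#' Clopper-Pearson exact binomial confidence interval.
#'
#' @param label_a,label_b Equal-length vectors of category labels for the
#'   two members of each pair.
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `accuracy`, `ci` (length-2 numeric), `n_pairs`,
#'   `n_agree`, `ci_level`.
#' @export
pairwise_accuracy <- function(label_a, label_b, ci_level = 0.95) {
  if (length(label_a) != length(label_b)) {
    stop_pw("label vectors must have equal length")
  }
  n <- length(label_a)
  if (n == 0) stop_pw("need at least one pair")
  k <- sum(label_a == label_b)
  bt <- stats::binom.test(k, n, conf.level = ci_level)
  list(accuracy = k / n, ci = as.numeric(bt$conf.int), n_pairs = n,
       n_agree = as.integer(k), ci_level = ci_level)
}

#' Agreement summary from a long-format annotation table
#'
#' Convenience wrapper: takes annotations as `item_id, rater_id, label` rows,
#' forms the item x category count matrix, computes Fleiss' kappa, and (if
#' explicit pairs are supplied) pairwise accuracy.
#'
#' @param annotations Data frame with columns `item_id`, `rater_id`, `label`.
#' @param pairs Optional two-column data frame / matrix of labels for
#'   designed annotation pairs (passed to [pairwise_accuracy()]).
#' @param ci_level Confidence level for the accuracy interval.
#' @return A list with `kappa`, `n_items`, `n_raters`, and when pairs are
#'   given, `accuracy` and `accuracy_ci`.
#' @export
agreement_summary <- function(annotations, pairs = NULL, ci_level = 0.95) {
  stopifnot(all(c("item_id", "rater_id", "label") %in% names(annotations)))
  if (!all(annotations$label %in% LABEL_LEVELS)) {
    stop_pw("labels must be in {", paste(LABEL_LEVELS, collapse = ", "), "}")
  }
  counts <- table(annotations$item_id,
                  factor(annotations$label, levels = LABEL_LEVELS))
  counts <- unclass(counts)
  out <- list(kappa = fleiss_kappa(counts), n_items = nrow(counts),
              n_raters = as.integer(rowSums(counts)[1]))
  if (!is.null(pairs)) {
    pa <- pairwise_accuracy(pairs[[1]], pairs[[2]], ci_level)
    out$accuracy <- pa$accuracy
    out$accuracy_ci <- pa$ci
  }
  out
}
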