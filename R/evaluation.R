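#' ROC curve and AUC
#'
#' Builds the empirical ROC curve over all distinct score thresholds
#' (classification convention: `score >= threshold` predicts positive)
#' and computes the area under it by the trapezoidal rule, which equals
#' the Mann--Whitney concordance probability with midranks for ties.
#'
#' @param y_true Binary 0/1 (or logical) outcome vector; both classes must
#'   be present.
#' @param scores Predicted probabilities in `[0, 1]`.
#' @return Object of class `roc_curve`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`, ordered by increasing FPR), `auc`, and the
#'   Youden-selected `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(y_true, scores) {
  y <- as.integer(y_true)
  if (length(unique(y)) < 2) {
    abort_nutricate("both classes must be present")
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    abort_nutricate("scores must be probabilities in [0, 1]")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  # cumulative counts: predicted positive iff score >= threshold
  tpr <- vapply(thresholds, function(t) sum(y == 1 & scores >= t), 0) / n_pos
  fpr <- vapply(thresholds, function(t) sum(y == 0 & scores >= t), 0) / n_neg
  curve <- tibble::tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  sel <- select_cutoff(y, scores)
  structure(list(curve = curve, auc = auc, cutoff = sel$cutoff,
                 sensitivity = sel$sensitivity,
                 specificity = sel$specificity),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f, cutoff = %.3f (sensitivity %.1f%%, specificity %.1f%%)\n",
    x$auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Youden-optimal classification cutoff
#'
#' Selects the threshold maximizing Youden's
#' `J = sensitivity + specificity - 1` over the distinct observed scores,
#' with `score >= cutoff` predicting positive; ties are broken toward the
#' lower cutoff.
#'
#' @param y_true Binary outcome vector with both classes present.
#' @param scores Probability scores.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
select_cutoff <- function(y_true, scores) {
  y <- as.integer(y_true)
  if (length(unique(y)) < 2) {
    abort_nutricate("both classes must be present")
  }
  cand <- sort(unique(scores))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  sens <- vapply(cand, function(t) sum(y == 1 & scores >= t), 0) / n_pos
  spec <- vapply(cand, function(t) sum(y == 0 & scores < t), 0) / n_neg
  j <- sens + spec - 1
  # candidates ascending -> lowest cutoff; tolerance so that exact-rational
  # ties are not broken by binary-fraction noise
  best <- which(j >= max(j) - 1e-9)[1]
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Summarize an individual-treatment-effect distribution
#'
#' Histogram bin counts (conserving n) plus the mean, SD and the 2.5, 25,
#' 50, 75 and 97.5% quantiles of the per-child effects.
#'
#' @param theta Numeric vector of individual treatment effects (n >= 1).
#' @param bins Number of equal-width bins (default 30).
#' @return List of class `ite_summary` with `histogram` (tibble `mid`,
#'   `lower`, `upper`, `count`), `mean`, `sd`, `quantiles`, `n`.
#' @export
summarize_ite <- function(theta, bins = 30L) {
  if (length(theta) == 0) abort_nutricate("empty input")
  stopifnot(bins >= 1)
  rng <- range(theta)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * 1e-8
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(theta, edges, rightmost.closed = TRUE), 1L),
              bins)
  counts <- tabulate(idx, nbins = bins)
  histogram <- tibble::tibble(
    lower = edges[-length(edges)], upper = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2, count = counts
  )
  qs <- stats::quantile(theta, c(0.025, 0.25, 0.5, 0.75, 0.975))
  structure(list(histogram = histogram, mean = mean(theta),
                 sd = stats::sd(theta), quantiles = qs,
                 n = length(theta)),
            class = "ite_summary")
}

#' @export
print.ite_summary <- function(x, ...) {
  cat(sprintf("ITE summary: n = %d, mean = %.4f, sd = %.4f\n",
              x$n, x$mean, if (is.na(x$sd)) 0 else x$sd))
  print(round(x$quantiles, 4))
  invisible(x)
}
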