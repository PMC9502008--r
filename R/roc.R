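#' ROC curve with Mann-Whitney AUC and Youden cutoff
#'
#' Builds the full ROC of a score against binary outcome labels. The AUC is
#' the Mann-Whitney two-sample statistic with ties counted one half — the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, plus half the tie probability. Candidate thresholds are the
#' midpoints between adjacent distinct observed scores (plus sentinels
#' below and above the data); an observation is called positive when its
#' score is strictly greater than the threshold. The Youden cutoff
#' maximises sensitivity + specificity - 1, with ties broken toward higher
#' specificity (the larger threshold).
#'
#' Per-observation placement values (the Hajek projection components of the
#' AUC) are retained for the DeLong comparison of correlated ROC curves.
#'
#' @param scores numeric score per observation (higher = more positive).
#' @param labels binary outcome per observation (logical, 0/1, or a factor
#'   whose second level is the positive class).
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutoff`, `placement_pos`,
#'   `placement_neg`, `labels`, `scores`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) {
    stop("both outcome classes must be present")
  }

  # placement values: for each positive, the fraction of negatives it
  # beats (ties half); symmetrically for negatives. AUC is the mean of
  # either set.
  placement_pos <- vapply(pos, function(s) {
    mean((s > neg) + 0.5 * (s == neg))
  }, numeric(1L))
  placement_neg <- vapply(neg, function(s) {
    mean((pos > s) + 0.5 * (pos == s))
  }, numeric(1L))
  auc <- mean(placement_pos)

  uq <- sort(unique(scores))
  thresholds <- c(uq[1L] - 1,
                  if (length(uq) > 1L) (uq[-1L] + uq[-length(uq)]) / 2,
                  uq[length(uq)] + 1)
  sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1L))
  spec <- vapply(thresholds, function(t) mean(neg <= t), numeric(1L))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  youden_cutoff <- thresholds[best[length(best)]]  # larger t = higher spec

  structure(list(thresholds = thresholds,
                 sensitivity = sens,
                 specificity = spec,
                 auc = auc,
                 youden_cutoff = youden_cutoff,
                 placement_pos = placement_pos,
                 placement_neg = placement_neg,
                 labels = labels,
                 scores = scores),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d pos / %d neg), Youden cutoff %g\n",
              x$auc, sum(x$labels), sum(!x$labels), x$youden_cutoff))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) != 2L) stop("labels must have exactly two classes")
    labels <- labels == u[2L]
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  as.logical(labels)
}

#' Optimal Youden cutoff of a descriptor
#'
#' Convenience wrapper: the threshold of `values` that maximises
#' sensitivity + specificity - 1 for discriminating the outcome, as used to
#' dichotomise continuous descriptors before scoring.
#'
#' @param values descriptor values.
#' @param labels binary outcome labels.
#' @return The cutoff value.
#' @export
optimal_cutoff <- function(values, labels) {
  if (length(unique(values)) < 2L) {
    stop("descriptor is constant; no cutoff exists")
  }
  roc_curve(values, labels)$youden_cutoff
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired nonparametric test for the difference of two AUCs computed on the
#' same observations, using the DeLong (1988) variance built from
#' per-observation placement values: the variance of the AUC difference is
#' `var(V10_a - V10_b)/m + var(V01_a - V01_b)/n` over the m positives and n
#' negatives, and the test statistic is the normal z-score of the
#' difference.
#'
#' @param roc_a,roc_b `roc_result` objects on the same observations (same
#'   labels in the same order).
#' @return A list: `auc_diff` (a minus b), `se`, `ci95` (length-2), `z`,
#'   `p_value`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (length(roc_a$labels) != length(roc_b$labels) ||
      any(roc_a$labels != roc_b$labels)) {
    stop("the two ROC curves must be computed on the same observations")
  }
  m <- length(roc_a$placement_pos)
  n <- length(roc_a$placement_neg)
  d10 <- roc_a$placement_pos - roc_b$placement_pos
  d01 <- roc_a$placement_neg - roc_b$placement_neg
  var_diff <- stats::var(d10) / m + stats::var(d01) / n
  diff <- roc_a$auc - roc_b$auc
  se <- sqrt(var_diff)
  if (se == 0) {
    z <- 0
    p <- 1
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_diff = diff, se = se,
       ci95 = c(diff - 1.96 * se, diff + 1.96 * se),
       z = z, p_value = p)
}
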