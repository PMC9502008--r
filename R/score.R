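#' Allocate integer points from multivariate odds ratios
#'
#' Converts the odds ratios of the retained independent risk factors into
#' integer predictive-score points. The default rule divides each OR by the
#' smallest retained OR and rounds the quotient up
#' (`points = ceiling(OR / min OR)`), the simplest mapping consistent with
#' published point triples such as (23, 1, 2) from ORs
#' (70.322, 3.171, 5.740). Alternatives: `"round_or"` rounds the OR ratio
#' to the nearest integer (minimum 1); `"round_beta"` uses the ratio of
#' log-odds instead.
#'
#' Protective factors (OR below 1) are not representable in an additive
#' positive-point scheme and are rejected.
#'
#' @param odds_ratios named numeric vector of ORs (or a `clogit_fit`, whose
#'   ORs are used).
#' @param rule point-allocation rule.
#' @return Named integer vector of points.
#' @examples
#' allocate_points(c(LSA = 70.322, CHP = 3.171, WSSG = 5.740))
#' @export
allocate_points <- function(odds_ratios,
                            rule = c("ceiling_or", "round_or",
                                     "round_beta")) {
  rule <- match.arg(rule)
  if (inherits(odds_ratios, "clogit_fit")) {
    odds_ratios <- odds_ratios$odds_ratio
  }
  if (!length(odds_ratios)) stop("no odds ratios to allocate points from")
  if (any(odds_ratios <= 1)) {
    stop("all retained odds ratios must exceed 1; protective terms are ",
         "not supported by an additive positive-point score")
  }
  pts <- switch(rule,
    ceiling_or = ceiling(odds_ratios / min(odds_ratios)),
    round_or = pmax(1, round(odds_ratios / min(odds_ratios))),
    round_beta = pmax(1, round(log(odds_ratios) / min(log(odds_ratios)))))
  stats::setNames(as.integer(pts), names(odds_ratios))
}

#' Construct a point-based rupture risk score model
#'
#' A risk score is a sum of weighted terms, one per retained risk factor:
#' continuous terms contribute `points * value`; indicator terms contribute
#' `points` when the descriptor strictly exceeds its threshold and 0
#' otherwise.
#'
#' @param terms data.frame with columns `covariate`, `kind`
#'   (`"continuous"` or `"indicator"`), `threshold` (`NA` for continuous
#'   terms), `points` (positive).
#' @param cutoff optional score cutoff separating high from low predicted
#'   risk.
#' @return An object of class `risk_score_model`.
#' @export
risk_score_model <- function(terms, cutoff = NA_real_) {
  need <- c("covariate", "kind", "threshold", "points")
  if (!all(need %in% names(terms))) {
    stop("`terms` needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(terms$kind %in% c("continuous", "indicator"))) {
    stop("term kind must be 'continuous' or 'indicator'")
  }
  if (any(terms$points <= 0)) stop("points must be positive")
  if (any(terms$kind == "indicator" & is.na(terms$threshold))) {
    stop("indicator terms require a threshold")
  }
  structure(list(terms = terms, cutoff = cutoff),
            class = "risk_score_model")
}

#' @export
print.risk_score_model <- function(x, ...) {
  part <- ifelse(
    x$terms$kind == "continuous",
    sprintf("%g*%s", x$terms$points, x$terms$covariate),
    sprintf("%g*1{%s > %g}", x$terms$points, x$terms$covariate,
            x$terms$threshold))
  cat("risk score =", paste(part, collapse = " + "), "\n")
  if (!is.na(x$cutoff)) cat("high-risk cutoff: score >", x$cutoff, "\n")
  invisible(x)
}

#' The published three-factor rupture score
#'
#' The reference predictive model for mirror-aneurysm rupture:
#' `23 * LSA + 1 * 1{mean CHP > 0.087} + 2 * 1{WSSG ratio > 893.180}`, with
#' a high-risk score cutoff of 1.283 (and 0.016 as the companion univariate
#' LSA cutoff, attached as attribute `lsa_cutoff`). Use it to score new
#' descriptor tables without refitting.
#'
#' @return A [risk_score_model()].
#' @export
published_risk_model <- function() {
  m <- risk_score_model(
    data.frame(
      covariate = c("LSA", "CHP_mean", "WSSG_ratio"),
      kind = c("continuous", "indicator", "indicator"),
      threshold = c(NA, 0.087, 893.180),
      points = c(23, 1, 2)),
    cutoff = 1.283)
  attr(m, "lsa_cutoff") <- 0.016
  m
}

#' Score aneurysms with a risk model
#'
#' @param model a [risk_score_model()].
#' @param descriptors data.frame with one row per aneurysm and a column per
#'   model covariate (e.g. the output of [compute_descriptors()]).
#' @return Numeric score per row; if the model has a cutoff, a logical
#'   attribute `high_risk` flags scores above it.
#' @export
score_aneurysms <- function(model, descriptors) {
  stopifnot(inherits(model, "risk_score_model"))
  miss <- setdiff(model$terms$covariate, names(descriptors))
  if (length(miss)) {
    stop("descriptor table lacks model covariate(s): ",
         paste(miss, collapse = ", "))
  }
  total <- rep(0, nrow(descriptors))
  for (i in seq_len(nrow(model$terms))) {
    tm <- model$terms[i, ]
    v <- descriptors[[tm$covariate]]
    if (anyNA(v)) {
      stop("missing values in model covariate ", tm$covariate)
    }
    total <- total + if (tm$kind == "continuous") {
      tm$points * v
    } else {
      tm$points * as.numeric(v > tm$threshold)
    }
  }
  if (!is.na(model$cutoff)) attr(total, "high_risk") <- total > model$cutoff
  total
}
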