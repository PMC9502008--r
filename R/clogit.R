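#' Matched 1:1 case-control cohort
#'
#' Container for a matched-pair cohort: one ruptured (case) and one
#' unruptured (control) member per pair, with a shared covariate vector
#' layout. Built either directly from case/control covariate matrices or
#' from a long-format data frame with `pair_id` and `member` columns via
#' [as_matched_cohort()].
#'
#' @param case numeric matrix, one row per pair, covariates of the case.
#' @param control numeric matrix, same shape, covariates of the control.
#' @param pair_id optional pair identifiers (default `1..n`).
#' @return An object of class `matched_cohort`.
#' @export
matched_cohort <- function(case, control, pair_id = NULL) {
  case <- as.matrix(case)
  control <- as.matrix(control)
  if (!all(dim(case) == dim(control))) {
    stop("case and control matrices must have identical shape")
  }
  if (nrow(case) < 1L) stop("cohort must contain at least one pair")
  if (anyNA(case) || anyNA(control)) {
    stop("missing covariate values; complete-case preprocessing required")
  }
  if (is.null(colnames(case))) {
    colnames(case) <- paste0("x", seq_len(ncol(case)))
  }
  colnames(control) <- colnames(case)
  rownames(case) <- rownames(control) <- NULL
  if (is.null(pair_id)) pair_id <- seq_len(nrow(case))
  structure(list(case = case, control = control,
                 pair_id = pair_id,
                 covariate_names = colnames(case)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$case), "pairs,",
      length(x$covariate_names), "covariates (",
      paste(x$covariate_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Convert a long cohort table to a matched cohort
#'
#' @param df data.frame with columns `pair_id`, `member`
#'   (`"case"`/`"control"`), and one numeric column per covariate.
#' @param covariates covariate column names; default all remaining columns.
#' @return A [matched_cohort()].
#' @export
as_matched_cohort <- function(df, covariates = NULL) {
  need <- c("pair_id", "member")
  if (!all(need %in% names(df))) {
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(covariates)) covariates <- setdiff(names(df), need)
  ca <- df[df$member == "case", , drop = FALSE]
  co <- df[df$member == "control", , drop = FALSE]
  ids <- sort(unique(df$pair_id))
  if (!all(ids %in% ca$pair_id) || !all(ids %in% co$pair_id)) {
    stop("every pair must have exactly one case and one control member")
  }
  ca <- ca[match(ids, ca$pair_id), covariates, drop = FALSE]
  co <- co[match(ids, co$pair_id), covariates, drop = FALSE]
  matched_cohort(as.matrix(ca), as.matrix(co), pair_id = ids)
}

#' Within-pair covariate differences (case minus control)
#'
#' @param cohort a [matched_cohort()].
#' @param covariates optional subset of covariate names.
#' @return Numeric matrix of differences, one row per pair.
#' @export
pair_differences <- function(cohort, covariates = NULL) {
  if (is.null(covariates)) covariates <- cohort$covariate_names
  missing_cov <- setdiff(covariates, cohort$covariate_names)
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  cohort$case[, covariates, drop = FALSE] -
    cohort$control[, covariates, drop = FALSE]
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximises the exact 1:1 conditional likelihood
#' `prod exp(b'x_case) / (exp(b'x_case) + exp(b'x_control))` — equivalently
#' a binary logit without intercept on the within-pair differences — by
#' Newton-Raphson, iterating until the gradient norm falls below `tol`.
#' The covariance is the inverse observed information; odds ratios, Wald
#' 95% intervals and Wald p-values follow.
#'
#' Pairs in which every selected covariate is tied carry no information and
#' contribute `log(1/2)` each to the log-likelihood. If the likelihood is
#' monotone in some direction (complete separation: a covariate whose
#' within-pair difference is always on the case side), the Newton iterates
#' diverge; this is detected and reported with the offending covariate
#' named.
#'
#' @param cohort a [matched_cohort()].
#' @param covariates covariate names to include (default all).
#' @param tol convergence threshold on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @return An object of class `clogit_fit` with elements `beta`,
#'   `covariance`, `se`, `odds_ratio`, `ci95` (matrix with `lower`/`upper`),
#'   `p_value`, `loglik`, `null_loglik`, `n_pairs`, `covariates`.
#' @export
conditional_logit_fit <- function(cohort, covariates = NULL,
                                  tol = 1e-8, max_iter = 50L) {
  d <- pair_differences(cohort, covariates)
  covariates <- colnames(d)
  n <- nrow(d)
  p <- ncol(d)
  informative <- rowSums(d != 0) > 0
  if (!any(informative)) {
    beta <- rep(0, p)
    names(beta) <- covariates
    return(new_clogit_fit(beta, matrix(NA_real_, p, p), n * log(0.5), n,
                          covariates))
  }

  # Separation screen: a covariate whose nonzero differences all share one
  # sign drives beta to +/- Inf in a univariate fit, and is the usual
  # culprit multivariately.
  sep <- vapply(seq_len(p), function(j) {
    dj <- d[, j]
    nz <- dj[dj != 0]
    length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  }, logical(1L))
  if (any(sep)) {
    stop("complete separation: conditional likelihood is unbounded in ",
         "covariate(s) ", paste(covariates[sep], collapse = ", "))
  }

  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(d %*% beta)
    pr <- stats::plogis(eta)                 # P(observed case | pair)
    grad <- as.numeric(crossprod(d, 1 - pr))
    w <- pr * (1 - pr)
    info <- crossprod(d * sqrt(w))           # observed information
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix; covariates may be collinear: ",
           paste(covariates, collapse = ", "))
    }
    # halve overly aggressive steps to keep the likelihood ascending
    ll_old <- sum(stats::plogis(eta, log.p = TRUE))
    for (h in 0:20) {
      cand <- beta + step / 2^h
      ll_new <- sum(stats::plogis(as.numeric(d %*% cand), log.p = TRUE))
      if (ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    if (max(abs(beta)) > 50) {
      bad <- covariates[which.max(abs(beta))]
      if (any(sep)) bad <- paste(covariates[sep], collapse = ", ")
      stop("complete separation: conditional likelihood is unbounded in ",
           "covariate(s) ", bad)
    }
  }
  if (!converged) {
    eta <- as.numeric(d %*% beta)
    grad <- as.numeric(crossprod(d, 1 - stats::plogis(eta)))
    if (max(abs(grad)) >= tol) {
      stop("Newton iterations failed to converge after ", max_iter,
           " steps (gradient norm ", format(max(abs(grad))), ")")
    }
  }
  eta <- as.numeric(d %*% beta)
  pr <- stats::plogis(eta)
  info <- crossprod(d * sqrt(pr * (1 - pr)))
  covariance <- tryCatch(solve(info), error = function(e) {
    stop("singular information matrix at the optimum")
  })
  covariance <- (covariance + t(covariance)) / 2
  names(beta) <- covariates
  new_clogit_fit(beta, covariance,
                 sum(stats::plogis(eta, log.p = TRUE)), n, covariates)
}

new_clogit_fit <- function(beta, covariance, loglik, n_pairs, covariates) {
  se <- sqrt(diag(as.matrix(covariance)))
  z <- beta / se
  structure(
    list(beta = beta,
         covariance = covariance,
         se = se,
         odds_ratio = exp(beta),
         ci95 = cbind(lower = exp(beta - 1.96 * se),
                      upper = exp(beta + 1.96 * se)),
         p_value = 2 * stats::pnorm(-abs(z)),
         loglik = loglik,
         null_loglik = n_pairs * log(0.5),
         n_pairs = n_pairs,
         covariates = covariates),
    class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("1:1 conditional logistic fit,", x$n_pairs, "pairs, log-likelihood",
      format(x$loglik, digits = 6), "\n")
  if (length(x$beta) == 0L) {
    cat("  (empty model)\n")
    return(invisible(x))
  }
  tab <- data.frame(beta = round(x$beta, 3),
                    OR = round(x$odds_ratio, 3),
                    ci_low = round(x$ci95[, "lower"], 3),
                    ci_high = round(x$ci95[, "upper"], 3),
                    p = signif(x$p_value, 3))
  print(tab)
  invisible(x)
}

#' Odds ratios with 95% Wald intervals
#'
#' @param fit a `clogit_fit`.
#' @return data.frame with `covariate`, `beta`, `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
or_with_ci <- function(fit) {
  stopifnot(inherits(fit, "clogit_fit"))
  data.frame(covariate = fit$covariates,
             beta = unname(fit$beta),
             odds_ratio = unname(fit$odds_ratio),
             ci_lower = unname(fit$ci95[, "lower"]),
             ci_upper = unname(fit$ci95[, "upper"]),
             p_value = unname(fit$p_value),
             row.names = NULL)
}

#' Univariate conditional logistic scan
#'
#' Fits a single-covariate conditional logistic model per descriptor,
#' flagging covariates significant at `alpha`. A covariate whose fit fails
#' (separation, no informative pairs) is recorded with an `error` message
#' and the scan continues.
#'
#' @param cohort a [matched_cohort()].
#' @param covariates names to scan (default all).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per covariate: `covariate`, `beta`,
#'   `se`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`, `significant`,
#'   `error`.
#' @export
univariate_scan <- function(cohort, covariates = NULL, alpha = 0.05) {
  if (is.null(covariates)) covariates <- cohort$covariate_names
  rows <- lapply(covariates, function(cv) {
    fit <- tryCatch(conditional_logit_fit(cohort, cv),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(covariate = cv, beta = NA_real_, se = NA_real_,
                        odds_ratio = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_,
                        significant = FALSE,
                        error = conditionMessage(fit)))
    }
    data.frame(covariate = cv, beta = unname(fit$beta),
               se = unname(fit$se),
               odds_ratio = unname(fit$odds_ratio),
               ci_lower = unname(fit$ci95[, "lower"]),
               ci_upper = unname(fit$ci95[, "upper"]),
               p_value = unname(fit$p_value),
               significant = !is.na(fit$p_value) && fit$p_value < alpha,
               error = NA_character_)
  })
  do.call(rbind, rows)
}

#' Stepwise-forward conditional logistic model selection
#'
#' Starts from the empty model. At each step the candidate with the
#' smallest likelihood-ratio p-value enters if that p-value is below
#' `p_enter`; after every entry, retained covariates whose Wald p-value has
#' risen above `p_stay` are removed (worst first). The procedure stops when
#' no entry or removal occurs. Ties are broken by candidate order, so the
#' result is deterministic given the input ordering.
#'
#' @param cohort a [matched_cohort()].
#' @param candidates candidate covariate names (typically the univariately
#'   significant set).
#' @param p_enter likelihood-ratio entry threshold (default 0.05).
#' @param p_stay Wald stay threshold (default 0.10).
#' @return A `clogit_fit` on the retained covariates; a fit with zero
#'   covariates (empty model, `loglik = n log(1/2)`) if none enter. The
#'   selection path is attached as attribute `path`.
#' @export
stepwise_forward <- function(cohort, candidates = NULL,
                             p_enter = 0.05, p_stay = 0.10) {
  if (is.null(candidates)) candidates <- cohort$covariate_names
  retained <- character(0)
  path <- character(0)
  loglik_of <- function(cov) {
    if (!length(cov)) return(nrow(cohort$case) * log(0.5))
    conditional_logit_fit(cohort, cov)$loglik
  }
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, retained)
    if (length(pool)) {
      ll0 <- loglik_of(retained)
      lr_p <- vapply(pool, function(cv) {
        ll1 <- tryCatch(loglik_of(c(retained, cv)),
                        error = function(e) NA_real_)
        if (is.na(ll1)) return(NA_real_)
        stats::pchisq(2 * (ll1 - ll0), df = 1L, lower.tail = FALSE)
      }, numeric(1L))
      ok <- which(!is.na(lr_p) & lr_p < p_enter)
      if (length(ok)) {
        enter <- pool[ok[which.min(lr_p[ok])]]
        retained <- c(retained, enter)
        path <- c(path, paste0("+", enter))
        changed <- TRUE
      }
    }
    # removal pass on Wald p-values
    repeat {
      if (length(retained) == 0L) break
      fit <- conditional_logit_fit(cohort, retained)
      worst <- which.max(fit$p_value)
      if (fit$p_value[worst] > p_stay) {
        path <- c(path, paste0("-", retained[worst]))
        retained <- retained[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- if (length(retained)) {
    conditional_logit_fit(cohort, retained)
  } else {
    new_clogit_fit(stats::setNames(numeric(0), character(0)),
                   matrix(numeric(0), 0L, 0L),
                   nrow(cohort$case) * log(0.5),
                   nrow(cohort$case), character(0))
  }
  attr(fit, "path") <- path
  fit
}
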