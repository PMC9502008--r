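#' Extract descriptor tables from surface-series files
#'
#' Runs the descriptor stage over a set of mesh+WSS inputs: each input is
#' either a path to a file written by [write_surface_series()] or an
#' in-memory `list(mesh =, series =)`. Per-aneurysm failures (unreadable
#' file, missing regions) are logged and the run continues; failed inputs
#' are reported in the `failures` attribute and excluded from the table.
#'
#' @param inputs named list (or character vector of paths); names become
#'   the `id` column, defaulting to file basenames.
#' @param output_csv optional path; when given, the full-precision table is
#'   written there and a 3-decimal report variant to
#'   `<output_csv base>_report.csv`.
#' @param chp_cfg a [chp_config()].
#' @param quiet suppress per-aneurysm messages.
#' @return data.frame of descriptors, one row per successful input, with
#'   attribute `failures` (named character vector of error messages).
#' @export
run_extract <- function(inputs, output_csv = NULL, chp_cfg = chp_config(),
                        quiet = FALSE) {
  if (is.character(inputs)) {
    nm <- if (is.null(names(inputs))) basename(inputs) else names(inputs)
    inputs <- stats::setNames(as.list(inputs), nm)
  }
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("aneurysm_", seq_along(inputs))
  }
  rows <- list()
  failures <- character(0)
  for (nm in names(inputs)) {
    res <- tryCatch({
      x <- inputs[[nm]]
      if (is.character(x)) x <- read_surface_series(x)
      compute_descriptors(x$mesh, x$series, chp_cfg = chp_cfg, id = nm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      if (!quiet) message("extract failed for ", nm, ": ", failures[nm])
    } else {
      rows[[nm]] <- res
      if (!quiet) message("extracted ", nm)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame()
  if (!is.null(output_csv) && length(rows)) {
    utils::write.csv(out, output_csv, row.names = FALSE)
    report <- sub("(\\.[^.]+)?$", "_report\\1", output_csv)
    utils::write.csv(round_descriptors(out), report, row.names = FALSE)
  }
  attr(out, "failures") <- failures
  out
}

#' Run the full matched-pair rupture study
#'
#' Reproduces the analysis sequence on a matched cohort: univariate
#' conditional logistic scan, stepwise-forward multivariate model on the
#' significant covariates, OR-to-points score construction, ROC of the
#' combined score and of each retained factor, and DeLong comparisons of
#' the combined score's AUC against each single factor. Continuous
#' candidates can be dichotomised at their Youden cutoff before entering
#' the multivariate step.
#'
#' @param cohort a [matched_cohort()] (or a long-format data.frame /
#'   CSV path accepted by [as_matched_cohort()] / [read_cohort_csv()]).
#' @param dichotomize character vector of covariate names to replace by
#'   their `> Youden-cutoff` indicator (named `<covariate>_high`) before
#'   the multivariate step; default none.
#' @param p_enter,p_stay stepwise thresholds (see [stepwise_forward()]).
#' @param point_rule allocation rule for [allocate_points()].
#' @param alpha univariate significance threshold.
#' @param seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return A list of class `study_report`: `univariate` (scan table),
#'   `multivariate` ([or_with_ci()] table or empty), `fit`, `score_model`
#'   (or NULL for an empty model), `scores` (per-member score table),
#'   `roc` (named list of `roc_result`), `delong` (named list),
#'   `provenance`.
#' @export
run_study <- function(cohort, dichotomize = character(0),
                      p_enter = 0.05, p_stay = 0.10,
                      point_rule = "ceiling_or", alpha = 0.05,
                      seed = NA_integer_) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (is.data.frame(cohort)) cohort <- as_matched_cohort(cohort)
  stopifnot(inherits(cohort, "matched_cohort"))

  config <- list(dichotomize = dichotomize, p_enter = p_enter,
                 p_stay = p_stay, point_rule = point_rule, alpha = alpha,
                 seed = seed)

  uni <- univariate_scan(cohort, alpha = alpha)
  work <- cohort
  cut_map <- list()
  for (cv in dichotomize) {
    vals <- c(work$case[, cv], work$control[, cv])
    labels <- rep(c(TRUE, FALSE), each = nrow(work$case))
    cut <- optimal_cutoff(vals, labels)
    cut_map[[cv]] <- cut
    nm <- paste0(cv, "_high")
    add_col <- function(m, v) {
      cbind(m, matrix(v, ncol = 1L, dimnames = list(NULL, nm)))
    }
    work$case <- add_col(work$case, as.numeric(work$case[, cv] > cut))
    work$control <- add_col(work$control,
                            as.numeric(work$control[, cv] > cut))
    work$covariate_names <- colnames(work$case)
  }
  sig <- uni$covariate[uni$significant]
  candidates <- unlist(lapply(sig, function(cv) {
    if (cv %in% dichotomize) paste0(cv, "_high") else cv
  }))

  fit <- stepwise_forward(work, candidates = candidates,
                          p_enter = p_enter, p_stay = p_stay)
  retained <- fit$covariates

  score_model <- NULL
  scores_tab <- NULL
  rocs <- list()
  delong <- list()
  if (length(retained)) {
    pts <- allocate_points(fit, rule = point_rule)
    # covariates dichotomised in this run become indicator terms carrying
    # their Youden threshold; everything else (including covariates that
    # are already 0/1 in the input) is scored as points * value
    thresholds <- vapply(retained, function(cv) {
      base <- sub("_high$", "", cv)
      if (grepl("_high$", cv) && !is.null(cut_map[[base]])) {
        cut_map[[base]]
      } else NA_real_
    }, numeric(1L))
    terms <- data.frame(
      # indicator terms are named after the underlying descriptor so the
      # model can be applied to raw descriptor tables
      covariate = ifelse(is.na(thresholds), retained,
                         sub("_high$", "", retained)),
      kind = ifelse(is.na(thresholds), "continuous", "indicator"),
      threshold = thresholds,
      points = as.numeric(pts))
    # in the working cohort the dichotomised columns are already 0/1, so
    # member scores are points * column value under the work-space names
    inner <- risk_score_model(data.frame(
      covariate = retained, kind = "continuous", threshold = NA_real_,
      points = as.numeric(pts)))

    members <- rbind(
      data.frame(pair_id = work$pair_id, member = "case",
                 as.data.frame(work$case), check.names = FALSE),
      data.frame(pair_id = work$pair_id, member = "control",
                 as.data.frame(work$control), check.names = FALSE))
    sc <- score_aneurysms(inner, members)
    labels <- members$member == "case"
    rocs$score <- roc_curve(sc, labels)
    score_model <- risk_score_model(terms, cutoff = rocs$score$youden_cutoff)
    scores_tab <- data.frame(pair_id = members$pair_id,
                             member = members$member, score = sc,
                             high_risk = sc > score_model$cutoff)
    for (cv in retained) {
      rocs[[cv]] <- roc_curve(members[[cv]], labels)
      delong[[cv]] <- delong_compare(rocs$score, rocs[[cv]])
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("aneuhemo")),
    config = config,
    config_hash = rlang::hash(config),
    n_pairs = nrow(cohort$case),
    covariates = cohort$covariate_names,
    cutoffs = cut_map,
    timestamp = NA)  # deliberately constant so reruns are identical
  structure(list(univariate = uni,
                 multivariate = if (length(retained)) or_with_ci(fit) else
                   data.frame(),
                 fit = fit,
                 score_model = score_model,
                 scores = scores_tab,
                 roc = rocs,
                 delong = delong,
                 provenance = provenance),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== matched-pair rupture study ==\n")
  cat("pairs:", x$provenance$n_pairs, "\n\n")
  cat("-- univariate conditional logistic scan --\n")
  u <- x$univariate
  u[c("beta", "odds_ratio", "ci_lower", "ci_upper")] <-
    lapply(u[c("beta", "odds_ratio", "ci_lower", "ci_upper")], round, 3)
  u$p_value <- signif(u$p_value, 3)
  print(u[c("covariate", "beta", "odds_ratio", "ci_lower", "ci_upper",
            "p_value", "significant")], row.names = FALSE)
  cat("\n-- multivariate model (stepwise forward) --\n")
  if (nrow(x$multivariate)) {
    m <- x$multivariate
    m[c("beta", "odds_ratio", "ci_lower", "ci_upper")] <-
      lapply(m[c("beta", "odds_ratio", "ci_lower", "ci_upper")], round, 3)
    m$p_value <- signif(m$p_value, 3)
    print(m, row.names = FALSE)
    cat("\n")
    print(x$score_model)
    cat(sprintf("\ncombined-score AUC: %.3f\n", x$roc$score$auc))
    for (cv in setdiff(names(x$roc), "score")) {
      dl <- x$delong[[cv]]
      cat(sprintf("  vs %s: AUC %.3f, DeLong p = %.4g\n",
                  cv, x$roc[[cv]]$auc, dl$p_value))
    }
  } else {
    cat("no covariate entered the model\n")
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' JSON (machine-readable, full precision) plus a plain-text rendering of
#' the printed report.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    univariate = report$univariate,
    multivariate = report$multivariate,
    score_model = if (!is.null(report$score_model)) {
      list(terms = report$score_model$terms,
           cutoff = report$score_model$cutoff)
    },
    auc = lapply(report$roc, function(r) r$auc),
    delong = lapply(report$delong, function(d) {
      d[c("auc_diff", "se", "ci95", "p_value")]
    }),
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "study_report.txt"))
  if (!is.null(report$scores)) {
    utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
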