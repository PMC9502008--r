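test_that("fully tied pairs give beta 0 and the null log-likelihood", {
  x <- matrix(rnorm(20), 10L, 2L, dimnames = list(NULL, c("a", "b")))
  cohort <- matched_cohort(x, x)
  fit <- conditional_logit_fit(cohort)
  expect_equal(unname(fit$beta), c(0, 0))
  expect_equal(fit$loglik, 10 * log(0.5))
})

test_that("fit matches a fine grid search of the conditional likelihood", {
  d <- c(0.8, -0.3, 1.2, 0.4, -0.9, 0.6, 1.5, -0.2)
  cohort <- matched_cohort(matrix(d, ncol = 1L,
                                  dimnames = list(NULL, "x")),
                           matrix(0, 8L, 1L))
  fit <- conditional_logit_fit(cohort)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, cond_loglik_1d, numeric(1L), d = d)
  expect_lt(abs(unname(fit$beta) - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-8)
})

test_that("fit agrees with survival::clogit on a simulated cohort", {
  library(survival)
  cohort <- simulate_matched_cohort(
    cohort_spec(n_pairs = 150L, betas = c(u = 0.8, v = -0.5),
                difference_distributions = list(
                  u = list(family = "normal", mean = 0, sd = 1),
                  v = list(family = "normal", mean = 0, sd = 1)),
                seed = 31L))
  fit <- conditional_logit_fit(cohort)

  long <- rbind(data.frame(y = 1, stratum = seq_len(150L), cohort$case),
                data.frame(y = 0, stratum = seq_len(150L), cohort$control))
  ref <- clogit(y ~ u + v + strata(stratum), data = long)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("estimator is invariant to storage order and flips with labels", {
  cohort <- simulate_matched_cohort(
    cohort_spec(n_pairs = 80L, betas = c(x = 1),
                difference_distributions = list(
                  x = list(family = "normal", mean = 0, sd = 1)),
                seed = 5L))
  fit <- conditional_logit_fit(cohort)
  # permute pair storage order: identical fit
  perm <- sample(80L)
  fit_perm <- conditional_logit_fit(
    matched_cohort(cohort$case[perm, , drop = FALSE],
                   cohort$control[perm, , drop = FALSE]))
  expect_equal(fit_perm$beta, fit$beta, tolerance = 1e-10)
  # swap case/control labels: beta flips sign
  fit_swap <- conditional_logit_fit(
    matched_cohort(cohort$control, cohort$case))
  expect_equal(unname(fit_swap$beta), -unname(fit$beta), tolerance = 1e-8)
})

test_that("complete separation is diagnosed with the covariate named", {
  d <- abs(rnorm(12)) + 0.1
  cohort <- matched_cohort(
    matrix(d, ncol = 1L, dimnames = list(NULL, "lsa")),
    matrix(0, 12L, 1L))
  expect_error(conditional_logit_fit(cohort), "separation.*lsa")
})

test_that("the univariate scan is deterministic and survives failures", {
  cohort <- simulate_matched_cohort(
    cohort_spec(n_pairs = 60L, betas = c(x = 1.2),
                difference_distributions = list(
                  x = list(family = "normal", mean = 0, sd = 1)),
                seed = 9L))
  # duplicate the covariate under a second name and add a constant one
  dup <- matched_cohort(
    cbind(cohort$case, x2 = cohort$case[, "x"], flat = 1),
    cbind(cohort$control, x2 = cohort$control[, "x"], flat = 1))
  scan <- univariate_scan(dup)
  expect_equal(scan$beta[scan$covariate == "x2"],
               scan$beta[scan$covariate == "x"])
  expect_equal(scan$p_value[scan$covariate == "x2"],
               scan$p_value[scan$covariate == "x"])
  # the constant covariate is uninformative: null fit, never significant
  flat_row <- scan[scan$covariate == "flat", ]
  expect_false(flat_row$significant)
  expect_true(is.na(flat_row$p_value))
  expect_equal(nrow(scan), 3L)
})

test_that("the scan has near-nominal power for a strong effect", {
  hits <- vapply(1:200, function(i) {
    cohort <- simulate_matched_cohort(
      cohort_spec(n_pairs = 91L, betas = c(x = 1),
                  difference_distributions = list(
                    x = list(family = "normal", mean = 0, sd = 1)),
                  seed = 1000L + i))
    univariate_scan(cohort)$p_value < 0.05
  }, logical(1L))
  expect_gt(mean(hits), 0.95)
})

test_that("stepwise forward returns the empty model when nothing enters", {
  x <- matrix(rnorm(40), 20L, 2L, dimnames = list(NULL, c("a", "b")))
  cohort <- matched_cohort(x, x)  # fully tied: no candidate can enter
  fit <- stepwise_forward(cohort)
  expect_length(fit$covariates, 0L)
  expect_equal(fit$loglik, 20 * log(0.5))
})

test_that("stepwise forward keeps a strong predictor and drops noise", {
  runs <- lapply(1:200, function(i) {
    cohort <- simulate_matched_cohort(
      cohort_spec(n_pairs = 91L,
                  betas = c(signal = 2, noise1 = 0, noise2 = 0),
                  difference_distributions = list(
                    signal = list(family = "normal", mean = 0, sd = 1),
                    noise1 = list(family = "normal", mean = 0, sd = 1),
                    noise2 = list(family = "normal", mean = 0, sd = 1)),
                  seed = 2000L + i))
    stepwise_forward(cohort)$covariates
  })
  # the true effect always survives selection
  expect_gt(mean(vapply(runs, function(r) "signal" %in% r, logical(1L))),
            0.99)
  # each null covariate enters at about its nominal 5% entry rate
  noise_rate <- mean(vapply(runs, function(r) any(grepl("noise", r)),
                            logical(1L)))
  expect_lt(noise_rate, 0.2)  # nominal 1 - 0.95^2, wide MC band
  expect_gt(mean(vapply(runs, function(r) identical(r, "signal"),
                        logical(1L))), 0.8)
})

test_that("stepwise recovers the published three-predictor structure", {
  n_all <- vapply(1:20, function(i) {
    cohort <- simulate_matched_cohort(
      cohort_spec(n_pairs = 400L, seed = 3000L + i))
    fit <- stepwise_forward(cohort)
    setequal(fit$covariates,
             c("lsa", "chp_mean_high", "wssg_ratio_high"))
  }, logical(1L))
  expect_gt(mean(n_all), 0.5)
})

test_that("odds ratios and Wald intervals derive exactly from beta", {
  cohort <- simulate_matched_cohort(
    cohort_spec(n_pairs = 100L, betas = c(x = 0.7),
                difference_distributions = list(
                  x = list(family = "normal", mean = 0, sd = 1)),
                seed = 77L))
  fit <- conditional_logit_fit(cohort)
  tab <- or_with_ci(fit)
  expect_equal(tab$odds_ratio, exp(tab$beta))
  expect_equal(tab$ci_lower, exp(tab$beta - 1.96 * fit$se[[1L]]))
  expect_equal(tab$ci_upper, exp(tab$beta + 1.96 * fit$se[[1L]]))
})
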