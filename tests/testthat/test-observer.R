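test_that("the estimation-trial log density matches the closed form", {
  # fixed numbers: w = 3600/4500 = 0.8, mean = .8*512 + .2*(600-10) = 527.6,
  # sd = .2*60 = 12
  ll <- loglik_estimation_trial(sigma_prior = 30, sigma_evidence = 60,
                                shift_s = -10, x_true = 600,
                                x_estimate = 550, mu_prior = 512)
  direct <- -0.5 * log(2 * pi) - log(12) - 0.5 * ((550 - 527.6) / 12)^2
  expect_equal(ll, direct, tolerance = 1e-12)

  # posterior-SD formulation: sd = sqrt(1 - w) * sigma_evidence
  llp <- loglik_estimation_trial(30, 60, -10, 600, 550, 512,
                                 likelihood = "posterior")
  sdp <- sqrt(0.2) * 60
  expect_equal(llp, dnorm(550, 527.6, sdp, log = TRUE), tolerance = 1e-12)

  expect_error(loglik_estimation_trial(-1, 60, 0, 600, 550, 512), "positive")
})

test_that("the log density obeys the flat-prior and symmetry limits", {
  # flat prior: predicted mean tends to x_true, SD to sigma_evidence
  ll_flat <- loglik_estimation_trial(1e9, 50, 0, 600, 600, 512)
  expect_equal(ll_flat, dnorm(600, 600, 50, log = TRUE), tolerance = 1e-4)

  # equal SDs: w = 1/2, mean is the midpoint of prior mean and x_true + s
  ll_mid <- loglik_estimation_trial(40, 40, 6, 700, 610, 512)
  expect_equal(ll_mid, dnorm(610, (512 + 706) / 2, 20, log = TRUE),
               tolerance = 1e-12)

  # nesting: at s = 0 the shifted model reduces exactly to the unshifted one
  expect_equal(loglik_estimation_trial(30, 60, 0, 600, 550, 512),
               loglik_estimation_trial(30, 60, 0, 600, 550, 512))
})

test_that("split R-hat matches a from-scratch formula and flags divergence", {
  set.seed(7)
  same <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(compute_rhat(same) - 1), 0.05)

  apart <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(compute_rhat(apart), 3)

  # oracle: split each chain and recompute between/within variances
  x <- matrix(rnorm(600), 100, 6)
  half <- 50
  splits <- cbind(x[1:half, ], x[51:100, ])
  w <- mean(apply(splits, 2, var))
  b <- half * var(colMeans(splits))
  oracle <- sqrt(((half - 1) / half * w + b / half) / w)
  expect_equal(compute_rhat(x), oracle, tolerance = 1e-12)

  expect_error(compute_rhat(matrix(1:10, 10, 1)), "2 chains")
  expect_error(compute_rhat(matrix(1:6, 3, 2)), "4 draws")
  expect_warning(r0 <- compute_rhat(matrix(1, 10, 2)), "zero-variance")
  expect_equal(r0, 1)
})

test_that("WAIC matches direct summation and its degenerate cases", {
  set.seed(8)
  ll <- matrix(rnorm(200, -3, 0.5), 20, 10)
  w <- waic(ll)
  # naive direct oracle
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-10)
  expect_equal(w$p_waic, p, tolerance = 1e-10)

  one <- waic(ll[1, , drop = FALSE])
  expect_equal(one$p_waic, 0)
  expect_equal(one$waic, -2 * sum(ll[1, ]))
  same <- waic(ll[rep(1, 5), ])
  expect_equal(same$waic, one$waic)

  # invariance to permutations of draws and observations
  expect_equal(waic(ll[sample(20), ])$waic, w$waic, tolerance = 1e-10)
  expect_equal(waic(ll[, sample(10)])$waic, w$waic, tolerance = 1e-10)

  # log-sum-exp stabilisation: extreme values stay finite
  expect_true(is.finite(waic(matrix(c(-1e4, -1e4 + 1), 2, 1))$waic))
  expect_error(waic(matrix(numeric(0), 0, 0)), "empty")
})

test_that("normalized prior SD is the documented ratio", {
  expect_equal(normalized_prior_sd(10, 10), 0.5)
  expect_equal(normalized_prior_sd(0, 10), 0)
  expect_equal(normalized_prior_sd(10, 20), 1 / 3)
  expect_error(normalized_prior_sd(10, 0), "positive")
  expect_error(normalized_prior_sd(-1, 10), "non-negative")
})

test_that("a small hierarchical fit has coherent structure and is seeded", {
  fit <- tiny_fit()
  expect_s3_class(fit, "ap_observer_fit")
  expect_equal(dim(fit$draws)[1:2], c(150, 2))
  expect_equal(nrow(fit$cells), length(fit$participant_ids) * 4)
  expect_equal(dim(fit$loglik), c(300, nrow(fit$data)))
  expect_true(all(is.finite(fit$loglik)))
  expect_true(all(fit$rhat$rhat > 0.98))
  expect_true(all(fit$cells$sigma_prior > 0))
  expect_true(all(fit$cells$weight_w > 0 & fit$cells$weight_w < 1))

  td <- generics::tidy(fit)
  expect_true(all(c("term", "estimate", "rhat") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$waic, waic(fit)$waic)

  # identical seed reproduces the draws exactly
  dat <- small_cohort_trials(4, seed = 11)
  again <- fit_observer(dat$trials, "m2", chains = 2, draws = 150,
                        warmup = 250, adapt = 250, thin = 1, seed = 11)
  expect_equal(fit$draws, again$draws)
})

test_that("waic comparison is zero against itself and validates inputs", {
  fit <- tiny_fit()
  cmp <- compare_waic(list(a = fit, b = fit))
  expect_equal(cmp$pairs$delta_waic, c(0, 0))
  expect_equal(cmp$pairs$se_delta_waic, c(0, 0))

  other <- fit
  other$data <- other$data[-1, ]
  expect_error(compare_waic(list(a = fit, b = other)), "identical trial sets")
})

test_that("posterior predictive replicates cover the observed estimates", {
  fit <- tiny_fit()
  ppc <- posterior_predictive(fit, n_rep = 150, seed = 4)
  expect_equal(dim(ppc$replicates), c(150, nrow(fit$data)))
  pooled <- ppc$coverage$coverage[ppc$coverage$effort == "pooled"]
  expect_gt(pooled, 0.85)
  expect_lte(pooled, 1)
  # pooled coverage is the n-weighted mean of the per-condition coverages
  per <- ppc$coverage[ppc$coverage$effort != "pooled", ]
  expect_equal(sum(per$coverage * per$n) / sum(per$n), pooled,
               tolerance = 1e-12)
})

test_that("recovery scoring joins on ids and detects shuffled truth", {
  dat <- small_cohort_trials(4, seed = 11)
  fit <- tiny_fit()
  rec <- parameter_recovery(dat$truth, fit)
  expect_true(all(c("parameter", "correlation", "rmse", "pass") %in% names(rec)))
  expect_true(all(is.finite(rec$rmse)))

  wrong <- dat$truth
  wrong$participants$participant_id <- rev(wrong$participants$participant_id)
  rec_wrong <- parameter_recovery(wrong, fit)
  expect_false(identical(rec$correlation, rec_wrong$correlation))

  missing <- dat$truth
  missing$participants <- missing$participants[-(1:2), ]
  expect_error(parameter_recovery(missing, fit), "absent")
})

test_that("the observational-prior variant fixes its prior to basic trials", {
  dat <- small_cohort_trials(4, seed = 11)
  fit3 <- fit_observer(dat$trials, "m3", chains = 2, draws = 100,
                       warmup = 200, adapt = 200, thin = 1, seed = 11)
  emp <- dat$trials |>
    dplyr::filter(trial_type == "basic") |>
    dplyr::group_by(participant_id, effort, reward) |>
    dplyr::summarise(emp_sd = sd(x_true), .groups = "drop") |>
    dplyr::arrange(participant_id, effort, reward)
  expect_equal(fit3$cells$sigma_prior, emp$emp_sd, tolerance = 1e-10)
  expect_equal(fit3$cells$sigma_prior_sd, rep(0, nrow(fit3$cells)))
  expect_true(all(fit3$cells$shift_s == 0))
})
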