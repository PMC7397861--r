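test_that("there are exactly ten candidate specifications", {
  specs <- weighting_model_specs()
  expect_equal(nrow(specs), 10)
  expect_equal(anyDuplicated(specs$spec_id), 0)
  expect_true("i_none.s_none" %in% specs$spec_id)
  # 3 intercept-only, 3 slope-only, 3 joint adjustments
  expect_equal(sum(specs$intercept_adj != "none" & specs$slope_adj == "none"), 3)
  expect_equal(sum(specs$intercept_adj == "none" & specs$slope_adj != "none"), 3)
  expect_equal(sum(specs$intercept_adj != "none" & specs$slope_adj != "none"), 3)
})

test_that("degenerate estimates pin the slope to its endpoints", {
  on_target <- degenerate_trials(estimate = "target")
  fit <- suppressWarnings(fit_weighting_model(on_target))
  expect_equal(fit$fixed$estimate[2], -1, tolerance = 1e-6)

  veridical <- degenerate_trials(estimate = "true")
  fit0 <- suppressWarnings(fit_weighting_model(veridical))
  expect_equal(fit0$fixed$estimate[2], 0, tolerance = 1e-6)
})

test_that("the group slope recovers -w on simulated cohorts", {
  dat <- small_cohort_trials(10, seed = 81,
                             settings = fixed_w_settings(w = 0.7))
  fit <- suppressWarnings(fit_weighting_model(dat$trials))
  expect_equal(fit$fixed$estimate[2], -0.7, tolerance = 0.05)
  # conditional participant slopes sit around the same value
  expect_lt(max(abs(fit$participant_slopes$slope + 0.7)), 0.2)
})

test_that("cAIC reduces to the fixed-model AIC when random effects vanish", {
  # participants are exchangeable: no between-participant structure
  set.seed(9)
  trials <- degenerate_trials(n_participants = 6, n_trials = 120)
  trials$x_estimate <- trials$x_target - 0.5 * trials$performance_error +
    rnorm(nrow(trials), 0, 25)
  trials$estimation_error <- trials$x_estimate - trials$x_true
  fit <- suppressWarnings(fit_weighting_model(trials))
  if (all(lme4::getME(fit$fit, "theta") < 1e-6)) {
    lmfit <- stats::lm(estimation_error ~ performance_error, data = trials)
    expect_equal(fit$effective_dof, 3, tolerance = 0.05)
    expect_equal(fit$caic, stats::AIC(lmfit), tolerance = 0.5)
  } else {
    # some random-effect variance survived: edof exceeds the fixed count
    expect_gt(fit$effective_dof, 3)
  }
  # direct degeneracy check: with the random-effect covariance forced to
  # zero, the hat-trace reduces to the fixed-effect hat matrix
  X <- lme4::getME(fit$fit, "X")
  Z <- as.matrix(lme4::getME(fit$fit, "Z"))
  M <- cbind(X, Z)
  P0 <- diag(1e12, ncol(Z))   # vanishing variance = infinite penalty
  A <- crossprod(M)
  A[3:ncol(M), 3:ncol(M)] <- A[3:ncol(M), 3:ncol(M)] + P0
  expect_equal(sum(diag(solve(A, crossprod(M)))), ncol(X), tolerance = 1e-3)
})

test_that("effective dof matches an augmented-least-squares hat-trace oracle", {
  dat <- small_cohort_trials(4, seed = 91)
  est <- dplyr::filter(dat$trials, !is.na(estimation_error))
  est <- est[seq_len(200), ]
  fit <- suppressWarnings(fit_weighting_model(est))
  m <- fit$fit

  X <- lme4::getME(m, "X")
  Z <- as.matrix(lme4::getME(m, "Z"))
  Lam <- as.matrix(lme4::getME(m, "Lambda"))
  G <- tcrossprod(Lam)
  ridge <- max(diag(G), 1) * 1e-10
  P <- solve(G + diag(ridge, nrow(G)))
  M <- cbind(X, Z)
  # independent route: augmented QR, column by column of the hat matrix
  aug <- rbind(M, cbind(matrix(0, ncol(Z), ncol(X)), chol(P)))
  qr_aug <- qr(aug)
  n <- nrow(M)
  trace <- sum(vapply(seq_len(n), function(i) {
    rhs <- c(rep(0, n), rep(0, ncol(Z)))
    rhs[i] <- 1
    coefs <- qr.coef(qr_aug, rhs)
    sum(M[i, ] * coefs)
  }, 0))
  expect_equal(fit$effective_dof, trace + 1, tolerance = 1e-6)
})

test_that("pure-noise random terms never decrease the effective dof", {
  dat <- small_cohort_trials(5, seed = 95)
  base <- suppressWarnings(fit_weighting_model(dat$trials, "i_none.s_none"))
  richer <- suppressWarnings(fit_weighting_model(dat$trials, "i_both.s_none"))
  expect_gte(richer$effective_dof, base$effective_dof - 1e-6)
})

test_that("model selection recovers the generating structure", {
  specs <- weighting_model_specs()
  single <- specs[specs$spec_id == "i_none.s_none", ]

  # single candidate: trivially selected with delta zero
  dat <- small_cohort_trials(5, seed = 101)
  sel1 <- suppressWarnings(select_weighting_model(dat$trials, single))
  expect_equal(sel1$best$spec_id, "i_none.s_none")
  expect_equal(sel1$table$delta_caic, 0)

  # condition-varying weighting: slope-adjusted candidates should win
  set.seed(13)
  hits <- 0
  reps <- 4
  for (r in seq_len(reps)) {
    varying <- cohort_settings(
      sigma_prior_px = 40, sigma_prior_log_sd = 0.1,
      sigma_prior_perf_link = 0,
      sigma_prior_effort_shift = 1.2,   # strong effort effect on w
      sigma_prior_reward_shift = 0, sigma_prior_cell_log_sd = 0,
      sigma_evidence_log_sd = 0.1, sigma_evidence_cell_log_sd = 0,
      shift_mean_px = 0, shift_sd_px = 0, shift_cell_sd_px = 0)
    dat <- small_cohort_trials(10, seed = 110 + r, settings = varying)
    sel <- suppressWarnings(select_weighting_model(dat$trials))
    if (sel$best$spec_id %in%
          specs$spec_id[specs$slope_adj %in% c("effort", "both")]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 3)

  # baseline-generated data: baseline stays within reach of the best
  dat0 <- small_cohort_trials(10, seed = 121,
                              settings = fixed_w_settings(w = 0.6))
  sel0 <- suppressWarnings(select_weighting_model(dat0$trials))
  base_delta <- sel0$table$delta_caic[sel0$table$spec_id == "i_none.s_none"]
  expect_lt(base_delta, 25)
})

test_that("tidy and glance expose slope, weighting and cAIC", {
  dat <- small_cohort_trials(4, seed = 131)
  fit <- suppressWarnings(fit_weighting_model(dat$trials))
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  gl <- generics::glance(fit)
  expect_equal(gl$weight_w, -gl$slope)
  expect_equal(gl$caic, -2 * gl$conditional_loglik + 2 * gl$effective_dof)
})
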