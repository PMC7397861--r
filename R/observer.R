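#' Log density of one estimation trial under an observer model
#'
#' The reported estimate is modelled as Gaussian with mean
#' `w * mu_prior + (1 - w) * (x_true + s)` where
#' `w = sigma_evidence^2 / (sigma_evidence^2 + sigma_prior^2)`.
#' Under the default trial-level sensory-sample formulation the SD is
#' `(1 - w) * sigma_evidence` (the prior-weighted propagation of one noisy
#' sensory sample); the alternative `"posterior"` formulation uses the
#' Bayes-posterior SD `sqrt(1 - w) * sigma_evidence`.
#'
#' @param sigma_prior,sigma_evidence Positive SDs in pixels.
#' @param shift_s Signed sensory shift in pixels (0 under the no-shift and
#'   observational-prior variants).
#' @param x_true True final ball position (px).
#' @param x_estimate Reported estimate (px).
#' @param mu_prior Prior mean (target position, or the empirical
#'   performance mean under the observational-prior variant).
#' @param likelihood `"sensory"` (default) or `"posterior"`.
#' @return Log density (vectorised over trials).
#' @export
loglik_estimation_trial <- function(sigma_prior, sigma_evidence, shift_s,
                                    x_true, x_estimate, mu_prior,
                                    likelihood = c("sensory", "posterior")) {
  likelihood <- match.arg(likelihood)
  if (any(sigma_prior <= 0) || any(sigma_evidence <= 0)) {
    stop("SD parameters must be positive", call. = FALSE)
  }
  w <- sigma_evidence^2 / (sigma_evidence^2 + sigma_prior^2)
  mu <- w * mu_prior + (1 - w) * (x_true + shift_s)
  sd <- switch(likelihood,
               sensory = (1 - w) * sigma_evidence,
               posterior = sqrt(1 - w) * sigma_evidence)
  stats::dnorm(x_estimate, mu, sd, log = TRUE)
}

#' Split-chain potential scale reduction statistic
#'
#' Each chain is split in half; R-hat compares the between- and
#' within-half-chain variances (`sqrt(var_plus / W)`). Values below 1.01
#' are taken as converged. Chains with zero total variance return 1 by
#' convention, with a warning.
#'
#' @param draws A numeric matrix, iterations x chains (>= 2 chains, >= 4
#'   iterations).
#' @return The split R-hat value.
#' @export
compute_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (ncol(draws) < 2 || n < 4) {
    stop("need at least 2 chains of at least 4 draws", call. = FALSE)
  }
  half <- floor(n / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  if (stats::var(as.vector(splits)) == 0) {
    warning("zero-variance draws; R-hat set to 1 by convention", call. = FALSE)
    return(1)
  }
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

#' Fit a hierarchical Bayesian observer model
#'
#' Estimates, by MCMC, the precision-weighted observer that generates
#' performance estimates on estimation trials. Three variants are
#' supported:
#' \describe{
#'   \item{m1}{target-centred prior; free `sigma_prior`, `sigma_evidence`
#'     per participant and condition.}
#'   \item{m2}{as m1 plus a sensory shift `s` (by default shared across
#'     conditions within a participant; `shift_level = "cell"` frees it per
#'     condition).}
#'   \item{m3}{observational prior: the prior mean and SD are fixed at each
#'     participant-condition's basic-trial performance mean and SD; only
#'     `sigma_evidence` is free.}
#' }
#' The hierarchy has three levels (group, participant, condition);
#' positivity of SD parameters is enforced on the log scale, and
#' condition-level deviations are non-centred for sampling stability. The
#' shift enters the likelihood through the identified intercept
#' `alpha = (1 - w) * s`. Sampling is done in JAGS with per-chain seeded
#' generators, so results are reproducible for a fixed seed.
#'
#' @param trials Canonical trial tibble (preprocessed); estimation rows
#'   supply the likelihood, basic rows the empirical prior for `m3`.
#' @param variant `"m1"`, `"m2"`, or `"m3"`.
#' @param chains,draws Number of chains and retained post-warmup draws per
#'   chain.
#' @param warmup,adapt Burn-in and adaptation iterations.
#' @param thin Thinning interval (the sampler runs `draws * thin`
#'   iterations per chain and keeps every `thin`-th).
#' @param seed Integer seed.
#' @param shift_level `"participant"` (default) or `"cell"`, for `m2`.
#' @param likelihood `"sensory"` or `"posterior"` (see
#'   [loglik_estimation_trial()]).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `ap_observer_fit` with posterior draws,
#'   per-parameter split R-hat, cell- and participant-level posterior
#'   summaries of `sigma_prior`, `sigma_evidence` and `s`, the pointwise
#'   log-likelihood matrix (draws x estimation trials), and sampler
#'   settings.
#' @export
fit_observer <- function(trials, variant = c("m2", "m1", "m3"),
                         chains = 4, draws = 500, warmup = 1000,
                         adapt = 1000, thin = 16, seed = 1L,
                         shift_level = c("participant", "cell"),
                         likelihood = c("sensory", "posterior"),
                         quiet = TRUE) {
  variant <- match.arg(variant)
  shift_level <- match.arg(shift_level)
  likelihood <- match.arg(likelihood)
  prep <- observer_data(trials, variant)
  if (prep$n_participants < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  model_string <- observer_model_string(variant, shift_level, likelihood)
  dat <- prep$jags_data
  inits <- observer_inits(prep, variant, shift_level, chains, seed)
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  pb <- if (quiet) "none" else "text"
  stats::update(jm, warmup, progress.bar = pb)
  monitors <- observer_monitors(variant, shift_level)
  samp <- rjags::coda.samples(jm, monitors, n.iter = draws * thin,
                              thin = thin, progress.bar = pb)
  build_observer_fit(samp, prep, variant, shift_level, likelihood,
                     list(chains = chains, draws = draws, warmup = warmup,
                          adapt = adapt, thin = thin, seed = seed))
}

# assemble indices, per-trial data and (for m3) empirical prior moments
observer_data <- function(trials, variant) {
  est <- dplyr::filter(trials, .data$trial_type == "estimation",
                       !is.na(.data$x_estimate))
  if (nrow(est) == 0) stop("no estimation trials", call. = FALSE)
  cells <- est |>
    dplyr::distinct(.data$participant_id, .data$effort, .data$reward) |>
    dplyr::arrange(.data$participant_id, .data$effort, .data$reward)
  cells$cell <- seq_len(nrow(cells))
  ids <- unique(cells$participant_id)
  cells$pid <- match(cells$participant_id, ids)
  est <- dplyr::left_join(est, cells,
                          by = c("participant_id", "effort", "reward"))
  if (variant == "m3") {
    emp <- trials |>
      dplyr::filter(.data$trial_type == "basic") |>
      dplyr::group_by(.data$participant_id, .data$effort, .data$reward) |>
      dplyr::summarise(emp_mu = mean(.data$x_true),
                       emp_sd = stats::sd(.data$x_true), .groups = "drop")
    cells <- dplyr::left_join(cells, emp,
                              by = c("participant_id", "effort", "reward"))
    if (anyNA(cells$emp_sd) || any(cells$emp_sd <= 0)) {
      stop("observational prior needs basic trials in every cell", call. = FALSE)
    }
    mu_prior <- cells$emp_mu[est$cell]
  } else {
    mu_prior <- est$x_target
  }
  jags_data <- list(
    N = nrow(est), j = est$cell, x_true = est$x_true,
    x_est = est$x_estimate, mu_prior = mu_prior,
    NCELL = nrow(cells), pid = cells$pid, NP = length(ids))
  if (variant == "m3") jags_data$log_sp <- log(cells$emp_sd)
  list(est = est, cells = cells, participant_ids = ids,
       n_participants = length(ids), jags_data = jags_data,
       mu_prior = mu_prior)
}

observer_model_string <- function(variant, shift_level, likelihood) {
  sd_expr <- switch(likelihood,
    sensory = "omw[k] * exp(log_se[k])",
    posterior = "sqrt(omw[k]) * exp(log_se[k])")
  alpha_expr <- if (variant != "m2") {
    "    alpha[k] <- 0"
  } else if (shift_level == "participant") {
    "    alpha[k] <- omw[k] * s_mu[pid[k]]"
  } else {
    paste0("    z_s[k] ~ dnorm(0, 1)\n",
           "    s_cell[k] <- s_mu[pid[k]] + sd_s_w * z_s[k]\n",
           "    alpha[k] <- omw[k] * s_cell[k]")
  }
  sp_block <- if (variant == "m3") {
    ""   # log_sp supplied as data
  } else {
    paste0("    z_sp[k] ~ dnorm(0, 1)\n",
           "    log_sp[k] <- lp_mu[pid[k]] + sd_lp_w * z_sp[k]\n")
  }
  participant_sp <- if (variant == "m3") "" else
    "    lp_mu[i] ~ dnorm(g_lp_mu, prec_lp_g)\n"
  participant_s <- if (variant == "m2")
    "    s_mu[i] ~ dnorm(g_s_mu, prec_s_g)\n" else ""
  hyper_sp <- if (variant == "m3") "" else paste0(
    "  g_lp_mu ~ dnorm(0, 1.0E-4)\n",
    "  sd_lp_w ~ dnorm(0, 1) T(0,)\n",
    "  sd_lp_g ~ dnorm(0, 1) T(0,)\n",
    "  prec_lp_g <- 1 / (sd_lp_g * sd_lp_g)\n")
  hyper_s <- if (variant != "m2") "" else paste0(
    "  g_s_mu ~ dnorm(0, 2.5E-3)\n",
    "  sd_s_g ~ dnorm(0, 2.5E-3) T(0,)\n",
    "  prec_s_g <- 1 / (sd_s_g * sd_s_g)\n",
    if (shift_level == "cell") "  sd_s_w ~ dnorm(0, 0.01) T(0,)\n" else "")
  paste0(
    "model {\n",
    "  for (t in 1:N) {\n",
    "    mu_est[t] <- w[j[t]] * mu_prior[t] + (1 - w[j[t]]) * x_true[t] + alpha[j[t]]\n",
    "    x_est[t] ~ dnorm(mu_est[t], tau_est[j[t]])\n",
    "  }\n",
    "  for (k in 1:NCELL) {\n",
    sp_block,
    "    z_se[k] ~ dnorm(0, 1)\n",
    "    log_se[k] <- le_mu[pid[k]] + sd_le_w * z_se[k]\n",
    "    w[k] <- exp(2 * log_se[k]) / (exp(2 * log_se[k]) + exp(2 * log_sp[k]))\n",
    "    omw[k] <- 1 - w[k]\n",
    alpha_expr, "\n",
    "    sd_est[k] <- ", sd_expr, "\n",
    "    tau_est[k] <- 1 / (sd_est[k] * sd_est[k])\n",
    "  }\n",
    "  for (i in 1:NP) {\n",
    participant_sp,
    "    le_mu[i] ~ dnorm(g_le_mu, prec_le_g)\n",
    participant_s,
    "  }\n",
    hyper_sp,
    "  g_le_mu ~ dnorm(0, 1.0E-4)\n",
    "  sd_le_w ~ dnorm(0, 1) T(0,)\n",
    "  sd_le_g ~ dnorm(0, 1) T(0,)\n",
    "  prec_le_g <- 1 / (sd_le_g * sd_le_g)\n",
    hyper_s,
    "}\n")
}

observer_monitors <- function(variant, shift_level) {
  mon <- c("log_se", "le_mu", "g_le_mu", "sd_le_w", "sd_le_g")
  if (variant != "m3") {
    mon <- c(mon, "log_sp", "lp_mu", "g_lp_mu", "sd_lp_w", "sd_lp_g")
  }
  if (variant == "m2") {
    mon <- c(mon, "s_mu", "g_s_mu", "sd_s_g")
    if (shift_level == "cell") mon <- c(mon, "s_cell", "sd_s_w")
  }
  mon
}

# moment-based initial values, jittered per chain from the seed
observer_inits <- function(prep, variant, shift_level, chains, seed) {
  est <- prep$est
  slope <- tryCatch(
    stats::coef(stats::lm(estimation_error ~ performance_error, data = est))[2],
    error = function(e) -0.7)
  w0 <- min(max(-slope, 0.05), 0.95)
  r0 <- stats::sd(stats::residuals(
    stats::lm(estimation_error ~ performance_error, data = est)))
  se0 <- max(r0 / (1 - w0), 1)
  sp0 <- max(se0 * sqrt((1 - w0) / w0), 1)
  np <- prep$n_participants
  ncell <- nrow(prep$cells)
  withr::with_seed(seed, {
    lapply(seq_len(chains), function(ch) {
      ini <- list(
        .RNG.name = "base::Mersenne-Twister",
        .RNG.seed = (seed %% 1000000L) * 1000L + ch,
        le_mu = log(se0) + stats::rnorm(np, 0, 0.1))
      if (variant != "m3") {
        ini$lp_mu <- log(sp0) + stats::rnorm(np, 0, 0.1)
        ini$z_sp <- rep(0, ncell)
      }
      ini$z_se <- rep(0, ncell)
      if (variant == "m2") {
        ini$s_mu <- stats::rnorm(np, 0, 1)
        if (shift_level == "cell") ini$z_s <- rep(0, ncell)
      }
      ini
    })
  })
}

build_observer_fit <- function(samp, prep, variant, shift_level, likelihood,
                               settings) {
  arr <- coda_to_array(samp)          # iter x chain x parameter
  par_names <- dimnames(arr)[[3]]
  rhat <- vapply(par_names, function(p) compute_rhat(arr[, , p]), 0)
  flat <- apply(arr, 3, identity)     # (iter*chain) x parameter
  cells <- prep$cells
  ncell <- nrow(cells)

  cell_par <- function(base, transform = identity) {
    cols <- paste0(base, "[", seq_len(ncell), "]")
    if (!all(cols %in% par_names)) return(NULL)
    transform(flat[, cols, drop = FALSE])
  }
  sp_draws <- if (variant == "m3") {
    matrix(rep(exp(prep$jags_data$log_sp), each = nrow(flat)), nrow(flat))
  } else {
    cell_par("log_sp", exp)
  }
  se_draws <- cell_par("log_se", exp)
  s_draws <- if (variant != "m2") {
    matrix(0, nrow(flat), ncell)
  } else if (shift_level == "cell") {
    cell_par("s_cell")
  } else {
    smu <- flat[, paste0("s_mu[", seq_len(prep$n_participants), "]"),
                drop = FALSE]
    smu[, cells$pid, drop = FALSE]
  }
  w_draws <- se_draws^2 / (se_draws^2 + sp_draws^2)

  cell_summary <- cells |>
    dplyr::select("participant_id", "effort", "reward", "cell") |>
    dplyr::mutate(
      sigma_prior = colMeans(sp_draws),
      sigma_prior_sd = apply(sp_draws, 2, stats::sd),
      sigma_evidence = colMeans(se_draws),
      sigma_evidence_sd = apply(se_draws, 2, stats::sd),
      shift_s = colMeans(s_draws),
      shift_s_sd = apply(s_draws, 2, stats::sd),
      weight_w = colMeans(w_draws))
  participant_summary <- cell_summary |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(sigma_prior = mean(.data$sigma_prior),
                     sigma_evidence = mean(.data$sigma_evidence),
                     shift_s = mean(.data$shift_s),
                     weight_w = mean(.data$weight_w), .groups = "drop")

  # pointwise log-likelihood, draws x trials
  est <- prep$est
  sd_fun <- switch(likelihood,
                   sensory = function(w, se) (1 - w) * se,
                   posterior = function(w, se) sqrt(1 - w) * se)
  jj <- est$cell
  mu_p <- prep$mu_prior
  ll <- matrix(NA_real_, nrow(flat), nrow(est))
  for (m in seq_len(nrow(flat))) {
    wv <- w_draws[m, jj]
    mu <- wv * mu_p + (1 - wv) * (est$x_true + s_draws[m, jj])
    ll[m, ] <- stats::dnorm(est$x_estimate, mu,
                            sd_fun(w_draws[m, jj], se_draws[m, jj]),
                            log = TRUE)
  }

  structure(
    list(variant = variant, shift_level = shift_level,
         likelihood = likelihood, draws = arr,
         rhat = tibble::tibble(parameter = par_names, rhat = unname(rhat)),
         cells = cell_summary, participants = participant_summary,
         loglik = ll, data = est, mu_prior = mu_p,
         participant_ids = prep$participant_ids, settings = settings),
    class = "ap_observer_fit"
  )
}

coda_to_array <- function(samp) {
  mats <- lapply(samp, as.matrix)
  array(unlist(mats),
        dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats))) |>
    aperm(c(1, 3, 2)) -> arr
  dimnames(arr) <- list(NULL, NULL, colnames(mats[[1]]))
  arr
}

#' @export
print.ap_observer_fit <- function(x, ...) {
  cat(sprintf("<ap_observer_fit> variant %s (%s likelihood)\n",
              x$variant, x$likelihood))
  cat(sprintf("  %d participants, %d estimation trials; %d chains x %d draws\n",
              length(x$participant_ids), nrow(x$data),
              x$settings$chains, x$settings$draws))
  cat(sprintf("  max split R-hat = %.4f; mean weighting w = %.2f\n",
              max(x$rhat$rhat), mean(x$cells$weight_w)))
  invisible(x)
}

#' Widely applicable information criterion
#'
#' `waic = -2 * (lppd - p_waic)` from a pointwise log-likelihood matrix:
#' `lppd` is the summed log of draw-averaged pointwise likelihoods
#' (log-sum-exp stabilised) and `p_waic` the summed posterior variance of
#' the pointwise log-likelihood.
#'
#' @param x An `ap_observer_fit` or a draws-by-observations log-likelihood
#'   matrix.
#' @return A list of class `ap_waic`: `waic`, `p_waic`, `lppd`, and a
#'   `pointwise` tibble (`lppd`, `p_waic`, `elpd`).
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "ap_observer_fit")) x$loglik else as.matrix(x)
  if (length(ll) == 0) stop("empty log-likelihood matrix", call. = FALSE)
  if (any(!is.finite(ll))) stop("non-finite log-likelihood values", call. = FALSE)
  s <- nrow(ll)
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- if (s == 1) rep(0, ncol(ll)) else apply(ll, 2, stats::var)
  structure(
    list(waic = -2 * (sum(lppd_i) - sum(p_i)),
         p_waic = sum(p_i), lppd = sum(lppd_i),
         pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i,
                                    elpd = lppd_i - p_i)),
    class = "ap_waic")
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' @export
print.ap_waic <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (p_waic = %.1f, lppd = %.1f)\n",
              x$waic, x$p_waic, x$lppd))
  invisible(x)
}

#' Compare observer models by WAIC
#'
#' Pairwise WAIC differences with standard errors computed from the
#' pointwise contributions: `SE = sd(pointwise differences) * sqrt(n)`.
#' All fits must be on the identical trial set.
#'
#' @param fits A named list of `ap_observer_fit` objects.
#' @return A list of class `ap_model_comparison`: `table` (per model:
#'   `model`, `waic`, `p_waic`, `delta_waic` to the best),
#'   `pairs` (per pair: `model_a`, `model_b`, `delta_waic`,
#'   `se_delta_waic`), and `best`.
#' @export
compare_waic <- function(fits) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$variant, "")
  }
  key <- lapply(fits, function(f)
    paste(f$data$participant_id, f$data$block, f$data$trial_in_block))
  if (!all(vapply(key, identical, TRUE, key[[1]]))) {
    stop("fits are not on identical trial sets", call. = FALSE)
  }
  ws <- lapply(fits, waic)
  tab <- tibble::tibble(
    model = names(fits),
    waic = vapply(ws, function(w) w$waic, 0),
    p_waic = vapply(ws, function(w) w$p_waic, 0))
  tab$delta_waic <- tab$waic - min(tab$waic)
  pairs <- tidyr::expand_grid(model_a = names(fits), model_b = names(fits)) |>
    dplyr::filter(.data$model_a != .data$model_b)
  pairs <- dplyr::bind_cols(pairs, purrr::map2_dfr(
    pairs$model_a, pairs$model_b, function(a, b) {
      da <- -2 * ws[[a]]$pointwise$elpd
      db <- -2 * ws[[b]]$pointwise$elpd
      tibble::tibble(delta_waic = sum(da) - sum(db),
                     se_delta_waic = stats::sd(da - db) * sqrt(length(da)))
    }))
  structure(list(table = dplyr::arrange(tab, .data$waic), pairs = pairs,
                 best = tab$model[which.min(tab$waic)]),
            class = "ap_model_comparison")
}

#' @export
print.ap_model_comparison <- function(x, ...) {
  cat(sprintf("<ap_model_comparison> best: %s\n", x$best))
  print(x$table)
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates replicated estimate sets from `n_rep` posterior draws and
#' summarises how well the central predictive intervals cover the observed
#' estimates, pooled and per condition.
#'
#' @param fit An `ap_observer_fit`.
#' @param n_rep Number of posterior draws to replicate from.
#' @param seed Integer seed.
#' @param prob Central interval probability (default 0.95).
#' @return A list of class `ap_ppc`: `replicates` (n_rep x trials matrix),
#'   `coverage` (tibble per condition plus `pooled`), and `prob`.
#' @export
posterior_predictive <- function(fit, n_rep = 200, seed = 1L, prob = 0.95) {
  stopifnot(inherits(fit, "ap_observer_fit"))
  est <- fit$data
  flatdim <- dim(fit$draws)
  n_draws <- flatdim[1] * flatdim[2]
  sp <- cell_draw_matrix(fit, "sigma_prior")
  se <- cell_draw_matrix(fit, "sigma_evidence")
  sv <- cell_draw_matrix(fit, "shift_s")
  w <- se^2 / (se^2 + sp^2)
  jj <- est$cell
  sd_fun <- switch(fit$likelihood,
                   sensory = function(w, s) (1 - w) * s,
                   posterior = function(w, s) sqrt(1 - w) * s)
  withr::with_seed(seed, {
    take <- sample.int(n_draws, n_rep, replace = n_rep > n_draws)
    reps <- matrix(NA_real_, n_rep, nrow(est))
    for (r in seq_len(n_rep)) {
      m <- take[r]
      wv <- w[m, jj]
      mu <- wv * fit$mu_prior + (1 - wv) * (est$x_true + sv[m, jj])
      reps[r, ] <- stats::rnorm(nrow(est), mu, sd_fun(wv, se[m, jj]))
    }
  })
  alpha <- (1 - prob) / 2
  lo <- apply(reps, 2, stats::quantile, probs = alpha)
  hi <- apply(reps, 2, stats::quantile, probs = 1 - alpha)
  inside <- est$x_estimate >= lo & est$x_estimate <= hi
  per_cond <- tibble::tibble(effort = est$effort, reward = est$reward,
                             inside = inside) |>
    dplyr::group_by(.data$effort, .data$reward) |>
    dplyr::summarise(coverage = mean(.data$inside), n = dplyr::n(),
                     .groups = "drop")
  pooled <- tibble::tibble(effort = "pooled", reward = "pooled",
                           coverage = mean(inside), n = length(inside))
  structure(list(replicates = reps,
                 coverage = dplyr::bind_rows(per_cond, pooled),
                 prob = prob),
            class = "ap_ppc")
}

# draws x cell matrices on the natural parameter scale
cell_draw_matrix <- function(fit, what) {
  arr <- fit$draws
  flat <- apply(arr, 3, identity)
  par_names <- dimnames(arr)[[3]]
  ncell <- nrow(fit$cells)
  pick <- function(base) {
    cols <- paste0(base, "[", seq_len(ncell), "]")
    if (all(cols %in% par_names)) flat[, cols, drop = FALSE] else NULL
  }
  switch(what,
    sigma_prior = {
      x <- pick("log_sp")
      if (is.null(x)) {
        matrix(rep(fit$cells$sigma_prior, each = nrow(flat)), nrow(flat))
      } else exp(x)
    },
    sigma_evidence = exp(pick("log_se")),
    shift_s = {
      if (fit$variant != "m2") return(matrix(0, nrow(flat), ncell))
      x <- pick("s_cell")
      if (is.null(x)) {
        smu <- flat[, paste0("s_mu[", seq_along(fit$participant_ids), "]"),
                    drop = FALSE]
        x <- smu[, match(fit$cells$participant_id, fit$participant_ids),
                 drop = FALSE]
      }
      x
    })
}

#' Extract posterior prior-SD estimates
#'
#' @param fit An `ap_observer_fit`.
#' @param level `"participant"` (mean over conditions) or `"cell"`.
#' @return A tibble with ids and posterior-mean `sigma_prior`.
#' @export
extract_prior_sd <- function(fit, level = c("participant", "cell")) {
  stopifnot(inherits(fit, "ap_observer_fit"))
  level <- match.arg(level)
  if (level == "participant") {
    fit$participants[, c("participant_id", "sigma_prior")]
  } else {
    fit$cells[, c("participant_id", "effort", "reward", "sigma_prior")]
  }
}

#' Normalize prior SD by performance SD
#'
#' The scale-free index `sigma_prior / (sigma_prior + perf_sd)`, in
#' `[0, 1)`; values below 0.5 mean the prior is narrower than the true
#' performance distribution.
#'
#' @param sigma_prior Prior SD(s), >= 0.
#' @param perf_sd Performance SD(s), > 0.
#' @return The normalized ratio.
#' @examples
#' normalized_prior_sd(10, 20)  # 1/3
#' @export
normalized_prior_sd <- function(sigma_prior, perf_sd) {
  if (any(perf_sd <= 0)) stop("perf_sd must be positive", call. = FALSE)
  if (any(sigma_prior < 0)) stop("sigma_prior must be non-negative", call. = FALSE)
  sigma_prior / (sigma_prior + perf_sd)
}

#' Score parameter recovery against ground truth
#'
#' Correlates posterior means with the generating values across
#' participants (and cells) and reports RMSEs, with pass/fail against
#' documented thresholds.
#'
#' @param truth An [sample_cohort()] object.
#' @param fit An `ap_observer_fit` on data simulated from `truth`.
#' @param thresholds Named correlation thresholds.
#' @return A tibble of class `ap_recovery`: `parameter`, `level`,
#'   `correlation`, `rmse`, `threshold`, `pass`.
#' @export
parameter_recovery <- function(truth, fit,
                               thresholds = c(sigma_prior = 0.7,
                                              sigma_evidence = 0.7,
                                              shift_s = 0.5)) {
  stopifnot(inherits(truth, "ap_cohort_truth"),
            inherits(fit, "ap_observer_fit"))
  tp <- truth$participants
  if (!all(fit$participants$participant_id %in% tp$participant_id)) {
    stop("fit contains participant ids absent from the ground truth",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(
    fit$participants, tp,
    by = "participant_id", suffix = c("_hat", "_true"))
  row <- function(parameter, est, tru) {
    thr <- unname(thresholds[parameter])
    cc <- stats::cor(est, tru)
    tibble::tibble(parameter = parameter, level = "participant",
                   correlation = cc,
                   rmse = sqrt(mean((est - tru)^2)),
                   threshold = thr,
                   pass = !is.na(cc) & cc >= thr)
  }
  out <- dplyr::bind_rows(
    row("sigma_prior", joined$sigma_prior, joined$mean_sigma_prior),
    row("sigma_evidence", joined$sigma_evidence, joined$mean_sigma_evidence),
    if (fit$variant == "m2")
      row("shift_s", joined$shift_s, joined$mean_shift_s))
  class(out) <- c("ap_recovery", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
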