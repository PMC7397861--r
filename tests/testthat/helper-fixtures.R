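# shared fixtures, all generated in code

# compact task: 8 blocks x 27 trials, 10 estimation per block
# (80 estimation trials = 20 per condition per participant)
small_task <- function() {
  task_config(blocks_per_condition = 2, n_blocks = 8,
              estimation_per_block = 10, basic_per_block = 17)
}

# cohort settings with every cell's weighting w fixed exactly
fixed_w_settings <- function(w, sigma_prior = 40, shift = 0) {
  cohort_settings(
    sigma_prior_px = sigma_prior,
    sigma_evidence_px = sigma_prior * sqrt(w / (1 - w)),
    sigma_prior_log_sd = 0, sigma_prior_perf_link = 0,
    sigma_prior_effort_shift = 0, sigma_prior_reward_shift = 0,
    sigma_prior_cell_log_sd = 0,
    sigma_evidence_log_sd = 0, sigma_evidence_cell_log_sd = 0,
    shift_mean_px = shift, shift_sd_px = 0, shift_cell_sd_px = 0)
}

small_cohort_trials <- function(n = 6, seed = 42, settings = cohort_settings()) {
  truth <- sample_cohort(n, small_task(), seed = seed, settings = settings)
  trials <- simulate_trials(truth, seed = seed + 1)
  list(truth = truth, trials = trials)
}

# one tiny observer fit shared across observer tests
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- small_cohort_trials(4, seed = 11)
      cache <<- fit_observer(dat$trials, "m2", chains = 2, draws = 150,
                             warmup = 250, adapt = 250, thin = 1, seed = 11)
    }
    cache
  }
})

# small estimation-trial table with exactly prescribed estimates
degenerate_trials <- function(n_participants = 4, n_trials = 60,
                              estimate = c("target", "true"), seed = 1) {
  estimate <- match.arg(estimate)
  set.seed(seed)
  base <- tidyr::expand_grid(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    effort = c("low", "high"), reward = c("no", "yes"))
  trials <- tidyr::uncount(base, n_trials / 4)
  trials$block <- 1L
  trials$trial_in_block <- seq_len(nrow(trials))
  trials$trial_type <- "estimation"
  trials$x_target <- ifelse(trials$effort == "high", 896, 512)
  trials$x_true <- trials$x_target + rnorm(nrow(trials), 0, 100)
  trials$x_estimate <- switch(estimate,
                              target = trials$x_target,
                              true = trials$x_true)
  trials$performance_error <- trials$x_true - trials$x_target
  trials$estimation_error <- trials$x_estimate - trials$x_true
  trials$force_response <- 0.5
  trials$force_error <- 0
  trials
}

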