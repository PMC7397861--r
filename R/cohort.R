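#' Default generative settings for synthetic cohorts
#'
#' Population hyperparameters of the synthetic cohort generator. Values are
#' chosen to emulate the qualitative structure of the task data the pipeline
#' is designed for: participants undershoot the far target and are more
#' variable under high effort, reward tightens performance, prior SDs are
#' markedly smaller than performance SDs and correlated with them, the group
#' mean weighting w is about 0.7, and a leftward sensory shift of a few
#' pixels is present.
#'
#' @param sigma_prior_px Group median prior SD (pixels).
#' @param sigma_prior_log_sd Between-participant SD of log prior SD.
#' @param sigma_prior_perf_link Loading of log prior SD on the standardized
#'   participant log performance variability (induces the prior-SD /
#'   performance-SD correlation).
#' @param sigma_prior_effort_shift,sigma_prior_reward_shift Additive shifts
#'   of log prior SD under high effort / reward.
#' @param sigma_prior_cell_log_sd Within-participant (condition-level) SD of
#'   log prior SD.
#' @param sigma_evidence_px,sigma_evidence_log_sd,sigma_evidence_cell_log_sd
#'   Same structure for the sensory-evidence SD.
#' @param shift_mean_px,shift_sd_px Population mean and SD of the
#'   participant-level sensory shift (pixels; negative = leftward).
#' @param shift_cell_sd_px Condition-level jitter of the shift.
#' @param perf_sd_pct Group median performance SD, % of maximum force.
#' @param perf_sd_log_sd Between-participant SD of log performance SD.
#' @param perf_sd_effort_mult,perf_sd_reward_mult Multipliers on performance
#'   SD under high effort / reward.
#' @param perf_bias_low_pct,perf_bias_high_pct Mean force error (% max
#'   force) in the low/high effort conditions; high effort undershoots.
#' @param perf_bias_reward_mult Multiplier shrinking the bias under reward.
#' @param perf_bias_subj_sd Between-participant SD of the bias offset.
#' @param max_force_mean_n,max_force_sd_n Maximum voluntary force (newtons).
#' @param trait_link_rho Target partial correlation between participant mean
#'   prior SD and the behavioural-activation apathy score, adjusting for
#'   performance variability.
#' @return A named list of generative settings.
#' @export
cohort_settings <- function(sigma_prior_px = 40,
                            sigma_prior_log_sd = 0.30,
                            sigma_prior_perf_link = 0.45,
                            sigma_prior_effort_shift = 0.12,
                            sigma_prior_reward_shift = 0.08,
                            sigma_prior_cell_log_sd = 0.15,
                            sigma_evidence_px = 65,
                            sigma_evidence_log_sd = 0.25,
                            sigma_evidence_cell_log_sd = 0.12,
                            shift_mean_px = -15,
                            shift_sd_px = 8,
                            shift_cell_sd_px = 4,
                            perf_sd_pct = 5,
                            perf_sd_log_sd = 0.25,
                            perf_sd_effort_mult = 1.5,
                            perf_sd_reward_mult = 0.9,
                            perf_bias_low_pct = -0.5,
                            perf_bias_high_pct = -3,
                            perf_bias_reward_mult = 0.7,
                            perf_bias_subj_sd = 1,
                            max_force_mean_n = 60,
                            max_force_sd_n = 12,
                            trait_link_rho = 0.37) {
  as.list(environment())
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws participant- and condition-level generative parameters from
#' group-level distributions (see [cohort_settings()]): observer parameters
#' (prior SD, evidence SD, sensory shift), performance bias and variability
#' per condition, maximum force, and trait apathy scores linked to the
#' participant-mean prior SD via [link_trait()].
#'
#' @param n_participants Number of participants (>= 2).
#' @param config An [task_config()] object.
#' @param seed Integer seed.
#' @param settings A [cohort_settings()] list.
#' @return An object of class `ap_cohort_truth`: a list with
#'   `participants` (one row per participant: `participant_id`, `max_force`,
#'   AMI scores, participant-level parameter means), `cells` (one row per
#'   participant x condition: `sigma_prior`, `sigma_evidence`, `shift_s`,
#'   `mu_prior`, `weight_w`, `perf_bias_pct`, `perf_sd_pct`), the `settings`,
#'   and the `config`.
#' @export
sample_cohort <- function(n_participants = 47, config = task_config(),
                          seed = 1L, settings = cohort_settings()) {
  if (n_participants < 2) stop("need at least 2 participants", call. = FALSE)
  validate_task_config(config)
  s <- settings
  withr::with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_participants))
    max_force <- pmax(20, stats::rnorm(n_participants, s$max_force_mean_n,
                                       s$max_force_sd_n))
    # participant performance variability drives the prior-SD correlation
    z_var <- stats::rnorm(n_participants)
    log_perf_sd <- log(s$perf_sd_pct) + s$perf_sd_log_sd * z_var
    lp_mu <- log(s$sigma_prior_px) + s$sigma_prior_perf_link * z_var +
      stats::rnorm(n_participants, 0, s$sigma_prior_log_sd)
    le_mu <- log(s$sigma_evidence_px) +
      stats::rnorm(n_participants, 0, s$sigma_evidence_log_sd)
    s_mu <- stats::rnorm(n_participants, s$shift_mean_px, s$shift_sd_px)
    bias_off <- stats::rnorm(n_participants, 0, s$perf_bias_subj_sd)

    cells <- tidyr::expand_grid(
      participant_id = ids,
      effort = c("low", "high"),
      reward = c("no", "yes")
    )
    i <- match(cells$participant_id, ids)
    hi <- cells$effort == "high"
    rw <- cells$reward == "yes"
    cells$sigma_prior <- exp(lp_mu[i] +
                               s$sigma_prior_effort_shift * hi +
                               s$sigma_prior_reward_shift * rw +
                               stats::rnorm(nrow(cells), 0, s$sigma_prior_cell_log_sd))
    cells$sigma_evidence <- exp(le_mu[i] +
                                  stats::rnorm(nrow(cells), 0, s$sigma_evidence_cell_log_sd))
    cells$shift_s <- s_mu[i] + stats::rnorm(nrow(cells), 0, s$shift_cell_sd_px)
    cells$mu_prior <- target_position(cells$effort, config)
    cells$weight_w <- cells$sigma_evidence^2 /
      (cells$sigma_evidence^2 + cells$sigma_prior^2)
    cells$perf_bias_pct <- (ifelse(hi, s$perf_bias_high_pct, s$perf_bias_low_pct) +
                              bias_off[i]) *
      ifelse(rw, s$perf_bias_reward_mult, 1)
    cells$perf_sd_pct <- exp(log_perf_sd[i]) *
      ifelse(hi, s$perf_sd_effort_mult, 1) *
      ifelse(rw, s$perf_sd_reward_mult, 1)

    participants <- tibble::tibble(
      participant_id = ids,
      max_force = max_force,
      mean_sigma_prior = exp(lp_mu),
      mean_sigma_evidence = exp(le_mu),
      mean_shift_s = s_mu,
      mean_perf_sd_pct = exp(log_perf_sd)
    )
    ami <- link_trait(participants$mean_sigma_prior,
                      participants$mean_perf_sd_pct,
                      rho = s$trait_link_rho,
                      seed = sample.int(2^30, 1))
  })
  participants <- dplyr::bind_cols(participants, ami)
  structure(
    list(participants = participants, cells = cells,
         settings = s, config = config),
    class = "ap_cohort_truth"
  )
}

#' @export
print.ap_cohort_truth <- function(x, ...) {
  cat(sprintf("<ap_cohort_truth> %d participants x %d conditions\n",
              nrow(x$participants), 4L))
  cat(sprintf("  group mean weighting w = %.2f; trait link rho = %.2f\n",
              mean(x$cells$weight_w), x$settings$trait_link_rho))
  invisible(x)
}

#' Construct trait apathy scores linked to prior precision
#'
#' Builds Apathy Motivation Index subscale means (each the mean of six
#' 0-4 items; the total is the mean of all 18 items) so that the
#' behavioural-activation subscale has a target partial correlation `rho`
#' with the participants' prior SDs, adjusting for performance variability.
#' The other two subscales are independent noise.
#'
#' @param sigma_priors Participant-level prior SDs.
#' @param performance_sds Participant-level performance variabilities (the
#'   adjustment variable).
#' @param rho Target partial correlation, in (-1, 1).
#' @param seed Integer seed.
#' @param ba_mean,ba_sd Location and scale of the behavioural-activation
#'   scores before clipping into \[0, 4\].
#' @return A tibble with columns `ami_ba`, `ami_es`, `ami_sm`, `ami_total`.
#' @export
link_trait <- function(sigma_priors, performance_sds, rho = 0.37, seed = 1L,
                       ba_mean = 1.9, ba_sd = 0.65) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  n <- length(sigma_priors)
  stopifnot(length(performance_sds) == n, n >= 2)
  withr::with_seed(seed, {
    rx <- stats::residuals(stats::lm(sigma_priors ~ performance_sds))
    rx <- as.numeric(scale(rx))
    ba_std <- rho * rx + sqrt(1 - rho^2) * stats::rnorm(n)
    ba <- clip04(ba_mean + ba_sd * ba_std)
    es <- clip04(stats::rnorm(n, 1.6, 0.6))
    sm <- clip04(stats::rnorm(n, 1.7, 0.6))
  })
  tibble::tibble(ami_ba = ba, ami_es = es, ami_sm = sm,
                 ami_total = (ba + es + sm) / 3)
}

clip04 <- function(x) pmin(4, pmax(0, x))

#' Simulate trial-level data for a cohort
#'
#' For every participant the schedule is replayed: the force response is
#' drawn as `nominal force + Normal(bias, performance SD)` (in % of maximum
#' force) and mapped through [force_to_position()]. On estimation trials a
#' sensory sample `x_s ~ Normal(x_true + s, sigma_evidence)` is drawn and
#' the reported estimate is the precision-weighted combination
#' `w * mu_prior + (1 - w) * x_s`.
#'
#' @param truth An [sample_cohort()] object.
#' @param schedule A schedule from [generate_schedule()] (without
#'   participant ids; it is replicated per participant). If `NULL`, a fresh
#'   schedule is generated per participant from derived seeds.
#' @param seed Integer seed.
#' @return A tibble in the canonical trial format: `participant_id`,
#'   `block`, `trial_in_block`, `effort`, `reward`, `trial_type`,
#'   `force_response`, `force_error`, `x_true`, `x_target`,
#'   `performance_error`, `x_estimate`, `estimation_error`.
#' @export
simulate_trials <- function(truth, schedule = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ap_cohort_truth"))
  cfg <- truth$config
  ids <- truth$participants$participant_id
  trials <- withr::with_seed(seed, {
    purrr::map_dfr(seq_along(ids), function(i) {
      sch <- if (is.null(schedule)) {
        generate_schedule(cfg, seed = sample.int(2^30, 1),
                          participant_id = ids[i])
      } else {
        dplyr::mutate(schedule, participant_id = ids[i])
      }
      simulate_participant(sch, ids[i], truth, cfg)
    })
  })
  trials
}

simulate_participant <- function(sch, id, truth, cfg) {
  cells <- dplyr::filter(truth$cells, .data$participant_id == id)
  key <- match(paste(sch$effort, sch$reward),
               paste(cells$effort, cells$reward))
  f_nom <- nominal_force(sch$effort, cfg)
  f_resp <- f_nom + (cells$perf_bias_pct[key] +
                       stats::rnorm(nrow(sch), 0, cells$perf_sd_pct[key])) / 100
  f_resp <- pmax(f_resp, 0)
  x_true <- force_to_position(f_resp, sch$effort, cfg)
  x_target <- target_position(sch$effort, cfg)
  est <- sch$trial_type == "estimation"
  x_estimate <- rep(NA_real_, nrow(sch))
  if (any(est)) {
    k <- key[est]
    x_s <- stats::rnorm(sum(est), x_true[est] + cells$shift_s[k],
                        cells$sigma_evidence[k])
    x_estimate[est] <- cells$weight_w[k] * cells$mu_prior[k] +
      (1 - cells$weight_w[k]) * x_s
  }
  tibble::tibble(
    participant_id = id,
    block = sch$block,
    trial_in_block = sch$trial_in_block,
    effort = sch$effort,
    reward = sch$reward,
    trial_type = sch$trial_type,
    force_response = f_resp,
    force_error = 100 * (f_resp - f_nom),
    x_true = x_true,
    x_target = x_target,
    performance_error = x_true - x_target,
    x_estimate = x_estimate,
    estimation_error = x_estimate - x_true
  )
}

#' Read and write the canonical trial and participant tables
#'
#' The canonical trial CSV has exactly the columns produced by
#' [simulate_trials()]; readers reject unknown schemas loudly. The
#' participants CSV carries `participant_id`, `max_force` and the four AMI
#' scores. Ground truth serializes to a JSON sidecar for recovery scoring.
#'
#' @param trials,participants,truth Objects to write.
#' @param path File path.
#' @return Readers return tibbles (or an `ap_cohort_truth`); writers return
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trial_columns(names(trials))
  readr::write_csv(trials[, trial_columns()], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = trial_col_types())
  check_trial_columns(names(trials))
  trials
}

#' @rdname write_trials
#' @export
write_participants <- function(participants, path) {
  cols <- c("participant_id", "max_force", "ami_ba", "ami_es", "ami_sm",
            "ami_total")
  stopifnot(all(cols %in% names(participants)))
  readr::write_csv(participants[, cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_participants <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_trials
#' @export
write_cohort_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ap_cohort_truth"))
  jsonlite::write_json(
    list(participants = truth$participants, cells = truth$cells,
         settings = truth$settings, config = unclass(truth$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_cohort_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(participants = tibble::as_tibble(raw$participants),
         cells = tibble::as_tibble(raw$cells),
         settings = raw$settings,
         config = do.call(task_config, raw$config[names(formals(task_config))])),
    class = "ap_cohort_truth"
  )
}

trial_columns <- function() {
  c("participant_id", "block", "trial_in_block", "effort", "reward",
    "trial_type", "force_response", "force_error", "x_true", "x_target",
    "performance_error", "x_estimate", "estimation_error")
}

trial_col_types <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    block = readr::col_integer(),
    trial_in_block = readr::col_integer(),
    effort = readr::col_character(),
    reward = readr::col_character(),
    trial_type = readr::col_character(),
    .default = readr::col_double()
  )
}

check_trial_columns <- function(nms) {
  missing <- setdiff(trial_columns(), nms)
  extra <- setdiff(nms, trial_columns())
  if (length(missing) > 0 || length(extra) > 0) {
    stop("trial table does not match the canonical schema",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  invisible(nms)
}
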