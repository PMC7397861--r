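#' Task configuration
#'
#' Geometry, physics and scheduling constants of the force-aiming task. A
#' ball starts near the left screen margin and travels rightward with an
#' initial velocity proportional to the applied force; a constant per-effort
#' deceleration brings it to rest, so the force response uniquely determines
#' the final position. Targets sit close (low effort) or far (high effort)
#' from the start, placed so that the nominal effort force (35% or 65% of a
#' participant's maximum) lands exactly on the target centre.
#'
#' @param screen_width_px Screen width in pixels.
#' @param start_x_px Ball start position (x, pixels).
#' @param close_target_x_px,far_target_x_px Target centres for the low- and
#'   high-effort conditions (pixels from the left margin).
#' @param ball_radius_px,target_radius_px Radii in pixels (display only; the
#'   physics uses centre positions).
#' @param velocity_per_quarter_maxforce Initial speed, as a fraction of
#'   screen width per second, produced by pressing at 25% of maximum force
#'   (before `force_scale`).
#' @param force_scale Multiplier applied to the force before the
#'   force-to-velocity conversion.
#' @param effort_fractions Named list, nominal force (fraction of maximum)
#'   that lands on the target in each effort condition.
#' @param reward_max Maximum payout per rewarded trial (pounds).
#' @param reward_zero_distance Named list, fraction of screen width at which
#'   the linear payout reaches zero, per effort condition.
#' @param n_blocks,trials_per_block,basic_per_block,estimation_per_block,blocks_per_condition
#'   Trial scheduling counts.
#' @param sampling_rate_hz Force-sensor sampling rate.
#'
#' @return An object of class `ap_task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$far_target_x_px
#' @export
task_config <- function(screen_width_px = 1280,
                        start_x_px = 128,
                        close_target_x_px = 512,
                        far_target_x_px = 896,
                        ball_radius_px = 32,
                        target_radius_px = 38,
                        velocity_per_quarter_maxforce = 0.30,
                        force_scale = 0.5,
                        effort_fractions = list(low = 0.35, high = 0.65),
                        reward_max = 1,
                        reward_zero_distance = list(low = 0.15, high = 0.30),
                        n_blocks = 40,
                        trials_per_block = 27,
                        basic_per_block = 19,
                        estimation_per_block = 8,
                        blocks_per_condition = 10,
                        sampling_rate_hz = 60) {
  cfg <- structure(
    list(
      screen_width_px = screen_width_px,
      start_x_px = start_x_px,
      close_target_x_px = close_target_x_px,
      far_target_x_px = far_target_x_px,
      ball_radius_px = ball_radius_px,
      target_radius_px = target_radius_px,
      velocity_per_quarter_maxforce = velocity_per_quarter_maxforce,
      force_scale = force_scale,
      effort_fractions = effort_fractions,
      reward_max = reward_max,
      reward_zero_distance = reward_zero_distance,
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      basic_per_block = basic_per_block,
      estimation_per_block = estimation_per_block,
      blocks_per_condition = blocks_per_condition,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "ap_task_config"
  )
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "ap_task_config"))
  if (cfg$basic_per_block + cfg$estimation_per_block != cfg$trials_per_block) {
    stop("basic_per_block + estimation_per_block must equal trials_per_block",
         call. = FALSE)
  }
  if (cfg$n_blocks != 4L * cfg$blocks_per_condition) {
    stop("n_blocks must equal 4 * blocks_per_condition", call. = FALSE)
  }
  if (!(cfg$start_x_px < cfg$close_target_x_px &&
        cfg$close_target_x_px < cfg$far_target_x_px &&
        cfg$far_target_x_px < cfg$screen_width_px)) {
    stop("positions must satisfy start < close target < far target < screen width",
         call. = FALSE)
  }
  for (nm in c("low", "high")) {
    if (is.null(cfg$effort_fractions[[nm]]) ||
        is.null(cfg$reward_zero_distance[[nm]])) {
      stop("effort_fractions and reward_zero_distance need 'low' and 'high' entries",
           call. = FALSE)
    }
  }
  cfg
}

#' @export
print.ap_task_config <- function(x, ...) {
  cat("<ap_task_config>\n")
  cat(sprintf("  screen %d px; start %g px; targets %g / %g px\n",
              x$screen_width_px, x$start_x_px,
              x$close_target_x_px, x$far_target_x_px))
  cat(sprintf("  schedule: %d blocks x %d trials (%d basic + %d estimation)\n",
              x$n_blocks, x$trials_per_block,
              x$basic_per_block, x$estimation_per_block))
  invisible(x)
}

#' Read or write a task configuration file
#'
#' Configurations serialize as YAML (or JSON, which YAML parses); every
#' default of [task_config()] can be overridden in the file.
#'
#' @param path File path.
#' @return `read_task_config()` returns an `ap_task_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(task_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown task config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(task_config, raw)
}

#' @rdname read_task_config
#' @param config An `ap_task_config`.
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

target_position <- function(effort, config) {
  ifelse(effort == "high", config$far_target_x_px, config$close_target_x_px)
}

nominal_force <- function(effort, config) {
  ifelse(effort == "high",
         config$effort_fractions$high,
         config$effort_fractions$low)
}
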