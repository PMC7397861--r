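#' Map a force response to the ball's final position
#'
#' The initial velocity is `(force_scale * force / 0.25) *
#' velocity_per_quarter_maxforce * screen_width` px/s, and the ball
#' decelerates at a constant per-effort rate, so the final position is
#' `start + v^2 / (2 a)`. The deceleration for each effort level is
#' calibrated so that the nominal effort force (35% or 65% of maximum)
#' stops exactly on the corresponding target centre; positions are clipped
#' to the screen.
#'
#' @param force_fraction Applied force as a fraction of maximum force
#'   (vectorised, must be >= 0).
#' @param effort `"low"` or `"high"` (vectorised, recycled against
#'   `force_fraction`).
#' @param config An [task_config()] object.
#' @return Final x position(s) in pixels.
#' @examples
#' force_to_position(0.35, "low")   # lands on the close target (512)
#' force_to_position(0.65, "high")  # lands on the far target (896)
#' @export
force_to_position <- function(force_fraction, effort, config = task_config()) {
  validate_task_config(config)
  if (any(force_fraction < 0)) {
    stop("force_fraction must be non-negative", call. = FALSE)
  }
  effort <- match_effort(effort)
  v <- initial_velocity(force_fraction, config)
  a <- deceleration(effort, config)
  x <- config$start_x_px + v^2 / (2 * a)
  pmin(pmax(x, config$start_x_px), config$screen_width_px)
}

#' Invert the force-to-position map
#'
#' @inheritParams force_to_position
#' @param x_px Final position(s) in pixels, within
#'   `[start_x_px, screen_width_px]`.
#' @return Force fraction(s) of maximum force.
#' @export
position_to_force <- function(x_px, effort, config = task_config()) {
  validate_task_config(config)
  if (any(x_px < config$start_x_px | x_px > config$screen_width_px)) {
    stop("x_px outside [start_x_px, screen_width_px]", call. = FALSE)
  }
  effort <- match_effort(effort)
  a <- deceleration(effort, config)
  v <- sqrt(2 * a * (x_px - config$start_x_px))
  v / (config$force_scale / 0.25 * config$velocity_per_quarter_maxforce *
         config$screen_width_px)
}

# px/s for a given force fraction
initial_velocity <- function(force_fraction, config) {
  (config$force_scale * force_fraction / 0.25) *
    config$velocity_per_quarter_maxforce * config$screen_width_px
}

# constant deceleration (px/s^2) calibrated per effort level so the nominal
# force lands on the target centre
deceleration <- function(effort, config) {
  f_nom <- nominal_force(effort, config)
  v_nom <- initial_velocity(f_nom, config)
  dist <- target_position(effort, config) - config$start_x_px
  v_nom^2 / (2 * dist)
}

match_effort <- function(effort) {
  if (!all(effort %in% c("low", "high"))) {
    stop("effort must be 'low' or 'high'", call. = FALSE)
  }
  effort
}

#' Force trace container
#'
#' A fixed-rate recording from the force sensor.
#'
#' @param samples Numeric vector of force values in newtons, sampled at
#'   `rate_hz`; all values must be non-negative.
#' @param rate_hz Sampling rate (Hz).
#' @return An object of class `ap_force_trace`.
#' @export
force_trace <- function(samples, rate_hz = 60) {
  if (any(samples < 0)) stop("force samples must be >= 0", call. = FALSE)
  structure(
    list(samples = as.numeric(samples),
         rate_hz = rate_hz,
         duration_s = length(samples) / rate_hz),
    class = "ap_force_trace"
  )
}

#' Extract the force response from a trial recording
#'
#' The response is the mean force over the half-open window \[2.0 s, 2.5 s)
#' of the sustained press, expressed as a fraction of the participant's
#' maximum force.
#'
#' @param trace An [force_trace()] of at least 2.5 s.
#' @param max_force The participant's maximum force (newtons).
#' @return Force response as a fraction of maximum force.
#' @export
extract_force_response <- function(trace, max_force) {
  stopifnot(inherits(trace, "ap_force_trace"), max_force > 0)
  if (trace$duration_s < 2.5) {
    stop("force trace must be at least 2.5 s long", call. = FALSE)
  }
  i0 <- floor(2.0 * trace$rate_hz) + 1L
  i1 <- floor(2.5 * trace$rate_hz)      # half-open: [2.0, 2.5)
  mean(trace$samples[i0:i1]) / max_force
}

#' Calibrate a participant's maximum force
#'
#' Each of three 10-s maximal presses is summarised by the mean force over
#' the 5-s window with the lowest sample variance (sliding one sample at a
#' time); the participant's maximum force is the highest of the three
#' per-trial values.
#'
#' @param traces A list of exactly three [force_trace()] objects, each at
#'   least 10 s long.
#' @return Maximum force in newtons.
#' @export
calibrate_max_force <- function(traces) {
  if (length(traces) != 3 || !all(vapply(traces, inherits, TRUE, "ap_force_trace"))) {
    stop("calibration needs exactly three force traces", call. = FALSE)
  }
  if (any(vapply(traces, function(t) t$duration_s, 0) < 10)) {
    stop("calibration traces must be at least 10 s long", call. = FALSE)
  }
  max(vapply(traces, steadiest_window_mean, 0))
}

# mean of the minimum-variance 5-s window of one trace
steadiest_window_mean <- function(trace) {
  x <- trace$samples
  wlen <- as.integer(5 * trace$rate_hz)
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  starts <- 1:(n - wlen + 1)
  sums <- cs[starts + wlen] - cs[starts]
  sums2 <- cs2[starts + wlen] - cs2[starts]
  vars <- (sums2 - sums^2 / wlen) / (wlen - 1)
  best <- which.min(vars)
  sums[best] / wlen
}

#' Reward for a rewarded trial
#'
#' The payout is maximal for a perfect landing and decreases linearly with
#' absolute performance error, reaching zero at an effort-specific fraction
#' of the screen width (the payout criterion is laxer for the far target so
#' that reward and effort are not confounded). Never negative.
#'
#' @param performance_error Signed performance error(s) in pixels.
#' @inheritParams force_to_position
#' @return Reward in pounds.
#' @examples
#' reward_points(0, "low")    # 1
#' reward_points(96, "low")   # 0.5
#' @export
reward_points <- function(performance_error, effort, config = task_config()) {
  validate_task_config(config)
  effort <- match_effort(effort)
  zero_at <- ifelse(effort == "high",
                    config$reward_zero_distance$high,
                    config$reward_zero_distance$low) * config$screen_width_px
  pmax(0, config$reward_max * (1 - abs(performance_error) / zero_at))
}
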