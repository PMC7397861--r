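#' Participant-level task performance
#'
#' "Average task performance" for the exclusion rule: the participant's mean
#' absolute force error (% of maximum force) over all trials.
#'
#' @param trials Canonical trial tibble.
#' @return A tibble with `participant_id` and `performance`.
#' @export
participant_performance <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(performance = mean(abs(.data$force_error)),
                     .groups = "drop")
}

#' Exclude participants with aberrant performance
#'
#' A participant is excluded when their performance value deviates from the
#' group median by at least `k` times the scaled median absolute deviation
#' (MAD, consistency constant 1.4826). A zero group MAD disables the rule
#' with a warning.
#'
#' @param performance A tibble with `participant_id` and a `performance`
#'   column (see [participant_performance()]), or a bare numeric vector.
#' @param k MAD multiplier (default 3).
#' @return A tibble with `participant_id` (or index), `performance`, and
#'   logical `excluded`; the threshold is stored in attribute `"threshold"`.
#' @examples
#' exclude_participants(c(1, 2, 3, 4, 100))  # only 100 excluded
#' @export
exclude_participants <- function(performance, k = 3) {
  if (is.numeric(performance)) {
    performance <- tibble::tibble(
      participant_id = as.character(seq_along(performance)),
      performance = performance)
  }
  if (nrow(performance) < 3) stop("need at least 3 participants", call. = FALSE)
  med <- stats::median(performance$performance)
  m <- stats::mad(performance$performance)   # scaled, constant 1.4826
  if (m == 0) {
    warning("group MAD is zero; no participants excluded", call. = FALSE)
    out <- dplyr::mutate(performance, excluded = FALSE)
    attr(out, "threshold") <- Inf
    return(out)
  }
  out <- dplyr::mutate(performance,
                       excluded = abs(.data$performance - med) >= k * m)
  attr(out, "threshold") <- k * m
  if (any(out$excluded)) {
    message(sprintf("excluding %d participant(s): %s", sum(out$excluded),
                    paste(out$participant_id[out$excluded], collapse = ", ")))
  }
  out
}

#' Drop the first trial of every block
#'
#' Removes condition-switch effects: exactly one trial (within-block index
#' 1) per participant per block.
#'
#' @param trials Canonical trial tibble.
#' @return The filtered tibble.
#' @export
drop_first_trials <- function(trials) {
  dplyr::filter(trials, .data$trial_in_block != 1L)
}

#' Filter outlying force errors per participant and condition
#'
#' Within each participant-by-effort-by-reward cell, removes trials whose
#' force error lies more than `k` scaled MADs from the cell median. Cells
#' with zero MAD are left untouched with a warning.
#'
#' @param trials Canonical trial tibble.
#' @param k MAD multiplier (default 3).
#' @return The filtered tibble; removal counts per cell are stored in
#'   attribute `"removed"` (a tibble).
#' @export
mad_filter_force_errors <- function(trials, k = 3) {
  grouped <- dplyr::group_by(trials, .data$participant_id, .data$effort,
                             .data$reward)
  flagged <- dplyr::mutate(
    grouped,
    .cell_mad = stats::mad(.data$force_error),
    .out = abs(.data$force_error - stats::median(.data$force_error)) >
      k * .data$.cell_mad & .data$.cell_mad > 0)
  if (any(flagged$.cell_mad == 0)) {
    warning("cells with zero MAD left unfiltered", call. = FALSE)
  }
  removed <- flagged |>
    dplyr::summarise(n_removed = sum(.data$.out), .groups = "drop")
  out <- flagged |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$.out) |>
    dplyr::select(-".cell_mad", -".out")
  attr(out, "removed") <- removed
  out
}

#' Summarise task performance
#'
#' Per participant and condition: the median and interquartile range of the
#' force error (% maximum force; quartiles use the linear-interpolation
#' type-7 convention). Per participant: the standard deviation of the
#' performance error (pixels) over all basic trials, pooled across
#' conditions — the performance-variability index used for adjustment in
#' trait analyses.
#'
#' @param trials Preprocessed canonical trial tibble.
#' @return A list of class `ap_performance_summary` with tibbles `cells`
#'   (`participant_id`, `effort`, `reward`, `median_force_error`,
#'   `iqr_force_error`) and `participants` (`participant_id`,
#'   `sd_performance_error`).
#' @export
summarize_performance <- function(trials) {
  cells <- trials |>
    dplyr::group_by(.data$participant_id, .data$effort, .data$reward) |>
    dplyr::summarise(
      median_force_error = stats::median(.data$force_error),
      iqr_force_error = stats::IQR(.data$force_error, type = 7),
      .groups = "drop")
  basics <- dplyr::filter(trials, .data$trial_type == "basic")
  if (nrow(basics) == 0) {
    warning("no basic trials; performance variability is missing", call. = FALSE)
  }
  participants <- basics |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(sd_performance_error = stats::sd(.data$performance_error),
                     .groups = "drop")
  structure(list(cells = cells, participants = participants),
            class = "ap_performance_summary")
}

#' @export
print.ap_performance_summary <- function(x, ...) {
  cat(sprintf("<ap_performance_summary> %d participants, %d cells\n",
              nrow(x$participants), nrow(x$cells)))
  invisible(x)
}

#' Standard preprocessing for one cohort
#'
#' Applies, in order: participant exclusion by the group MAD rule on mean
#' absolute force error, first-trial removal per block, and the per-cell MAD
#' filter on force errors.
#'
#' @param trials Canonical trial tibble.
#' @param k MAD multiplier for both rules.
#' @return A list with `trials` (the cleaned tibble), `excluded`
#'   (exclusion table), and `removed` (per-cell removal counts).
#' @export
preprocess_trials <- function(trials, k = 3) {
  excl <- exclude_participants(participant_performance(trials), k = k)
  kept <- dplyr::filter(trials, .data$participant_id %in%
                          excl$participant_id[!excl$excluded])
  kept <- drop_first_trials(kept)
  kept <- mad_filter_force_errors(kept, k = k)
  list(trials = kept, excluded = excl, removed = attr(kept, "removed"))
}
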