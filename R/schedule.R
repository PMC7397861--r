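#' Generate a pseudorandom trial schedule
#'
#' Produces the full trial list for one participant: `n_blocks` blocks of
#' `trials_per_block` trials, with `blocks_per_condition` blocks per
#' effort-by-reward cell in a seeded pseudorandom order. Within every block
#' the first three trials are basic, the block contains exactly
#' `estimation_per_block` estimation trials, and no two estimation trials
#' are adjacent. Within-block orders are drawn by rejection sampling, so
#' the output is reproducible for a fixed seed.
#'
#' @param config An [task_config()] object.
#' @param seed Integer seed.
#' @param participant_id Optional id stamped on every row.
#' @return A tibble with columns `participant_id`, `block`,
#'   `trial_in_block`, `effort`, `reward`, `trial_type`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' nrow(sched)                                  # 1080
#' sum(sched$trial_type == "estimation")        # 320
#' @export
generate_schedule <- function(config = task_config(), seed = 1L,
                              participant_id = NA_character_) {
  validate_task_config(config)
  n_lead <- min(3L, config$trials_per_block)
  free <- config$trials_per_block - n_lead
  # no-adjacency capacity among the post-lead slots
  if (config$estimation_per_block > ceiling(free / 2)) {
    stop("estimation_per_block too large: no-adjacency constraint unsatisfiable",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    cells <- tidyr::expand_grid(effort = c("low", "high"),
                                reward = c("no", "yes"))
    order <- sample(rep(seq_len(4), config$blocks_per_condition))
    blocks <- cells[order, ]
    types <- lapply(seq_len(config$n_blocks), function(b) {
      block_trial_types(config$trials_per_block, n_lead,
                        config$estimation_per_block)
    })
  })
  tibble::tibble(
    participant_id = participant_id,
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    trial_in_block = rep(seq_len(config$trials_per_block), config$n_blocks),
    effort = rep(blocks$effort, each = config$trials_per_block),
    reward = rep(blocks$reward, each = config$trials_per_block),
    trial_type = unlist(types)
  )
}

# rejection-sample one block's trial-type sequence
block_trial_types <- function(n_trials, n_lead, n_estimation) {
  free <- n_trials - n_lead
  repeat {
    slots <- sort(sample.int(free, n_estimation))
    if (n_estimation < 2 || all(diff(slots) > 1)) break
  }
  types <- rep("basic", n_trials)
  types[n_lead + slots] <- "estimation"
  types
}
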