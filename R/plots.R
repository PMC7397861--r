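#' Force-error distributions by condition
#'
#' Boxplots of force error per effort-by-reward cell, optionally for a
#' single participant — the task's accuracy/variability picture at a
#' glance.
#'
#' @param trials Canonical trial tibble.
#' @param participant Optional participant id to restrict to.
#' @return A ggplot object.
#' @export
plot_force_errors <- function(trials, participant = NULL) {
  if (!is.null(participant)) {
    trials <- dplyr::filter(trials, .data$participant_id %in% participant)
  }
  ggplot2::ggplot(trials,
                  ggplot2::aes(x = .data$reward, y = .data$force_error,
                               fill = .data$reward)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, show.legend = FALSE) +
    ggplot2::facet_wrap(~effort, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "reward", y = "force error (% max force)") +
    ggplot2::theme_minimal()
}

#' Estimation error against performance error
#'
#' The weighting picture: each estimation trial's estimation error plotted
#' against its performance error, with the pooled regression line whose
#' slope estimates `-w`.
#'
#' @param trials Canonical trial tibble.
#' @param participant Optional participant id(s) to restrict to.
#' @return A ggplot object.
#' @export
plot_weighting <- function(trials, participant = NULL) {
  est <- dplyr::filter(trials, !is.na(.data$estimation_error))
  if (!is.null(participant)) {
    est <- dplyr::filter(est, .data$participant_id %in% participant)
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$performance_error,
                                    y = .data$estimation_error)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = "performance error (px)", y = "estimation error (px)") +
    ggplot2::theme_minimal()
}

#' Posterior predictive check plot
#'
#' Observed estimates as a histogram with replicated predictive densities
#' overlaid.
#'
#' @param object An `ap_ppc` from [posterior_predictive()].
#' @param fit The `ap_observer_fit` the check was computed from.
#' @param n_show Number of replicate densities to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ap_ppc
#' @export
autoplot.ap_ppc <- function(object, fit, n_show = 20, ...) {
  obs <- tibble::tibble(x = fit$data$x_estimate)
  idx <- seq_len(min(n_show, nrow(object$replicates)))
  reps <- purrr::map_dfr(idx, function(r)
    tibble::tibble(rep = r, x = object$replicates[r, ]))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", colour = "grey60") +
    ggplot2::geom_density(data = reps,
                          ggplot2::aes(group = .data$rep),
                          colour = "steelblue", alpha = 0.3, linewidth = 0.3) +
    ggplot2::labs(x = "estimated final position (px)", y = "density") +
    ggplot2::theme_minimal()
}

#' Parameter-recovery scatter
#'
#' Posterior means against generating values across participants, one
#' panel per parameter, with the identity line.
#'
#' @param truth An [sample_cohort()] object.
#' @param fit An `ap_observer_fit` on data simulated from `truth`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(truth, fit) {
  joined <- dplyr::inner_join(fit$participants, truth$participants,
                              by = "participant_id",
                              suffix = c("_hat", "_true"))
  long <- dplyr::bind_rows(
    tibble::tibble(parameter = "sigma_prior",
                   true = joined$mean_sigma_prior,
                   recovered = joined$sigma_prior),
    tibble::tibble(parameter = "sigma_evidence",
                   true = joined$mean_sigma_evidence,
                   recovered = joined$sigma_evidence),
    if (fit$variant == "m2")
      tibble::tibble(parameter = "shift_s",
                     true = joined$mean_shift_s,
                     recovered = joined$shift_s))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior mean") +
    ggplot2::theme_minimal()
}

#' Trait-association scatter
#'
#' Participant prior SDs against a trait scale.
#'
#' @param estimates Tibble with `participant_id` and `sigma_prior`.
#' @param participants Tibble with `participant_id` and the trait column.
#' @param scale Trait column name.
#' @return A ggplot object.
#' @export
plot_trait_association <- function(estimates, participants,
                                   scale = "ami_ba") {
  d <- dplyr::inner_join(estimates, participants, by = "participant_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[scale]], y = .data$sigma_prior)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = scale, y = "prior SD (px)") +
    ggplot2::theme_minimal()
}
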