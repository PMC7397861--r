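#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an observer-model fit
#'
#' One row per monitored parameter: posterior mean, SD, central 95%
#' interval, and split R-hat.
#'
#' @param x An `ap_observer_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @method tidy ap_observer_fit
#' @export
tidy.ap_observer_fit <- function(x, ...) {
  arr <- x$draws
  flat <- apply(arr, 3, identity)
  tibble::tibble(
    term = dimnames(arr)[[3]],
    estimate = colMeans(flat),
    std.error = apply(flat, 2, stats::sd),
    conf.low = apply(flat, 2, stats::quantile, 0.025),
    conf.high = apply(flat, 2, stats::quantile, 0.975),
    rhat = x$rhat$rhat[match(dimnames(arr)[[3]], x$rhat$parameter)])
}

#' @rdname tidy.ap_observer_fit
#' @method glance ap_observer_fit
#' @export
glance.ap_observer_fit <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(
    variant = x$variant,
    n_participants = length(x$participant_ids),
    n_trials = nrow(x$data),
    n_draws = dim(x$draws)[1] * dim(x$draws)[2],
    max_rhat = max(x$rhat$rhat),
    waic = w$waic,
    p_waic = w$p_waic)
}

#' Tidy a weighting-model fit
#'
#' @param x An `ap_weighting_fit`.
#' @param ... Unused.
#' @return Fixed-effect tibble (`term`, `estimate`, `conf.low`,
#'   `conf.high`).
#' @method tidy ap_weighting_fit
#' @export
tidy.ap_weighting_fit <- function(x, ...) x$fixed

#' @rdname tidy.ap_weighting_fit
#' @method glance ap_weighting_fit
#' @export
glance.ap_weighting_fit <- function(x, ...) {
  tibble::tibble(
    spec_id = x$spec_id,
    slope = x$fixed$estimate[2],
    weight_w = -x$fixed$estimate[2],
    conditional_loglik = x$conditional_loglik,
    effective_dof = x$effective_dof,
    caic = x$caic,
    singular = x$singular)
}

#' Tidy a weighting-model selection
#'
#' @param x An `ap_weighting_selection`.
#' @param ... Unused.
#' @return The candidate table (spec, cAIC, delta cAIC, convergence).
#' @method tidy ap_weighting_selection
#' @export
tidy.ap_weighting_selection <- function(x, ...) x$table

#' Tidy a model comparison
#'
#' @param x An `ap_model_comparison`.
#' @param ... Unused.
#' @return The pairwise table with WAIC differences and their SEs.
#' @method tidy ap_model_comparison
#' @export
tidy.ap_model_comparison <- function(x, ...) x$pairs
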