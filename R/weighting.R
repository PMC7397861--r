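#' The ten candidate weighting models
#'
#' The weighting regression of estimation error on performance error is
#' fitted as a Gaussian linear mixed model. The baseline lets the intercept
#' and slope vary by participant; nine further candidates additionally let
#' the intercept, the slope, or both vary within participants by effort,
#' reward, or both (condition adjustments nested within participant).
#'
#' @return A tibble with `spec_id`, `intercept_adj`, `slope_adj`, `formula`.
#' @export
weighting_model_specs <- function() {
  adj <- c("none", "effort", "reward", "both")
  grid <- tidyr::expand_grid(intercept_adj = adj, slope_adj = adj)
  grid <- grid[grid$intercept_adj == "none" | grid$slope_adj == "none" |
                 grid$intercept_adj == grid$slope_adj, ]
  grid$spec_id <- paste0("i_", grid$intercept_adj, ".s_", grid$slope_adj)
  grid$formula <- purrr::map2_chr(grid$intercept_adj, grid$slope_adj,
                                  weighting_formula)
  tibble::as_tibble(grid[, c("spec_id", "intercept_adj", "slope_adj", "formula")])
}

weighting_formula <- function(intercept_adj, slope_adj) {
  terms <- c("estimation_error ~ performance_error",
             "(1 + performance_error | participant_id)")
  int_terms <- switch(intercept_adj,
    none = character(),
    effort = "(1 | participant_id:effort)",
    reward = "(1 | participant_id:reward)",
    both = c("(1 | participant_id:effort)", "(1 | participant_id:reward)"))
  slope_terms <- switch(slope_adj,
    none = character(),
    effort = "(0 + performance_error | participant_id:effort)",
    reward = "(0 + performance_error | participant_id:reward)",
    both = c("(0 + performance_error | participant_id:effort)",
             "(0 + performance_error | participant_id:reward)"))
  paste(c(terms, int_terms, slope_terms), collapse = " + ")
}

#' Fit one weighting model
#'
#' Maximum-likelihood fit (not REML, so conditional AICs are comparable
#' across candidates) of the regression of estimation error on performance
#' error. For data generated by precision-weighted cue combination the
#' fixed slope estimates `-w`: -1 is full reliance on the prior, 0 is
#' disregard of the prior.
#'
#' @param trials Canonical trial tibble; only estimation trials (rows with
#'   a non-missing `estimation_error`) are used.
#' @param spec One row of [weighting_model_specs()] (or a spec_id string).
#' @return An object of class `ap_weighting_fit`: list with the `lme4` fit,
#'   `spec_id`, fixed-effect table, per-participant conditional slopes,
#'   conditional log-likelihood, effective dof, and `caic`.
#' @export
fit_weighting_model <- function(trials, spec = weighting_model_specs()[1, ]) {
  if (is.character(spec)) {
    specs <- weighting_model_specs()
    spec <- specs[specs$spec_id == spec, ]
    if (nrow(spec) != 1) stop("unknown spec_id", call. = FALSE)
  }
  est <- dplyr::filter(trials, !is.na(.data$estimation_error))
  if (dplyr::n_distinct(est$participant_id) < 2) {
    stop("need at least 2 participants with estimation trials", call. = FALSE)
  }
  est$participant_id <- factor(est$participant_id)
  fit <- suppressMessages(lme4::lmer(stats::as.formula(spec$formula),
                                     data = est, REML = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning(sprintf("singular random-effect structure in '%s'", spec$spec_id),
            call. = FALSE)
  }
  beta <- lme4::fixef(fit)
  ci <- tryCatch(suppressMessages(stats::confint(fit, parm = "beta_", method = "Wald")),
                 error = function(e) matrix(NA_real_, 2, 2))
  slopes <- stats::coef(fit)$participant_id
  cll <- conditional_loglik(fit)
  ed <- effective_dof(fit)
  structure(
    list(fit = fit, spec_id = spec$spec_id,
         fixed = tibble::tibble(
           term = names(beta), estimate = unname(beta),
           conf.low = ci[, 1], conf.high = ci[, 2]),
         participant_slopes = tibble::tibble(
           participant_id = rownames(slopes),
           slope = slopes[["performance_error"]]),
         conditional_loglik = cll,
         effective_dof = ed,
         caic = -2 * cll + 2 * ed,
         singular = singular),
    class = "ap_weighting_fit"
  )
}

#' @export
print.ap_weighting_fit <- function(x, ...) {
  cat(sprintf("<ap_weighting_fit> %s\n", x$spec_id))
  cat(sprintf("  slope = %.3f (weighting w = %.3f); cAIC = %.1f (edof %.1f)\n",
              x$fixed$estimate[2], -x$fixed$estimate[2], x$caic,
              x$effective_dof))
  invisible(x)
}

# conditional log-likelihood: Gaussian density at the conditional fitted
# values (Xb + Zb) with the ML residual SD
conditional_loglik <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  sum(stats::dnorm(y, stats::fitted(fit), stats::sigma(fit), log = TRUE))
}

# effective degrees of freedom: trace of the conditional hat matrix
# (Vaida & Blanchard), plus one for the residual variance. The trace is
# tr(A^-1 M'M) with M = [X Z] and A the mixed-model-equation matrix with
# the random-effect penalty (Lambda Lambda')^-1; zero variance components
# are handled by a vanishing ridge, under which the corresponding columns
# drop out and the trace tends to the fixed-effect count.
effective_dof <- function(fit) {
  X <- lme4::getME(fit, "X")
  Z <- as.matrix(lme4::getME(fit, "Z"))
  Lam <- as.matrix(lme4::getME(fit, "Lambda"))
  G <- tcrossprod(Lam)
  ridge <- max(diag(G), 1) * 1e-10
  Ginv <- solve(G + diag(ridge, nrow(G)))
  M <- cbind(X, Z)
  MtM <- crossprod(M)
  A <- MtM
  q <- ncol(Z)
  p <- ncol(X)
  A[(p + 1):(p + q), (p + 1):(p + q)] <-
    A[(p + 1):(p + q), (p + 1):(p + q)] + Ginv
  sum(diag(solve(A, MtM))) + 1
}

#' Conditional AIC of a weighting-model fit
#'
#' `cAIC = -2 * conditional log-likelihood + 2 * effective dof`, with the
#' effective dof from the hat-matrix trace. When the random-effect variances
#' vanish this reduces to the ordinary AIC of the fixed-effects model.
#'
#' @param fit An `ap_weighting_fit` or an `lme4` model fitted by ML.
#' @return The cAIC value.
#' @export
conditional_aic <- function(fit) {
  if (inherits(fit, "ap_weighting_fit")) return(fit$caic)
  if (!inherits(fit, "merMod")) stop("not a mixed-model fit", call. = FALSE)
  if (lme4::isREML(fit)) stop("cAIC requires an ML fit", call. = FALSE)
  -2 * conditional_loglik(fit) + 2 * effective_dof(fit)
}

#' Select the most parsimonious weighting model
#'
#' Fits all ten candidates by ML and selects the lowest conditional AIC.
#' Candidates that fail to converge are dropped with a warning.
#'
#' @param trials Canonical trial tibble (estimation trials used).
#' @param specs Candidate table, defaults to [weighting_model_specs()].
#' @return A list of class `ap_weighting_selection`: `best` (the winning
#'   `ap_weighting_fit`), `table` (tibble with `spec_id`, `intercept_adj`,
#'   `slope_adj`, `caic`, `delta_caic`, `converged`), and `fits`.
#' @export
select_weighting_model <- function(trials, specs = weighting_model_specs()) {
  fits <- purrr::map(seq_len(nrow(specs)), function(i) {
    tryCatch(suppressWarnings(fit_weighting_model(trials, specs[i, ])),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("all candidate fits failed", call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("dropped %d non-converged candidate(s): %s", sum(!ok),
                    paste(specs$spec_id[!ok], collapse = ", ")), call. = FALSE)
  }
  caic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$caic, 0)
  tab <- tibble::tibble(
    spec_id = specs$spec_id,
    intercept_adj = specs$intercept_adj,
    slope_adj = specs$slope_adj,
    caic = caic,
    delta_caic = caic - min(caic, na.rm = TRUE),
    converged = ok
  ) |> dplyr::arrange(.data$caic)
  structure(list(best = fits[[which.min(caic)]], table = tab, fits = fits),
            class = "ap_weighting_selection")
}

#' @export
print.ap_weighting_selection <- function(x, ...) {
  cat("<ap_weighting_selection>\n")
  print(x$table, n = nrow(x$table))
  invisible(x)
}
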