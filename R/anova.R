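#' Two-by-two repeated-measures ANOVA with generalized eta-squared
#'
#' Fully within-subjects decomposition for a balanced effort-by-reward
#' design: each effect is tested against its subject-by-effect interaction
#' stratum. Effect size is generalized eta-squared for fully within designs,
#' `SS_effect / (SS_effect + SS_subjects + sum of all error SS)`
#' (Bakeman 2005). With 1-df effects no sphericity correction is needed.
#'
#' @param data A tibble with one value per subject and condition cell.
#' @param value Name of the value column (string).
#' @param subject,effort,reward Names of the id and factor columns.
#' @return A tibble of class `ap_anova` with columns `effect`, `df1`, `df2`,
#'   `statistic` (F), `p.value`, and `ges`.
#' @export
rm_anova_2x2 <- function(data, value = "value", subject = "participant_id",
                         effort = "effort", reward = "reward") {
  d <- tibble::tibble(
    y = data[[value]],
    s = factor(data[[subject]]),
    a = factor(data[[effort]]),
    b = factor(data[[reward]])
  )
  if (anyNA(d$y)) stop("missing cell values are not supported", call. = FALSE)
  counts <- table(d$s, d$a, d$b)
  if (any(counts != 1)) {
    stop("design must be complete and balanced: one value per subject per cell",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = d)
  sm <- summary(fit)
  ss <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    idx <- match(term, trimws(rownames(tab)))
    tab[idx, c("Df", "Sum Sq")]
  }
  zero_tol <- 1e-12 * (sum(d$y^2) + 1)   # numerically-null sums of squares
  ss_subj <- ss("Error: s", "Residuals")["Sum Sq"]
  rows <- list(
    effort = list(eff = ss("Error: s:a", "a"), err = ss("Error: s:a", "Residuals")),
    reward = list(eff = ss("Error: s:b", "b"), err = ss("Error: s:b", "Residuals")),
    `effort:reward` = list(eff = ss("Error: s:a:b", "a:b"),
                           err = ss("Error: s:a:b", "Residuals"))
  )
  ss_err_total <- sum(vapply(rows, function(r) r$err[["Sum Sq"]], 0))
  if (ss_err_total < zero_tol) ss_err_total <- 0
  if (ss_subj[["Sum Sq"]] < zero_tol) ss_subj[["Sum Sq"]] <- 0
  out <- purrr::imap_dfr(rows, function(r, nm) {
    ss_eff <- r$eff[["Sum Sq"]]
    if (ss_eff < zero_tol) ss_eff <- 0
    ms_eff <- ss_eff / r$eff[["Df"]]
    ms_err <- r$err[["Sum Sq"]] / r$err[["Df"]]
    if (ms_err < zero_tol) ms_err <- 0
    denom <- ss_eff + ss_subj[["Sum Sq"]] + ss_err_total
    tibble::tibble(
      effect = nm,
      df1 = as.integer(r$eff[["Df"]]),
      df2 = as.integer(r$err[["Df"]]),
      statistic = if (ms_err > 0) ms_eff / ms_err else 0,
      p.value = if (ms_err > 0) stats::pf(ms_eff / ms_err, r$eff[["Df"]],
                                          r$err[["Df"]], lower.tail = FALSE)
                else NA_real_,
      ges = if (denom > 0) ss_eff / denom else 0
    )
  })
  class(out) <- c("ap_anova", class(out))
  out
}

#' Repeated-measures ANCOVA with a continuous between-subject covariate
#'
#' Tests covariate-by-within-factor interactions through the
#' within-subject contrast formulation: each subject's effort contrast,
#' reward contrast, and interaction contrast is regressed on the
#' mean-centred covariate; the slope's F test is the interaction test.
#' Centring leaves the F statistics unchanged.
#'
#' @inheritParams rm_anova_2x2
#' @param covariate A tibble with one row per subject and a covariate
#'   column, or a named numeric vector (names = subject ids).
#' @param covariate_col Column name when `covariate` is a tibble.
#' @return A tibble with one row per covariate interaction: `effect`,
#'   `df1`, `df2`, `statistic`, `p.value`.
#' @export
rm_ancova_covariate <- function(data, covariate, value = "value",
                                subject = "participant_id",
                                effort = "effort", reward = "reward",
                                covariate_col = "covariate") {
  if (is.numeric(covariate) && !is.null(names(covariate))) {
    covariate <- tibble::tibble(participant_id = names(covariate),
                                covariate = unname(covariate))
    covariate_col <- "covariate"
    names(covariate)[1] <- subject
  }
  wide <- tibble::tibble(
    s = as.character(data[[subject]]),
    a = data[[effort]], b = data[[reward]],
    y = data[[value]]
  )
  cmat <- wide |>
    dplyr::group_by(.data$s) |>
    dplyr::summarise(
      eff = mean(.data$y[.data$a == "high"]) - mean(.data$y[.data$a == "low"]),
      rew = mean(.data$y[.data$b == "yes"]) - mean(.data$y[.data$b == "no"]),
      int = (.data$y[.data$a == "high" & .data$b == "yes"] -
               .data$y[.data$a == "high" & .data$b == "no"]) -
        (.data$y[.data$a == "low" & .data$b == "yes"] -
           .data$y[.data$a == "low" & .data$b == "no"]),
      .groups = "drop")
  cv <- covariate[[covariate_col]][match(cmat$s, as.character(covariate[[subject]]))]
  if (anyNA(cv)) stop("covariate missing for some subjects", call. = FALSE)
  if (stats::sd(cv) == 0) stop("covariate is constant", call. = FALSE)
  cvc <- cv - mean(cv)
  one <- function(contrast, nm) {
    fit <- stats::lm(contrast ~ cvc)
    an <- stats::anova(fit)
    tibble::tibble(effect = nm, df1 = as.integer(an$Df[1]),
                   df2 = as.integer(an$Df[2]),
                   statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1])
  }
  dplyr::bind_rows(
    one(cmat$eff, "effort:covariate"),
    one(cmat$rew, "reward:covariate"),
    one(cmat$int, "effort:reward:covariate")
  )
}
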