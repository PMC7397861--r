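#' Partial correlation with one adjustment variable
#'
#' Pearson partial correlation of `x` and `y` given `z`, via the
#' correlation-matrix formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` (identical to
#' correlating the residuals of `x` and `y` after regressing out `z`).
#' The p-value comes from the t transform with `df = n - 3`, and the Bayes
#' factor from [jzs_correlation_bf()] with one covariate.
#'
#' @param x,y,z Equal-length numeric vectors, `n >= 4`, none constant.
#' @param bf Compute the Bayes factor (set `FALSE` to skip the
#'   integration).
#' @return A one-row tibble: `r`, `df`, `statistic`, `p.value`, `bf10`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, z)
#' @export
partial_correlation <- function(x, y, z, bf = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("constant input", call. = FALSE)
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(
    r = r, df = df, statistic = tstat, p.value = p,
    bf10 = if (bf) jzs_correlation_bf(r, n, n_covariates = 1) else NA_real_)
}

#' Holm step-down adjustment of p-values
#'
#' Wraps `stats::p.adjust(method = "holm")` with range validation: sorted
#' ascending, the rank-i p-value is multiplied by `m - i + 1`, a running
#' maximum is enforced, values are capped at 1, and the original order is
#' restored.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_adjust(c(0.011, 0.226, 0.464, 0.464))
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Default-prior correlation Bayes factor
#'
#' Jeffreys's exact test for a Pearson correlation: the Bayes factor in
#' favour of a nonzero population correlation, with a uniform (stretched
#' beta, kappa = 1) prior on rho, computed by one-dimensional numerical
#' integration of the exact sampling density of r. For partial
#' correlations the effective sample size is reduced by the number of
#' covariates.
#'
#' @param r Observed (partial) correlation, `|r| < 1`.
#' @param n Number of observations.
#' @param n_covariates Number of adjustment variables (0 for a simple
#'   correlation).
#' @return The Bayes factor BF10.
#' @examples
#' jzs_correlation_bf(0.37, 47, n_covariates = 1)
#' @export
jzs_correlation_bf <- function(r, n, n_covariates = 0) {
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  ne <- n - n_covariates
  if (ne < 4) stop("effective sample size too small", call. = FALSE)
  num <- tryCatch(
    stats::integrate(function(rho) dcorr(r, rho, ne) / 2, -1, 1,
                     rel.tol = 1e-8)$value,
    error = function(e) stop("Bayes factor integration failed: ",
                             conditionMessage(e), call. = FALSE))
  num / dcorr(r, 0, ne)
}

# Gauss hypergeometric 2F1 by its defining series (z < 1)
hyp2f1 <- function(a, b, c, z, tol = 1e-12, kmax = 10000L) {
  term <- 1
  s <- 1
  for (k in 0:kmax) {
    term <- term * (a + k) * (b + k) / ((c + k) * (1 + k)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

# exact sampling density of the Pearson correlation r under bivariate
# normality with population correlation rho (Hotelling's 2F1 form);
# vectorised over rho
dcorr <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  lf <- lc + (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r)
  h <- vapply(rho, function(p) hyp2f1(0.5, 0.5, n - 0.5, (1 + p * r) / 2), 0)
  exp(lf) * h
}

#' Exact power of the two-sided Pearson correlation test
#'
#' Integrates the exact sampling density of r over the rejection region of
#' the t test (`|t| > t_crit`, `t = r sqrt((n-2)/(1-r^2))`).
#'
#' @param rho True correlation, 0 < rho < 1.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
correlation_power <- function(rho, n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  up <- stats::integrate(function(r) dcorr_r(r, rho, n), rc, 1,
                         rel.tol = 1e-9)$value
  lo <- stats::integrate(function(r) dcorr_r(r, rho, n), -1, -rc,
                         rel.tol = 1e-9)$value
  up + lo
}

# dcorr vectorised over r at fixed rho
dcorr_r <- function(r, rho, n) {
  vapply(r, function(ri) dcorr(ri, rho, n), 0)
}

#' Minimum sample size for detecting a correlation
#'
#' Smallest integer n at which the two-sided Pearson correlation test
#' reaches the target power. The default `"exact"` method uses the exact
#' sampling distribution of r ([correlation_power()]); `"fisher_z"` is the
#' closed-form approximation
#' `n = ((z_{alpha/2} + z_beta) / atanh(rho))^2 + 3`, which typically
#' returns one more participant.
#'
#' @param rho True correlation to detect, 0 < rho < 1.
#' @param alpha Two-sided significance level.
#' @param power Target power, in (0, 1).
#' @param method `"exact"` or `"fisher_z"`.
#' @param n_max Search cap for the exact method.
#' @return The required sample size (integer).
#' @examples
#' sample_size_for_correlation(0.4)                      # 46
#' sample_size_for_correlation(0.4, method = "fisher_z") # 47
#' @export
sample_size_for_correlation <- function(rho, alpha = 0.05, power = 0.80,
                                        method = c("exact", "fisher_z"),
                                        n_max = 100000L) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  method <- match.arg(method)
  n_fz <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
             atanh(rho))^2 + 3
  if (method == "fisher_z") return(as.integer(ceiling(n_fz)))
  # exact: walk outward from the Fisher-z guess
  n <- max(4L, as.integer(floor(n_fz)) - 5L)
  while (n <= n_max && correlation_power(rho, n, alpha) < power) {
    n <- n + 1L
  }
  if (n > n_max) stop("no feasible sample size below n_max", call. = FALSE)
  n
}

#' Trait-association table
#'
#' Partial correlations between a participant-level model estimate (for
#' example the posterior-mean prior SD) and each trait scale, adjusting
#' for performance variability, with Holm correction over the scale family
#' and Jeffreys exact Bayes factors.
#'
#' @param estimates Tibble with `participant_id` and an `estimate` column.
#' @param participants Tibble with `participant_id` and the trait columns.
#' @param adjust_for Tibble with `participant_id` and an adjustment column
#'   (for example `sd_performance_error` from [summarize_performance()]).
#' @param estimate_col,adjust_col Column names.
#' @param scales Trait columns to test (the Holm family).
#' @return A tibble: `scale`, `r`, `df`, `p.value`, `p.holm`, `bf10`.
#' @export
associate_traits <- function(estimates, participants, adjust_for,
                             estimate_col = "sigma_prior",
                             adjust_col = "sd_performance_error",
                             scales = c("ami_total", "ami_ba", "ami_es",
                                        "ami_sm")) {
  d <- estimates |>
    dplyr::inner_join(participants, by = "participant_id") |>
    dplyr::inner_join(adjust_for, by = "participant_id")
  out <- purrr::map_dfr(scales, function(sc) {
    pc <- partial_correlation(d[[estimate_col]], d[[sc]], d[[adjust_col]])
    tibble::tibble(scale = sc, r = pc$r, df = pc$df, p.value = pc$p.value,
                   bf10 = pc$bf10)
  })
  out$p.holm <- holm_adjust(out$p.value)
  out[, c("scale", "r", "df", "p.value", "p.holm", "bf10")]
}
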