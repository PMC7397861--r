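# three vectors with exactly prescribed pairwise sample correlations,
# built from an orthonormal centred basis and a Cholesky factor
exact_corr_vectors <- function(R, n = 12) {
  set.seed(99)
  raw <- matrix(rnorm(n * 3), n, 3)
  raw <- scale(raw, scale = FALSE)
  q <- qr.Q(qr(raw))
  q <- scale(q, center = FALSE, scale = apply(q, 2, sd))
  q %*% chol(R)
}

test_that("the partial correlation matches its closed forms", {
  # all pairwise correlations 0.5: partial r is exactly 1/3
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  v <- exact_corr_vectors(R)
  pc <- partial_correlation(v[, 1], v[, 2], v[, 3], bf = FALSE)
  expect_equal(pc$r, 1 / 3, tolerance = 1e-10)
  expect_equal(pc$df, nrow(v) - 3)

  # unrelated adjustment variable: partial r equals the raw correlation
  R0 <- diag(3); R0[1, 2] <- R0[2, 1] <- 0.4
  v0 <- exact_corr_vectors(R0)
  pc0 <- partial_correlation(v0[, 1], v0[, 2], v0[, 3], bf = FALSE)
  expect_equal(pc0$r, 0.4, tolerance = 1e-10)

  # p from the t transform with df = n - 3
  tstat <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  expect_equal(pc$p.value, 2 * pt(-abs(tstat), pc$df), tolerance = 1e-12)
})

test_that("the matrix formula equals the residual method", {
  set.seed(2)
  for (i in 1:5) {
    z <- rnorm(40)
    x <- 0.5 * z + rnorm(40)
    y <- -0.3 * z + rnorm(40)
    pc <- partial_correlation(x, y, z, bf = FALSE)
    res <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
    expect_equal(pc$r, res, tolerance = 1e-10)
  }
  expect_error(partial_correlation(1:3, 1:3, 1:3), "at least 4")
  expect_error(partial_correlation(rep(1, 5), rnorm(5), rnorm(5)), "constant")
})

test_that("Holm adjustment matches hand computation", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.011, 0.226, 0.464, 0.464)),
               c(0.044, 0.678, 0.928, 0.928), tolerance = 1e-12)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  # monotone in sorted order and dominates the raw p-values
  set.seed(3)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the correlation Bayes factor behaves and hits the printed anchors", {
  # null data favour the null
  expect_lt(jzs_correlation_bf(0, 100), 1)
  # monotone in |r| at fixed n, and in n at fixed r
  bfs_r <- vapply(c(0.1, 0.2, 0.3, 0.4), jzs_correlation_bf, 0, n = 50)
  expect_true(all(diff(bfs_r) > 0))
  bfs_n <- vapply(c(20, 40, 80, 160), function(n)
    jzs_correlation_bf(0.3, n), 0)
  expect_true(all(diff(bfs_n) > 0))
  expect_equal(jzs_correlation_bf(0.3, 50), jzs_correlation_bf(-0.3, 50),
               tolerance = 1e-8)

  # reported partial-correlation Bayes factors, within rounding of the
  # printed two-decimal correlations (N = 47, one covariate)
  expect_equal(jzs_correlation_bf(0.37, 47, 1), 3.99, tolerance = 0.2)
  expect_equal(jzs_correlation_bf(0.18, 47, 1), 0.36, tolerance = 0.2)
  expect_equal(jzs_correlation_bf(0.11, 47, 1), 0.23, tolerance = 0.2)
  expect_equal(jzs_correlation_bf(-0.38, 47, 1), 5.12, tolerance = 0.25)

  expect_error(jzs_correlation_bf(1.2, 50), "< 1")
  expect_error(jzs_correlation_bf(0.5, 5, 3), "too small")
})

test_that("the exact power analysis reproduces the planning numbers", {
  expect_identical(sample_size_for_correlation(0.4), 46L)
  expect_identical(sample_size_for_correlation(0.4, method = "fisher_z"), 47L)
  expect_identical(sample_size_for_correlation(0.2, method = "fisher_z"), 194L)
  # the exact threshold is sharp: power crosses 0.80 exactly at n = 46
  expect_gte(correlation_power(0.4, 46), 0.80)
  expect_lt(correlation_power(0.4, 45), 0.80)
  expect_error(sample_size_for_correlation(1.2), "rho")
  expect_error(sample_size_for_correlation(0.4, alpha = 0), "alpha")
})

test_that("exact power agrees with a Monte-Carlo experiment", {
  set.seed(4)
  n <- 46; rho <- 0.4; reps <- 4000
  tcrit <- qt(0.975, n - 2)
  hits <- replicate(reps, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- cor(x, y)
    abs(r * sqrt((n - 2) / (1 - r^2))) > tcrit
  })
  expect_equal(mean(hits), correlation_power(rho, n),
               tolerance = 3 * sqrt(0.8 * 0.2 / reps) / 0.8)
})

test_that("the trait-association table assembles all four scales", {
  set.seed(5)
  n <- 30
  ids <- sprintf("p%02d", 1:n)
  est <- tibble::tibble(participant_id = ids,
                        sigma_prior = exp(rnorm(n, log(40), 0.3)))
  parts <- tibble::tibble(participant_id = ids,
                          ami_ba = runif(n, 0, 4), ami_es = runif(n, 0, 4),
                          ami_sm = runif(n, 0, 4))
  parts$ami_total <- (parts$ami_ba + parts$ami_es + parts$ami_sm) / 3
  adj <- tibble::tibble(participant_id = ids,
                        sd_performance_error = est$sigma_prior * runif(n, 2, 3))
  tab <- associate_traits(est, parts, adj)
  expect_equal(tab$scale, c("ami_total", "ami_ba", "ami_es", "ami_sm"))
  expect_equal(tab$df, rep(n - 3, 4))
  expect_equal(tab$p.holm, holm_adjust(tab$p.value))
  expect_true(all(tab$bf10 > 0))
})
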