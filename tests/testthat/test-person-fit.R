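test_that("individual_loglik matches hand values", {
  # univariate standard normal at its mean: -1/2 log(2 pi)
  expect_equal(individual_loglik(0, 0, matrix(1)), -0.5 * log(2 * pi))
  # one sd away: -1/2 (log(2 pi) + 1)
  expect_equal(individual_loglik(1, 0, matrix(1)), -0.5 * (log(2 * pi) + 1))
  # scaling: variance 4 at distance 2 = 1 sd
  expect_equal(individual_loglik(2, 0, matrix(4)),
               -0.5 * (log(2 * pi) + log(4) + 1))
  # bivariate independent case = sum of univariate terms
  expect_equal(individual_loglik(c(1, 2), c(0, 0), diag(2)),
               individual_loglik(1, 0, matrix(1)) +
                 individual_loglik(2, 0, matrix(1)))
  expect_error(individual_loglik(c(1, 2), c(0, 0), matrix(1, 2, 2)),
               "positive definite")
})

test_that("y1 is exactly zero when implied moments equal sample moments", {
  sim <- small_sim(n = 120, seed = 31)
  fit <- suppressWarnings(fit_ml_cfa(sim$data))
  # force the implied moments to the sample moments: the index collapses to 0
  fit$implied_mean <- fit$sample_mean
  fit$implied_cov <- fit$sample_cov
  y1 <- person_fit_y1(sim$data, fit)
  expect_equal(y1, rep(0, 120), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("y1 equals -2 times the log-likelihood difference", {
  sim <- small_sim(n = 80, seed = 32)
  fit <- suppressWarnings(fit_ml_cfa(sim$data))
  Y <- as.matrix(sim$data$responses[, -1])
  y1 <- person_fit_y1(sim$data, fit)
  for (i in c(1, 40, 80)) {
    direct <- -2 * (individual_loglik(Y[i, ], fit$implied_mean, fit$implied_cov) -
                      individual_loglik(Y[i, ], fit$sample_mean, fit$sample_cov))
    expect_equal(y1[i], direct, tolerance = 1e-10)
  }
})

test_that("mean sample-moment Mahalanobis distance obeys the trace identity", {
  # sum_i (y_i - ybar)' S^-1 (y_i - ybar) = (N - 1) tr(S^-1 S) = (N - 1) p
  sim <- small_sim(n = 100, seed = 33)
  fit <- suppressWarnings(fit_ml_cfa(sim$data))
  Y <- as.matrix(sim$data$responses[, -1])
  d2 <- vapply(seq_len(nrow(Y)), function(i) {
    z <- Y[i, ] - fit$sample_mean
    drop(z %*% solve(fit$sample_cov, z))
  }, numeric(1))
  p <- ncol(Y)
  expect_equal(sum(d2), (nrow(Y) - 1) * p, tolerance = 1e-8)
})

test_that("variability_y2 matches hand-computed identities", {
  df <- tibble::tibble(
    person_id = 1:3,
    A1 = c(4, 1, 1), A2 = c(4, 2, 1), A3 = c(4, 3, 1),
    A4 = c(4, 4, 1), A5 = c(4, 5, 6), A6 = c(4, 6, 6)
  )
  dat <- survey_data(df, c(A1 = 1, A2 = 1, A3 = 1, A4 = 1, A5 = 1, A6 = 1))
  y2 <- variability_y2(dat)
  expect_equal(y2[1], 0)                 # constant row
  expect_equal(y2[2], var(1:6))          # 1..6 -> 3.5
  expect_equal(y2[2], 3.5)
  expect_equal(y2[3], var(c(1, 1, 1, 1, 6, 6)))
})

test_that("variability_y2 averages the per-factor variances", {
  df <- tibble::tibble(person_id = 1, A1 = 1, A2 = 3, B1 = 2, B2 = 2)
  dat <- survey_data(df, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  # factor A: var(c(1,3)) = 2; factor B: var(c(2,2)) = 0; mean = 1
  expect_equal(variability_y2(dat), 1)
  d1 <- survey_data(tibble::tibble(person_id = 1, A1 = 1, B1 = 2, B2 = 2),
                    c(A1 = 1, B1 = 2, B2 = 2))
  expect_error(variability_y2(d1), ">= 2 mapped items")
})

test_that("bots score higher than humans on both indices on average", {
  sim <- generate_dataset(sim_design(n_persons = 400, prop_bots = 0.25,
                                     seed = 34))
  idx <- person_indices(sim$data, standardize = FALSE)
  bot <- sim$truth$class_labels == "bot"
  expect_gt(mean(idx$y2[bot]), mean(idx$y2[!bot]))
  expect_gt(mean(idx$y1[bot]), mean(idx$y1[!bot]))
  # uniform bots have E[within-factor variance] = 35/12
  expect_equal(mean(idx$y2[bot]), 35 / 12, tolerance = 0.15)
})

test_that("standardization is z-scoring, idempotent and recorded", {
  sim <- small_sim(n = 100, seed = 35)
  raw <- person_indices(sim$data, standardize = FALSE)
  std <- standardize_indices(raw)
  expect_equal(mean(std$y1), 0, tolerance = 1e-12)
  expect_equal(sd(std$y1), 1, tolerance = 1e-12)
  expect_equal(mean(std$y2), 0, tolerance = 1e-12)
  expect_equal(sd(std$y2), 1, tolerance = 1e-12)
  expect_true(attr(std, "standardized"))
  consts <- attr(std, "constants")
  expect_equal(unname(consts$y2[["mean"]]), mean(raw$y2))
  # idempotent
  expect_identical(standardize_indices(std), std)
  # default pipeline standardizes
  def <- person_indices(sim$data)
  expect_equal(def$y1, std$y1)
})

test_that("preliminary ML CFA recovers parameters on clean data", {
  sim <- generate_dataset(sim_design(n_persons = 2000, n_factors = 2,
                                     prop_bots = 0, seed = 36))
  fit <- fit_ml_cfa(sim$data)
  expect_true(fit$converged)
  # compare standardized implied correlations against the generating ones
  # (categorization attenuates absolute covariances, but structure survives)
  L <- sim$truth$loading_matrix
  true_cor <- cov2cor(L %*% sim$truth$factor_cov %*% t(L) +
                        diag(sim$truth$residual_variances))
  est_cor <- cov2cor(fit$implied_cov)
  expect_lt(max(abs(est_cor - true_cor)), 0.08)
  expect_equal(unname(fit$implied_mean), unname(colMeans(
    as.matrix(sim$data$responses[, -1]))))
})
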