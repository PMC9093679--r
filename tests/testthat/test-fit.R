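test_that("fit_lc_cfa returns a complete, well-formed fit object", {
  sim <- small_sim(n = 150, seed = 41)
  fit <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 7))
  expect_s3_class(fit, "lc_cfa_fit")
  keep <- 600
  expect_equal(dim(fit$draws), c(keep, 2, length(fit$param_names)))
  expect_equal(dimnames(fit$draws)[[3]], fit$param_names)
  # monitored blocks all present
  expect_true(all(c("tau1[F1_I1]", "lambda[F1_I2]", "phi[1,1]", "phi[2,1]",
                    "sigma2_1[F1_I1]", "tau2[F1_I1]", "sigma2_2[F1_I1]",
                    "beta[0]", "beta[1]", "beta[2]") %in% fit$param_names))
  # scaling loadings are not sampled
  expect_false("lambda[F1_I1]" %in% fit$param_names)
  expect_equal(nrow(fit$diagnostics), length(fit$param_names))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_length(fit$p_bot, 150)
  expect_true(all(fit$p_bot >= 0 & fit$p_bot <= 1))
  expect_equal(fit$classification$class,
               ifelse(fit$p_bot > 0.5, "bot", "human"))
  expect_identical(fit$converged, max(fit$diagnostics$rhat) < 1.01)
})

test_that("chains replay bit-identically under the same seed", {
  sim <- small_sim(n = 120, seed = 42)
  f1 <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 3))
  f2 <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 3))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$p_bot, f2$p_bot)
  f3 <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 4))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the mixture separates bots from humans on a moderate dataset", {
  sim <- generate_dataset(sim_design(n_persons = 250, prop_bots = 0.25,
                                     seed = 43))
  fit <- fit_lc_cfa(sim$data,
                    mcmc = mcmc_settings(n_chains = 2, n_iter = 2000,
                                         n_burnin = 1000, seed = 11))
  acc <- sensitivity_specificity(sim$truth$class_labels,
                                 fit$classification$class)
  expect_gt(acc$sensitivity, 0.9)
  expect_gt(acc$specificity, 0.9)
  # the variability coefficient pushes strongly away from the attentive class
  sig <- beta_significance(botcfa:::beta_draw_matrix(fit))
  expect_true(sig$significant[sig$term == "beta[2]"])
  expect_lt(sig$conf.high[sig$term == "beta[2]"], 0)
})

test_that("posterior bot probabilities track the true labels", {
  sim <- generate_dataset(sim_design(n_persons = 250, prop_bots = 0.25,
                                     seed = 44))
  fit <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 5))
  bot <- sim$truth$class_labels == "bot"
  expect_gt(mean(fit$p_bot[bot]), 0.85)
  expect_lt(mean(fit$p_bot[!bot]), 0.15)
})

test_that("classify_persons applies the threshold with ties to human", {
  sim <- small_sim(n = 100, seed = 45)
  fit <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 6))
  # monotone in the threshold
  n_low <- sum(classify_persons(fit, 0.2)$class == "bot")
  n_mid <- sum(classify_persons(fit, 0.5)$class == "bot")
  n_high <- sum(classify_persons(fit, 0.8)$class == "bot")
  expect_gte(n_low, n_mid)
  expect_gte(n_mid, n_high)
  # tie goes to human: threshold exactly at an observed probability
  fit$p_bot[1] <- 0.5
  cls <- classify_persons(fit, 0.5)
  expect_equal(cls$class[1], "human")
  expect_error(classify_persons(fit, 0), "threshold")
  expect_error(classify_persons(fit, 1), "threshold")
})

test_that("standardized loadings match the per-draw formula", {
  sim <- small_sim(n = 120, seed = 46)
  fit <- fit_lc_cfa(sim$data, mcmc = fast_mcmc(seed = 8))
  std <- standardized_loadings(fit, summarize = FALSE)
  # manual recomputation for a free item and a scaling item
  flat <- do.call(rbind, lapply(1:2, function(ch) fit$draws[, ch, ]))
  colnames(flat) <- fit$param_names
  lam <- flat[, "lambda[F2_I3]"]
  phi <- flat[, "phi[2,2]"]
  s2 <- flat[, "sigma2_1[F2_I3]"]
  expect_equal(std[, "F2_I3"], lam * sqrt(phi) / sqrt(lam^2 * phi + s2),
               ignore_attr = TRUE)
  phi1 <- flat[, "phi[1,1]"]
  s21 <- flat[, "sigma2_1[F1_I1]"]
  expect_equal(std[, "F1_I1"], sqrt(phi1) / sqrt(phi1 + s21),
               ignore_attr = TRUE)
  # summary is the mean of the draws
  smry <- standardized_loadings(fit)
  expect_equal(smry$estimate, unname(colMeans(std)))
  expect_true(all(smry$conf.low < smry$estimate &
                    smry$estimate < smry$conf.high))
})

test_that("baseline CFA recovers standardized loadings on clean data", {
  sim <- generate_dataset(sim_design(n_persons = 600, n_factors = 2,
                                     prop_bots = 0, seed = 47))
  fit <- fit_cfa_baseline(sim$data,
                          mcmc = mcmc_settings(n_chains = 2, n_iter = 1500,
                                               n_burnin = 750, seed = 2))
  expect_s3_class(fit, "cfa_fit")
  # no mixture blocks monitored
  expect_false(any(grepl("^beta|^tau2|^sigma2_2", fit$param_names)))
  std <- standardized_loadings(fit)
  tru <- true_standardized_loadings(sim$truth)
  expect_equal(std$estimate, tru$loading, tolerance = 0.12)
})

test_that("input validation catches mismatched indices and data", {
  sim <- small_sim(n = 80, seed = 48)
  other <- small_sim(n = 60, seed = 49)
  idx <- suppressWarnings(person_indices(other$data))
  expect_error(fit_lc_cfa(sim$data, indices = idx), "one row per respondent")
})

test_that("binary family fits end to end", {
  set.seed(50)
  n <- 150
  eta <- rnorm(n)
  p1 <- plogis(outer(eta, c(1, 0.8, 1.2)))
  Y <- matrix(rbinom(n * 3, 1, p1), n, 3)
  df <- tibble::as_tibble(as.data.frame(Y))
  names(df) <- c("b1", "b2", "b3")
  df$person_id <- 1:n
  dat <- survey_data(df, c(b1 = 1, b2 = 1, b3 = 1), family = "binary",
                     category_range = c(0, 1))
  fit <- fit_lc_cfa(dat, mcmc = mcmc_settings(n_chains = 2, n_iter = 600,
                                              n_burnin = 300, seed = 9))
  expect_s3_class(fit, "lc_cfa_fit")
  expect_false(any(grepl("^sigma2", fit$param_names)))
  expect_true(all(fit$p_bot >= 0 & fit$p_bot <= 1))
  expect_true(all(is.finite(fit$draws)))
})
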