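test_that("sensitivity and specificity match a hand-computed 2x2 table", {
  truth <- c("bot", "bot", "bot", "human", "human", "human", "human", "bot")
  pred  <- c("bot", "human", "bot", "human", "bot", "human", "human", "bot")
  # TP = 3, FN = 1, TN = 3, FP = 1
  out <- sensitivity_specificity(truth, pred)
  expect_equal(out$sensitivity, 3 / 4)
  expect_equal(out$specificity, 3 / 4)
})

test_that("empty denominators give NA, never zero", {
  out <- sensitivity_specificity(rep("human", 5), rep("human", 5))
  expect_true(is.na(out$sensitivity))
  expect_equal(out$specificity, 1)
  out2 <- sensitivity_specificity(rep("bot", 5), rep("bot", 5))
  expect_true(is.na(out2$specificity))
  expect_equal(out2$sensitivity, 1)
  expect_error(sensitivity_specificity(c("bot", "robot"), c("bot", "bot")),
               "human")
  expect_error(sensitivity_specificity(c("bot"), c("bot", "bot")))
})

test_that("percent bias is the mean of elementwise percent errors", {
  expect_equal(percent_bias(c(1.1, 0.9), c(1, 1)), 0)
  expect_equal(percent_bias(2, 4), -50)
  expect_equal(percent_bias(c(0.5, 0.6), c(0.5, 0.5)), 10)
  expect_warning(b <- percent_bias(c(1, 2), c(1, 0)), "zero true value")
  expect_equal(b, 0)
  expect_warning(b0 <- percent_bias(1, 0))
  expect_true(is.na(b0))
})

test_that("beta_significance flags intervals that exclude zero", {
  set.seed(50)
  draws <- cbind(`beta[0]` = rnorm(4000, 5, 0.5),
                 `beta[1]` = rnorm(4000, 0, 1),
                 `beta[2]` = rnorm(4000, -4, 0.5))
  sig <- beta_significance(draws)
  expect_equal(sig$term, c("beta[0]", "beta[1]", "beta[2]"))
  expect_equal(sig$significant, c(TRUE, FALSE, TRUE))
  expect_true(all(sig$conf.low < sig$conf.high))
  # a wider level can keep a marginal coefficient significant
  sig99 <- beta_significance(draws, level = 0.999)
  expect_false(sig99$significant[2])
})

test_that("study_conditions is the fixed 18-cell grid", {
  g <- study_conditions()
  expect_equal(nrow(g), 18)
  expect_setequal(unique(g$n_factors), c(3L, 6L))
  expect_setequal(unique(g$n_persons), c(200L, 400L, 800L))
  expect_setequal(unique(g$prop_bots), c(0.10, 0.25, 0.50))
  expect_equal(nrow(dplyr::distinct(g)), 18)
})

test_that("run_study is deterministic in its master seed and well-formed", {
  cond <- tibble::tibble(n_factors = 2L, n_persons = 120L, prop_bots = 0.25)
  mc <- mcmc_settings(n_chains = 2, n_iter = 700, n_burnin = 350)
  r1 <- run_study(cond, reps = 2, mcmc = mc, seed = 99, items_per_factor = 4)
  r2 <- run_study(cond, reps = 2, mcmc = mc, seed = 99, items_per_factor = 4)
  expect_equal(r1$replications, r2$replications)
  expect_s3_class(r1, "study_results")
  expect_equal(nrow(r1$replications), 2)
  expect_true(all(c("sensitivity", "specificity", "bias_lambda_lc",
                    "bias_lambda_cfa", "sig_y2", "converged_lc",
                    "communality_mean", "rho")
                  %in% names(r1$replications)))
  expect_equal(nrow(r1$summary), 1)
  # different seed, different replications
  r3 <- run_study(cond, reps = 2, mcmc = mc, seed = 100, items_per_factor = 4)
  expect_false(identical(r1$replications$data_seed, r3$replications$data_seed))
})

test_that("summaries aggregate over converged replications only", {
  reps <- tibble::tibble(
    n_factors = 3L, n_persons = 400L, prop_bots = 0.25,
    rep = 1:4, data_seed = 1:4,
    communality_mean = 0.4, rho = 0.3,
    converged_lc = c(TRUE, TRUE, FALSE, TRUE),
    converged_cfa = c(TRUE, FALSE, TRUE, TRUE),
    sensitivity = c(1, 0.9, 0, 0.95), specificity = c(1, 1, 0, 0.9),
    bias_lambda_lc = c(-1, -2, 50, -3),
    bias_var_lc = 0, bias_rho_lc = 0,
    bias_lambda_cfa = c(-25, 99, -30, -29),
    bias_var_cfa = 0, bias_rho_cfa = 0,
    sig_y1 = c(FALSE, FALSE, TRUE, TRUE),
    sig_y2 = c(TRUE, TRUE, FALSE, TRUE),
    error = NA_character_
  )
  s <- botcfa:::summarize_study(reps)
  expect_equal(s$convergence_rate, 75)
  expect_equal(s$sensitivity, mean(c(1, 0.9, 0.95)))
  expect_equal(s$bias_lambda_lc, mean(c(-1, -2, -3)))
  expect_equal(s$bias_lambda_cfa, mean(c(-25, -30, -29)))
  expect_equal(s$pct_sig_y2, 100)
  expect_equal(s$pct_sig_y1, 100 * mean(c(FALSE, FALSE, TRUE)))
})

test_that("a failing replication is recorded, not fatal", {
  # n_persons = 1 makes the preliminary CFA and sampler impossible
  cond <- tibble::tibble(n_factors = 2L, n_persons = 4L, prop_bots = 0)
  mc <- mcmc_settings(n_chains = 2, n_iter = 60, n_burnin = 30)
  expect_no_error({
    r <- suppressWarnings(
      run_study(cond, reps = 1, mcmc = mc, seed = 1, items_per_factor = 2)
    )
  })
  expect_equal(nrow(r$replications), 1)
  expect_false(r$replications$converged_lc)
})

test_that("filter_breakdown drops extreme variance-bias replications", {
  reps <- tibble::tibble(
    n_factors = 6L, n_persons = 200L, prop_bots = 0.5,
    rep = 1:3, data_seed = 1:3, communality_mean = 0.4, rho = 0.3,
    converged_lc = TRUE, converged_cfa = TRUE,
    sensitivity = c(0.9, 0.5, 0.95), specificity = c(0.9, 0.5, 0.95),
    bias_lambda_lc = c(-2, 80, -1), bias_var_lc = c(10, 900, -5),
    bias_rho_lc = 0,
    bias_lambda_cfa = -25, bias_var_cfa = 0, bias_rho_cfa = 0,
    sig_y1 = FALSE, sig_y2 = TRUE, error = NA_character_
  )
  res <- structure(list(replications = reps,
                        summary = botcfa:::summarize_study(reps)),
                   class = "study_results")
  filt <- filter_breakdown(res, cutoff = 200)
  expect_equal(nrow(filt$replications), 2)
  expect_equal(filt$summary$sensitivity, mean(c(0.9, 0.95)))
})
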