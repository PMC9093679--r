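test_that("model_spec validates the map and sets the link", {
  map <- c(a = 1, b = 1, c = 2, d = 2)
  sp <- model_spec(map)
  expect_equal(sp$family, "continuous")
  expect_equal(sp$link, "identity")
  expect_equal(sp$n_classes, 2L)
  expect_equal(model_spec(map, family = "binary")$link, "logit")
  expect_equal(model_spec(map, family = "count")$link, "log")
  expect_error(model_spec(c(1, 1, 2)), "named")
  expect_error(model_spec(c(a = 1, b = 3)), "1..m")
})

test_that("prior and mcmc settings carry the documented defaults", {
  pr <- prior_settings()
  expect_equal(pr$tau_var, 1)
  expect_equal(pr$lambda_var, 1)
  expect_equal(pr$beta_var, 10)
  expect_equal(pr$gamma_shape, 9)
  expect_equal(pr$gamma_rate, 4)
  expect_error(prior_settings(tau_var = 0))
  mc <- mcmc_settings()
  expect_equal(mc$n_chains, 3L)
  expect_equal(mc$n_iter, 12000L)
  expect_equal(mc$n_burnin, 6000L)
  expect_error(mcmc_settings(n_chains = 1), "n_chains")
  expect_error(mcmc_settings(n_iter = 100, n_burnin = 100))
})

test_that("class_probability is the logistic of the linear predictor", {
  expect_equal(class_probability(2, 1, c(0, 1, -1)), plogis(1))
  expect_equal(class_probability(0, 0, c(0, 0, 0)), 0.5)
  # vectorized and monotone in y2 for negative beta2
  p <- class_probability(0, c(-1, 0, 1), c(0.5, 0, -2))
  expect_true(all(diff(p) < 0))
  expect_equal(p[2], plogis(0.5))
  expect_error(class_probability(1, 1, c(0, 1)), "length")
})

test_that("continuous mixture log-likelihood matches a brute-force sum", {
  # 2-item, 1-factor toy with hand-assembled densities
  map <- c(i1 = 1, i2 = 1)
  sp <- model_spec(map)
  theta <- list(tau1 = c(0.2, -0.1), lambda = c(1, 0.8),
                Phi = matrix(0.9), sigma2_1 = c(0.5, 0.7),
                tau2 = c(0, 0), sigma2_2 = c(2, 2))
  y <- c(1.3, -0.4)
  pi_i <- 0.73
  Sig1 <- matrix(c(1 * 1, 1 * 0.8, 0.8 * 1, 0.8 * 0.8), 2) * 0.9 +
    diag(c(0.5, 0.7))
  f1 <- exp(-0.5 * (log(det(2 * pi * Sig1)) +
                      drop((y - theta$tau1) %*% solve(Sig1, y - theta$tau1))))
  f2 <- prod(dnorm(y, 0, sqrt(2)))
  expect_equal(mixture_loglik_person(y, theta, pi_i, sp),
               log(pi_i * f1 + (1 - pi_i) * f2), tolerance = 1e-10)
  # boundary probabilities collapse onto one component
  expect_equal(mixture_loglik_person(y, theta, 1, sp), log(f1),
               tolerance = 1e-10)
  expect_equal(mixture_loglik_person(y, theta, 0, sp), log(f2),
               tolerance = 1e-10)
})

test_that("binary mixture log-likelihood matches brute-force integration", {
  map <- c(i1 = 1, i2 = 1)
  sp <- model_spec(map, family = "binary")
  theta <- list(tau1 = c(0.3, -0.2), lambda = c(1, 1.4), Phi = matrix(0.6),
                tau2 = c(0.1, 0.1))
  y <- c(1, 0)
  # brute force: integrate the Bernoulli product over eta ~ N(0, 0.6)
  f1 <- integrate(function(e) {
    p1 <- plogis(0.3 + e); p2 <- plogis(-0.2 + 1.4 * e)
    p1 * (1 - p2) * dnorm(e, 0, sqrt(0.6))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  f2 <- plogis(0.1) * (1 - plogis(0.1))
  expect_equal(mixture_loglik_person(y, theta, 0.4, sp, n_nodes = 41),
               log(0.4 * f1 + 0.6 * f2), tolerance = 1e-8)
})

test_that("Gauss-Hermite rule integrates standard-normal moments exactly", {
  gh <- botcfa:::gauss_hermite_prob(21)
  expect_equal(sum(gh$weights), 1, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 3, tolerance = 1e-8)
})

test_that("logsumexp is stable and exact", {
  expect_equal(botcfa:::logsumexp(c(0, 0)), log(2))
  expect_equal(botcfa:::logsumexp(c(-1000, -1000)), log(2) - 1000)
  expect_equal(botcfa:::logsumexp(c(-1e4, 0)), 0, tolerance = 1e-12)
})
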