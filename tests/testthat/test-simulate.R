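test_that("sim_design validates its inputs", {
  expect_s3_class(sim_design(n_persons = 100), "sim_design")
  expect_error(sim_design(n_persons = 100, prop_bots = 1.2), "prop_bots")
  expect_error(sim_design(n_persons = 100, thresholds = c(1, 0, 2, 3, 4)),
               "increasing")
  expect_error(sim_design(n_persons = 100, thresholds = c(-1, 0, 1)),
               "length")
  expect_error(sim_design(n_persons = 100, communality_range = c(0, 0.6)),
               "communality_range")
})

test_that("generate_dataset has the exact deterministic bot count", {
  for (n in c(97, 100, 400)) {
    sim <- generate_dataset(sim_design(n_persons = n, prop_bots = 0.25,
                                       seed = 5))
    expect_equal(sum(sim$truth$class_labels == "bot"), round(0.25 * n))
    expect_equal(nrow(sim$data$responses), n)
  }
  sim0 <- generate_dataset(sim_design(n_persons = 120, prop_bots = 0,
                                      seed = 5))
  expect_equal(sum(sim0$truth$class_labels == "bot"), 0)
})

test_that("responses stay on the 1..K category grid", {
  sim <- generate_dataset(sim_design(n_persons = 300, prop_bots = 0.5,
                                     seed = 11))
  Y <- as.matrix(sim$data$responses[, -1])
  expect_true(all(Y %in% 1:6))
  expect_equal(sort(unique(as.vector(Y))), 1:6)
})

test_that("the seed makes the whole dataset replay bit-identically", {
  d <- sim_design(n_persons = 150, prop_bots = 0.25, seed = 77)
  s1 <- generate_dataset(d)
  s2 <- generate_dataset(d)
  expect_identical(s1$data$responses, s2$data$responses)
  expect_identical(s1$truth$class_labels, s2$truth$class_labels)
  expect_identical(s1$truth$loading_matrix, s2$truth$loading_matrix)
  s3 <- generate_dataset(sim_design(n_persons = 150, prop_bots = 0.25,
                                    seed = 78))
  expect_false(identical(s1$data$responses, s3$data$responses))
})

test_that("random design factors respect their intervals", {
  d <- sim_design(n_persons = 50, seed = NULL)
  set.seed(1)
  for (i in 1:25) {
    rf <- sample_design_factors(d)
    expect_gte(rf$communality_mean, 0.25)
    expect_lte(rf$communality_mean, 0.64)
    expect_gte(rf$rho, 0)
    expect_lte(rf$rho, 0.7)
  }
})

test_that("generating parameters are standardized simple structure", {
  d <- sim_design(n_persons = 50, n_factors = 3)
  set.seed(3)
  tp <- build_true_parameters(d, communality_mean = 0.45, rho = 0.3)
  L <- tp$loading_matrix
  expect_equal(dim(L), c(18, 3))
  # simple structure: one nonzero loading per item
  expect_true(all(rowSums(L != 0) == 1))
  # unit latent item variance: lambda^2 + residual = 1
  expect_equal(rowSums(L^2) + tp$residual_variances, rep(1, 18),
               ignore_attr = TRUE)
  # communalities stay inside the drawn band (clipped)
  h2 <- rowSums(L^2)
  expect_true(all(h2 >= 0.3 - 1e-12 & h2 <= 0.6 + 1e-12))
  expect_equal(unname(tp$factor_cov[1, 2]), 0.3)
  expect_equal(unname(diag(tp$factor_cov)), rep(1, 3))
  expect_equal(true_standardized_loadings(tp)$loading, unname(sqrt(h2)))
})

test_that("thresholding maps latent values to categories by findInterval", {
  # a zero-communality-free check through the exported generator:
  # with thresholds (-2,-1,0,1,2) a standard-normal latent response puts
  # pnorm masses on the six categories
  d <- sim_design(n_persons = 10, n_factors = 1, items_per_factor = 2)
  set.seed(4)
  tp <- build_true_parameters(d, communality_mean = 0.4, rho = 0)
  set.seed(5)
  y <- generate_human_responses(tp, 40000, c(-2, -1, 0, 1, 2))
  expect_true(all(y %in% 1:6))
  # latent responses are standard normal, so category 1 has mass pnorm(-2)
  expect_equal(mean(y == 1), pnorm(-2), tolerance = 0.05)
  expect_equal(mean(y <= 3), 0.5, tolerance = 0.02)
})

test_that("bot rows are uniform over categories and independent of structure", {
  set.seed(6)
  B <- generate_bot_responses(20000, 6, 6)
  expect_equal(dim(B), c(20000, 6))
  freq <- table(B) / length(B)
  expect_true(all(abs(freq - 1 / 6) < 0.01))
  # within-factor variability of a uniform row has mean 35/12
  v <- apply(B, 1, var)
  expect_equal(mean(v), 35 / 12, tolerance = 0.02)
})

test_that("humans induce within-factor correlation, bots none", {
  sim <- generate_dataset(sim_design(n_persons = 2000, n_factors = 3,
                                     prop_bots = 0.5, seed = 21))
  Y <- as.matrix(sim$data$responses[, -1])
  hum <- sim$truth$class_labels == "human"
  Rh <- cor(Y[hum, 1:6])
  Rb <- cor(Y[!hum, 1:6])
  expect_gt(mean(Rh[upper.tri(Rh)]), 0.15)
  expect_lt(max(abs(Rb[upper.tri(Rb)])), 0.12)
})
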