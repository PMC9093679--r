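# Shared helpers for the test suite.

# Small simulated dataset used by several unit tests.
small_sim <- function(n = 150, m = 3, prop_bots = 0.25, seed = 101) {
  generate_dataset(sim_design(
    n_persons = n, n_factors = m, prop_bots = prop_bots, seed = seed
  ))
}

# Short-chain MCMC settings for unit tests (not used for acceptance runs).
fast_mcmc <- function(seed = 1) {
  mcmc_settings(n_chains = 2, n_iter = 1200, n_burnin = 600, seed = seed)
}

# Deterministic fixture chains for the diagnostics oracle tests. The frozen
# reference values in test-diagnostics.R were computed for exactly these
# matrices by an independent reference implementation (arviz 0.23.4,
# rank-normalized split-Rhat and bulk ESS).
oracle_chains <- function() {
  set.seed(424242)
  iters <- 250
  chains <- 4
  x1 <- matrix(rnorm(iters * chains), iters, chains)
  x2 <- matrix(0, iters, chains)
  for (ch in 1:chains) {
    e <- rnorm(iters)
    for (t in 2:iters) x2[t, ch] <- 0.8 * x2[t - 1, ch] + e[t]
  }
  x3 <- matrix(rnorm(iters * chains), iters, chains) +
    outer(seq_len(iters) / iters, c(0, 0.5, 1, 2))
  x4 <- matrix(rt(iters * chains, df = 3), iters, chains)
  x5 <- matrix(exp(rnorm(iters * chains)), iters, chains)
  list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5)
}
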