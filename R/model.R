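#' Measurement-model specification
#'
#' Declares the two-class measurement model: class 1 is a simple-structure
#' CFA (`g(mu_ij) = tau_j1 + lambda_j eta_i`, the first mapped loading of
#' each factor fixed to 1 and factor means fixed to 0), class 2 is
#' intercept-only (`g(mu_ij) = tau_j2`). The number of classes is fixed at
#' two; class membership is predicted from the person indices.
#'
#' @param item_factor_map Named integer vector, item name -> factor index.
#' @param family `"continuous"` (identity link, normal), `"binary"` (logit,
#'   Bernoulli) or `"count"` (log, Poisson).
#' @param predictors Names of the class-model covariates (default the two
#'   person indices `y1`, `y2`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(item_factor_map,
                       family = c("continuous", "binary", "count"),
                       predictors = c("y1", "y2")) {
  family <- match.arg(family)
  fac <- as.integer(item_factor_map)
  if (is.null(names(item_factor_map))) stop("`item_factor_map` must be named")
  names(fac) <- names(item_factor_map)
  m <- max(fac)
  if (!setequal(unique(fac), seq_len(m))) {
    stop("factor indices must be 1..m with every factor used")
  }
  link <- switch(family, continuous = "identity", binary = "logit", count = "log")
  structure(
    list(item_factor_map = fac, family = family, link = link,
         n_classes = 2L, predictors = predictors),
    class = "model_spec"
  )
}

#' Prior settings for the Bayesian models
#'
#' Weakly informative defaults: intercepts `tau_jc ~ N(0, 1)`, free loadings
#' `lambda_jk ~ N(0, 1)` truncated positive, factor precision
#' `Phi^-1 ~ Wishart(I_m, m)`, class-model coefficients `beta_r ~ N(0, 10)`
#' (variance 10), residual precisions `sigma_jc^-2 ~ Gamma(9, 4)` for the
#' continuous family. All hyperparameters can be overridden.
#'
#' @param tau_mean,tau_var Intercept prior mean and variance.
#' @param lambda_var Variance of the positive-truncated loading prior.
#' @param wishart_scale Scale matrix of the Wishart prior on the factor
#'   precision (`NULL` = identity of the right dimension).
#' @param wishart_df Wishart degrees of freedom (`NULL` = number of factors,
#'   the minimal proper choice).
#' @param beta_var Variance of the class-model coefficient priors.
#' @param gamma_shape,gamma_rate Gamma prior on residual precisions.
#' @return An object of class `prior_settings`.
#' @export
prior_settings <- function(tau_mean = 0, tau_var = 1, lambda_var = 1,
                           wishart_scale = NULL, wishart_df = NULL,
                           beta_var = 10, gamma_shape = 9, gamma_rate = 4) {
  stopifnot(tau_var > 0, lambda_var > 0, beta_var > 0,
            gamma_shape > 0, gamma_rate > 0)
  structure(
    list(tau_mean = tau_mean, tau_var = tau_var, lambda_var = lambda_var,
         wishart_scale = wishart_scale, wishart_df = wishart_df,
         beta_var = beta_var, gamma_shape = gamma_shape,
         gamma_rate = gamma_rate),
    class = "prior_settings"
  )
}

#' MCMC settings
#'
#' Defaults mirror the reference analysis: three chains of 12,000 iterations,
#' the first 6,000 discarded as burn-in. The study runner scales these down.
#'
#' @param n_chains Number of chains (>= 2, required by split-Rhat).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param seed Integer seed; chain `k` is run under `seed + k - 1`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 12000, n_burnin = 6000,
                          seed = 1) {
  stopifnot(n_chains >= 2, n_burnin >= 0, n_iter > n_burnin)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burnin = as.integer(n_burnin), seed = as.integer(seed)),
    class = "mcmc_settings"
  )
}

#' Probability of attentive-class membership
#'
#' The multinomial-logistic class model with two classes:
#' `P(C = 1 | y1, y2) = expit(beta0 + beta1 y1 + beta2 y2)`.
#'
#' @param y1,y2 Person-index values (vectorized).
#' @param beta Coefficient vector `(beta0, beta1, beta2)`.
#' @return `P(C = 1)`, elementwise.
#' @export
#' @examples
#' class_probability(2, 1, c(0, 1, -1))  # expit(1)
class_probability <- function(y1, y2, beta) {
  stopifnot(length(beta) == 3, all(is.finite(y1)), all(is.finite(y2)))
  stats::plogis(beta[1] + beta[2] * y1 + beta[3] * y2)
}

#' Mixture log-likelihood of one response vector
#'
#' `log(pi f1(y | theta) + (1 - pi) f2(y | theta))`. For the continuous
#' family `f1` is the factor-marginalized multivariate normal density
#' `MVN(tau1, Lambda Phi Lambda' + diag(sigma1^2))` and `f2` a product of
#' univariate normals `N(tau_j2, sigma_j2^2)`. For binary/count families the
#' factors are integrated numerically (Gauss-Hermite product rule for up to
#' three factors, Monte Carlo beyond).
#'
#' @param y Response vector of length p.
#' @param theta List with `tau1`, `lambda` (p x m loading matrix or the
#'   length-p nonzero loadings), `Phi`, `sigma2_1`, `tau2`, `sigma2_2` (the
#'   sigma components for the continuous family only).
#' @param pi_i Prior probability of class 1 for this person (in `[0, 1]`;
#'   the boundary values collapse the mixture onto one component).
#' @param spec A [model_spec()].
#' @param n_nodes Gauss-Hermite nodes per dimension (binary/count).
#' @return The log mixture density (scalar).
#' @export
mixture_loglik_person <- function(y, theta, pi_i, spec, n_nodes = 21) {
  stopifnot(inherits(spec, "model_spec"), pi_i >= 0, pi_i <= 1)
  map <- spec$item_factor_map
  p <- length(map); m <- max(map)
  L <- theta$lambda
  if (is.null(dim(L))) {
    lam <- L
    L <- matrix(0, p, m)
    L[cbind(seq_len(p), unname(map))] <- lam
  }
  if (spec$family == "continuous") {
    Sig1 <- L %*% theta$Phi %*% t(L) + diag(theta$sigma2_1, p)
    l1 <- individual_loglik(y, theta$tau1, Sig1)
    l2 <- sum(stats::dnorm(y, theta$tau2, sqrt(theta$sigma2_2), log = TRUE))
  } else {
    cell_ll <- function(y, x) {
      if (spec$family == "binary") y * x - log1p(exp(x))
      else y * x - exp(x) - lgamma(y + 1)
    }
    eta_ll <- function(eta_mat) {  # rows = nodes/draws
      mu <- matrix(theta$tau1, nrow(eta_mat), p, byrow = TRUE) +
        eta_mat %*% t(L)
      rowSums(cell_ll(matrix(y, nrow(eta_mat), p, byrow = TRUE), mu))
    }
    if (m <= 3) {
      gh <- gauss_hermite_prob(n_nodes)
      grids <- rep(list(seq_len(n_nodes)), m)
      idx <- as.matrix(expand.grid(grids))
      z <- matrix(gh$nodes[idx], ncol = m)
      lw <- rowSums(matrix(log(gh$weights[idx]), ncol = m))
      eta_mat <- z %*% chol(theta$Phi)
      ll <- eta_ll(eta_mat) + lw
      l1 <- logsumexp(ll)
    } else {
      z <- matrix(stats::rnorm(4000 * m), ncol = m) %*% chol(theta$Phi)
      l1 <- logsumexp(eta_ll(z)) - log(4000)
    }
    l2 <- sum(cell_ll(y, theta$tau2))
  }
  if (pi_i == 1) return(l1)
  if (pi_i == 0) return(l2)
  logsumexp(c(log(pi_i) + l1, log(1 - pi_i) + l2))
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Gauss-Hermite nodes/weights for the standard normal (probabilists' scale),
# via the Golub-Welsch eigenvalue method.
gauss_hermite_prob <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i)
  J[cbind(i + 1, i)] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}
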