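#' Fit the latent-class CFA mixture by MCMC
#'
#' Estimates the two-class mixture — class 1 a simple-structure CFA, class 2
#' an intercept-only random-response model — with class membership predicted
#' from the person indices through a logistic model. Sampling is Gibbs with
#' conjugate updates (continuous family); the class-model coefficients are
#' drawn by independence Metropolis-Hastings from a multivariate-t Laplace
#' approximation of their conditional posterior, and parameter-expansion
#' moves rescale and recentre each factor jointly with its loadings and
#' intercepts to break the scale/location ridges of the CFA. Binary and
#' count families use Metropolis-within-Gibbs for the measurement parameters
#' and latent factors. Chains start from the preliminary ML CFA solution
#' (class-1 parameters) with per-chain jitter, and the class model starts in
#' the basin where class 1 means "attentive".
#'
#' Per-person posterior bot probabilities are computed at every kept draw by
#' Bayes' rule from the two component densities and the class-model
#' probability, then averaged over draws. Convergence is declared when the
#' rank-normalized split-Rhat of every monitored parameter is below 1.01;
#' a nonconvergent fit is returned with `converged = FALSE`, never silently.
#'
#' @param data A [survey_data()].
#' @param indices Optional [person_indices()] computed on the same data
#'   (computed, standardized, when `NULL`).
#' @param spec Optional [model_spec()] (derived from `data` when `NULL`).
#' @param priors A [prior_settings()].
#' @param mcmc An [mcmc_settings()].
#' @param threshold Classification threshold on the posterior bot
#'   probability (default 0.5; ties go to "human").
#' @return An object of class `lc_cfa_fit`; see [tidy.lc_cfa_fit()],
#'   [glance.lc_cfa_fit()], [classify_persons()], [standardized_loadings()].
#' @export
#' @examples
#' \donttest{
#' sim <- generate_dataset(sim_design(n_persons = 150, prop_bots = 0.25, seed = 1))
#' fit <- fit_lc_cfa(sim$data, mcmc = mcmc_settings(n_iter = 1500, n_burnin = 750))
#' glance(fit)
#' }
fit_lc_cfa <- function(data, indices = NULL, spec = NULL,
                       priors = prior_settings(), mcmc = mcmc_settings(),
                       threshold = 0.5) {
  stopifnot(inherits(data, "survey_data"))
  if (is.null(spec)) spec <- model_spec(data$item_factor_map, data$family)
  if (is.null(indices)) indices <- person_indices(data)
  if (nrow(indices) != nrow(data$responses)) {
    stop("`indices` must have one row per respondent of `data`")
  }
  X <- cbind(1, indices$y1, indices$y2)
  res <- run_sampler(data, spec, priors, mcmc, X = X, mixture = TRUE)
  p_bot <- res$p_bot
  cls <- tibble::tibble(person_id = data$responses$person_id, p_bot = p_bot,
                        class = ifelse(p_bot > threshold, "bot", "human"))
  beta_idx <- grep("^beta\\[", res$param_names)
  beta_draws <- apply(res$draws[, , beta_idx, drop = FALSE], 3, identity)
  beta_summary <- tibble::tibble(
    term = res$param_names[beta_idx],
    estimate = colMeans(beta_draws),
    conf.low = apply(beta_draws, 2, stats::quantile, 0.025),
    conf.high = apply(beta_draws, 2, stats::quantile, 0.975)
  )
  out <- c(res, list(indices = indices, threshold = threshold,
                     classification = cls, beta_summary = beta_summary,
                     spec = spec, priors = priors, mcmc = mcmc,
                     person_id = data$responses$person_id))
  class(out) <- c("lc_cfa_fit", "botcfa_fit")
  out
}

#' Fit the naive one-class Bayesian CFA baseline
#'
#' The standard Bayesian CFA: identical to the class-1 part of the mixture
#' (same likelihood, identification and priors) with every respondent treated
#' as attentive. Used to quantify the parameter bias a researcher incurs by
#' ignoring bots.
#'
#' @inheritParams fit_lc_cfa
#' @return An object of class `cfa_fit`.
#' @export
fit_cfa_baseline <- function(data, spec = NULL, priors = prior_settings(),
                             mcmc = mcmc_settings()) {
  stopifnot(inherits(data, "survey_data"))
  if (is.null(spec)) spec <- model_spec(data$item_factor_map, data$family)
  res <- run_sampler(data, spec, priors, mcmc, X = NULL, mixture = FALSE)
  out <- c(res, list(spec = spec, priors = priors, mcmc = mcmc,
                     person_id = data$responses$person_id))
  class(out) <- c("cfa_fit", "botcfa_fit")
  out
}

# Shared chain runner: builds inits, runs n_chains seeded chains, assembles
# the draw array and diagnostics.
run_sampler <- function(data, spec, priors, mcmc, X, mixture) {
  Y <- resp_matrix(data)
  map <- spec$item_factor_map
  if (!identical(names(map), names(data$item_factor_map))) {
    stop("`spec$item_factor_map` does not match the items of `data`")
  }
  N <- nrow(Y); p <- ncol(Y); m <- max(map)
  family_code <- match(spec$family, c("continuous", "binary", "count")) - 1L
  has_sigma <- spec$family == "continuous"
  wish_scale <- priors$wishart_scale %||% diag(m)
  wish_df <- priors$wishart_df %||% m
  if (wish_df < m) stop("Wishart df must be >= number of factors")
  pr <- list(tau_mean = priors$tau_mean, tau_var = priors$tau_var,
             lambda_var = priors$lambda_var, beta_var = priors$beta_var,
             gamma_shape = priors$gamma_shape, gamma_rate = priors$gamma_rate,
             wishart_scale = wish_scale, wishart_df = wish_df)
  base_init <- build_inits(Y, map, spec$family)
  if (is.null(X)) {
    X <- matrix(0, N, 3)
  } else {
    # start the chains in the basin where class 2 means "random responder":
    # the top 10% by the variability index begin in class 2, the class-2
    # measurement parameters describe those rows, and the class-model
    # coefficients come from a logistic fit to the starting indicators.
    # Without this, a chain can empty class 2 early on and get stuck in the
    # degenerate "everyone attentive" mode.
    base_init$C <- ifelse(X[, 3] > stats::quantile(X[, 3], 0.9), 2L, 1L)
    flagged <- base_init$C == 2L
    if (spec$family == "continuous" && sum(flagged) >= 3) {
      base_init$tau2 <- colMeans(Y[flagged, , drop = FALSE])
      base_init$sigma2_2 <- pmax(apply(Y[flagged, , drop = FALSE], 2,
                                       stats::var), 0.05)
    }
    glm_fit <- tryCatch(suppressWarnings(stats::glm.fit(
      X, as.numeric(!flagged), family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(glm_fit)) {
      base_init$beta <- pmin(pmax(glm_fit$coefficients, -5), 5)
    }
  }

  keep <- mcmc$n_iter - mcmc$n_burnin
  nm <- sampler_par_names(names(map), map, mixture, has_sigma)
  draws <- array(NA_real_, c(keep, mcmc$n_chains, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  p_bot <- matrix(0, N, mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    init <- jitter_inits(base_init, amount = 0.05 * (ch - 1))
    run <- lc_cfa_chain(Y, unname(map), X, family_code, mixture, pr,
                        mcmc$n_iter, mcmc$n_burnin, init)
    draws[, ch, ] <- run$draws
    p_bot[, ch] <- run$p_bot
  }
  diag_tbl <- tibble::tibble(
    term = nm,
    rhat = vapply(seq_along(nm), function(k) split_rhat(draws[, , k]),
                  numeric(1)),
    ess = vapply(seq_along(nm), function(k) effective_sample_size(draws[, , k]),
                 numeric(1))
  )
  max_rhat <- max(diag_tbl$rhat, na.rm = TRUE)
  list(draws = draws, param_names = nm, diagnostics = diag_tbl,
       p_bot = rowMeans(p_bot), converged = max_rhat < 1.01,
       max_rhat = max_rhat, n = N)
}

sampler_par_names <- function(items, map, mixture, has_sigma) {
  m <- max(map)
  first <- !duplicated(unname(map))
  phi_nm <- unlist(lapply(seq_len(m), function(cc)
    paste0("phi[", cc:m, ",", cc, "]")))
  nm <- c(paste0("tau1[", items, "]"),
          paste0("lambda[", items[!first], "]"),
          phi_nm)
  if (has_sigma) nm <- c(nm, paste0("sigma2_1[", items, "]"))
  if (mixture) {
    nm <- c(nm, paste0("tau2[", items, "]"))
    if (has_sigma) nm <- c(nm, paste0("sigma2_2[", items, "]"))
    nm <- c(nm, paste0("beta[", 0:2, "]"))
  }
  nm
}

build_inits <- function(Y, map, family) {
  N <- nrow(Y); p <- ncol(Y); m <- max(map)
  first <- !duplicated(unname(map))
  lam <- rep(1, p)
  Phi <- diag(m)
  s2 <- rep(1, p)
  if (family == "continuous") {
    dat <- survey_data(as.data.frame(Y), map, family = "continuous")
    fit <- tryCatch(suppressWarnings(fit_ml_cfa(dat)), error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      lam_hat <- rowSums(fit$loadings)
      lam <- pmin(pmax(lam_hat, 0.01), 10)
      lam[first] <- 1
      Phi <- fit$factor_cov
      s2 <- pmax(fit$residual_variances, 0.05)
    }
    tau1 <- colMeans(Y)
    tau2 <- colMeans(Y)
    s2_2 <- pmax(apply(Y, 2, stats::var), 0.05)
  } else if (family == "binary") {
    pr <- pmin(pmax(colMeans(Y), 0.02), 0.98)
    tau1 <- tau2 <- stats::qlogis(pr)
    lam[!first] <- 0.5
    s2_2 <- rep(1, p)
  } else {
    tau1 <- tau2 <- log(pmax(colMeans(Y), 0.05))
    lam[!first] <- 0.5
    s2_2 <- rep(1, p)
  }
  list(lambda = lam, tau1 = tau1, tau2 = tau2, sigma2_1 = s2, sigma2_2 = s2_2,
       Phi = Phi, beta = c(stats::qlogis(0.9), 0, 0),
       eta = matrix(0, N, m), C = rep(1L, N), fixed = first)
}

# Overdisperse chain starting points: chain 1 starts at the preliminary
# solution, later chains add increasing jitter.
jitter_inits <- function(init, amount) {
  if (amount <= 0) return(init)
  p <- length(init$tau1)
  init$tau1 <- init$tau1 + stats::rnorm(p, 0, amount)
  init$tau2 <- init$tau2 + stats::rnorm(p, 0, amount)
  lam_jit <- init$lambda * exp(stats::rnorm(p, 0, amount))
  init$lambda <- ifelse(init$fixed, 1, lam_jit)
  init$sigma2_1 <- init$sigma2_1 * exp(stats::rnorm(p, 0, amount))
  init$sigma2_2 <- init$sigma2_2 * exp(stats::rnorm(p, 0, amount))
  init$beta <- init$beta + stats::rnorm(3, 0, 2 * amount)
  init
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify respondents from a fitted mixture
#'
#' A respondent is flagged as a bot when the posterior bot probability
#' strictly exceeds the threshold; a probability exactly at the threshold is
#' conservatively kept as human.
#'
#' @param fit An [fit_lc_cfa()] result.
#' @param threshold Probability cut point in (0, 1).
#' @return A tibble with `person_id`, `p_bot`, `class`.
#' @export
classify_persons <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "lc_cfa_fit"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  tibble::tibble(person_id = fit$person_id, p_bot = fit$p_bot,
                 class = ifelse(fit$p_bot > threshold, "bot", "human"))
}

#' Standardized class-1 factor loadings
#'
#' Computed per posterior draw as
#' `lambda_jk sqrt(Phi_kk) / sqrt(lambda_jk^2 Phi_kk + sigma_j1^2)` and then
#' summarized. Continuous family only (the standardization uses the residual
#' variance).
#'
#' @param fit An `lc_cfa_fit` or `cfa_fit`.
#' @param summarize If `FALSE`, return the matrix of per-draw standardized
#'   loadings (all chains pooled) instead of the summary tibble.
#' @return A tibble with `item`, `factor`, `estimate`, `sd`, `conf.low`,
#'   `conf.high` (or a draws matrix).
#' @export
standardized_loadings <- function(fit, summarize = TRUE) {
  stopifnot(inherits(fit, "botcfa_fit"))
  if (fit$spec$family != "continuous") {
    stop("standardized loadings are defined for the continuous family")
  }
  map <- fit$spec$item_factor_map
  items <- names(map); p <- length(items); m <- max(map)
  nm <- fit$param_names
  flat <- do.call(rbind, lapply(seq_len(dim(fit$draws)[2]),
                                function(ch) fit$draws[, ch, ]))
  colnames(flat) <- nm
  first <- !duplicated(unname(map))
  lam <- matrix(1, nrow(flat), p)
  lam[, !first] <- flat[, paste0("lambda[", items[!first], "]"), drop = FALSE]
  phi_kk <- flat[, paste0("phi[", unname(map), ",", unname(map), "]"),
                 drop = FALSE]
  s2 <- flat[, paste0("sigma2_1[", items, "]"), drop = FALSE]
  num <- lam * sqrt(phi_kk)
  denom2 <- lam^2 * phi_kk + s2
  if (any(denom2 <= 0)) stop("nonpositive implied item variance in draws")
  std <- num / sqrt(denom2)
  colnames(std) <- items
  if (!summarize) return(std)
  tibble::tibble(
    item = items, factor = as.integer(unname(map)),
    estimate = unname(colMeans(std)),
    sd = unname(apply(std, 2, stats::sd)),
    conf.low = unname(apply(std, 2, stats::quantile, 0.025)),
    conf.high = unname(apply(std, 2, stats::quantile, 0.975))
  )
}

#' @export
print.lc_cfa_fit <- function(x, ...) {
  cat("<lc_cfa_fit> N = ", x$n, ", ", max(x$spec$item_factor_map),
      " factor(s), family = ", x$spec$family, "\n",
      "  chains = ", x$mcmc$n_chains, " x ", x$mcmc$n_iter,
      " (burn-in ", x$mcmc$n_burnin, "); converged = ", x$converged,
      " (max Rhat = ", round(x$max_rhat, 4), ")\n",
      "  classified bot: ", sum(x$classification$class == "bot"),
      " of ", x$n, " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("<cfa_fit> N = ", x$n, ", ", max(x$spec$item_factor_map),
      " factor(s), family = ", x$spec$family, "; converged = ", x$converged,
      " (max Rhat = ", round(x$max_rhat, 4), ")\n", sep = "")
  invisible(x)
}
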