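#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

posterior_summary_tbl <- function(fit) {
  flat <- do.call(rbind, lapply(seq_len(dim(fit$draws)[2]),
                                function(ch) fit$draws[, ch, ]))
  colnames(flat) <- fit$param_names
  tibble::tibble(
    term = fit$param_names,
    estimate = unname(colMeans(flat)),
    std.error = unname(apply(flat, 2, stats::sd)),
    conf.low = unname(apply(flat, 2, stats::quantile, 0.025)),
    conf.high = unname(apply(flat, 2, stats::quantile, 0.975)),
    rhat = fit$diagnostics$rhat,
    ess = fit$diagnostics$ess
  )
}

#' Tidy posterior summaries of a fitted latent-class CFA
#'
#' One row per monitored parameter: posterior mean, SD, central 95% credible
#' interval, split-Rhat and bulk ESS.
#'
#' @param x An `lc_cfa_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lc_cfa_fit <- function(x, ...) posterior_summary_tbl(x)

#' @rdname tidy.lc_cfa_fit
#' @export
tidy.cfa_fit <- function(x, ...) posterior_summary_tbl(x)

#' One-row summary of a fitted latent-class CFA
#'
#' @param x An `lc_cfa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample size, bot count at the stored
#'   threshold, convergence flag, worst Rhat and smallest ESS.
#' @export
glance.lc_cfa_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_bot = sum(x$classification$class == "bot"),
    prop_bot = mean(x$classification$class == "bot"),
    converged = x$converged, max_rhat = x$max_rhat,
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    n_chains = x$mcmc$n_chains, n_iter = x$mcmc$n_iter,
    n_burnin = x$mcmc$n_burnin
  )
}

#' @rdname glance.lc_cfa_fit
#' @export
glance.cfa_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, converged = x$converged, max_rhat = x$max_rhat,
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    n_chains = x$mcmc$n_chains, n_iter = x$mcmc$n_iter,
    n_burnin = x$mcmc$n_burnin
  )
}

#' Augment respondent data with posterior bot probabilities
#'
#' @param x An `lc_cfa_fit`.
#' @param data The [survey_data()] the model was fitted to.
#' @param ... Unused.
#' @return The response tibble with `.p_bot` and `.class` columns appended.
#' @export
augment.lc_cfa_fit <- function(x, data, ...) {
  stopifnot(inherits(data, "survey_data"))
  out <- data$responses
  out$.p_bot <- x$p_bot
  out$.class <- x$classification$class
  out
}

#' Tidy the preliminary ML CFA
#'
#' @param x A `cfa_ml_fit`.
#' @param ... Unused.
#' @return A tibble of loadings, factor (co)variances and residual variances.
#' @export
tidy.cfa_ml_fit <- function(x, ...) {
  map <- x$item_factor_map
  items <- names(map); m <- ncol(x$loadings)
  lam <- rowSums(x$loadings)
  phi <- x$factor_cov
  phi_terms <- unlist(lapply(seq_len(m), function(cc)
    paste0("phi[", cc:m, ",", cc, "]")))
  phi_vals <- unlist(lapply(seq_len(m), function(cc) phi[cc:m, cc]))
  tibble::tibble(
    term = c(paste0("lambda[", items, "]"), phi_terms,
             paste0("sigma2[", items, "]")),
    estimate = unname(c(lam, phi_vals, x$residual_variances))
  )
}

#' @rdname tidy.cfa_ml_fit
#' @export
glance.cfa_ml_fit <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x$loadings), n_factors = ncol(x$loadings),
    converged = x$converged, loglik = x$loglik
  )
}

#' Tidy study results
#'
#' @param x A `study_results`.
#' @param ... Unused.
#' @return The per-condition summary tibble (convergence rate, sensitivity,
#'   specificity, percent bias by model, percent significant coefficients).
#' @export
tidy.study_results <- function(x, ...) x$summary

#' @rdname tidy.study_results
#' @export
glance.study_results <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$summary),
    n_replications = nrow(x$replications),
    convergence_rate = 100 * mean(x$replications$converged_lc),
    mean_sensitivity = mean(x$replications$sensitivity[
      x$replications$converged_lc], na.rm = TRUE),
    mean_specificity = mean(x$replications$specificity[
      x$replications$converged_lc], na.rm = TRUE)
  )
}
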