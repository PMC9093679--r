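#' Maximum-likelihood CFA on all respondents
#'
#' Fits the simple-structure factor model to the full sample (bots included)
#' by quasi-Newton minimization of the Gaussian discrepancy
#' `log|Sigma| + tr(S Sigma^-1)` with the analytic implied covariance
#' `Sigma = Lambda Phi Lambda' + diag(sigma^2)`. The mean model is saturated,
#' so the implied mean equals the sample mean. Identification fixes the first
#' mapped loading of each factor to 1 and leaves the factor covariance free.
#' This preliminary fit only supplies the implied moments of the
#' likelihood-based person-fit index; integer Likert codes are treated as
#' continuous.
#'
#' Starting values are unit loadings, an identity factor covariance and half
#' the sample variances as residuals; convergence is declared at a relative
#' objective change below 1e-6 within 500 iterations. A near-singular sample
#' covariance is ridge-regularized by `1e-8 * mean(diag(S))`. On failure the
#' fit is returned at the starting values with `converged = FALSE` (the
#' person-fit index is still computable).
#'
#' @param data A [survey_data()].
#' @return An object of class `cfa_ml_fit` with the estimated `loadings`,
#'   `factor_cov`, `residual_variances`, the implied moments (`implied_mean`,
#'   `implied_cov`), the sample moments (`sample_mean`, `sample_cov`,
#'   unbiased denominator), `converged` and `loglik`.
#' @export
fit_ml_cfa <- function(data) {
  stopifnot(inherits(data, "survey_data"))
  Y <- resp_matrix(data)
  map <- data$item_factor_map
  N <- nrow(Y); p <- ncol(Y); m <- max(map)
  if (N <= p) warning("N <= p: the preliminary CFA may be unstable")
  ybar <- colMeans(Y)
  S <- stats::cov(Y)
  if (!is_pd(S)) {
    S <- S + diag(1e-8 * mean(diag(S)), p)
    warning("sample covariance near-singular; ridge regularization applied")
  }
  fac_items <- factor_item_index(map)
  scaling <- vapply(fac_items, `[`, integer(1), 1)  # loading fixed to 1
  free <- setdiff(seq_len(p), scaling)
  fac_of_item <- unname(map)

  build <- function(theta) {
    lam <- numeric(p); lam[scaling] <- 1
    lam[free] <- theta[seq_along(free)]
    Tm <- matrix(0, m, m)
    lt <- lower.tri(Tm, diag = TRUE)
    tpar <- theta[length(free) + seq_len(sum(lt))]
    Tm[lt] <- tpar
    diag(Tm) <- exp(diag(Tm))
    Phi <- Tm %*% t(Tm)
    sig2 <- exp(theta[length(free) + sum(lt) + seq_len(p)])
    L <- matrix(0, p, m)
    L[cbind(seq_len(p), fac_of_item)] <- lam
    list(L = L, Phi = Phi, sig2 = sig2,
         Sigma = L %*% Phi %*% t(L) + diag(sig2, p))
  }
  objective <- function(theta) {
    md <- build(theta)
    ch <- tryCatch(chol(md$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    val <- ldet + tr
    if (!is.finite(val)) 1e10 else val
  }
  n_tpar <- m * (m + 1) / 2
  start <- c(rep(1, length(free)), rep(0, n_tpar), log(diag(S) / 2))
  opt <- tryCatch(
    stats::optim(start, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-6)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    converged <- FALSE
    theta <- start
    warning("preliminary CFA failed to optimize; returning starting values")
  } else {
    converged <- opt$convergence == 0
    theta <- opt$par
    if (!converged) warning("preliminary CFA did not converge in 500 iterations")
  }
  md <- build(theta)
  ch <- chol(md$Sigma)
  ldet <- 2 * sum(log(diag(ch)))
  # Gaussian log-likelihood with saturated means: sum_i ll_i(ybar, Sigma)
  loglik <- -0.5 * (N * (p * log(2 * pi) + ldet) +
                      (N - 1) * sum(diag(chol2inv(ch) %*% S)))
  dimnames(md$Sigma) <- list(colnames(Y), colnames(Y))
  structure(
    list(loadings = md$L, factor_cov = md$Phi, residual_variances = md$sig2,
         implied_mean = ybar, implied_cov = md$Sigma,
         sample_mean = ybar, sample_cov = S,
         converged = converged, loglik = loglik,
         item_factor_map = map),
    class = "cfa_ml_fit"
  )
}

is_pd <- function(M) {
  !inherits(tryCatch(chol(M), error = function(e) e), "error")
}

#' @export
print.cfa_ml_fit <- function(x, ...) {
  cat("<cfa_ml_fit> ", nrow(x$loadings), " items, ", ncol(x$loadings),
      " factor(s); converged = ", x$converged,
      "; loglik = ", format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' Individual multivariate-normal log-likelihood contribution
#'
#' `-1/2 (p log(2 pi) + log|cov| + D2)` with the Mahalanobis distance
#' `D2 = (y - mean)' cov^-1 (y - mean)`.
#'
#' @param y Response vector of length p.
#' @param mean Mean vector of length p.
#' @param cov p x p positive-definite covariance matrix.
#' @return The log density (a scalar).
#' @export
#' @examples
#' individual_loglik(0, 0, matrix(1))  # -0.5 * log(2 * pi)
individual_loglik <- function(y, mean, cov) {
  cov <- as.matrix(cov)
  p <- length(y)
  stopifnot(length(mean) == p, all(dim(cov) == p))
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix `cov` is singular or not positive definite"))
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Mahalanobis distances of all rows of Y (internal, vectorized).
mahal_rows <- function(Y, mu, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is singular or not positive definite"))
  Z <- backsolve(ch, t(Y) - mu, transpose = TRUE)
  list(d2 = colSums(Z^2), ldet = 2 * sum(log(diag(ch))))
}

#' Likelihood-based person-fit index
#'
#' For each respondent, minus twice the difference between the individual
#' log-likelihood under the model-implied moments and under the sample
#' moments: `y1_i = log|Sigma| - log|S| + D2_i(mu, Sigma) - D2_i(ybar, S)`.
#' Large values flag response patterns the factor model explains poorly.
#'
#' @param data A [survey_data()].
#' @param fit A [fit_ml_cfa()] result on the same data.
#' @return A numeric vector of length N.
#' @export
person_fit_y1 <- function(data, fit) {
  stopifnot(inherits(data, "survey_data"), inherits(fit, "cfa_ml_fit"))
  Y <- resp_matrix(data)
  a <- mahal_rows(Y, fit$implied_mean, fit$implied_cov)
  b <- mahal_rows(Y, fit$sample_mean, fit$sample_cov)
  (a$ldet - b$ldet) + (a$d2 - b$d2)
}

#' Within-factor variability index
#'
#' For each respondent, the sample variance (denominator `items - 1`) of the
#' responses across the items of each factor, averaged over factors.
#' Attentive respondents answer items of the same construct similarly, so
#' their within-factor variability is small; uniform random responding yields
#' a large value regardless of content.
#'
#' @param data A [survey_data()].
#' @return A nonnegative numeric vector of length N.
#' @export
#' @examples
#' sim <- generate_dataset(sim_design(n_persons = 100, seed = 3))
#' summary(variability_y2(sim$data))
variability_y2 <- function(data) {
  stopifnot(inherits(data, "survey_data"))
  Y <- resp_matrix(data)
  idx <- factor_item_index(data$item_factor_map)
  sizes <- lengths(idx)
  if (any(sizes < 2)) {
    stop("every factor needs >= 2 mapped items for a within-factor variance")
  }
  vars <- vapply(idx, function(cols) {
    Yk <- Y[, cols, drop = FALSE]
    mu <- rowMeans(Yk)
    rowSums((Yk - mu)^2) / (length(cols) - 1)
  }, numeric(nrow(Y)))
  rowMeans(matrix(vars, nrow = nrow(Y)))
}

#' Person-level predictor indices
#'
#' Computes the likelihood-based person-fit index `y1` (via a preliminary ML
#' CFA when `fit` is not supplied) and the within-factor variability index
#' `y2` for every respondent.
#'
#' @param data A [survey_data()].
#' @param fit Optional precomputed [fit_ml_cfa()].
#' @param standardize If `TRUE` (default) z-score both indices across
#'   respondents before they enter the class model; the weakly informative
#'   N(0, 10) coefficient priors are only consistent across datasets on a
#'   standardized scale.
#' @return A tibble of class `person_indices` with columns `person_id`, `y1`,
#'   `y2`; attributes record whether and with which constants the columns
#'   were standardized.
#' @export
person_indices <- function(data, fit = NULL, standardize = TRUE) {
  stopifnot(inherits(data, "survey_data"))
  if (is.null(fit)) fit <- fit_ml_cfa(data)
  idx <- tibble::tibble(
    person_id = data$responses$person_id,
    y1 = person_fit_y1(data, fit),
    y2 = variability_y2(data)
  )
  idx <- tibble::new_tibble(idx, class = "person_indices")
  attr(idx, "standardized") <- FALSE
  attr(idx, "constants") <- NULL
  if (standardize) idx <- standardize_indices(idx) else idx
}

#' Standardize person indices
#'
#' Z-scores each index over respondents and records the centering/scaling
#' constants so class-model coefficients are reportable on either scale.
#' Idempotent; a zero-variance column is left unscaled with a warning.
#'
#' @param idx A [person_indices()] tibble.
#' @return The standardized tibble with `standardized`/`constants` attributes.
#' @export
standardize_indices <- function(idx) {
  stopifnot(inherits(idx, "person_indices"))
  if (isTRUE(attr(idx, "standardized"))) return(idx)
  consts <- list()
  for (col in c("y1", "y2")) {
    x <- idx[[col]]
    if (!all(is.finite(x))) stop("non-finite values in index `", col, "`")
    s <- stats::sd(x)
    if (s == 0) {
      warning("index `", col, "` has zero variance; left unscaled")
      consts[[col]] <- c(mean = 0, sd = 1)
    } else {
      consts[[col]] <- c(mean = mean(x), sd = s)
      idx[[col]] <- (x - mean(x)) / s
    }
  }
  attr(idx, "standardized") <- TRUE
  attr(idx, "constants") <- consts
  idx
}
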