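#' Rank-normalized split-Rhat
#'
#' The potential scale reduction factor of Vehtari et al. (2021): chains are
#' split in half, rank-normalized through the inverse normal CDF, and the
#' classic Rhat is taken as the maximum of the bulk statistic and the same
#' statistic on the median-folded draws. Values below 1.01 are taken as
#' evidence of convergence throughout the package.
#'
#' @param x Matrix of draws, iterations in rows, chains in columns
#'   (>= 2 chains, >= 4 draws per chain).
#' @return The split-Rhat (scalar). Draws with zero total variance return
#'   1.0 by convention, with a warning.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("split-Rhat needs >= 2 chains")
  if (nrow(x) < 4) stop("split-Rhat needs >= 4 draws per chain")
  if (stats::sd(x) == 0) {
    warning("zero total variance across draws; returning Rhat = 1")
    return(1.0)
  }
  sp <- split_half_chains(x)
  r_bulk <- rhat_classic(rank_normalize(sp))
  folded <- abs(sp - stats::median(sp))
  r_fold <- rhat_classic(rank_normalize(folded))
  max(r_bulk, r_fold)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws, computed on rank-normalized split
#' chains with Geyer's initial monotone positive sequence estimator of the
#' autocorrelation time. Anticorrelated chains can yield an ESS above the
#' number of draws (super-efficiency); that is allowed.
#'
#' @inheritParams split_rhat
#' @return The bulk ESS (scalar); zero-variance draws return `NA` with a
#'   warning.
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("ESS needs >= 2 chains")
  if (nrow(x) < 4) stop("ESS needs >= 4 draws per chain")
  if (stats::sd(x) == 0) {
    warning("zero total variance across draws; ESS undefined")
    return(NA_real_)
  }
  z <- rank_normalize(split_half_chains(x))
  ess_geyer(z)
}

# Split each chain into first/last half (odd middle draw dropped from the
# first half); returns iterations x (2 * chains).
split_half_chains <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(n - half + 1, n), , drop = FALSE])
}

# Pooled average ranks mapped through the inverse normal CDF with the
# Blom-type offset (r - 3/8) / (S + 1/4).
rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 0.375) / (length(x) + 0.25))
  matrix(z, nrow(x), ncol(x))
}

# Classic Rhat on already-split chains (iterations x chains).
rhat_classic <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer initial-monotone-sequence ESS on (already split and normalized)
# chains, iterations x chains.
ess_geyer <- function(x) {
  ndraw <- nrow(x); nchain <- ncol(x)
  acov <- vapply(seq_len(nchain), function(ch) {
    v <- x[, ch]
    stats::acf(v, lag.max = ndraw - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(ndraw))
  acov_m <- rowMeans(acov)                    # mean over chains, lag 0..n-1
  mean_var <- acov_m[1] * ndraw / (ndraw - 1) # within-chain variance W
  var_plus <- mean_var * (ndraw - 1) / ndraw
  if (nchain > 1) var_plus <- var_plus + stats::var(colMeans(x))

  rho <- numeric(ndraw)
  rho[1] <- 1
  rho_even <- 1
  rho_odd <- 1 - (mean_var - acov_m[2]) / var_plus
  rho[2] <- rho_odd
  t <- 1
  while (t < (ndraw - 3) && (rho_even + rho_odd) > 0) {
    rho_even <- 1 - (mean_var - acov_m[t + 2]) / var_plus
    rho_odd <- 1 - (mean_var - acov_m[t + 3]) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 2] <- rho_even
      rho[t + 3] <- rho_odd
    }
    t <- t + 2
  }
  max_t <- t - 2
  if (rho_even > 0) rho[max_t + 2] <- rho_even
  # enforce monotone decreasing sums of adjacent pairs
  t <- 1
  while (t <= max_t - 2) {
    if ((rho[t + 2] + rho[t + 3]) > (rho[t] + rho[t + 1])) {
      rho[t + 2] <- (rho[t] + rho[t + 1]) / 2
      rho[t + 3] <- rho[t + 2]
    }
    t <- t + 2
  }
  total <- nchain * ndraw
  tau <- -1 + 2 * sum(rho[seq_len(max_t + 1)]) + rho[max_t + 2]
  tau <- max(tau, 1 / log10(total))
  total / tau
}
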