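#' Simulation design for contaminated Likert-scale data
#'
#' Describes one cell of the Monte-Carlo design: attentive respondents answer
#' according to a simple-structure factor model whose latent responses are
#' thresholded onto a six-point scale, while bots pick categories uniformly at
#' random. Average item communality and the common factor correlation are
#' random design factors drawn anew for every replication.
#'
#' @param n_persons Number of respondents N.
#' @param n_factors Number of latent factors m (3 or 6 in the reference
#'   design; any m >= 1 is allowed).
#' @param items_per_factor Items per factor (default 6).
#' @param prop_bots Fraction of bot rows in `[0, 1]`. The bot count is the
#'   deterministic `round(prop_bots * n_persons)`.
#' @param communality_range Interval from which the average item communality
#'   is drawn each replication (default `c(0.25, 0.64)`).
#' @param communality_halfwidth Half-width of the per-item communality spread
#'   around the drawn average (default 0.15).
#' @param rho_range Interval for the common factor correlation rho
#'   (default `c(0, 0.7)`).
#' @param n_categories Number of response categories (default 6).
#' @param thresholds Strictly increasing cut points of length
#'   `n_categories - 1` applied to the standard-normal latent response
#'   (default `c(-2, -1, 0, 1, 2)`, i.e. equidistant steps).
#' @param seed Integer seed; `generate_dataset()` seeds the RNG with it so the
#'   whole dataset replays bit-identically.
#'
#' @return An object of class `sim_design` (a validated list of the above).
#' @export
#' @examples
#' sim_design(n_persons = 400, n_factors = 3, prop_bots = 0.25, seed = 7)
sim_design <- function(n_persons,
                       n_factors = 3,
                       items_per_factor = 6,
                       prop_bots = 0.25,
                       communality_range = c(0.25, 0.64),
                       communality_halfwidth = 0.15,
                       rho_range = c(0, 0.7),
                       n_categories = 6,
                       thresholds = c(-2, -1, 0, 1, 2),
                       seed = NULL) {
  stopifnot(n_persons >= 1, n_factors >= 1, items_per_factor >= 1,
            n_categories >= 2)
  if (prop_bots < 0 || prop_bots > 1) stop("`prop_bots` must lie in [0, 1]")
  if (length(thresholds) != n_categories - 1) {
    stop("`thresholds` must have length n_categories - 1")
  }
  if (any(diff(thresholds) <= 0)) stop("`thresholds` must be strictly increasing")
  ck_interval <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2]) stop("`", nm, "` must be an ordered interval")
  }
  ck_interval(communality_range, "communality_range")
  ck_interval(rho_range, "rho_range")
  if (communality_range[1] <= 0 || communality_range[2] >= 1) {
    stop("`communality_range` must lie inside (0, 1)")
  }
  if (communality_halfwidth < 0) stop("`communality_halfwidth` must be >= 0")
  structure(
    list(n_persons = as.integer(n_persons), n_factors = as.integer(n_factors),
         items_per_factor = as.integer(items_per_factor),
         prop_bots = prop_bots,
         communality_range = communality_range,
         communality_halfwidth = communality_halfwidth,
         rho_range = rho_range, n_categories = as.integer(n_categories),
         thresholds = as.numeric(thresholds),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_design"
  )
}

#' Draw the random design factors of one replication
#'
#' Samples the average item communality and the common factor correlation
#' uniformly from the intervals of the design. A degenerate interval
#' (`lo == hi`) returns the constant.
#'
#' @param design A [sim_design()].
#' @return A list with `communality_mean` and `rho`.
#' @export
sample_design_factors <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  list(
    communality_mean = stats::runif(1, design$communality_range[1],
                                    design$communality_range[2]),
    rho = stats::runif(1, design$rho_range[1], design$rho_range[2])
  )
}

#' Build generating parameters for one replication
#'
#' Per-item communalities are drawn uniformly in
#' `communality_mean +/- communality_halfwidth` (clipped to `(0.05, 0.95)` so
#' residual variances stay positive), loadings are their positive square
#' roots, and residual variances complete each item to unit variance, so the
#' pre-threshold latent responses are standard normal. The factor covariance
#' is an equicorrelation matrix with unit diagonal and off-diagonals `rho`;
#' intercepts are zero.
#'
#' @param design A [sim_design()].
#' @param communality_mean Average item communality of this replication.
#' @param rho Common factor correlation of this replication.
#' @return An object of class `true_parameters` with fields `loading_matrix`
#'   (p x m, simple structure), `factor_cov`, `residual_variances`,
#'   `intercepts`, `communality_mean`, `rho`, and (filled by
#'   [generate_dataset()]) `class_labels`.
#' @export
build_true_parameters <- function(design, communality_mean, rho) {
  stopifnot(inherits(design, "sim_design"))
  m <- design$n_factors
  p <- m * design$items_per_factor
  h2 <- stats::runif(p, communality_mean - design$communality_halfwidth,
                     communality_mean + design$communality_halfwidth)
  h2 <- pmin(pmax(h2, 0.05), 0.95)
  lambda <- sqrt(h2)
  L <- matrix(0, p, m)
  fac_of_item <- rep(seq_len(m), each = design$items_per_factor)
  L[cbind(seq_len(p), fac_of_item)] <- lambda
  Phi <- matrix(rho, m, m)
  diag(Phi) <- 1
  pd <- tryCatch({chol(Phi); TRUE}, error = function(e) FALSE)
  if (!pd) stop("factor covariance (equicorrelation rho = ", rho,
                ", m = ", m, ") is not positive definite")
  item_names <- paste0("F", fac_of_item, "_I",
                       rep(seq_len(design$items_per_factor), times = m))
  rownames(L) <- item_names
  structure(
    list(loading_matrix = L, factor_cov = Phi,
         residual_variances = 1 - h2, intercepts = rep(0, p),
         class_labels = NULL,
         communality_mean = communality_mean, rho = rho),
    class = "true_parameters"
  )
}

#' Generate attentive (human) responses
#'
#' Draws latent responses `Y* = tau + Lambda eta + eps` with
#' `eta ~ MVN(0, Phi)` and independent normal residuals, then maps each latent
#' value to category `k` when it falls in `[delta_{k-1}, delta_k)`, the cut
#' points being `(-Inf, thresholds, Inf)`. Categories are coded `1..K`.
#'
#' @param params A [build_true_parameters()] object.
#' @param n Number of respondents to draw.
#' @param thresholds Strictly increasing cut points.
#' @return An integer matrix (n x p) of category codes.
#' @export
generate_human_responses <- function(params, n, thresholds) {
  stopifnot(inherits(params, "true_parameters"), n >= 0)
  p <- nrow(params$loading_matrix)
  if (n == 0) {
    return(matrix(integer(0), 0, p, dimnames = list(NULL, rownames(params$loading_matrix))))
  }
  m <- ncol(params$loading_matrix)
  eta <- matrix(stats::rnorm(n * m), n, m) %*% chol(params$factor_cov)
  eps <- matrix(stats::rnorm(n * p), n, p) %*%
    diag(sqrt(params$residual_variances), p)
  ystar <- matrix(params$intercepts, n, p, byrow = TRUE) +
    eta %*% t(params$loading_matrix) + eps
  y <- matrix(findInterval(ystar, thresholds) + 1L, n, p)
  colnames(y) <- rownames(params$loading_matrix)
  y
}

#' Generate bot responses
#'
#' Every cell is independently uniform over the `n_categories` codes
#' `1..n_categories` — the content-free random-response pattern.
#'
#' @param n Number of bot rows (0 allowed).
#' @param n_items Number of items.
#' @param n_categories Number of response categories.
#' @return An integer matrix (n x n_items).
#' @export
generate_bot_responses <- function(n, n_items, n_categories = 6) {
  stopifnot(n >= 0, n_items >= 1, n_categories >= 2)
  matrix(sample.int(n_categories, n * n_items, replace = TRUE), n, n_items)
}

#' Generate one contaminated dataset with retained ground truth
#'
#' Seeds the RNG from `design$seed` (when given), draws the random design
#' factors, builds the generating parameters, stacks exactly
#' `round(prop_bots * n_persons)` bot rows with the human rows, and shuffles
#' the row order. All generating values, including the shuffled class labels,
#' are retained so recovery and bias can be scored later.
#'
#' @param design A [sim_design()].
#' @return A list of class `bot_simulation` with elements `data` (a
#'   [survey_data()]) and `truth` (a `true_parameters` whose `class_labels`
#'   aligns with the rows of `data$responses`).
#' @export
#' @examples
#' sim <- generate_dataset(sim_design(n_persons = 200, prop_bots = 0.25, seed = 42))
#' table(sim$truth$class_labels)
generate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  rf <- sample_design_factors(design)
  params <- build_true_parameters(design, rf$communality_mean, rf$rho)
  N <- design$n_persons
  p <- nrow(params$loading_matrix)
  n_bots <- round(design$prop_bots * N)
  if (design$prop_bots > 0 && n_bots == 0) {
    warning("prop_bots > 0 but round(prop_bots * n_persons) = 0; no bot rows generated")
  }
  H <- generate_human_responses(params, N - n_bots, design$thresholds)
  B <- generate_bot_responses(n_bots, p, design$n_categories)
  colnames(B) <- colnames(H)
  Y <- rbind(H, B)
  labels <- c(rep("human", N - n_bots), rep("bot", n_bots))
  ord <- sample.int(N)
  Y <- Y[ord, , drop = FALSE]
  params$class_labels <- labels[ord]
  map <- stats::setNames(rep(seq_len(design$n_factors),
                             each = design$items_per_factor),
                         colnames(Y))
  df <- tibble::as_tibble(as.data.frame(Y))
  df$person_id <- seq_len(N)
  dat <- survey_data(df, map, family = "continuous",
                     category_range = c(1, design$n_categories))
  structure(list(data = dat, truth = params, design = design),
            class = "bot_simulation")
}

#' @export
print.bot_simulation <- function(x, ...) {
  lab <- x$truth$class_labels
  cat("<bot_simulation> N = ", length(lab), " (", sum(lab == "bot"), " bots), ",
      x$design$n_factors, " factors, communality mean = ",
      round(x$truth$communality_mean, 3), ", rho = ",
      round(x$truth$rho, 3), "\n", sep = "")
  invisible(x)
}

#' True standardized loadings of a simulated dataset
#'
#' The nonzero generating loading of each item, i.e. the square root of its
#' drawn communality (generation is standardized, so these are already on the
#' standardized scale).
#'
#' @param truth A `true_parameters` object.
#' @return A tibble with columns `item`, `factor`, `loading`.
#' @export
true_standardized_loadings <- function(truth) {
  stopifnot(inherits(truth, "true_parameters"))
  L <- truth$loading_matrix
  fac <- apply(L != 0, 1, which.max)
  tibble::tibble(item = rownames(L), factor = as.integer(fac),
                 loading = L[cbind(seq_len(nrow(L)), fac)])
}
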