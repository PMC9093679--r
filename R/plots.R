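#' Scatter plot of the two person indices
#'
#' The bivariate view that motivates the class model: attentive respondents
#' cluster at low within-factor variability, random responders at high
#' variability, while the likelihood-based index separates less and less as
#' contamination grows.
#'
#' @param idx A [person_indices()] tibble.
#' @param labels Optional character vector of true or predicted classes used
#'   to color points.
#' @return A ggplot object.
#' @export
plot_indices <- function(idx, labels = NULL) {
  stopifnot(inherits(idx, "person_indices"))
  df <- tibble::as_tibble(idx)
  if (!is.null(labels)) df$class <- labels
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y1, y = .data$y2)) +
    ggplot2::labs(
      x = "person-fit index (y1)",
      y = "within-factor variability (y2)"
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    gg + ggplot2::geom_point(alpha = 0.6)
  } else {
    gg + ggplot2::geom_point(ggplot2::aes(color = .data$class), alpha = 0.6)
  }
}

#' Plot posterior bot probabilities
#'
#' Histogram of per-person posterior bot probabilities with the
#' classification threshold marked.
#'
#' @param object An `lc_cfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lc_cfa_fit <- function(object, ...) {
  df <- object$classification
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_bot, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "posterior bot probability", y = "respondents") +
    ggplot2::theme_minimal()
}

#' Plot study-level classification accuracy and bias
#'
#' Sensitivity/specificity and standardized-loading bias of the mixture vs
#' the naive CFA across conditions.
#'
#' @param object A `study_results`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_results <- function(object, ...) {
  s <- object$summary
  long <- tidyr::pivot_longer(
    dplyr::select(s, "n_factors", "n_persons", "prop_bots",
                  "bias_lambda_lc", "bias_lambda_cfa"),
    cols = c("bias_lambda_lc", "bias_lambda_cfa"),
    names_to = "model", values_to = "bias"
  )
  long$model <- ifelse(long$model == "bias_lambda_lc", "LC-CFA", "CFA")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$prop_bots), y = .data$bias,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(n_factors ~ n_persons,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "proportion of bots",
                  y = "standardized-loading percent bias") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
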