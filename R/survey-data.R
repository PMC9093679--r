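#' Survey dataset with an item-to-factor map
#'
#' Bundles a rectangular respondent-by-item response table with the
#' measurement structure every downstream function needs: which item loads on
#' which factor (simple structure), the response family, and the admissible
#' category range. This is the universal input object of the package.
#'
#' @param data A data frame with one row per respondent. All mapped items must
#'   be present as numeric (integer-codable) columns; a `person_id` column is
#'   added if absent. Unmapped columns other than `person_id` are ignored with
#'   a warning.
#' @param item_factor_map Named integer vector mapping item (column) names to
#'   factor indices `1..m`. Each item maps to exactly one factor.
#' @param family Response family: `"continuous"` (identity link, normal),
#'   `"binary"` (logit, Bernoulli) or `"count"` (log, Poisson). Integer Likert
#'   codes are treated as continuous by default, the convention used for
#'   six-point scales throughout the package.
#' @param category_range Length-2 integer vector of admissible codes for the
#'   categorical families; inferred from the data when `NULL`.
#'
#' @return An object of class `survey_data`: a list with elements `responses`
#'   (a tibble, `person_id` first), `item_factor_map`, `family` and
#'   `category_range`.
#' @export
#' @examples
#' sim <- generate_dataset(sim_design(n_persons = 50, seed = 1))
#' dat <- sim$data
#' dat$item_factor_map
survey_data <- function(data, item_factor_map,
                        family = c("continuous", "binary", "count"),
                        category_range = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), length(item_factor_map) >= 1)
  items <- names(item_factor_map)
  if (is.null(items) || any(!nzchar(items))) {
    stop("`item_factor_map` must be a named vector (item name -> factor index)")
  }
  missing_items <- setdiff(items, names(data))
  if (length(missing_items) > 0) {
    stop("mapped items absent from `data`: ", paste(missing_items, collapse = ", "))
  }
  fac <- as.integer(item_factor_map)
  if (any(is.na(fac)) || any(fac < 1)) stop("factor indices must be positive integers")
  if (!setequal(unique(fac), seq_len(max(fac)))) {
    stop("factor indices must cover 1..m with no gaps (every factor needs items)")
  }
  names(fac) <- items

  if (!"person_id" %in% names(data)) {
    data <- dplyr::mutate(data, person_id = dplyr::row_number(), .before = 1)
  }
  extra <- setdiff(names(data), c("person_id", items))
  if (length(extra) > 0) {
    warning("ignoring unmapped columns: ", paste(extra, collapse = ", "))
  }
  resp <- tibble::as_tibble(data)[c("person_id", items)]
  ymat <- as.matrix(resp[items])
  if (anyNA(ymat)) {
    bad <- which(rowSums(is.na(ymat)) > 0)
    stop("missing responses are not supported (rows: ",
         paste(utils::head(bad, 10), collapse = ", "), ")")
  }
  storage.mode(ymat) <- "double"
  if (family != "continuous" || is.null(category_range)) {
    category_range <- range(ymat)
  }
  if (family %in% c("continuous", "binary")) {
    if (any(ymat != round(ymat)) && family == "binary") {
      stop("binary family requires 0/1 codes")
    }
  }
  structure(
    list(responses = resp, item_factor_map = fac, family = family,
         category_range = as.numeric(category_range)),
    class = "survey_data"
  )
}

#' @export
print.survey_data <- function(x, ...) {
  cat("<survey_data> ", nrow(x$responses), " respondents x ",
      length(x$item_factor_map), " items, ",
      max(x$item_factor_map), " factor(s), family = ", x$family, "\n", sep = "")
  print(utils::head(x$responses, 5))
  invisible(x)
}

# Response matrix in map order (internal).
resp_matrix <- function(data) {
  stopifnot(inherits(data, "survey_data"))
  m <- as.matrix(data$responses[names(data$item_factor_map)])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

# Items of each factor, as a list of column indices into resp_matrix order.
factor_item_index <- function(map) {
  m <- max(map)
  lapply(seq_len(m), function(k) which(unname(map) == k))
}
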