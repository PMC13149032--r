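#' Tidy an invasion model
#'
#' One row per selected (nonzero-coefficient) gene.
#'
#' @param x An `invasion_model`.
#' @param ... Unused.
#' @return Tibble with `gene`, `beta`, `sign`.
#' @export
tidy.invasion_model <- function(x, ...) {
  x$selected
}

#' One-row model summary of an invasion model
#'
#' @param x An `invasion_model`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `n_features`, `n_selected`, `n_pro`,
#'   `n_anti`, `cv_mse`.
#' @export
glance.invasion_model <- function(x, ...) {
  cv_mse <- if (!is.null(x$cv)) min(x$cv$mse) else NA_real_
  tibble::tibble(
    lambda = x$lambda,
    n_features = length(x$features),
    n_selected = nrow(x$selected),
    n_pro = sum(x$selected$beta > 0),
    n_anti = sum(x$selected$beta < 0),
    cv_mse = cv_mse
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with the test summary.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_vessels = x$n_vessels, n_null = x$n_null,
    median_vessel = x$median_vessel, median_null = x$median_null,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' Tidy a state distance profile
#'
#' @param x A `state_distance_profile`.
#' @param ... Unused.
#' @return The pairwise test tibble (`state_a`, `state_b`, `p`, `p_adj`).
#' @export
tidy.state_distance_profile <- function(x, ...) {
  x$tests
}

#' Tidy an adjacency contrast
#'
#' @param x An `adjacency_contrast`.
#' @param ... Unused.
#' @return The contrast tibble (`contrast`, `p`, `p_adj`).
#' @export
tidy.adjacency_contrast <- function(x, ...) {
  x$tests
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
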