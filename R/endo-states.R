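#' Extract per-cell marker values from a normalized matrix
#'
#' @param expr_norm Normalized (log1p) genes x cells matrix.
#' @param markers Character vector of gene ids.
#' @param cells Optional cell ids to restrict to.
#' @return Tibble with `cell_id` and one column per marker.
#' @export
marker_values <- function(expr_norm, markers, cells = NULL) {
  miss <- setdiff(markers, rownames(expr_norm))
  if (length(miss) > 0) {
    rlang::abort(sprintf("marker gene(s) missing from the matrix: %s",
                         paste(miss, collapse = ", ")))
  }
  if (is.null(cells)) cells <- colnames(expr_norm)
  vals <- as.matrix(Matrix::t(expr_norm[markers, cells, drop = FALSE]))
  out <- tibble::as_tibble(vals)
  names(out) <- markers
  dplyr::bind_cols(tibble::tibble(cell_id = cells), out)
}

#' Classify endothelial remodelling states from PDE3A x VIM quadrants
#'
#' Every endothelial cell is assigned exactly one state by the quadrant rule
#' on the two markers: (PDE3A hi, VIM hi) -> caEC, (hi, low) -> R0,
#' (low, low) -> R1, (low, hi) -> R2, where "hi" means value >= threshold
#' (boundary values are hi).
#'
#' @param markers Tibble from [marker_values()] with columns `cell_id`,
#'   `PDE3A`, `VIM` (log1p-normalized values).
#' @param thresholds Either `"median"` (per-marker median over the supplied
#'   cells), `"percentile"` (with `percentile`), or a named numeric vector
#'   `c(PDE3A = ..., VIM = ...)`.
#' @param percentile Percentile in (0, 1) used when
#'   `thresholds = "percentile"`.
#' @return Tibble with `cell_id`, `PDE3A`, `VIM`, `pde3a_hi`, `vim_hi`,
#'   `state` (factor caEC/R0/R1/R2); attribute `thresholds` records the
#'   cutoffs and method used.
#' @export
classify_endo_states <- function(markers, thresholds = "median",
                                 percentile = 0.5) {
  .assert_cols(markers, c("cell_id", "PDE3A", "VIM"), "markers")
  if (is.character(thresholds)) {
    method <- match.arg(thresholds, c("median", "percentile"))
    q <- if (method == "median") 0.5 else percentile
    tau <- c(PDE3A = unname(stats::quantile(markers$PDE3A, q)),
             VIM = unname(stats::quantile(markers$VIM, q)))
  } else {
    if (!all(c("PDE3A", "VIM") %in% names(thresholds))) {
      rlang::abort("supplied thresholds must be named c(PDE3A=, VIM=)")
    }
    method <- "supplied"
    tau <- thresholds[c("PDE3A", "VIM")]
  }
  p_hi <- markers$PDE3A >= tau[["PDE3A"]]
  v_hi <- markers$VIM >= tau[["VIM"]]
  state <- dplyr::case_when(
    p_hi & v_hi ~ "caEC",
    p_hi & !v_hi ~ "R0",
    !p_hi & !v_hi ~ "R1",
    TRUE ~ "R2"
  )
  out <- dplyr::mutate(markers, pde3a_hi = p_hi, vim_hi = v_hi,
                       state = factor(state,
                                      levels = c("caEC", "R0", "R1", "R2")))
  attr(out, "thresholds") <- list(tau = tau, method = method)
  out
}

#' Bootstrap AUROC of a marker for a two-state contrast
#'
#' For each bootstrap replicate, cells are resampled with replacement and the
#' rank-based (midrank tie-corrected) AUROC of the marker for the contrast is
#' computed; the mean and standard deviation over replicates are reported.
#'
#' @param values Numeric marker values.
#' @param labels Class labels, same length as `values`.
#' @param positive The label treated as positive.
#' @param B Bootstrap replicates (default 10; must be >= 2).
#' @param seed Optional integer seed.
#' @return Tibble with `mean_auroc`, `sd_auroc`, `B`, `n`.
#' @export
bootstrap_auroc <- function(values, labels, positive, B = 10, seed = NULL) {
  .assert_scalar_num(B, "B", 2)
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    rlang::abort("bootstrap_auroc: contrast requires both classes present")
  }
  n <- length(values)
  .with_seed(seed, {
    reps <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(pos[idx]) && !all(pos[idx])) break
      }
      reps[b] <- .auroc(values[idx], pos[idx])
    }
    tibble::tibble(mean_auroc = mean(reps), sd_auroc = stats::sd(reps),
                   B = B, n = n)
  })
}

#' Spatial distance profile of endothelial states
#'
#' Summarises the absolute vessel-wall distance |d_V| per state and tests all
#' state pairs with two-sided rank-sum tests, Benjamini-Hochberg corrected.
#' States with no cells are excluded with a warning.
#'
#' @param states Tibble from [classify_endo_states()] (columns `cell_id`,
#'   `state`).
#' @param distances Distance table with `cell_id` and `d_vessel_px`.
#' @return Object of class `state_distance_profile`: list with `summary`
#'   (per-state n, median/mean |d_V|) and `tests` (pairwise `p`, `p_adj`).
#' @export
state_distance_profile <- function(states, distances) {
  .assert_cols(states, c("cell_id", "state"), "states")
  .assert_cols(distances, c("cell_id", "d_vessel_px"), "distances")
  df <- dplyr::inner_join(
    dplyr::select(states, "cell_id", "state"),
    dplyr::select(distances, "cell_id", "d_vessel_px"),
    by = "cell_id"
  ) |>
    dplyr::mutate(abs_d = abs(.data$d_vessel_px)) |>
    dplyr::filter(!is.na(.data$abs_d))
  present <- df |>
    dplyr::count(.data$state, .drop = FALSE) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::pull(.data$state)
  empty <- setdiff(levels(df$state), as.character(present))
  if (length(empty) > 0) {
    rlang::warn(sprintf("state(s) with 0 cells excluded: %s",
                        paste(empty, collapse = ", ")))
  }
  summary <- df |>
    dplyr::filter(.data$state %in% present) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n = dplyr::n(), median_abs_d = stats::median(.data$abs_d),
                     mean_abs_d = mean(.data$abs_d), .groups = "drop")
  pairs <- utils::combn(as.character(present), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- .ranksum_p(df$abs_d[df$state == a], df$abs_d[df$state == b])
    tibble::tibble(state_a = a, state_b = b, p = p)
  })
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  structure(list(summary = summary, tests = tests, data = df),
            class = "state_distance_profile")
}

#' @export
print.state_distance_profile <- function(x, ...) {
  cat("<state_distance_profile> |d_vessel| by endothelial state\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
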