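#' Simulate a signed gene-regulatory edge list with known categories
#'
#' Generates TF -> target edges in two lineage contexts (EVT and SCT) with
#' signed coefficients whose categories are known: each edge belongs to one of
#' EVT-activation, EVT-repression, SCT-activation or SCT-repression. A
#' configurable number of edges carries coefficient magnitudes below the
#' strength filter threshold so that threshold behaviour is testable.
#'
#' @param n_tfs Number of transcription factors per lineage.
#' @param n_targets Size of the target gene pool.
#' @param n_edges Number of edges to draw.
#' @param sign_mix Named proportions over the four categories
#'   (`evt_activation`, `evt_repression`, `sct_activation`,
#'   `sct_repression`); must sum to 1.
#' @param coef_range Range of |coefficient| for above-threshold edges.
#' @param n_below_threshold Number of edges drawn with |coefficient| below
#'   `threshold` (uniform on (0.01, threshold)).
#' @param threshold Strength filter threshold the magnitudes straddle
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List with `edges` (tibble `tf`, `target`, `coefficient`, `lineage`)
#'   and `truth` (tibble adding `category` and `above_threshold`, plus the
#'   lineage TF sets).
#' @export
simulate_grn <- function(n_tfs = 10, n_targets = 50, n_edges = 100,
                         sign_mix = c(evt_activation = 0.4,
                                      evt_repression = 0.1,
                                      sct_activation = 0.4,
                                      sct_repression = 0.1),
                         coef_range = c(0.15, 0.6),
                         n_below_threshold = 0,
                         threshold = 0.1,
                         seed = 1L) {
  if (abs(sum(sign_mix) - 1) > 1e-8) {
    rlang::abort("sign_mix proportions must sum to 1")
  }
  need <- c("evt_activation", "evt_repression", "sct_activation",
            "sct_repression")
  if (!setequal(names(sign_mix), need)) {
    rlang::abort(paste("sign_mix must be named:", paste(need, collapse = ", ")))
  }
  .with_seed(seed, {
    evt_tfs <- sprintf("ETF%02d", seq_len(n_tfs))
    sct_tfs <- sprintf("STF%02d", seq_len(n_tfs))
    targets <- sprintf("T%04d", seq_len(n_targets))
    category <- sample(need, n_edges, replace = TRUE, prob = sign_mix[need])
    lineage <- ifelse(startsWith(category, "evt"), "EVT", "SCT")
    tf <- ifelse(lineage == "EVT",
                 sample(evt_tfs, n_edges, replace = TRUE),
                 sample(sct_tfs, n_edges, replace = TRUE))
    target <- sample(targets, n_edges, replace = TRUE)
    mag <- stats::runif(n_edges, coef_range[1], coef_range[2])
    below <- rep(FALSE, n_edges)
    if (n_below_threshold > 0) {
      idx <- sample.int(n_edges, min(n_below_threshold, n_edges))
      mag[idx] <- stats::runif(length(idx), 0.01, threshold - 1e-6)
      below[idx] <- TRUE
    }
    coefficient <- ifelse(endsWith(category, "activation"), mag, -mag)
    edges <- tibble::tibble(tf = tf, target = target,
                            coefficient = coefficient, lineage = lineage) |>
      dplyr::distinct(.data$tf, .data$target, .data$lineage, .keep_all = TRUE)
    keep <- !duplicated(paste(tf, target, lineage))
    truth <- tibble::tibble(
      tf = tf[keep], target = target[keep], lineage = lineage[keep],
      category = category[keep], coefficient = coefficient[keep],
      above_threshold = !below[keep]
    )
    list(edges = edges, truth = c(list(edges = truth),
                                  list(evt_tfs = evt_tfs, sct_tfs = sct_tfs)))
  })
}
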