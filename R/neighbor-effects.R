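#' Assign EVTs to stromal-adjacency groups
#'
#' EVTs are grouped by grid-tile adjacency to decidual stromal cells:
#' `adjacent_focal` (at least one neighbor of the focal subtype; focal wins
#' over mixed neighborhoods), `adjacent_other` (at least one non-focal DSC
#' neighbor, no focal), and `matched_control` (EVTs with no DSC neighbor,
#' depth-matched to the focal group via [depth_match()]).
#'
#' @param cells Cell table with `cell_id`, `x_px`, `y_px`, `cell_type`,
#'   `subtype`.
#' @param distances Distance table with `cell_id`, `d_interface_px` (depths
#'   used for matching).
#' @param focal_subtype Focal DSC subtype (default `"DSC4"`).
#' @param dsc_type Cell type of stromal cells (default `"DSC"`).
#' @param tile_px,k_tiles Grid-adjacency parameters (defaults 50 px, 5 tiles).
#' @param bin_px Depth-matching bin width (default 100).
#' @param seed Optional integer seed (depth matching draws).
#' @return Tibble with `cell_id`, `group`, `depth_px`; attribute
#'   `depth_balance_p` (rank-sum p of focal vs matched-control depths).
#' @export
assign_adjacency_groups <- function(cells, distances, focal_subtype = "DSC4",
                                    dsc_type = "DSC", tile_px = 50,
                                    k_tiles = 5, bin_px = 100, seed = NULL) {
  .assert_cols(cells, c("cell_id", "x_px", "y_px", "cell_type", "subtype"),
               "cells")
  dsc <- cells[cells$cell_type == dsc_type, , drop = FALSE]
  if (!any(dsc$subtype == focal_subtype)) {
    rlang::abort(sprintf("no cells of focal subtype %s in the section",
                         focal_subtype))
  }
  evt <- cells[cells$cell_type == "EVT", , drop = FALSE]
  pairs <- tile_adjacency(cells, tile_px = tile_px, k_tiles = k_tiles,
                          from = evt$cell_id, to = dsc$cell_id)
  pairs <- dplyr::left_join(pairs,
                            dplyr::select(dsc, cell_b = "cell_id",
                                          dsc_subtype = "subtype"),
                            by = "cell_b")
  by_evt <- pairs |>
    dplyr::group_by(.data$cell_a) |>
    dplyr::summarise(has_focal = any(.data$dsc_subtype == focal_subtype),
                     .groups = "drop")
  depth <- dplyr::select(distances, "cell_id",
                         depth_px = "d_interface_px") |>
    dplyr::mutate(depth_px = abs(.data$depth_px))
  focal_ids <- by_evt$cell_a[by_evt$has_focal]
  other_ids <- by_evt$cell_a[!by_evt$has_focal]
  if (length(focal_ids) == 0) {
    rlang::abort(sprintf("no EVTs adjacent to focal subtype %s",
                         focal_subtype))
  }
  pool_ids <- setdiff(evt$cell_id, by_evt$cell_a)
  focal_df <- depth[depth$cell_id %in% focal_ids, , drop = FALSE]
  pool_df <- depth[depth$cell_id %in% pool_ids, , drop = FALSE]
  matched <- depth_match(focal_df, pool_df, bin_px = bin_px, seed = seed)
  out <- dplyr::bind_rows(
    dplyr::mutate(focal_df, group = "adjacent_focal"),
    dplyr::mutate(depth[depth$cell_id %in% other_ids, , drop = FALSE],
                  group = "adjacent_other"),
    dplyr::mutate(dplyr::select(matched, "cell_id", "depth_px"),
                  group = "matched_control")
  )
  attr(out, "depth_balance_p") <- attr(matched, "depth_balance_p")
  out
}

#' Contrast iScores across stromal-adjacency groups
#'
#' Two-sided rank-sum tests of the focal-adjacent group against (1) the
#' other-DSC-adjacent group and (2) the depth-matched non-adjacent controls,
#' Benjamini-Hochberg corrected over the two headline contrasts. The
#' depth-balance check p-value is carried through.
#'
#' @param groups Tibble from [assign_adjacency_groups()].
#' @param scores Tibble with `cell_id`, `iscore` (from [score_cells()]).
#' @param min_n Minimum group size (default 10).
#' @return Object of class `adjacency_contrast`: list with `summary`
#'   (per-group n and median iScore), `tests` (contrast, p, p_adj),
#'   `depth_balance_p`.
#' @export
contrast_iscores <- function(groups, scores, min_n = 10) {
  .assert_cols(groups, c("cell_id", "group"), "groups")
  .assert_cols(scores, c("cell_id", "iscore"), "scores")
  df <- dplyr::inner_join(groups, dplyr::select(scores, "cell_id", "iscore"),
                          by = "cell_id")
  want <- c("adjacent_focal", "adjacent_other", "matched_control")
  sizes <- table(factor(df$group, levels = want))
  if (any(sizes < min_n)) {
    rlang::abort(sprintf("undersized group(s): %s",
                         paste(sprintf("%s=%d", names(sizes), sizes),
                               collapse = ", ")))
  }
  gs <- function(g) df$iscore[df$group == g]
  tests <- tibble::tibble(
    contrast = c("focal_vs_other", "focal_vs_matched"),
    p = c(.ranksum_p(gs("adjacent_focal"), gs("adjacent_other")),
          .ranksum_p(gs("adjacent_focal"), gs("matched_control")))
  )
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  summary <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), median_iscore = stats::median(.data$iscore),
                     median_depth = stats::median(.data$depth_px),
                     .groups = "drop")
  structure(list(summary = summary, tests = tests,
                 depth_balance_p = attr(groups, "depth_balance_p"),
                 data = df),
            class = "adjacency_contrast")
}

#' @export
print.adjacency_contrast <- function(x, ...) {
  cat("<adjacency_contrast> EVT iScores by stromal adjacency\n")
  print(x$summary)
  print(x$tests)
  cat(sprintf("  depth-balance check p = %.3g\n",
              x$depth_balance_p %||% NA))
  invisible(x)
}
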