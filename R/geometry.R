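#' Signed distance from cells to the interface polyline
#'
#' Computes, for every cell, the unsigned Euclidean distance to the
#' maternal-fetal interface polyline (minimum point-to-segment distance over
#' all segments) and signs it by the side of the polyline the cell falls on:
#' positive on the maternal side, negative on the fetal side. Cells beyond the
#' polyline's extent take their distance from the nearest endpoint.
#'
#' @param cells A data frame with columns `cell_id`, `x_px`, `y_px`.
#' @param interface A list with `vertices` (an n x 2 matrix of ordered polyline
#'   vertices, in pixels) and `maternal_side` (`"right"` or `"left"`, the side
#'   of the directed polyline on which the maternal compartment lies).
#' @return A tibble with columns `cell_id`, `d_interface_px` (signed pixels,
#'   maternal positive) and `compartment` (`"maternal"`/`"fetal"`; cells at
#'   exactly zero distance are labelled maternal).
#' @export
distance_to_interface <- function(cells, interface) {
  .assert_cols(cells, c("cell_id", "x_px", "y_px"), "cells")
  V <- interface$vertices
  if (is.null(V) || nrow(V) < 2) {
    rlang::abort("interface polyline must have at least 2 vertices")
  }
  side <- interface$maternal_side %||% "right"
  if (!side %in% c("right", "left")) {
    rlang::abort("interface$maternal_side must be \"right\" or \"left\"")
  }
  A <- V[-nrow(V), , drop = FALSE]
  B <- V[-1, , drop = FALSE]
  hit <- .dist_to_segments(cells$x_px, cells$y_px, A, B)
  # cross > 0 means the point is on the left of the directed segment
  s <- sign(hit$cross)
  signed <- hit$dist * if (side == "right") -s else s
  tibble::tibble(
    cell_id = cells$cell_id,
    d_interface_px = signed,
    compartment = ifelse(signed >= 0, "maternal", "fetal")
  )
}

#' Signed distance from cells to the nearest vessel wall
#'
#' The vessel wall is distance zero; distances are positive intraluminal
#' (inside the vessel) and negative extraluminal. Ties between equidistant
#' vessels are broken by the lowest `vessel_id`. Cells in the fetal
#' compartment are flagged ineligible for vessel-proximity analyses (the
#' distance is still reported).
#'
#' @param cells Data frame with `cell_id`, `x_px`, `y_px` and optionally
#'   `compartment`.
#' @param vessels A vessel table as stored in a [tissue_section]: columns
#'   `vessel_id`, `kind` (`"circle"` or `"polygon"`), `cx`, `cy`, `r` (circle
#'   centre/radius) and `vertices` (list column of n x 2 matrices for
#'   polygons).
#' @return Tibble with `cell_id`, `d_vessel_px`, `nearest_vessel_id`,
#'   `vessel_eligible`.
#' @export
distance_to_vessels <- function(cells, vessels) {
  .assert_cols(cells, c("cell_id", "x_px", "y_px"), "cells")
  if (is.null(vessels) || nrow(vessels) == 0) {
    rlang::abort("at least one vessel is required")
  }
  vessels <- dplyr::arrange(vessels, .data$vessel_id)
  n <- nrow(cells)
  best_wall <- rep(Inf, n)
  best_signed <- rep(NA_real_, n)
  best_id <- rep(NA_integer_, n)
  for (j in seq_len(nrow(vessels))) {
    kind <- vessels$kind[j]
    if (kind == "circle") {
      dc <- sqrt((cells$x_px - vessels$cx[j])^2 + (cells$y_px - vessels$cy[j])^2)
      signed <- vessels$r[j] - dc
    } else {
      V <- vessels$vertices[[j]]
      ring_A <- V
      ring_B <- V[c(2:nrow(V), 1), , drop = FALSE]
      hit <- .dist_to_segments(cells$x_px, cells$y_px, ring_A, ring_B)
      inside <- .point_in_polygon(cells$x_px, cells$y_px, V)
      signed <- ifelse(inside, hit$dist, -hit$dist)
    }
    wall <- abs(signed)
    upd <- wall < best_wall  # strict: earlier (lower) vessel_id wins ties
    best_wall[upd] <- wall[upd]
    best_signed[upd] <- signed[upd]
    best_id[upd] <- vessels$vessel_id[j]
  }
  eligible <- if ("compartment" %in% names(cells)) {
    cells$compartment == "maternal"
  } else {
    rep(TRUE, n)
  }
  tibble::tibble(
    cell_id = cells$cell_id,
    d_vessel_px = best_signed,
    nearest_vessel_id = best_id,
    vessel_eligible = eligible
  )
}

#' Per-cell distance table for a tissue section
#'
#' Convenience wrapper computing signed interface and vessel-wall distances for
#' every cell of a section.
#'
#' @param section A [tissue_section].
#' @return Tibble with `cell_id`, `cell_type`, `subtype`, `d_interface_px`,
#'   `compartment`, and, when the section has vessels, `d_vessel_px`,
#'   `nearest_vessel_id`, `vessel_eligible`.
#' @export
compute_distances <- function(section) {
  stopifnot(inherits(section, "tissue_section"))
  di <- distance_to_interface(section$cells, section$landmarks$interface)
  out <- dplyr::left_join(
    dplyr::select(section$cells, "cell_id", "cell_type", "subtype"),
    di, by = "cell_id"
  )
  if (!is.null(section$landmarks$vessels) && nrow(section$landmarks$vessels) > 0) {
    dv <- distance_to_vessels(
      dplyr::mutate(section$cells, compartment = out$compartment),
      section$landmarks$vessels
    )
    out <- dplyr::left_join(out, dv, by = "cell_id")
  }
  out
}

#' Distance-binned cell-type composition profile
#'
#' Assigns cells to half-open distance bins `[kW, (k+1)W)` and computes
#' per-bin cell-type counts and proportions.
#'
#' @param data Data frame holding one row per cell with a distance column and a
#'   label column.
#' @param dist_col Name of the (signed) distance column, default
#'   `"d_interface_px"`.
#' @param label_col Name of the cell label column, default `"cell_type"`.
#' @param bin_width Bin width W in pixels (default 100).
#' @param side Restrict to `"maternal"` (distance >= 0), `"fetal"`
#'   (distance < 0) or `"both"`.
#' @param max_range Optional maximum |distance| in pixels; cells beyond it are
#'   excluded.
#' @return Tibble with `bin`, `bin_lo`, `bin_hi`, per-type `n`, `prop`, and the
#'   bin total `n_bin`. Empty input yields an empty profile.
#' @export
bin_composition <- function(data, dist_col = "d_interface_px",
                            label_col = "cell_type", bin_width = 100,
                            side = c("both", "maternal", "fetal"),
                            max_range = NULL) {
  side <- match.arg(side)
  .assert_scalar_num(bin_width, "bin_width", 0, strict = TRUE)
  .assert_cols(data, c(dist_col, label_col), "data")
  d <- data[[dist_col]]
  keep <- !is.na(d)
  if (side == "maternal") keep <- keep & d >= 0
  if (side == "fetal") keep <- keep & d < 0
  if (!is.null(max_range)) keep <- keep & abs(d) <= max_range
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) {
    return(tibble::tibble(bin = integer(), bin_lo = numeric(),
                          bin_hi = numeric(), label = character(),
                          n = integer(), n_bin = integer(), prop = numeric()))
  }
  data$bin <- floor(data[[dist_col]] / bin_width)
  out <- data |>
    dplyr::count(.data$bin, label = .data[[label_col]]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(n_bin = sum(.data$n), prop = .data$n / .data$n_bin) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = .data$bin * bin_width,
                  bin_hi = (.data$bin + 1) * bin_width) |>
    dplyr::select("bin", "bin_lo", "bin_hi", "label", "n", "n_bin", "prop") |>
    dplyr::arrange(.data$bin, .data$label)
  out
}

#' Grid-tile adjacency between cells
#'
#' Cells are binned to a square grid of side `tile_px`; two cells are adjacent
#' when their tiles are within Chebyshev distance `k_tiles`. Self-pairs are
#' excluded; the relation is symmetric (both orientations are returned when
#' `from`/`to` are not restricted).
#'
#' @param cells Data frame with `cell_id`, `x_px`, `y_px`.
#' @param tile_px Tile side in pixels (default 50, i.e. 25 micrometres).
#' @param k_tiles Maximum Chebyshev tile distance (default 5).
#' @param from,to Optional character vectors of cell ids restricting the pair
#'   set to `from` x `to`.
#' @return Tibble with columns `cell_a`, `cell_b`.
#' @export
tile_adjacency <- function(cells, tile_px = 50, k_tiles = 5,
                           from = NULL, to = NULL) {
  .assert_scalar_num(tile_px, "tile_px", 0, strict = TRUE)
  .assert_scalar_num(k_tiles, "k_tiles", 0)
  .assert_cols(cells, c("cell_id", "x_px", "y_px"), "cells")
  tiles <- tibble::tibble(
    cell_id = cells$cell_id,
    tx = floor(cells$x_px / tile_px),
    ty = floor(cells$y_px / tile_px)
  )
  a <- if (is.null(from)) tiles else tiles[tiles$cell_id %in% from, ]
  b <- if (is.null(to)) tiles else tiles[tiles$cell_id %in% to, ]
  offs <- expand.grid(dx = -k_tiles:k_tiles, dy = -k_tiles:k_tiles)
  pieces <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    shifted <- dplyr::mutate(b, tx = .data$tx - offs$dx[i],
                             ty = .data$ty - offs$dy[i])
    pieces[[i]] <- dplyr::inner_join(
      a, shifted, by = c("tx", "ty"), suffix = c("_a", "_b"),
      relationship = "many-to-many"
    )
  }
  out <- dplyr::bind_rows(pieces) |>
    dplyr::filter(.data$cell_id_a != .data$cell_id_b) |>
    dplyr::distinct(cell_a = .data$cell_id_a, cell_b = .data$cell_id_b)
  dplyr::arrange(out, .data$cell_a, .data$cell_b)
}

#' Depth-matched sampling from a pool of cells
#'
#' Stratified sampling: the pool is sampled so that its histogram of depths
#' (bins of `bin_px`) matches the reference group's, up to per-bin pool
#' availability. A rank-sum test on the matched depths is reported as a
#' post-check (expected non-significant).
#'
#' @param group_a Reference data frame with `cell_id` and `depth_px`.
#' @param pool Candidate data frame with `cell_id` and `depth_px`.
#' @param bin_px Stratification bin width in pixels (default 100).
#' @param seed Optional integer seed for the stratified draws.
#' @return Tibble of matched pool rows; attributes `depth_balance_p` (rank-sum
#'   p-value, reference vs matched) and `dropped_strata` (bins with an empty
#'   pool).
#' @export
depth_match <- function(group_a, pool, bin_px = 100, seed = NULL) {
  .assert_cols(group_a, c("cell_id", "depth_px"), "group_a")
  .assert_cols(pool, c("cell_id", "depth_px"), "pool")
  .assert_scalar_num(bin_px, "bin_px", 0, strict = TRUE)
  ga <- dplyr::mutate(group_a, .bin = floor(.data$depth_px / bin_px))
  po <- dplyr::mutate(pool, .bin = floor(.data$depth_px / bin_px))
  need <- dplyr::count(ga, .data$.bin, name = "need")
  picked <- .with_seed(seed, {
    res <- vector("list", nrow(need))
    dropped <- integer(0)
    for (i in seq_len(nrow(need))) {
      b <- need$.bin[i]
      cand <- po[po$.bin == b, , drop = FALSE]
      if (nrow(cand) == 0) {
        dropped <- c(dropped, b)
        next
      }
      take <- min(need$need[i], nrow(cand))
      res[[i]] <- cand[sample.int(nrow(cand), take), , drop = FALSE]
    }
    list(rows = dplyr::bind_rows(res), dropped = dropped)
  })
  if (length(picked$dropped) > 0) {
    rlang::warn(sprintf("depth_match: %d stratum(ta) had no pool cells and were dropped",
                        length(picked$dropped)))
  }
  matched <- picked$rows
  if (nrow(matched) == 0) {
    rlang::abort("depth_match: no pool cells available in any stratum")
  }
  p <- stats::wilcox.test(group_a$depth_px, matched$depth_px,
                          exact = FALSE)$p.value
  matched <- dplyr::select(matched, -".bin")
  attr(matched, "depth_balance_p") <- p
  attr(matched, "dropped_strata") <- picked$dropped
  matched
}
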