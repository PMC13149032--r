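#' EVT density in the annulus adjacent to each vessel wall
#'
#' For each vessel, counts cells of `cell_type` whose nearest vessel is that
#' vessel and whose signed wall distance lies in `[-annulus_px, 0]`
#' (extraluminal, within the annulus), and divides by the annulus area. For
#' circles the area is the exact `pi * ((r + w)^2 - r^2)`; for convex polygon
#' vessels the outward-buffer area `A + P * w + pi * w^2` is used.
#'
#' @param section A `tissue_section` with vessels.
#' @param distances Distance table from [compute_distances()].
#' @param annulus_px Annulus width w in pixels (default 100).
#' @param cell_type Label counted (default `"EVT"`).
#' @return Tibble with `vessel_id`, `n_cells`, `area_px2`, `density`
#'   (cells per px^2).
#' @export
vessel_evt_density <- function(section, distances, annulus_px = 100,
                               cell_type = "EVT") {
  .assert_scalar_num(annulus_px, "annulus_px", 0, strict = TRUE)
  vessels <- section$landmarks$vessels
  if (is.null(vessels) || nrow(vessels) == 0) {
    rlang::abort("section has no vessels")
  }
  .assert_cols(distances, c("cell_id", "cell_type", "d_vessel_px",
                            "nearest_vessel_id"), "distances")
  in_annulus <- distances$d_vessel_px <= 0 &
    distances$d_vessel_px >= -annulus_px &
    distances$cell_type == cell_type &
    (distances$vessel_eligible %||% TRUE)
  tallies <- distances[in_annulus, , drop = FALSE] |>
    dplyr::count(vessel_id = .data$nearest_vessel_id, name = "n_cells")
  areas <- vapply(seq_len(nrow(vessels)), function(j) {
    if (vessels$kind[j] == "circle") {
      pi * ((vessels$r[j] + annulus_px)^2 - vessels$r[j]^2)
    } else {
      # outward Minkowski buffer minus the polygon itself (convex polygons)
      .polygon_perimeter(vessels$vertices[[j]]) * annulus_px +
        pi * annulus_px^2
    }
  }, numeric(1))
  out <- vessels |>
    dplyr::mutate(area_px2 = areas) |>
    dplyr::select("vessel_id", "area_px2") |>
    dplyr::left_join(tallies, by = "vessel_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L),
                  density = .data$n_cells / .data$area_px2)
  if (any(out$area_px2 <= 0)) {
    rlang::abort("vessel with zero annulus area")
  }
  out
}

.polygon_area <- function(V) {
  x <- V[, 1]; y <- V[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.polygon_perimeter <- function(V) {
  W <- rbind(V, V[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(W)^2)))
}

#' Null EVT densities from randomized size-equivalent decidual regions
#'
#' For each vessel, places `draws` congruent annuli (same lumen radius and
#' width) uniformly at random in the maternal compartment, rejecting
#' placements whose annulus crosses the interface, leaves the section, or
#' intersects any vessel lumen, and computes the EVT density of each placed
#' annulus identically to [vessel_evt_density()].
#'
#' @param section A `tissue_section` with circular vessels.
#' @param distances Distance table from [compute_distances()] (used for
#'   compartment labels).
#' @param annulus_px Annulus width in pixels (default 100).
#' @param draws Random congruent regions per vessel (default 10).
#' @param max_attempts Placement attempts per draw before failing.
#' @param seed Optional integer seed.
#' @param cell_type Label counted (default `"EVT"`).
#' @return Tibble with `vessel_id`, `draw`, `cx`, `cy`, `n_cells`,
#'   `area_px2`, `density`.
#' @export
sample_null_regions <- function(section, distances, annulus_px = 100,
                                draws = 10, max_attempts = 1000, seed = NULL,
                                cell_type = "EVT") {
  .assert_scalar_num(draws, "draws", 1)
  vessels <- section$landmarks$vessels
  if (is.null(vessels) || nrow(vessels) == 0) {
    rlang::abort("section has no vessels")
  }
  if (!all(vessels$kind == "circle")) {
    rlang::abort("null-region sampling requires circular vessels")
  }
  iface <- section$landmarks$interface
  target_ids <- distances$cell_id[distances$cell_type == cell_type &
                                    distances$compartment == "maternal"]
  xy <- section$cells[section$cells$cell_id %in% target_ids, , drop = FALSE]
  tx <- xy$x_px
  ty <- xy$y_px
  width <- max(iface$vertices[, 1])
  .with_seed(seed, {
    rows <- list()
    for (j in seq_len(nrow(vessels))) {
      r <- vessels$r[j]
      outer_r <- r + annulus_px
      area <- pi * (outer_r^2 - r^2)
      for (d in seq_len(draws)) {
        ok <- FALSE
        for (a in seq_len(max_attempts)) {
          cx <- stats::runif(1, outer_r, width - outer_r)
          cy <- stats::runif(1, outer_r, max(iface$vertices[, 2]))
          # outer disk must sit wholly in the maternal compartment
          di <- .dist_to_segments(cx, cy,
                                  iface$vertices[-nrow(iface$vertices), , drop = FALSE],
                                  iface$vertices[-1, , drop = FALSE])
          side <- sign(di$cross)
          maternal <- if ((iface$maternal_side %||% "right") == "right")
            side < 0 else side > 0
          if (!maternal || di$dist < outer_r || cy < outer_r) next
          # annulus must not intersect any vessel lumen
          dc <- sqrt((vessels$cx - cx)^2 + (vessels$cy - cy)^2)
          clash <- any(dc < outer_r + vessels$r & dc + vessels$r > r)
          if (clash) next
          ok <- TRUE
          break
        }
        if (!ok) {
          rlang::abort(sprintf(
            "null-region placement failed for vessel %d after %d attempts",
            vessels$vessel_id[j], max_attempts))
        }
        dd <- sqrt((tx - cx)^2 + (ty - cy)^2)
        n_in <- sum(dd >= r & dd <= outer_r)
        rows[[length(rows) + 1]] <- tibble::tibble(
          vessel_id = vessels$vessel_id[j], draw = d, cx = cx, cy = cy,
          n_cells = n_in, area_px2 = area, density = n_in / area)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Rank-sum test for perivascular EVT enrichment
#'
#' Compares per-vessel annulus densities against null densities from
#' randomized congruent decidual regions with a two-sided Wilcoxon rank-sum
#' test (exact enumeration when both groups have at most 10 untied values,
#' normal approximation with tie correction otherwise).
#'
#' @param vessel_densities Numeric vector (or tibble with `density`) of
#'   per-vessel annulus densities.
#' @param null_densities Numeric vector (or tibble with `density`) of null
#'   region densities.
#' @return An object of class `enrichment_result`: a list with `p_value`,
#'   `statistic`, `n_vessels`, `n_null`, `median_vessel`, `median_null`, and
#'   the two density vectors.
#' @export
enrichment_test <- function(vessel_densities, null_densities) {
  if (is.data.frame(vessel_densities)) vessel_densities <- vessel_densities$density
  if (is.data.frame(null_densities)) null_densities <- null_densities$density
  if (length(vessel_densities) == 0 || length(null_densities) == 0) {
    rlang::abort("both density groups must be nonempty")
  }
  exact <- length(vessel_densities) <= 10 && length(null_densities) <= 10 &&
    !any(duplicated(c(vessel_densities, null_densities)))
  ht <- stats::wilcox.test(vessel_densities, null_densities,
                           alternative = "two.sided", exact = exact,
                           correct = !exact)
  structure(
    list(p_value = ht$p.value, statistic = unname(ht$statistic),
         n_vessels = length(vessel_densities),
         n_null = length(null_densities),
         median_vessel = stats::median(vessel_densities),
         median_null = stats::median(null_densities),
         vessel_densities = vessel_densities,
         null_densities = null_densities),
    class = "enrichment_result"
  )
}

#' Perivascular EVT enrichment analysis of a section
#'
#' Convenience pipeline: per-vessel annulus densities, randomized null
#' regions, and the pooled rank-sum comparison.
#'
#' @inheritParams sample_null_regions
#' @return An `enrichment_result` (see [enrichment_test()]) with the
#'   per-vessel and null density tables attached.
#' @export
test_vessel_enrichment <- function(section, distances = NULL,
                                   annulus_px = 100, draws = 10,
                                   seed = NULL, cell_type = "EVT") {
  if (is.null(distances)) distances <- compute_distances(section)
  dens <- vessel_evt_density(section, distances, annulus_px, cell_type)
  null <- sample_null_regions(section, distances, annulus_px, draws,
                              seed = seed, cell_type = cell_type)
  res <- enrichment_test(dens$density, null$density)
  res$vessel_table <- dens
  res$null_table <- null
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> perivascular density vs randomized regions\n")
  cat(sprintf("  vessels: n=%d, median density %.3g px^-2\n",
              x$n_vessels, x$median_vessel))
  cat(sprintf("  null:    n=%d, median density %.3g px^-2\n",
              x$n_null, x$median_null))
  cat(sprintf("  two-sided rank-sum p = %.3g\n", x$p_value))
  invisible(x)
}
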