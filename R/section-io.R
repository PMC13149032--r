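#' Write a section bundle to disk
#'
#' A bundle directory holds `cells.tsv` (cell table, sorted by `cell_id`),
#' `landmarks.geojson` (FeatureCollection: interface LineString with
#' `role = "interface"` and `maternal_side`; vessels as Point features with a
#' `radius_px` property for circles or Polygon features, `role = "vessel"`),
#' and, when expression is attached, `matrix.mtx` (MatrixMarket coordinate,
#' 1-based, columns in `cells.tsv` order) with `genes.tsv` (gene_id,
#' gene_name). An optional `truth.json` stores planted ground truth.
#' Coordinates are 0.5-micrometre pixels, origin lower-left, y upward.
#'
#' @param section A `tissue_section`.
#' @param dir Output directory (created if absent).
#' @param truth Optional ground-truth list to serialize as `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_section_bundle <- function(section, dir, truth = NULL) {
  stopifnot(inherits(section, "tissue_section"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- dplyr::arrange(section$cells, .data$cell_id)
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))

  features <- list()
  iface <- section$landmarks$interface
  features[[1]] <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = unname(apply(iface$vertices, 1, as.list,
                                               simplify = FALSE))),
    properties = list(role = "interface",
                      maternal_side = iface$maternal_side %||% "right")
  )
  vessels <- section$landmarks$vessels
  if (!is.null(vessels) && nrow(vessels) > 0) {
    for (j in seq_len(nrow(vessels))) {
      if (vessels$kind[j] == "circle") {
        geom <- list(type = "Point",
                     coordinates = list(vessels$cx[j], vessels$cy[j]))
        props <- list(role = "vessel", vessel_id = vessels$vessel_id[j],
                      radius_px = vessels$r[j])
      } else {
        V <- vessels$vertices[[j]]
        ring <- rbind(V, V[1, , drop = FALSE])  # closed ring per GeoJSON
        geom <- list(type = "Polygon",
                     coordinates = list(unname(apply(ring, 1, as.list,
                                                     simplify = FALSE))))
        props <- list(role = "vessel", vessel_id = vessels$vessel_id[j])
      }
      features[[length(features) + 1]] <- list(type = "Feature",
                                               geometry = geom,
                                               properties = props)
    }
  }
  gj <- list(type = "FeatureCollection",
             properties = list(units = "0.5um_pixel", origin = "lower-left",
                               section_id = section$section_id),
             features = features)
  jsonlite::write_json(gj, file.path(dir, "landmarks.geojson"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(section$expression)) {
    x <- section$expression[, cells$cell_id, drop = FALSE]
    Matrix::writeMM(x, file.path(dir, "matrix.mtx"))
    genes <- section$genes %||%
      tibble::tibble(gene_id = rownames(x), gene_name = rownames(x))
    readr::write_tsv(genes, file.path(dir, "genes.tsv"))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

.parse_landmarks <- function(path) {
  gj <- jsonlite::read_json(path)
  interface <- NULL
  vrows <- list()
  for (f in gj$features) {
    role <- f$properties$role
    if (identical(role, "interface")) {
      V <- do.call(rbind, lapply(f$geometry$coordinates,
                                 function(p) c(p[[1]], p[[2]])))
      if (is.null(V) || nrow(V) < 2) {
        rlang::abort("landmarks: interface LineString needs >= 2 vertices")
      }
      interface <- list(vertices = unname(V),
                        maternal_side = f$properties$maternal_side %||% "right")
    } else if (identical(role, "vessel")) {
      vid <- f$properties$vessel_id
      if (identical(f$geometry$type, "Point")) {
        vrows[[length(vrows) + 1]] <- tibble::tibble(
          vessel_id = as.integer(vid), kind = "circle",
          cx = f$geometry$coordinates[[1]], cy = f$geometry$coordinates[[2]],
          r = f$properties$radius_px, vertices = list(NULL))
      } else if (identical(f$geometry$type, "Polygon")) {
        ring <- f$geometry$coordinates[[1]]
        V <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        if (nrow(V) < 4 ||
            any(V[1, ] != V[nrow(V), ])) {
          rlang::abort(sprintf(
            "landmarks: vessel %s polygon ring must be closed (first vertex repeated)",
            vid))
        }
        vrows[[length(vrows) + 1]] <- tibble::tibble(
          vessel_id = as.integer(vid), kind = "polygon",
          cx = NA_real_, cy = NA_real_, r = NA_real_,
          vertices = list(unname(V[-nrow(V), , drop = FALSE])))
      } else {
        rlang::abort(sprintf("landmarks: unsupported vessel geometry %s",
                             f$geometry$type))
      }
    }
  }
  if (is.null(interface)) {
    rlang::abort("landmarks: no feature with role=\"interface\" found")
  }
  vessels <- if (length(vrows) > 0) {
    dplyr::arrange(dplyr::bind_rows(vrows), .data$vessel_id)
  } else {
    tibble::tibble(vessel_id = integer(), kind = character(), cx = numeric(),
                   cy = numeric(), r = numeric(), vertices = list())
  }
  list(interface = interface, vessels = vessels,
       section_id = gj$properties$section_id %||% NA_character_)
}

#' Read a section bundle from disk
#'
#' @param dir Bundle directory written by [write_section_bundle()]. Must
#'   contain `cells.tsv` and `landmarks.geojson`; `matrix.mtx` + `genes.tsv`
#'   are attached when present.
#' @return A `tissue_section`.
#' @export
read_section_bundle <- function(dir) {
  cells_path <- file.path(dir, "cells.tsv")
  lm_path <- file.path(dir, "landmarks.geojson")
  for (p in c(cells_path, lm_path)) {
    if (!file.exists(p)) rlang::abort(sprintf("bundle is missing %s", basename(p)))
  }
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE,
                           progress = FALSE)
  .assert_cols(cells, c("cell_id", "x_px", "y_px", "cell_type"), "cells.tsv")
  if (anyDuplicated(cells$cell_id)) {
    rlang::abort("cells.tsv contains duplicate cell_id values")
  }
  if (!all(is.finite(cells$x_px)) || !all(is.finite(cells$y_px))) {
    rlang::abort("cells.tsv contains non-finite coordinates")
  }
  lm <- .parse_landmarks(lm_path)
  expression <- NULL
  genes <- NULL
  mtx_path <- file.path(dir, "matrix.mtx")
  if (file.exists(mtx_path)) {
    genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    x <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
    if (nrow(x) != nrow(genes) || ncol(x) != nrow(cells)) {
      rlang::abort("matrix.mtx dimensions do not match genes.tsv / cells.tsv")
    }
    dimnames(x) <- list(genes$gene_id, cells$cell_id)
    expression <- x
  }
  structure(
    list(section_id = lm$section_id, cells = tibble::as_tibble(cells),
         landmarks = list(interface = lm$interface, vessels = lm$vessels),
         expression = expression, genes = genes),
    class = "tissue_section"
  )
}

#' Quality-control filter on cells
#'
#' Excludes cells with low complexity (detected genes strictly below
#' `min_genes`), excessive transcript totals (strictly above `max_counts`),
#' or high mitochondrial content (fraction strictly above `max_mito_frac`).
#' Boundary values are retained. The per-criterion removal counts are attached
#' as the `qc_report` attribute. Filtering is idempotent.
#'
#' @param section A `tissue_section` with expression attached.
#' @param min_genes Minimum detected genes (default 100); `0` disables.
#' @param max_counts Maximum total transcript count per cell (default 10000);
#'   `Inf` disables.
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.20).
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @param max_genes Optional cap on detected genes (strictly above excluded);
#'   `NULL` disables.
#' @return The filtered `tissue_section`, with attribute `qc_report`.
#' @export
filter_cells <- function(section, min_genes = 100, max_counts = 10000,
                         max_mito_frac = 0.20, mito_prefix = "MT-",
                         max_genes = NULL) {
  stopifnot(inherits(section, "tissue_section"))
  if (is.null(section$expression)) {
    rlang::abort("filter_cells: section has no expression attached")
  }
  x <- section$expression[, section$cells$cell_id, drop = FALSE]
  total <- Matrix::colSums(x)
  ngene <- Matrix::colSums(x > 0)
  mito_rows <- startsWith(rownames(x), mito_prefix)
  mito_frac <- if (any(mito_rows)) {
    Matrix::colSums(x[mito_rows, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(x))
  }
  low_complexity <- ngene < min_genes
  excessive <- total > max_counts
  high_mito <- mito_frac > max_mito_frac
  too_many_genes <- if (is.null(max_genes)) rep(FALSE, ncol(x)) else
    ngene > max_genes
  drop <- low_complexity | excessive | high_mito | too_many_genes
  keep_ids <- section$cells$cell_id[!drop]
  section$cells <- section$cells[!drop, , drop = FALSE]
  section$expression <- section$expression[, keep_ids, drop = FALSE]
  attr(section, "qc_report") <- tibble::tibble(
    criterion = c("low_complexity", "excessive_counts", "high_mito",
                  "excessive_genes", "total_removed", "retained"),
    n = c(sum(low_complexity), sum(excessive), sum(high_mito),
          sum(too_many_genes), sum(drop), sum(!drop))
  )
  section
}
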