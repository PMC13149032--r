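# shared small fixtures, generated in code

small_section_config <- function(seed = 1, ...) {
  defaults <- list(
    width_px = 3000, height_px = 2000,
    interface_amplitude_px = 120, interface_period_px = 1200,
    n_vessels = 3, vessel_radius_px = 90, vessel_clearance_px = 250,
    cell_counts = c(EVT = 800, DSC = 300, Immune = 150, EC = 120,
                    VCT = 150, SCT = 150),
    seed = seed
  )
  do.call(section_config, utils::modifyList(defaults, list(...)))
}

small_expression_config <- function(seed = 1, ...) {
  expression_config(n_genes = 400, n_invasion_genes = 12,
                    n_mimicry_genes = 12, seed = seed, ...)
}

# hand-built section: flat interface at y = y0 (maternal below), no vessels
flat_section <- function(cells, y0 = 1000, width = 4000, vessels = NULL) {
  vr <- if (is.null(vessels)) {
    tibble::tibble(vessel_id = integer(), kind = character(), cx = numeric(),
                   cy = numeric(), r = numeric(), vertices = list())
  } else {
    vessels
  }
  structure(
    list(section_id = "handmade", cells = cells,
         landmarks = list(
           interface = list(vertices = cbind(c(0, width), c(y0, y0)),
                            maternal_side = "right"),
           vessels = vr),
         expression = NULL, genes = NULL),
    class = "tissue_section")
}

# test-side oracle: brute-force distance from one point to polygon edges
oracle_polygon_distance <- function(px, py, V) {
  n <- nrow(V)
  best <- Inf
  for (i in seq_len(n)) {
    a <- V[i, ]; b <- V[if (i == n) 1 else i + 1, ]
    ab <- b - a
    t <- sum((c(px, py) - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    q <- a + t * ab
    best <- min(best, sqrt((px - q[1])^2 + (py - q[2])^2))
  }
  best
}

random_convex_polygon <- function(cx, cy, r, n = 8) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.6 * r, r)
  cbind(cx + rad * cos(th), cy + rad * sin(th))
}
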