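#' Configuration for a synthetic tissue section
#'
#' Describes the geometry and cell content of a simulated basal-plate section:
#' a sinusoid-perturbed interface polyline splits the section into a fetal
#' compartment (above) and a maternal decidua (below); circular spiral-artery
#' cross-sections sit wholly in the decidua. Units are 0.5-micrometre pixels.
#'
#' @param width_px,height_px Section dimensions in pixels.
#' @param interface_amplitude_px,interface_period_px Amplitude and period of
#'   the sinusoidal perturbation of the interface polyline.
#' @param interface_frac Vertical position of the interface baseline as a
#'   fraction of `height_px` (fetal side above).
#' @param n_vessels Number of circular vessels to place in the decidua.
#' @param vessel_radius_px Vessel lumen radius.
#' @param vessel_clearance_px Minimum clearance between a vessel wall and the
#'   interface, the section border, and other vessel walls.
#' @param cell_counts Named integer vector of cells per type. Recognised types:
#'   `EVT`, `DSC`, `Immune`, `EC`, `VCT`, `SCT`.
#' @param evt_depth_decay_px Length scale of the exponential decline of EVT
#'   density with decidual depth. `Inf` gives uniform depth placement.
#' @param evt_vessel_frac Fraction of EVTs placed in perivascular rings
#'   (within `evt_vessel_range_px` of a vessel wall), emulating perivascular
#'   EVT aggregation.
#' @param evt_vessel_range_px Outer reach (pixels) of the perivascular EVT
#'   placement ring.
#' @param evt_annulus_factor Multiplier on the background EVT density planted
#'   inside the width-`100` px annulus of every vessel (1 = no extra planting);
#'   used to construct sections with known perivascular enrichment.
#' @param evt_subtype_props Named proportions of EVT subtypes `iEVT`, `eEVT`,
#'   `pEVT`. Endovascular/perivascular subtypes are placed at the vessel wall.
#' @param dsc_subtype_props Named proportions of DSC subtypes `DSC1`-`DSC4`.
#' @param dsc4_depth_scale_px Exponential depth scale of the superficial DSC4
#'   subtype; other DSC subtypes are uniform over the decidua.
#' @param ec_state_props Named proportions of endothelial states `caEC`, `R0`,
#'   `R1`, `R2`.
#' @param ec_state_offsets_px Named radial wall offsets (pixels, outward) per
#'   endothelial state.
#' @param ec_offset_jitter_px Gaussian jitter on endothelial wall offsets.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return An object of class `section_config`.
#' @export
section_config <- function(width_px = 6000, height_px = 4000,
                           interface_amplitude_px = 250,
                           interface_period_px = 2500,
                           interface_frac = 0.65,
                           n_vessels = 6, vessel_radius_px = 120,
                           vessel_clearance_px = 400,
                           cell_counts = c(EVT = 4000, DSC = 1200, Immune = 600,
                                           EC = 240, VCT = 600, SCT = 600),
                           evt_depth_decay_px = 1500,
                           evt_vessel_frac = 0.2,
                           evt_vessel_range_px = 300,
                           evt_annulus_factor = 1,
                           evt_subtype_props = c(iEVT = 0.85, eEVT = 0.1,
                                                 pEVT = 0.05),
                           dsc_subtype_props = c(DSC1 = 0.3, DSC2 = 0.3,
                                                 DSC3 = 0.15, DSC4 = 0.25),
                           dsc4_depth_scale_px = 250,
                           ec_state_props = c(caEC = 0.25, R0 = 0.25,
                                              R1 = 0.25, R2 = 0.25),
                           ec_state_offsets_px = c(caEC = 5, R0 = 5,
                                                   R1 = 30, R2 = 120),
                           ec_offset_jitter_px = 2,
                           seed = 1L) {
  for (nm in c("width_px", "height_px", "interface_amplitude_px",
               "interface_period_px", "vessel_radius_px",
               "vessel_clearance_px", "dsc4_depth_scale_px")) {
    .assert_scalar_num(get(nm), nm, 0, strict = TRUE)
  }
  .assert_scalar_num(n_vessels, "n_vessels", 0)
  .assert_scalar_num(evt_vessel_frac, "evt_vessel_frac", 0)
  .assert_scalar_num(evt_annulus_factor, "evt_annulus_factor", 0)
  if (any(cell_counts < 0)) rlang::abort("cell_counts must be >= 0")
  if (!(evt_depth_decay_px > 0)) rlang::abort("evt_depth_decay_px must be > 0")
  cfg <- as.list(environment())
  structure(cfg, class = "section_config")
}

.interface_y <- function(x, cfg) {
  # placement must agree with the emitted polyline, so once the discretized
  # interface exists all placement queries interpolate it linearly
  if (!is.null(cfg$interface_fun)) return(cfg$interface_fun(x))
  cfg$interface_frac * cfg$height_px +
    cfg$interface_amplitude_px * sin(2 * pi * x / cfg$interface_period_px)
}

.interface_vertices <- function(cfg, n_seg = 60) {
  x <- seq(0, cfg$width_px, length.out = n_seg + 1)
  unname(cbind(x, .interface_y(x, cfg)))
}

.place_vessels <- function(cfg) {
  if (cfg$n_vessels == 0) {
    return(tibble::tibble(vessel_id = integer(), kind = character(),
                          cx = numeric(), cy = numeric(), r = numeric(),
                          vertices = list()))
  }
  r <- cfg$vessel_radius_px
  clr <- cfg$vessel_clearance_px
  y_interface_min <- cfg$interface_frac * cfg$height_px - cfg$interface_amplitude_px
  y_max <- y_interface_min - r - clr
  y_min <- r + clr
  x_min <- r + clr
  x_max <- cfg$width_px - r - clr
  if (y_max <= y_min || x_max <= x_min) {
    rlang::abort("vessel placement error: section too small for the requested vessels")
  }
  centers <- matrix(NA_real_, cfg$n_vessels, 2)
  placed <- 0
  attempts <- 0
  max_attempts <- 2000 * cfg$n_vessels
  while (placed < cfg$n_vessels) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      rlang::abort(sprintf(
        "vessel placement error: could not fit %d non-overlapping vessels",
        cfg$n_vessels))
    }
    cand <- c(stats::runif(1, x_min, x_max), stats::runif(1, y_min, y_max))
    if (placed > 0) {
      dd <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 2, byrow = TRUE))^2))
      if (any(dd < 2 * r + clr)) next
    }
    placed <- placed + 1
    centers[placed, ] <- cand
  }
  tibble::tibble(
    vessel_id = seq_len(cfg$n_vessels),
    kind = "circle",
    cx = centers[, 1], cy = centers[, 2], r = r,
    vertices = replicate(cfg$n_vessels, NULL, simplify = FALSE)
  )
}

# rejection-sample maternal points outside vessel lumina
.sample_maternal_uniform <- function(n, cfg, vessels, max_depth = Inf) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    x <- stats::runif(m, 0, cfg$width_px)
    ytop <- .interface_y(x, cfg)
    y <- stats::runif(m, 0, ytop)
    ok <- (ytop - y) <= max_depth
    if (nrow(vessels) > 0) {
      for (j in seq_len(nrow(vessels))) {
        ok <- ok & ((x - vessels$cx[j])^2 + (y - vessels$cy[j])^2 >
                      vessels$r[j]^2)
      }
    }
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# depth-decaying EVT positions: depth ~ Exp(decay) truncated to local depth
.sample_depth_decay <- function(n, cfg, vessels) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    x <- stats::runif(m, 0, cfg$width_px)
    ytop <- .interface_y(x, cfg)
    depth <- if (is.finite(cfg$evt_depth_decay_px)) {
      stats::rexp(m, rate = 1 / cfg$evt_depth_decay_px)
    } else {
      stats::runif(m, 0, ytop)
    }
    y <- ytop - depth
    ok <- y > 0
    if (nrow(vessels) > 0) {
      for (j in seq_len(nrow(vessels))) {
        ok <- ok & ((x - vessels$cx[j])^2 + (y - vessels$cy[j])^2 >
                      vessels$r[j]^2)
      }
    }
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# uniform positions in the ring [r + lo, r + hi] outside a vessel lumen,
# clipped to the maternal compartment
.sample_vessel_ring <- function(n, vessel, lo, hi, cfg) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 50L)
    rad <- sqrt(stats::runif(m, (vessel$r + lo)^2, (vessel$r + hi)^2))
    th <- stats::runif(m, 0, 2 * pi)
    x <- vessel$cx + rad * cos(th)
    y <- vessel$cy + rad * sin(th)
    ok <- x >= 0 & x <= cfg$width_px & y > 0 & y < .interface_y(x, cfg)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a tissue section with known ground truth
#'
#' Generates landmarks (interface polyline, circular vessels) and places cells
#' according to the configured spatial programmes: EVT density decays with
#' decidual depth (with an optional perivascular aggregation fraction), DSC4
#' cells concentrate in superficial decidua, endothelial cells sit on or near
#' vessel walls with state-dependent outward offsets, and fetal VCT/SCT cells
#' occupy the villous side.
#'
#' @param config A [section_config].
#' @return A list with `section` (a `tissue_section`: `section_id`, `cells`
#'   tibble, `landmarks`) and `truth` (planted placement parameters, per-cell
#'   planted depth and endothelial state labels).
#' @export
simulate_section <- function(config) {
  stopifnot(inherits(config, "section_config"))
  cfg <- config
  V_interface <- .interface_vertices(cfg)
  cfg$interface_fun <- stats::approxfun(V_interface[, 1], V_interface[, 2],
                                        rule = 2)
  res <- .with_seed(cfg$seed, {
    vessels <- .place_vessels(cfg)
    counts <- cfg$cell_counts
    rows <- list()
    add_cells <- function(xy, type, subtype, depth = NA_real_, comp = "maternal") {
      if (nrow(xy) == 0) return(invisible(NULL))
      rows[[length(rows) + 1]] <<- tibble::tibble(
        x_px = xy[, 1], y_px = xy[, 2], cell_type = type,
        subtype = subtype, compartment = comp, planted_depth_px = depth
      )
      invisible(NULL)
    }

    ct <- function(nm) if (nm %in% names(counts)) unname(counts[[nm]]) else 0

    # EVTs
    n_evt <- ct("EVT")
    if (n_evt > 0) {
      sub <- sample(names(cfg$evt_subtype_props), n_evt, replace = TRUE,
                    prob = cfg$evt_subtype_props)
      n_i <- sum(sub == "iEVT")
      n_e <- sum(sub == "eEVT")
      n_p <- sum(sub == "pEVT")
      have_vessels <- nrow(vessels) > 0
      # interstitial: depth-decaying, plus a perivascular aggregation fraction
      n_peri <- if (have_vessels) stats::rbinom(1, n_i, cfg$evt_vessel_frac) else 0L
      xy_deep <- .sample_depth_decay(n_i - n_peri, cfg, vessels)
      add_cells(xy_deep, "EVT", "iEVT",
                depth = .interface_y(xy_deep[, 1], cfg) - xy_deep[, 2])
      if (n_peri > 0) {
        vs <- sample.int(nrow(vessels), n_peri, replace = TRUE)
        for (j in sort(unique(vs))) {
          nv <- sum(vs == j)
          xy <- .sample_vessel_ring(nv, vessels[j, ], 0, cfg$evt_vessel_range_px, cfg)
          add_cells(xy, "EVT", "iEVT",
                    depth = .interface_y(xy[, 1], cfg) - xy[, 2])
        }
      }
      # endovascular: on/inside the wall; perivascular: narrow outer ring
      if (have_vessels && n_e > 0) {
        vs <- sample.int(nrow(vessels), n_e, replace = TRUE)
        for (j in sort(unique(vs))) {
          nv <- sum(vs == j)
          rad <- stats::runif(nv, 0.7 * vessels$r[j], vessels$r[j])
          th <- stats::runif(nv, 0, 2 * pi)
          xy <- cbind(vessels$cx[j] + rad * cos(th),
                      vessels$cy[j] + rad * sin(th))
          add_cells(xy, "EVT", "eEVT",
                    depth = .interface_y(xy[, 1], cfg) - xy[, 2])
        }
      }
      if (have_vessels && n_p > 0) {
        vs <- sample.int(nrow(vessels), n_p, replace = TRUE)
        for (j in sort(unique(vs))) {
          nv <- sum(vs == j)
          xy <- .sample_vessel_ring(nv, vessels[j, ], 0, 100, cfg)
          add_cells(xy, "EVT", "pEVT",
                    depth = .interface_y(xy[, 1], cfg) - xy[, 2])
        }
      }
      if (!have_vessels && (n_e + n_p) > 0) {
        xy <- .sample_depth_decay(n_e + n_p, cfg, vessels)
        add_cells(xy, "EVT", rep(c("eEVT", "pEVT"), c(n_e, n_p)),
                  depth = .interface_y(xy[, 1], cfg) - xy[, 2])
      }
      # planted perivascular enrichment over the background density
      if (have_vessels && cfg$evt_annulus_factor > 1) {
        area_m <- cfg$width_px * cfg$interface_frac * cfg$height_px
        rho <- n_evt / area_m
        for (j in seq_len(nrow(vessels))) {
          ann_area <- pi * ((vessels$r[j] + 100)^2 - vessels$r[j]^2)
          n_extra <- stats::rpois(1, (cfg$evt_annulus_factor - 1) * rho * ann_area)
          if (n_extra > 0) {
            xy <- .sample_vessel_ring(n_extra, vessels[j, ], 0, 100, cfg)
            add_cells(xy, "EVT", "iEVT",
                      depth = .interface_y(xy[, 1], cfg) - xy[, 2])
          }
        }
      }
    }

    # DSCs
    n_dsc <- ct("DSC")
    if (n_dsc > 0) {
      sub <- sample(names(cfg$dsc_subtype_props), n_dsc, replace = TRUE,
                    prob = cfg$dsc_subtype_props)
      n4 <- sum(sub == "DSC4")
      xy_u <- .sample_maternal_uniform(n_dsc - n4, cfg, vessels)
      add_cells(xy_u, "DSC", sub[sub != "DSC4"],
                depth = .interface_y(xy_u[, 1], cfg) - xy_u[, 2])
      if (n4 > 0) {
        out <- matrix(NA_real_, 0, 2)
        while (nrow(out) < n4) {
          m <- max(2L * (n4 - nrow(out)), 50L)
          x <- stats::runif(m, 0, cfg$width_px)
          ytop <- .interface_y(x, cfg)
          depth <- stats::rexp(m, 1 / cfg$dsc4_depth_scale_px)
          y <- ytop - depth
          ok <- y > 0
          if (nrow(vessels) > 0) {
            for (j in seq_len(nrow(vessels))) {
              ok <- ok & ((x - vessels$cx[j])^2 + (y - vessels$cy[j])^2 >
                            vessels$r[j]^2)
            }
          }
          out <- rbind(out, cbind(x[ok], y[ok]))
        }
        out <- out[seq_len(n4), , drop = FALSE]
        add_cells(out, "DSC", "DSC4",
                  depth = .interface_y(out[, 1], cfg) - out[, 2])
      }
    }

    # immune cells: uniform over decidua
    n_imm <- ct("Immune")
    if (n_imm > 0) {
      xy <- .sample_maternal_uniform(n_imm, cfg, vessels)
      add_cells(xy, "Immune", "Immune",
                depth = .interface_y(xy[, 1], cfg) - xy[, 2])
    }

    # endothelial cells on vessel walls with state-dependent outward offsets
    n_ec <- ct("EC")
    if (n_ec > 0) {
      if (nrow(vessels) == 0) {
        rlang::abort("cannot place endothelial cells without vessels")
      }
      st <- sample(names(cfg$ec_state_props), n_ec, replace = TRUE,
                   prob = cfg$ec_state_props)
      vs <- sample.int(nrow(vessels), n_ec, replace = TRUE)
      off <- pmax(0, cfg$ec_state_offsets_px[st] +
                    stats::rnorm(n_ec, 0, cfg$ec_offset_jitter_px))
      th <- stats::runif(n_ec, 0, 2 * pi)
      rad <- vessels$r[vs] + off
      xy <- cbind(vessels$cx[vs] + rad * cos(th),
                  vessels$cy[vs] + rad * sin(th))
      add_cells(xy, "EC", st, depth = .interface_y(xy[, 1], cfg) - xy[, 2])
    }

    # fetal cells: VCT hug the interface from above, SCT uniform in villi
    n_vct <- ct("VCT")
    if (n_vct > 0) {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < n_vct) {
        m <- max(2L * (n_vct - nrow(out)), 50L)
        x <- stats::runif(m, 0, cfg$width_px)
        ybot <- .interface_y(x, cfg)
        y <- ybot + stats::rexp(m, 1 / 200)
        ok <- y < cfg$height_px
        out <- rbind(out, cbind(x[ok], y[ok]))
      }
      add_cells(out[seq_len(n_vct), , drop = FALSE], "VCT", "VCT",
                comp = "fetal")
    }
    n_sct <- ct("SCT")
    if (n_sct > 0) {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < n_sct) {
        m <- max(2L * (n_sct - nrow(out)), 50L)
        x <- stats::runif(m, 0, cfg$width_px)
        y <- stats::runif(m, 0, cfg$height_px)
        ok <- y > .interface_y(x, cfg)
        out <- rbind(out, cbind(x[ok], y[ok]))
      }
      add_cells(out[seq_len(n_sct), , drop = FALSE], "SCT", "SCT",
                comp = "fetal")
    }

    cells <- dplyr::bind_rows(rows)
    if (nrow(cells) == 0) {
      cells <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                              cell_type = character(), subtype = character(),
                              compartment = character(),
                              planted_depth_px = numeric())
    }
    cells <- dplyr::mutate(cells,
                           cell_id = sprintf("c%06d", dplyr::row_number()),
                           .before = 1)
    list(cells = cells, vessels = vessels)
  })

  truth <- list(
    config = unclass(cfg)[setdiff(names(cfg), c("cell_counts", "interface_fun"))],
    cell_depths = dplyr::select(res$cells, "cell_id", "planted_depth_px"),
    ec_states = dplyr::filter(res$cells, .data$cell_type == "EC") |>
      dplyr::select("cell_id", state = "subtype"),
    vessels = dplyr::select(res$vessels, -"vertices")
  )
  section <- structure(
    list(
      section_id = sprintf("synthetic-seed%d", cfg$seed),
      cells = dplyr::select(res$cells, -"planted_depth_px"),
      landmarks = list(
        interface = list(vertices = V_interface,
                         maternal_side = "right"),
        vessels = res$vessels
      ),
      expression = NULL,
      genes = NULL
    ),
    class = "tissue_section"
  )
  list(section = section, truth = truth)
}

#' @export
print.tissue_section <- function(x, ...) {
  cat(sprintf("<tissue_section> %s\n", x$section_id))
  cat(sprintf("  cells: %d (%s)\n", nrow(x$cells),
              paste(sprintf("%s=%d", names(table(x$cells$cell_type)),
                            table(x$cells$cell_type)), collapse = ", ")))
  nv <- if (is.null(x$landmarks$vessels)) 0 else nrow(x$landmarks$vessels)
  cat(sprintf("  landmarks: interface (%d vertices), %d vessel(s)\n",
              nrow(x$landmarks$interface$vertices), nv))
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d genes x %d cells\n",
                nrow(x$expression), ncol(x$expression)))
  }
  invisible(x)
}
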