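#' Configuration for synthetic expression counts
#'
#' Counts are negative binomial with a shared dispersion; each gene's log-mean
#' is a per-gene baseline plus planted terms: a depth-linear invasion
#' programme in maternal EVTs, an endothelium-mimicry term that decays with
#' distance from the vessel wall, PDE3A/VIM quadrant means that define
#' endothelial remodelling states, and a local suppression of the invasion
#' programme in EVTs close to a focal DSC subtype.
#'
#' @param n_genes Size of the gene universe (includes the named marker and
#'   mitochondrial genes).
#' @param base_logmean_range Range (natural-log scale) of the per-gene baseline
#'   log-mean counts, drawn uniformly.
#' @param theta Negative binomial dispersion (size); must be > 0.
#' @param n_invasion_genes Number of planted invasion-programme genes.
#' @param invasion_slope_range Range of planted slope magnitudes, in log-mean
#'   change per 1,000 px of decidual depth.
#' @param invasion_prop_positive Fraction of invasion genes with positive
#'   slopes (up-regulated with depth, pro-invasive); the rest carry negative
#'   slopes (anti-invasive). Mixing signs keeps per-cell library totals
#'   depth-stable.
#' @param invasion_base_logmean Baseline log-mean of invasion genes.
#' @param n_mimicry_genes Number of planted endothelium-mimicry genes.
#' @param mimicry_amplitude Log-mean elevation of mimicry genes in EVTs at the
#'   vessel wall.
#' @param mimicry_plateau_px Wall-adjacent plateau width over which the full
#'   amplitude applies.
#' @param mimicry_decay_px Exponential decay length of the mimicry term beyond
#'   the plateau.
#' @param mimicry_base_logmean Baseline log-mean of mimicry genes (set high so
#'   the planted shift survives the log1p transform).
#' @param marker_logmeans Named vector with `hi` and `lo` log-means for the
#'   PDE3A/VIM endothelial state markers.
#' @param suppression_delta Log-mean shift applied along the invasion axis in
#'   EVTs within `suppression_radius_px` of a focal DSC cell: each
#'   positive-slope (pro-invasive) gene is shifted by `suppression_delta` and
#'   each negative-slope gene by `-suppression_delta`, so a negative delta
#'   moves the whole invasion programme toward the non-invasive phenotype.
#' @param suppression_radius_px Radius of the local suppression effect; 0
#'   disables it.
#' @param focal_subtype DSC subtype exerting the suppression (default
#'   `"DSC4"`).
#' @param seed Integer seed.
#' @return An object of class `expression_config`.
#' @export
expression_config <- function(n_genes = 3000,
                              base_logmean_range = log(c(0.05, 2)),
                              theta = 1.1,
                              n_invasion_genes = 40,
                              invasion_slope_range = c(0.7, 1),
                              invasion_prop_positive = 0.5,
                              invasion_base_logmean = log(8),
                              n_mimicry_genes = 40,
                              mimicry_amplitude = 0.8,
                              mimicry_plateau_px = 100,
                              mimicry_decay_px = 100,
                              mimicry_base_logmean = log(8),
                              marker_logmeans = c(hi = log(30), lo = log(0.5)),
                              suppression_delta = -1,
                              suppression_radius_px = 0,
                              focal_subtype = "DSC4",
                              seed = 1L) {
  .assert_scalar_num(theta, "theta", 0, strict = TRUE)
  .assert_scalar_num(suppression_radius_px, "suppression_radius_px", 0)
  .assert_scalar_num(n_genes, "n_genes", 10)
  structure(as.list(environment()), class = "expression_config")
}

# gene universe: named markers + mitochondrial genes + numbered filler genes
.gene_universe <- function(n_genes) {
  mito <- c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND2", "MT-CYB")
  fixed <- c("PDE3A", "VIM", mito)
  c(fixed, sprintf("G%04d", seq_len(n_genes - length(fixed))))
}

#' Simulate expression counts for a section, with planted ground truth
#'
#' @param section A `tissue_section` (from [simulate_section()]).
#' @param config An [expression_config].
#' @return A list with `section` (the input section carrying the sparse
#'   genes x cells count matrix in `$expression`) and `truth`: planted
#'   invasion genes and slopes, mimicry genes, marker/state parameters, and
#'   the ids of suppression-affected EVTs.
#' @export
simulate_expression <- function(section, config) {
  stopifnot(inherits(section, "tissue_section"),
            inherits(config, "expression_config"))
  cfg <- config
  cells <- section$cells
  n_cells <- nrow(cells)
  genes <- .gene_universe(cfg$n_genes)
  if (n_cells == 0) rlang::abort("section has no cells")

  dist <- compute_distances(section)
  depth <- pmax(dist$d_interface_px, 0)  # maternal depth; 0 on the fetal side
  is_evt <- cells$cell_type == "EVT" & dist$compartment == "maternal"
  is_ec <- cells$cell_type == "EC"
  d_wall <- if ("d_vessel_px" %in% names(dist)) abs(dist$d_vessel_px) else
    rep(NA_real_, n_cells)

  res <- .with_seed(cfg$seed, {
    base <- stats::runif(cfg$n_genes, cfg$base_logmean_range[1],
                         cfg$base_logmean_range[2])
    names(base) <- genes
    base[c("PDE3A", "VIM")] <- cfg$marker_logmeans[["lo"]]
    base[startsWith(genes, "MT-")] <- log(5)

    pool <- genes[startsWith(genes, "G")]
    inv_genes <- sample(pool, cfg$n_invasion_genes)
    mim_genes <- sample(setdiff(pool, inv_genes), cfg$n_mimicry_genes)
    n_pos <- round(cfg$invasion_prop_positive * cfg$n_invasion_genes)
    sgn <- sample(rep(c(1, -1), c(n_pos, cfg$n_invasion_genes - n_pos)))
    slopes <- sgn * stats::runif(cfg$n_invasion_genes,
                                 cfg$invasion_slope_range[1],
                                 cfg$invasion_slope_range[2])
    names(slopes) <- inv_genes
    base[inv_genes] <- cfg$invasion_base_logmean
    base[mim_genes] <- cfg$mimicry_base_logmean

    # suppression-affected EVTs: within radius of a focal DSC cell
    affected <- character(0)
    if (cfg$suppression_radius_px > 0 && cfg$suppression_delta != 0) {
      focal <- cells[cells$cell_type == "DSC" &
                       cells$subtype == cfg$focal_subtype, , drop = FALSE]
      if (nrow(focal) > 0 && any(is_evt)) {
        ev <- cells[is_evt, , drop = FALSE]
        r2 <- cfg$suppression_radius_px^2
        near <- rep(FALSE, nrow(ev))
        for (j in seq_len(nrow(focal))) {
          near <- near | ((ev$x_px - focal$x_px[j])^2 +
                            (ev$y_px - focal$y_px[j])^2 <= r2)
        }
        affected <- ev$cell_id[near]
      }
    }

    # log-mean matrix, built as baseline plus planted submatrix terms
    L <- matrix(base, nrow = cfg$n_genes, ncol = n_cells)
    evt_idx <- which(is_evt)
    if (length(evt_idx) > 0) {
      gi <- match(inv_genes, genes)
      L[gi, evt_idx] <- L[gi, evt_idx] +
        outer(slopes, depth[evt_idx] / 1000)
      if (any(!is.na(d_wall[evt_idx]))) {
        gm <- match(mim_genes, genes)
        w <- d_wall[evt_idx]
        mim_term <- cfg$mimicry_amplitude *
          exp(-pmax(0, w - cfg$mimicry_plateau_px) / cfg$mimicry_decay_px)
        mim_term[is.na(mim_term)] <- 0
        L[gm, evt_idx] <- L[gm, evt_idx] +
          matrix(mim_term, length(gm), length(evt_idx), byrow = TRUE)
      }
      if (length(affected) > 0) {
        ai <- match(affected, cells$cell_id)
        # suppression moves cells down the invasion axis: genes that rise
        # with depth drop by |delta|, anti-invasive genes rise by |delta|
        dir <- ifelse(slopes >= 0, 1, -1)
        L[gi, ai] <- L[gi, ai] + cfg$suppression_delta * dir
      }
    }
    if (any(is_ec)) {
      st <- cells$subtype[is_ec]
      hi <- cfg$marker_logmeans[["hi"]]
      lo <- cfg$marker_logmeans[["lo"]]
      # quadrant rule: caEC hi/hi, R0 PDE3A-hi VIM-lo, R1 lo/lo, R2 PDE3A-lo VIM-hi
      pde <- ifelse(st %in% c("caEC", "R0"), hi, lo)
      vim <- ifelse(st %in% c("caEC", "R2"), hi, lo)
      L[match("PDE3A", genes), is_ec] <- pde
      L[match("VIM", genes), is_ec] <- vim
    }

    counts <- matrix(
      stats::rnbinom(length(L), mu = exp(L), size = cfg$theta),
      nrow = cfg$n_genes, ncol = n_cells,
      dimnames = list(genes, cells$cell_id)
    )
    x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    list(x = x, inv = tibble::tibble(gene = inv_genes, slope = unname(slopes)),
         mim = mim_genes, affected = affected)
  })

  section$expression <- res$x
  section$genes <- tibble::tibble(gene_id = genes, gene_name = genes)
  truth <- list(
    invasion_genes = res$inv,
    mimicry_genes = res$mim,
    mimicry = list(amplitude = cfg$mimicry_amplitude,
                   plateau_px = cfg$mimicry_plateau_px,
                   decay_px = cfg$mimicry_decay_px),
    suppression = list(delta = cfg$suppression_delta,
                       radius_px = cfg$suppression_radius_px,
                       focal_subtype = cfg$focal_subtype,
                       affected_cells = res$affected),
    marker_logmeans = cfg$marker_logmeans,
    theta = cfg$theta
  )
  list(section = section, truth = truth)
}

#' Library-size normalize and log1p-transform a count matrix
#'
#' Counts are scaled to `scale_factor` per cell and transformed as
#' `log1p(count / total * scale_factor)`. Sparsity is preserved.
#'
#' @param counts A genes x cells matrix (dense or `dgCMatrix`).
#' @param scale_factor Per-cell target total (default 1e4).
#' @return A `dgCMatrix` of normalized values.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  tot <- Matrix::colSums(x)
  tot[tot == 0] <- 1
  percol <- rep.int(tot, diff(x@p))
  x@x <- log1p(x@x / percol * scale_factor)
  x
}
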