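#' Composite differential-expression score between two cell groups
#'
#' For each gene the score combines the fold change with the difference in
#' the percentage of expressing cells:
#' `log2FC = log2((mu_a + 1) / (mu_b + 1))` on normalized group means,
#' `delta_pct = 100 * (frac expressing in a - frac expressing in b)`
#' (percentage points), and the composite
#' `score = sign(log2FC) * |log2FC * delta_pct|`: the magnitude is the
#' product of the two evidence terms and the sign follows the fold change,
#' which makes the score exactly antisymmetric under a group swap (a raw
#' product of two sign-flipping factors would be symmetric).
#'
#' @param expr_norm Normalized (log1p) genes x cells matrix.
#' @param cells_a,cells_b Disjoint character vectors of cell ids.
#' @return Tibble with `gene`, `mean_a`, `mean_b`, `log2fc`, `pct_a`, `pct_b`,
#'   `delta_pct`, `score`, `p`, `fdr`.
#' @export
composite_deg_score <- function(expr_norm, cells_a, cells_b) {
  if (length(intersect(cells_a, cells_b)) > 0) {
    rlang::abort("cells_a and cells_b overlap")
  }
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    rlang::abort("each group needs at least 2 cells")
  }
  xa <- expr_norm[, cells_a, drop = FALSE]
  xb <- expr_norm[, cells_b, drop = FALSE]
  mu_a <- Matrix::rowMeans(xa)
  mu_b <- Matrix::rowMeans(xb)
  pct_a <- 100 * Matrix::rowMeans(xa > 0)
  pct_b <- 100 * Matrix::rowMeans(xb > 0)
  log2fc <- log2((mu_a + 1) / (mu_b + 1))
  delta_pct <- pct_a - pct_b
  # vectorised two-sample rank-sum test (normal approximation with tie
  # correction), one test per gene
  na <- length(cells_a)
  nb <- length(cells_b)
  X <- cbind(as.matrix(xa), as.matrix(xb))
  p <- apply(X, 1, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    tie <- table(v)
    sigma2 <- na * nb / 12 *
      ((na + nb + 1) - sum(tie^3 - tie) / ((na + nb) * (na + nb - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - na * nb / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  })
  tibble::tibble(
    gene = rownames(expr_norm), mean_a = unname(mu_a), mean_b = unname(mu_b),
    log2fc = unname(log2fc), pct_a = unname(pct_a), pct_b = unname(pct_b),
    delta_pct = unname(delta_pct),
    score = unname(sign(log2fc) * abs(log2fc * delta_pct)),
    p = unname(p), fdr = unname(stats::p.adjust(p, method = "BH"))
  )
}

#' Select top marker genes from a composite DEG table
#'
#' The top `n` genes by composite score among genes with FDR below the
#' cutoff; ties on the score are broken by larger |log2FC|, then by gene id.
#'
#' @param deg Tibble from [composite_deg_score()].
#' @param n Number of markers (default 100).
#' @param fdr_cutoff FDR eligibility cutoff (default 0.05).
#' @return Character vector of gene ids, best first. A warning is raised when
#'   fewer than `n` genes are eligible.
#' @export
top_markers <- function(deg, n = 100, fdr_cutoff = 0.05) {
  .assert_cols(deg, c("gene", "score", "log2fc", "fdr"), "deg")
  elig <- deg |>
    dplyr::filter(.data$fdr < fdr_cutoff) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(abs(.data$log2fc)),
                   .data$gene)
  if (nrow(elig) < n) {
    rlang::warn(sprintf("only %d of %d requested marker genes are eligible",
                        nrow(elig), n))
  }
  utils::head(elig$gene, n)
}

#' Bin-controlled module score
#'
#' All genes are ranked by mean expression into `n_bins` equal-frequency
#' bins; for each signature gene, `n_controls` control genes are drawn
#' without replacement from its bin (signature genes are never controls).
#' The per-cell score is the mean normalized expression of the signature
#' minus the mean over the control draws.
#'
#' @param expr_norm Normalized (log1p) genes x cells matrix.
#' @param signature Character vector of signature gene ids.
#' @param n_bins Expression bins (default 25, >= 2).
#' @param n_controls Control genes drawn per signature gene (default 100;
#'   capped at bin size).
#' @param seed Optional integer seed for the control draws.
#' @param controls Optional precomputed control draws (the `controls`
#'   attribute of a previous score), bypassing bin construction; useful to
#'   hold the control pool fixed across matrices.
#' @return Tibble with `cell_id`, `score`; attribute `controls` lists the
#'   drawn control genes per signature gene.
#' @export
module_score <- function(expr_norm, signature, n_bins = 25, n_controls = 100,
                         seed = NULL, controls = NULL) {
  .assert_scalar_num(n_bins, "n_bins", 2)
  .assert_scalar_num(n_controls, "n_controls", 1)
  miss <- setdiff(signature, rownames(expr_norm))
  if (length(miss) > 0) {
    rlang::abort(sprintf("signature gene(s) absent from the matrix: %s",
                         paste(miss, collapse = ", ")))
  }
  gene_means <- Matrix::rowMeans(expr_norm)
  bin <- dplyr::ntile(rank(gene_means, ties.method = "first"), n_bins)
  names(bin) <- rownames(expr_norm)
  .with_seed(seed, {
    if (is.null(controls)) {
      controls <- lapply(signature, function(g) {
        cand <- names(bin)[bin == bin[[g]]]
        cand <- setdiff(cand, signature)
        if (length(cand) == 0) {
          rlang::abort(sprintf("no control candidates in the bin of gene %s", g))
        }
        cand[sample.int(length(cand), min(n_controls, length(cand)))]
      })
      names(controls) <- signature
    }
    sig_mean <- Matrix::colMeans(expr_norm[signature, , drop = FALSE])
    ctrl_mat <- vapply(controls, function(cs) {
      Matrix::colMeans(expr_norm[cs, , drop = FALSE])
    }, numeric(ncol(expr_norm)))
    ctrl_mean <- rowMeans(ctrl_mat)
    out <- tibble::tibble(cell_id = colnames(expr_norm),
                          score = unname(sig_mean - ctrl_mean))
    attr(out, "controls") <- controls
    out
  })
}

#' Spearman association between a per-cell score and vessel distance
#'
#' @param scores Tibble with `cell_id`, `score`.
#' @param distances Distance table with `cell_id`, `d_vessel_px`.
#' @param cells Optional cell ids restricting the analysis.
#' @param min_n Minimum cells required (default 10).
#' @return Tibble with `rho`, `p` (two-sided), `n`.
#' @export
score_vs_distance <- function(scores, distances, cells = NULL, min_n = 10) {
  df <- dplyr::inner_join(scores,
                          dplyr::select(distances, "cell_id", "d_vessel_px"),
                          by = "cell_id") |>
    dplyr::filter(!is.na(.data$d_vessel_px))
  if (!is.null(cells)) df <- df[df$cell_id %in% cells, , drop = FALSE]
  if (nrow(df) < min_n) {
    rlang::abort(sprintf("score_vs_distance needs at least %d cells", min_n))
  }
  ct <- suppressWarnings(
    stats::cor.test(df$score, abs(df$d_vessel_px), method = "spearman",
                    exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(df))
}
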