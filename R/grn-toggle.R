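#' Select lineage-specific transcription factors from DEG tables
#'
#' Per lineage, retains transcription factors from the supplied universe with
#' FDR below the threshold and a positive composite score (up-regulated in
#' that lineage); the cross-lineage overlap is reported.
#'
#' @param deg_tables Named list of composite DEG tables (one per lineage,
#'   from [composite_deg_score()] with that lineage as group a).
#' @param tf_universe Character vector of transcription factor gene ids.
#' @param fdr FDR threshold (default 0.01).
#' @return List with one character vector per lineage plus `shared` (TFs
#'   significant in more than one lineage).
#' @export
select_lineage_tfs <- function(deg_tables, tf_universe, fdr = 0.01) {
  if (length(tf_universe) == 0) rlang::abort("empty TF universe")
  thr <- fdr
  sets <- lapply(deg_tables, function(deg) {
    .assert_cols(deg, c("gene", "score", "fdr"), "deg table")
    hits <- deg |>
      dplyr::filter(.data$gene %in% tf_universe, .data$fdr < .env$thr,
                    .data$score > 0)
    sort(hits$gene)
  })
  shared <- character(0)
  if (length(sets) > 1) {
    all_tfs <- unlist(sets)
    shared <- sort(unique(all_tfs[duplicated(all_tfs)]))
  }
  c(sets, list(shared = shared))
}

#' Filter GRN edges by coefficient strength
#'
#' Retains edges with `|coefficient| > c_min` (strict inequality; an edge at
#' exactly the threshold is excluded).
#'
#' @param edges Tibble with `tf`, `target`, `coefficient` (and optionally
#'   `lineage`).
#' @param c_min Strength threshold (default 0.1).
#' @return The filtered tibble, with attribute `n_dropped`.
#' @export
filter_grn_edges <- function(edges, c_min = 0.1) {
  .assert_cols(edges, c("tf", "target", "coefficient"), "edges")
  keep <- abs(edges$coefficient) > c_min
  out <- edges[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Classify signed TF-target edges into toggle-switch categories
#'
#' An edge in lineage context L whose transcription factor is L-upregulated
#' is classified as `L_activation` when its coefficient is positive and
#' `L_repression` when negative. Edges from transcription factors outside
#' their context's lineage set are dropped (count recorded). TFs significant
#' in both lineages are flagged `shared`.
#'
#' @param edges Filtered edge tibble with `tf`, `target`, `coefficient`,
#'   `lineage` (context labels must match `names(lineage_tfs)` up to case,
#'   e.g. `"EVT"`/`"SCT"`).
#' @param lineage_tfs Named list of lineage TF sets (e.g. from
#'   [select_lineage_tfs()]; a `shared` element is ignored for matching).
#' @return Tibble with `tf`, `target`, `coefficient`, `lineage`, `category`
#'   (`<lineage>_activation` / `<lineage>_repression`), `shared`; attributes
#'   `n_dropped` and `category_counts`.
#' @export
classify_grn_edges <- function(edges, lineage_tfs) {
  .assert_cols(edges, c("tf", "target", "coefficient", "lineage"), "edges")
  sets <- lineage_tfs[setdiff(names(lineage_tfs), "shared")]
  in_set <- mapply(function(tf, lin) {
    lin %in% names(sets) && tf %in% sets[[lin]]
  }, edges$tf, edges$lineage)
  n_dropped <- sum(!in_set)
  out <- edges[in_set, , drop = FALSE]
  membership <- vapply(out$tf, function(tf) {
    sum(vapply(sets, function(s) tf %in% s, logical(1)))
  }, integer(1))
  out <- dplyr::mutate(
    out,
    category = paste0(tolower(.data$lineage),
                      ifelse(.data$coefficient > 0, "_activation",
                             "_repression")),
    shared = unname(membership > 1)
  )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "category_counts") <- table(out$category)
  out
}

#' Contrast target-gene expression against genome background
#'
#' For each edge category, compares the per-gene mean normalized expression
#' of the category's target genes in each lineage's cells against the
#' genome-wide background (genes expressed in at least `min_pct` of that
#' lineage's cells; targets themselves excluded from the background by
#' default), with two-sided rank-sum tests, BH-corrected over the family.
#'
#' @param classification Tibble from [classify_grn_edges()].
#' @param expr_norm Normalized genes x cells matrix.
#' @param lineage_cells Named list of cell-id vectors per lineage (names
#'   matching the classification's lineage labels).
#' @param min_pct Background expression floor as a fraction of lineage cells
#'   (default 0.01).
#' @param exclude_targets Exclude the targets from the background
#'   (default TRUE).
#' @param min_targets Categories with fewer targets are skipped with a
#'   warning (default 5).
#' @return Tibble with `category`, `lineage`, `n_targets`, `n_background`,
#'   `median_target`, `median_background`, `direction`, `p`, `p_adj`.
#' @export
target_contrast <- function(classification, expr_norm, lineage_cells,
                            min_pct = 0.01, exclude_targets = TRUE,
                            min_targets = 5) {
  .assert_cols(classification, c("target", "category"), "classification")
  rows <- list()
  for (cat in sort(unique(classification$category))) {
    targets <- unique(classification$target[classification$category == cat])
    targets <- intersect(targets, rownames(expr_norm))
    if (length(targets) < min_targets) {
      rlang::warn(sprintf("category %s has < %d targets; skipped",
                          cat, min_targets))
      next
    }
    for (lin in names(lineage_cells)) {
      cells <- lineage_cells[[lin]]
      sub <- expr_norm[, cells, drop = FALSE]
      gmeans <- Matrix::rowMeans(sub)
      expressed <- Matrix::rowMeans(sub > 0) >= min_pct
      bg <- rownames(sub)[expressed]
      if (exclude_targets) bg <- setdiff(bg, targets)
      tv <- gmeans[targets]
      bv <- gmeans[bg]
      p <- .ranksum_p(tv, bv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        category = cat, lineage = lin, n_targets = length(targets),
        n_background = length(bg),
        median_target = stats::median(tv),
        median_background = stats::median(bv),
        direction = ifelse(stats::median(tv) > stats::median(bv), "up",
                           "down"),
        p = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Jaccard overlap of a shared TF's target sets across lineages
#'
#' @param classification Tibble from [classify_grn_edges()].
#' @param tf A transcription factor present in both lineage contexts.
#' @param lineages The two lineage context labels (default `c("EVT", "SCT")`).
#' @return The Jaccard index `|A intersect B| / |A union B|`.
#' @export
shared_tf_jaccard <- function(classification, tf,
                              lineages = c("EVT", "SCT")) {
  sets <- lapply(lineages, function(lin) {
    unique(classification$target[classification$tf == tf &
                                   classification$lineage == lin])
  })
  if (any(lengths(sets) == 0)) {
    rlang::abort(sprintf("TF %s is absent from one of the lineage contexts",
                         tf))
  }
  length(intersect(sets[[1]], sets[[2]])) /
    length(union(sets[[1]], sets[[2]]))
}
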