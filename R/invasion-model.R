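#' Split EVTs into training and test sets
#'
#' Vessel-associated EVTs are excluded first (endovascular/perivascular
#' subtypes, and any EVT within `vessel_exclusion_px` of a vessel wall); the
#' remaining maternal-side EVTs are randomly partitioned at the given ratio.
#'
#' @param distances Distance table from [compute_distances()] (EVT rows are
#'   selected by `cell_type == "EVT"`).
#' @param ratio Fraction assigned to training (default 0.5).
#' @param seed Optional integer seed.
#' @param vessel_exclusion_px Exclusion radius around vessel walls
#'   (default 200); `0` disables.
#' @param exclude_subtypes Subtypes excluded as vessel-associated
#'   (default eEVT, pEVT).
#' @return List with `train`, `test` (disjoint cell-id vectors whose union is
#'   the eligible set) and `excluded`.
#' @export
split_evt_train_test <- function(distances, ratio = 0.5, seed = NULL,
                                 vessel_exclusion_px = 200,
                                 exclude_subtypes = c("eEVT", "pEVT")) {
  .assert_cols(distances, c("cell_id", "cell_type", "compartment"),
               "distances")
  evt <- distances[distances$cell_type == "EVT" &
                     distances$compartment == "maternal", , drop = FALSE]
  near_vessel <- if ("d_vessel_px" %in% names(evt) && vessel_exclusion_px > 0) {
    !is.na(evt$d_vessel_px) & abs(evt$d_vessel_px) <= vessel_exclusion_px
  } else {
    rep(FALSE, nrow(evt))
  }
  sub_excl <- if ("subtype" %in% names(evt)) {
    evt$subtype %in% exclude_subtypes
  } else {
    rep(FALSE, nrow(evt))
  }
  excluded <- evt$cell_id[near_vessel | sub_excl]
  eligible <- sort(setdiff(evt$cell_id, excluded))
  if (length(eligible) < 20) {
    rlang::abort("too few eligible EVTs to split (need >= 20)")
  }
  .with_seed(seed, {
    n_train <- floor(length(eligible) * ratio)
    train <- sort(sample(eligible, n_train))
    list(train = train, test = setdiff(eligible, train), excluded = excluded)
  })
}

#' Depth-window pseudobulk profiles
#'
#' Cells are sorted by depth (ties broken by cell id) and grouped into
#' consecutive windows of `k` cells; each window's profile is the arithmetic
#' mean of its members' normalized expression, and its depth is the mean of
#' their depths. A trailing remainder of fewer than `k` cells is dropped.
#'
#' @param expr_norm Normalized (log1p) genes x cells matrix.
#' @param depths Tibble with `cell_id`, `depth_px` for the cells to window.
#' @param k Cells per window (default 10, >= 2).
#' @return Object of class `depth_windows`: list with `x` (windows x genes
#'   matrix), `depth` (window mean depths), `members` (list of cell ids),
#'   `n_dropped`.
#' @export
build_depth_windows <- function(expr_norm, depths, k = 10) {
  .assert_scalar_num(k, "k", 2)
  .assert_cols(depths, c("cell_id", "depth_px"), "depths")
  depths <- dplyr::arrange(depths, .data$depth_px, .data$cell_id)
  n_win <- nrow(depths) %/% k
  n_drop <- nrow(depths) - n_win * k
  if (n_win == 0) rlang::abort("fewer cells than one window")
  if (n_drop > 0) {
    rlang::inform(sprintf("build_depth_windows: dropped trailing %d cell(s) (< k)",
                          n_drop))
  }
  idx <- split(seq_len(n_win * k), rep(seq_len(n_win), each = k))
  X <- matrix(0, n_win, nrow(expr_norm),
              dimnames = list(NULL, rownames(expr_norm)))
  depth <- numeric(n_win)
  members <- vector("list", n_win)
  sub <- expr_norm[, depths$cell_id[seq_len(n_win * k)], drop = FALSE]
  for (w in seq_len(n_win)) {
    cols <- idx[[w]]
    X[w, ] <- Matrix::rowMeans(sub[, cols, drop = FALSE])
    depth[w] <- mean(depths$depth_px[cols])
    members[[w]] <- depths$cell_id[cols]
  }
  structure(list(x = X, depth = depth, members = members, k = k,
                 n_dropped = n_drop),
            class = "depth_windows")
}

#' Low-level L1-penalized least-squares fit
#'
#' Thin wrapper around a coordinate-descent elastic-net solver restricted to
#' the lasso, minimizing `1/(2n) * RSS + lambda * sum(|beta|)`. Exposed so
#' the fitted path can be checked against closed-form solutions.
#'
#' @param x Predictor matrix (observations x features).
#' @param y Response vector.
#' @param lambda Penalty (single value or decreasing sequence).
#' @param intercept Fit an intercept (default TRUE).
#' @param standardize Standardize predictors internally (default FALSE; the
#'   higher-level model standardizes explicitly).
#' @param thresh Convergence threshold.
#' @return Named coefficient matrix (features x lambdas) with attribute
#'   `intercept` (vector of intercepts per lambda).
#' @export
fit_lasso <- function(x, y, lambda, intercept = TRUE, standardize = FALSE,
                      thresh = 1e-12) {
  if (stats::sd(y) == 0) {
    # constant response: every penalized solution is beta = 0
    beta <- matrix(0, ncol(x), length(lambda),
                   dimnames = list(colnames(x), NULL))
    return(structure(beta,
                     intercept = rep(if (intercept) mean(y) else 0,
                                     length(lambda))))
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                        intercept = intercept, standardize = standardize,
                        thresh = thresh, maxit = 1e7)
  cf <- as.matrix(stats::coef(fit))
  beta <- cf[-1, , drop = FALSE]
  structure(beta, intercept = cf[1, ])
}

#' Fit the invasion model (iScore) on training windows
#'
#' Features are standardized with training statistics (zero-variance features
#' dropped and recorded); the penalty is chosen by k-fold cross-validated
#' mean squared error over a lasso path, and the final model is refit on all
#' training windows at the chosen penalty. Genes with nonzero coefficients
#' are the selected invasion programme: positive coefficients mark genes
#' whose expression rises with decidual depth (pro-invasive), negative
#' coefficients the reverse.
#'
#' @param windows A `depth_windows` object (training windows).
#' @param features Character vector of feature genes (default: all genes in
#'   the windows).
#' @param lambda Optional penalty sequence (default: glmnet's path).
#' @param cv_folds Cross-validation folds (default 5).
#' @param one_se Choose the penalty by the one-standard-error rule (default)
#'   rather than the raw CV minimum; the 1-SE rule gives a sparser, more
#'   stable selection when the CV curve is flat near its minimum.
#' @param seed Optional integer seed (controls fold assignment).
#' @param train_cells Optional cell ids used for training (recorded to guard
#'   validation against train/test overlap).
#' @return Object of class `invasion_model`: list with `features`, `mu`,
#'   `sigma`, `lambda`, `beta` (named, all features), `intercept`,
#'   `selected` (tibble gene/beta/sign), `cv` (lambda, mse, nzero),
#'   `dropped_features`, `seed`, `train_cells`.
#' @export
fit_invasion_model <- function(windows, features = NULL, lambda = NULL,
                               cv_folds = 5, one_se = TRUE, seed = NULL,
                               train_cells = NULL) {
  stopifnot(inherits(windows, "depth_windows"))
  .assert_scalar_num(cv_folds, "cv_folds", 2)
  X <- windows$x
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss) > 0) {
      rlang::abort(sprintf("feature gene(s) absent from windows: %s",
                           paste(utils::head(miss, 5), collapse = ", ")))
    }
    X <- X[, features, drop = FALSE]
  }
  if (nrow(X) < cv_folds) {
    rlang::abort("fewer windows than cross-validation folds")
  }
  y <- windows$depth
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sigma == 0 | !is.finite(sigma)]
  keep <- setdiff(colnames(X), dropped)
  if (length(keep) == 0) {
    rlang::abort("all features have zero variance")
  }
  Z <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sigma[keep])
  .with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), nrow(Z)))
    cv <- glmnet::cv.glmnet(Z, y, alpha = 1, foldid = foldid,
                            lambda = lambda, standardize = FALSE,
                            thresh = 1e-10)
    lam <- if (one_se) cv$lambda.1se else cv$lambda.min
    beta_k <- fit_lasso(Z, y, lambda = cv$glmnet.fit$lambda,
                        intercept = TRUE, thresh = 1e-10)
    j <- which.min(abs(cv$glmnet.fit$lambda - lam))
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    beta[keep] <- beta_k[, j]
    selected <- tibble::tibble(
      gene = names(beta)[beta != 0],
      beta = unname(beta[beta != 0])
    ) |>
      dplyr::mutate(sign = ifelse(.data$beta > 0, "pro-invasive",
                                  "anti-invasive")) |>
      dplyr::arrange(dplyr::desc(abs(.data$beta)))
    structure(
      list(features = colnames(X), mu = mu, sigma = sigma, lambda = lam,
           beta = beta, intercept = unname(attr(beta_k, "intercept")[j]),
           selected = selected,
           cv = tibble::tibble(lambda = cv$lambda, mse = cv$cvm,
                               nzero = as.integer(cv$nzero)),
           dropped_features = dropped, seed = seed,
           train_cells = train_cells),
      class = "invasion_model"
    )
  })
}

#' Score cells with a fitted invasion model
#'
#' The raw iScore of a cell is `sum_g beta_g * (x_g - mu_g) / sigma_g` over
#' the selected genes; scores are then normalized to mean 0, sd 1 within each
#' tissue section. The intercept is not part of the score.
#'
#' @param model An `invasion_model`.
#' @param expr_norm Normalized (log1p) genes x cells matrix.
#' @param cells Optional cell ids to score (default: all columns).
#' @param section_ids Optional per-cell section labels (single section
#'   assumed when `NULL`).
#' @param standardize `"train"` (selected genes centred/scaled with training
#'   statistics; a cell at the training means scores 0) or `"independent"`
#'   (z-scored within the scored data, matching independent test-set
#'   standardization).
#' @return Tibble with `cell_id`, `section_id`, `iscore_raw`, `iscore`.
#' @export
score_cells <- function(model, expr_norm, cells = NULL, section_ids = NULL,
                        standardize = c("train", "independent")) {
  stopifnot(inherits(model, "invasion_model"))
  standardize <- match.arg(standardize)
  if (is.null(cells)) cells <- colnames(expr_norm)
  sel <- model$selected$gene
  present <- intersect(sel, rownames(expr_norm))
  if (length(present) < 0.5 * length(sel)) {
    rlang::abort(sprintf(
      "expression covers only %d of %d selected genes (< 50%%)",
      length(present), length(sel)))
  }
  if (length(present) < length(sel)) {
    rlang::warn(sprintf("%d selected gene(s) missing; scoring on %d genes",
                        length(sel) - length(present), length(present)))
  }
  X <- as.matrix(Matrix::t(expr_norm[present, cells, drop = FALSE]))
  if (standardize == "train") {
    Z <- scale(X, center = model$mu[present], scale = model$sigma[present])
  } else {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- scale(X, center = colMeans(X), scale = sdv)
  }
  raw <- drop(Z %*% model$beta[present])
  section_ids <- section_ids %||% rep("section1", length(cells))
  out <- tibble::tibble(cell_id = cells, section_id = section_ids,
                        iscore_raw = unname(raw))
  out <- out |>
    dplyr::group_by(.data$section_id) |>
    dplyr::mutate(iscore = if (dplyr::n() >= 2) {
      as.numeric(scale(.data$iscore_raw))
    } else {
      rlang::warn("section with 1 cell: normalization skipped")
      .data$iscore_raw
    }) |>
    dplyr::ungroup()
  out
}

#' Validate an invasion model on held-out cells
#'
#' Spearman correlation between single-cell iScores and observed decidual
#' depth on the held-out set. Errors if the cells overlap the model's
#' training cells.
#'
#' @param model An `invasion_model` with `train_cells` recorded.
#' @param expr_norm Normalized genes x cells matrix.
#' @param depths Tibble with `cell_id`, `depth_px` for the test cells.
#' @param standardize Standardization mode passed to [score_cells()]
#'   (default `"independent"`, test data standardized with its own
#'   statistics).
#' @return Tibble with `rho`, `p`, `n`.
#' @export
validate_model <- function(model, expr_norm, depths,
                           standardize = "independent") {
  stopifnot(inherits(model, "invasion_model"))
  .assert_cols(depths, c("cell_id", "depth_px"), "depths")
  if (!is.null(model$train_cells) &&
      length(intersect(depths$cell_id, model$train_cells)) > 0) {
    rlang::abort("test cells overlap the model's training cells")
  }
  sc <- score_cells(model, expr_norm, cells = depths$cell_id,
                    standardize = standardize)
  ct <- suppressWarnings(
    stats::cor.test(sc$iscore_raw, depths$depth_px, method = "spearman",
                    exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(depths))
}

#' Benchmark the invasion model on an external dataset
#'
#' External counts are log1p-normalized and z-scored per gene within the
#' external dataset, scored with the model coefficients, and the two groups
#' are compared with a two-sided rank-sum test.
#'
#' @param model An `invasion_model`.
#' @param counts External genes x cells count matrix (shared gene namespace).
#' @param groups Per-cell group labels (exactly two levels).
#' @return List with `scores` (tibble `cell_id`, `group`, `iscore`),
#'   `medians`, and `p_value`.
#' @export
benchmark_iscore <- function(model, counts, groups) {
  stopifnot(inherits(model, "invasion_model"))
  if (length(unique(groups)) != 2) {
    rlang::abort("benchmark_iscore expects exactly two groups")
  }
  xn <- normalize_log1p(counts)
  sel <- model$selected$gene
  present <- intersect(sel, rownames(xn))
  if (length(present) < 0.5 * length(sel)) {
    rlang::abort(sprintf(
      "external matrix covers only %d of %d selected genes (< 50%%)",
      length(present), length(sel)))
  }
  sc <- score_cells(model, xn, standardize = "independent")
  df <- tibble::tibble(cell_id = sc$cell_id, group = groups,
                       iscore = sc$iscore_raw)
  g <- unique(groups)
  p <- stats::wilcox.test(df$iscore[df$group == g[1]],
                          df$iscore[df$group == g[2]],
                          exact = FALSE)$p.value
  med <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_iscore = stats::median(.data$iscore),
                     n = dplyr::n(), .groups = "drop")
  list(scores = df, medians = med, p_value = p)
}

#' Serialize / deserialize an invasion model as JSON
#'
#' @param model An `invasion_model`.
#' @param path Output file.
#' @return `path` invisibly; `read_invasion_model()` returns the model.
#' @export
write_invasion_model <- function(model, path) {
  stopifnot(inherits(model, "invasion_model"))
  obj <- list(
    features = model$features,
    mu = as.list(model$mu), sigma = as.list(model$sigma),
    lambda = model$lambda, beta = as.list(model$beta),
    intercept = model$intercept,
    selected = model$selected,
    dropped_features = model$dropped_features,
    seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_invasion_model
#' @export
read_invasion_model <- function(path) {
  obj <- jsonlite::read_json(path)
  beta <- unlist(obj$beta)
  mu <- unlist(obj$mu)
  sigma <- unlist(obj$sigma)
  selected <- dplyr::bind_rows(lapply(obj$selected, tibble::as_tibble))
  structure(
    list(features = unlist(obj$features), mu = mu, sigma = sigma,
         lambda = obj$lambda, beta = beta, intercept = obj$intercept,
         selected = selected,
         cv = NULL, dropped_features = unlist(obj$dropped_features),
         seed = obj$seed, train_cells = NULL),
    class = "invasion_model"
  )
}

#' @export
print.invasion_model <- function(x, ...) {
  cat("<invasion_model> L1-penalized depth regression (iScore)\n")
  cat(sprintf("  features: %d (%d zero-variance dropped)\n",
              length(x$features), length(x$dropped_features)))
  cat(sprintf("  lambda: %.4g; selected genes: %d (%d pro-, %d anti-invasive)\n",
              x$lambda, nrow(x$selected),
              sum(x$selected$beta > 0), sum(x$selected$beta < 0)))
  invisible(x)
}
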