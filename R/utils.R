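# internal helpers shared across modules

`%theninform%` <- function(n, msg) {
  if (n > 0) rlang::inform(sprintf(msg, n))
  invisible(n)
}

.assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("%s is missing required column(s): %s",
                         what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

.assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    rlang::abort(sprintf("`%s` must be %s %s", name,
                         if (strict) ">" else ">=", format(lower)))
  }
  invisible(x)
}

# scoped RNG: seed the computation without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# rank-based AUROC with midrank tie handling: P(X_pos > X_neg) + 0.5 P(=)
.auroc <- function(values, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUROC needs both classes present")
  }
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# even-odd (ray casting) point-in-polygon; vertices: n x 2 matrix, open ring
.point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from points to a set of segments, with the side (cross
# product sign) of the winning segment; segments as matrices A, B (m x 2)
.dist_to_segments <- function(px, py, A, B) {
  len2 <- rowSums((B - A)^2)
  keep <- len2 > 0
  if (!any(keep)) {
    rlang::abort("degenerate polyline: all segments have zero length")
  }
  A <- A[keep, , drop = FALSE]
  B <- B[keep, , drop = FALSE]
  len2 <- len2[keep]
  best_d2 <- rep(Inf, length(px))
  best_cross <- numeric(length(px))
  best_interior <- rep(FALSE, length(px))
  for (j in seq_len(nrow(A))) {
    abx <- B[j, 1] - A[j, 1]; aby <- B[j, 2] - A[j, 2]
    apx <- px - A[j, 1]; apy <- py - A[j, 2]
    t_raw <- (apx * abx + apy * aby) / len2[j]
    t <- pmin(1, pmax(0, t_raw))
    dx <- apx - t * abx; dy <- apy - t * aby
    d2 <- dx * dx + dy * dy
    cr <- abx * apy - aby * apx
    interior <- t_raw > 0 & t_raw < 1
    tol <- 1e-9 * (1 + d2)
    better <- d2 < best_d2 - tol
    # equidistant from two segments (a shared vertex): a perpendicular-foot
    # hit decides the side; with two clamped endpoints, sum the crosses
    tie <- !better & abs(d2 - best_d2) <= tol
    take_tie <- tie & interior & !best_interior
    sum_tie <- tie & !interior & !best_interior
    upd <- better | take_tie
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_cross[upd] <- cr[upd]
      best_interior[upd] <- interior[upd]
    }
    if (any(sum_tie)) {
      best_cross[sum_tie] <- best_cross[sum_tie] + cr[sum_tie]
    }
  }
  list(dist = sqrt(best_d2), cross = best_cross)
}

# two-sided rank-sum p-value with a guard for fully tied samples
.ranksum_p <- function(a, b, exact = FALSE) {
  if (stats::sd(c(a, b)) == 0) return(1)
  stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                     correct = !exact)$p.value
}
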