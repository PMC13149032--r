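make_distances <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("c%04d", 1:n),
    cell_type = "EVT", subtype = "iEVT", compartment = "maternal",
    d_interface_px = runif(n, 0, 2000),
    d_vessel_px = -runif(n, 250, 2000),
    nearest_vessel_id = 1L, vessel_eligible = TRUE))
}

test_that("the train/test split is a seeded partition at the stated ratio", {
  d <- make_distances(1000)
  sp <- split_evt_train_test(d, ratio = 0.5, seed = 3)
  expect_length(sp$train, 500)
  expect_length(sp$test, 500)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), d$cell_id)
  sp2 <- split_evt_train_test(d, ratio = 0.5, seed = 3)
  expect_identical(sp, sp2)
})

test_that("vessel-associated EVTs are excluded before splitting", {
  d <- make_distances(100)
  d$d_vessel_px[1:10] <- -150        # within the 200 px exclusion radius
  d$subtype[11:15] <- "eEVT"
  d$subtype[16:20] <- "pEVT"
  sp <- split_evt_train_test(d, seed = 1)
  expect_setequal(sp$excluded, d$cell_id[1:20])
  expect_length(c(sp$train, sp$test), 80)
})

test_that("depth windows average consecutive depth-sorted cells", {
  x <- Matrix::Matrix(
    matrix(c(1, 2, 3, 4, 5, 6, 10, 20, 30, 40, 50, 60), nrow = 2,
           byrow = TRUE),
    sparse = TRUE, dimnames = list(c("gA", "gB"), sprintf("c%d", 1:6)))
  depths <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                           depth_px = c(5, 4, 3, 20, 30, 10))
  w <- build_depth_windows(methods::as(x, "CsparseMatrix"), depths, k = 3)
  # sorted order: c3 (3), c2 (4), c1 (5) | c6 (10), c4 (20), c5 (30)
  expect_equal(w$depth, c(4, 20))
  expect_equal(unname(w$x[1, ]), c(mean(c(3, 2, 1)), mean(c(30, 20, 10))))
  expect_equal(w$members[[2]], c("c6", "c4", "c5"))

  # 10 cells with k = 10: one window at the mean depth
  x10 <- Matrix::Matrix(matrix(1, 1, 10), sparse = TRUE,
                        dimnames = list("g", sprintf("d%02d", 1:10)))
  d10 <- tibble::tibble(cell_id = sprintf("d%02d", 1:10), depth_px = 1:10)
  w10 <- build_depth_windows(methods::as(x10, "CsparseMatrix"), d10, k = 10)
  expect_equal(w10$depth, 5.5)

  # 25 cells with k = 10: two windows, 5 dropped
  x25 <- Matrix::Matrix(matrix(1, 1, 25), sparse = TRUE,
                        dimnames = list("g", sprintf("e%02d", 1:25)))
  d25 <- tibble::tibble(cell_id = sprintf("e%02d", 1:25), depth_px = 1:25)
  expect_message(w25 <- build_depth_windows(methods::as(x25, "CsparseMatrix"),
                                            d25, k = 10),
                 "dropped trailing 5")
  expect_length(w25$depth, 2)
  expect_equal(w25$n_dropped, 5)

  expect_error(build_depth_windows(x10, d10, k = 1), "k")
})

test_that("a constant response yields the all-zero lasso solution", {
  withr::local_seed(2)
  X <- matrix(rnorm(200), 40, 5)
  b <- fit_lasso(X, rep(7, 40), lambda = c(1, 0.1, 0.01))
  expect_true(all(b == 0))
  expect_equal(unname(attr(b, "intercept")), rep(7, 3))
})

test_that("lambda = 0 reproduces the normal-equations OLS fit", {
  withr::local_seed(3)
  X <- matrix(rnorm(90), 30, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(30, 0, 0.3)
  b <- fit_lasso(X, y, lambda = 0, intercept = FALSE, thresh = 1e-14)
  ols <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(b[, 1]), drop(ols), tolerance = 1e-6)
})

test_that("orthonormal designs soft-threshold the OLS estimate", {
  withr::local_seed(4)
  n <- 40; p <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # t(X) %*% X / n = I
  y <- rnorm(n)
  bols <- drop(crossprod(Q, y) / n)
  for (lam in c(0.05, 0.15)) {
    b <- fit_lasso(Q, y, lambda = lam, intercept = FALSE, thresh = 1e-16)
    expect_equal(unname(b[, 1]), sign(bols) * pmax(abs(bols) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("sparsity is non-increasing along the penalty path", {
  withr::local_seed(5)
  X <- matrix(rnorm(60 * 30), 60, 30)
  y <- drop(X[, 1:4] %*% c(3, -2, 1.5, 1)) + rnorm(60)
  fit <- glmnet::glmnet(X, y, alpha = 1)
  b <- fit_lasso(X, y, lambda = fit$lambda)
  nz <- colSums(b != 0)
  expect_true(all(diff(nz) >= 0))  # lambda sequence is decreasing
})

toy_model <- function() {
  structure(list(
    features = c("g1", "g2", "g3"),
    mu = c(g1 = 1, g2 = 2, g3 = 3),
    sigma = c(g1 = 1, g2 = 2, g3 = 1),
    lambda = 0.1,
    beta = c(g1 = 2, g2 = -1, g3 = 0),
    intercept = 5,
    selected = tibble::tibble(gene = c("g1", "g2"), beta = c(2, -1),
                              sign = c("pro-invasive", "anti-invasive")),
    cv = NULL, dropped_features = character(0), seed = 1,
    train_cells = c("t1", "t2")), class = "invasion_model")
}

test_that("scoring centres on training means and scales with beta", {
  m <- toy_model()
  x <- Matrix::Matrix(matrix(c(1, 2, 3, 3, 6, 3), 3,
                             dimnames = list(c("g1", "g2", "g3"),
                                             c("atmean", "off"))),
                      sparse = TRUE)
  sc <- score_cells(m, methods::as(x, "CsparseMatrix"),
                    standardize = "train")
  expect_equal(sc$iscore_raw[1], 0)   # cell at the training means
  expect_equal(sc$iscore_raw[2], 2 * (3 - 1) / 1 + (-1) * (6 - 2) / 2)

  # doubling beta doubles raw scores; section-normalized scores unchanged
  m2 <- m; m2$beta <- 2 * m$beta
  m2$selected$beta <- 2 * m$selected$beta
  sc2 <- score_cells(m2, x, standardize = "train")
  expect_equal(sc2$iscore_raw, 2 * sc$iscore_raw)
  expect_equal(sc2$iscore, sc$iscore)

  # identical cells get identical scores
  x3 <- cbind(x, x[, 2, drop = FALSE])
  colnames(x3) <- c("a", "b", "b2")
  sc3 <- score_cells(m, methods::as(x3, "CsparseMatrix"),
                     standardize = "train")
  expect_equal(sc3$iscore_raw[2], sc3$iscore_raw[3])
})

test_that("per-section normalization is exact and validation guards leakage", {
  m <- toy_model()
  withr::local_seed(6)
  x <- Matrix::Matrix(matrix(rpois(300, 4), 3,
                             dimnames = list(c("g1", "g2", "g3"),
                                             sprintf("s%03d", 1:100))),
                      sparse = TRUE)
  sc <- score_cells(m, methods::as(x, "CsparseMatrix"),
                    section_ids = rep(c("A", "B"), 50))
  for (sid in c("A", "B")) {
    v <- sc$iscore[sc$section_id == sid]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }

  expect_error(
    validate_model(m, x, tibble::tibble(cell_id = c("t1", "s001"),
                                        depth_px = c(1, 2))),
    "overlap")
})

test_that("validation reports a null correlation on permuted depths", {
  m <- toy_model()
  withr::local_seed(7)
  n <- 2000
  x <- Matrix::Matrix(matrix(rpois(3 * n, 4), 3,
                             dimnames = list(c("g1", "g2", "g3"),
                                             sprintf("n%04d", 1:n))),
                      sparse = TRUE)
  v <- validate_model(m, methods::as(x, "CsparseMatrix"),
                      tibble::tibble(cell_id = colnames(x),
                                     depth_px = runif(n, 0, 2000)))
  expect_lt(abs(v$rho), 0.05)
})

test_that("the serialized model round-trips through JSON", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_invasion_model(m, path)
  m2 <- read_invasion_model(path)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$selected$gene, m$selected$gene)
})

test_that("external benchmarking detects a planted low-invasion group", {
  m <- toy_model()
  withr::local_seed(8)
  n <- 500
  mk <- function(shift) {
    matrix(rpois(3 * n, lambda = exp(c(2, 2, 2) + shift * c(1, -1, 0))), 3)
  }
  counts <- cbind(mk(0), mk(-0.5))
  dimnames(counts) <- list(c("g1", "g2", "g3"),
                           sprintf("x%04d", 1:(2 * n)))
  groups <- rep(c("normal", "low"), each = n)
  res <- benchmark_iscore(m, counts, groups)
  med <- setNames(res$medians$median_iscore, res$medians$group)
  expect_lt(med[["low"]], med[["normal"]])
  expect_lt(res$p_value, 0.01)

  # swapping group labels gives the same p with the direction reversed
  res2 <- benchmark_iscore(m, counts, rev(groups))
  expect_equal(res2$p_value, res$p_value)

  expect_error(benchmark_iscore(m, counts, rep("one", 2 * n)), "two groups")
})

test_that("tidy and glance summarise fitted models", {
  m <- toy_model()
  td <- tidy(m)
  expect_equal(td$gene, c("g1", "g2"))
  gl <- glance(m)
  expect_equal(gl$n_selected, 2L)
  expect_equal(gl$n_features, 3L)
})
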