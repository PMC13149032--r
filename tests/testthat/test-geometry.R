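test_that("axis-aligned interface distances carry the maternal/fetal sign", {
  # horizontal polyline, maternal = lower half-plane (right of +x direction)
  iface <- list(vertices = cbind(c(0, 100), c(0, 0)), maternal_side = "right")
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          x_px = c(10, 10, 50), y_px = c(-50, 50, 0))
  d <- distance_to_interface(cells, iface)
  expect_equal(d$d_interface_px, c(50, -50, 0))
  expect_equal(d$compartment, c("maternal", "fetal", "maternal"))

  # flipping the orientation flag flips every sign
  iface$maternal_side <- "left"
  d2 <- distance_to_interface(cells, iface)
  expect_equal(d2$d_interface_px, c(-50, 50, 0))
})

test_that("cells beyond the polyline extent use the nearest endpoint", {
  iface <- list(vertices = cbind(c(0, 100), c(0, 0)), maternal_side = "right")
  cells <- tibble::tibble(cell_id = "a", x_px = 130, y_px = -40)
  d <- distance_to_interface(cells, iface)
  expect_equal(abs(d$d_interface_px), 50)  # hypot(30, 40)
})

test_that("degenerate polylines are rejected", {
  iface <- list(vertices = cbind(c(5, 5), c(7, 7)), maternal_side = "right")
  cells <- tibble::tibble(cell_id = "a", x_px = 0, y_px = 0)
  expect_error(distance_to_interface(cells, iface), "degenerate")
})

test_that("circle vessel distances follow the signed wall convention", {
  vessels <- tibble::tibble(vessel_id = 1L, kind = "circle", cx = 0, cy = 0,
                            r = 100, vertices = list(NULL))
  cells <- tibble::tibble(cell_id = c("in", "out", "wall"),
                          x_px = c(60, 150, 100), y_px = 0)
  d <- distance_to_vessels(cells, vessels)
  expect_equal(d$d_vessel_px, c(40, -50, 0))
})

test_that("nearest-vessel ties break to the lowest vessel id", {
  vessels <- tibble::tibble(vessel_id = c(2L, 1L), kind = "circle",
                            cx = c(0, 200), cy = 0, r = 50,
                            vertices = list(NULL, NULL))
  cells <- tibble::tibble(cell_id = "mid", x_px = 100, y_px = 0)
  d <- distance_to_vessels(cells, vessels)
  expect_equal(d$nearest_vessel_id, 1L)
})

test_that("polygon vessel distances match a brute-force oracle", {
  skip_if_not_installed("mgcv")
  withr::local_seed(42)
  vessels <- tibble::tibble(
    vessel_id = 1:3, kind = "polygon", cx = NA_real_, cy = NA_real_,
    r = NA_real_,
    vertices = list(random_convex_polygon(300, 300, 150),
                    random_convex_polygon(900, 500, 120),
                    random_convex_polygon(500, 900, 180)))
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:500),
                          x_px = runif(500, 0, 1200),
                          y_px = runif(500, 0, 1200))
  d <- distance_to_vessels(cells, vessels)
  # oracle: per-cell minimum over all vessels of edge distance, sign by
  # point-in-polygon from an independent implementation (mgcv::in.out)
  for (i in seq_len(nrow(cells))) {
    mags <- vapply(vessels$vertices, function(V) {
      oracle_polygon_distance(cells$x_px[i], cells$y_px[i], V)
    }, numeric(1))
    j <- which.min(mags)
    inside <- mgcv::in.out(rbind(vessels$vertices[[j]],
                                 vessels$vertices[[j]][1, ]),
                           cbind(cells$x_px[i], cells$y_px[i]))
    expect_equal(abs(d$d_vessel_px[i]), mags[j], tolerance = 1e-9)
    expect_identical(d$d_vessel_px[i] > 0, as.logical(inside))
  }
})

test_that("distances are invariant under rigid motion of cells and landmarks", {
  withr::local_seed(7)
  V <- cbind(seq(0, 1000, length.out = 15),
             cumsum(rnorm(15, 0, 30)) + 500)
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:200),
                          x_px = runif(200, 0, 1000),
                          y_px = runif(200, 0, 1000))
  d0 <- distance_to_interface(cells, list(vertices = V,
                                          maternal_side = "right"))
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(123, -456)
  Vr <- sweep(V %*% t(Rm), 2, -shift)
  pr <- sweep(as.matrix(cells[, c("x_px", "y_px")]) %*% t(Rm), 2, -shift)
  cells_r <- tibble::tibble(cell_id = cells$cell_id,
                            x_px = pr[, 1], y_px = pr[, 2])
  d1 <- distance_to_interface(cells_r, list(vertices = Vr,
                                            maternal_side = "right"))
  expect_equal(d1$d_interface_px, d0$d_interface_px, tolerance = 1e-6)
})

test_that("composition binning uses half-open bins and conserves cells", {
  df <- tibble::tibble(cell_id = c("a", "b", "c"),
                       d_interface_px = c(10, 110, 150),
                       cell_type = "EVT")
  prof <- bin_composition(df, bin_width = 100)
  expect_equal(prof$bin, c(0, 1))
  expect_equal(prof$n, c(1L, 2L))
  expect_true(all(prof$prop == 1))
  expect_equal(sum(prof$n), nrow(df))

  # shuffling rows leaves the profile unchanged
  prof2 <- bin_composition(df[c(3, 1, 2), ], bin_width = 100)
  expect_equal(prof2, prof)

  # boundary value 100 falls into bin [100, 200)
  prof3 <- bin_composition(tibble::tibble(cell_id = "x",
                                          d_interface_px = 100,
                                          cell_type = "EVT"),
                           bin_width = 100)
  expect_equal(prof3$bin, 1)

  # empty input is an empty profile, not an error
  expect_equal(nrow(bin_composition(df[0, ], bin_width = 100)), 0)
})

test_that("per-bin proportions sum to one with multiple cell types", {
  withr::local_seed(3)
  df <- tibble::tibble(cell_id = as.character(1:500),
                       d_interface_px = runif(500, -400, 600),
                       cell_type = sample(c("EVT", "DSC", "Immune"), 500,
                                          replace = TRUE))
  prof <- bin_composition(df, bin_width = 100)
  sums <- tapply(prof$prop, prof$bin, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(sum(prof$n), 500L)
  # maternal restriction keeps only nonnegative distances
  profm <- bin_composition(df, bin_width = 100, side = "maternal")
  expect_true(all(profm$bin_lo >= 0))
  expect_equal(sum(profm$n), sum(df$d_interface_px >= 0))
})

test_that("tile adjacency obeys the Chebyshev rule", {
  cells <- tibble::tibble(cell_id = c("a", "b"),
                          x_px = c(10, 40), y_px = c(10, 45))
  expect_equal(nrow(tile_adjacency(cells, tile_px = 50, k_tiles = 0)), 2)

  cells2 <- tibble::tibble(cell_id = c("a", "b", "c"),
                           x_px = c(25, 325, 275), y_px = 25)
  adj <- tile_adjacency(cells2, tile_px = 50, k_tiles = 5)
  pairs <- paste(adj$cell_a, adj$cell_b)
  expect_false("a b" %in% pairs)  # tiles 0 and 6
  expect_true("a c" %in% pairs)   # tiles 0 and 5
})

test_that("tile adjacency matches an all-pairs Chebyshev oracle", {
  withr::local_seed(11)
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:200),
                          x_px = runif(200, 0, 600),
                          y_px = runif(200, 0, 600))
  adj <- tile_adjacency(cells, tile_px = 50, k_tiles = 2)
  tx <- floor(cells$x_px / 50); ty <- floor(cells$y_px / 50)
  oracle <- outer(tx, tx, function(a, b) abs(a - b)) <= 2 &
    outer(ty, ty, function(a, b) abs(a - b)) <= 2
  diag(oracle) <- FALSE
  got <- matrix(FALSE, 200, 200, dimnames = list(cells$cell_id,
                                                 cells$cell_id))
  got[cbind(adj$cell_a, adj$cell_b)] <- TRUE
  expect_identical(unname(got), oracle)
})

test_that("depth matching reproduces the reference histogram", {
  withr::local_seed(5)
  ga <- tibble::tibble(cell_id = sprintf("a%03d", 1:150),
                       depth_px = runif(150, 0, 1000))
  # pool == group: matched histogram identical, balance check passes
  m <- depth_match(ga, ga, bin_px = 100, seed = 1)
  expect_equal(nrow(m), 150)
  expect_equal(table(floor(m$depth_px / 100)),
               table(floor(ga$depth_px / 100)))
  expect_gt(attr(m, "depth_balance_p"), 0.5)

  # group concentrated in one bin draws only from that bin
  ga1 <- tibble::tibble(cell_id = c("x", "y"), depth_px = c(250, 260))
  pool <- tibble::tibble(cell_id = sprintf("p%03d", 1:300),
                         depth_px = runif(300, 0, 1000))
  m1 <- depth_match(ga1, pool, bin_px = 100, seed = 1)
  expect_true(all(m1$depth_px >= 200 & m1$depth_px < 300))

  # matching a shallow group from a deeper pool restricts and rebalances
  ga2 <- tibble::tibble(cell_id = sprintf("s%03d", 1:200),
                        depth_px = runif(200, 0, 1000))
  pool2 <- tibble::tibble(cell_id = sprintf("q%04d", 1:2000),
                          depth_px = runif(2000, 0, 2000))
  m2 <- depth_match(ga2, pool2, bin_px = 100, seed = 2)
  expect_true(all(m2$depth_px <= 1000))
  expect_gt(attr(m2, "depth_balance_p"), 0.05)

  # empty strata
  suppressWarnings(
    expect_error(depth_match(ga1, ga1[0, ], bin_px = 100), "no pool cells")
  )
})
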