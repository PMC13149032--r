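test_that("an all-zero cell count config yields landmarks only", {
  cfg <- small_section_config(seed = 1, cell_counts = c(EVT = 0, DSC = 0))
  gs <- simulate_section(cfg)
  expect_equal(nrow(gs$section$cells), 0)
  expect_equal(nrow(gs$section$landmarks$vessels), 3)
  expect_gt(nrow(gs$section$landmarks$interface$vertices), 2)
})

test_that("generation is a pure function of (config, seed)", {
  a <- simulate_section(small_section_config(seed = 9))
  b <- simulate_section(small_section_config(seed = 9))
  expect_identical(a$section$cells, b$section$cells)
  expect_identical(a$section$landmarks$vessels$cx,
                   b$section$landmarks$vessels$cx)
  c <- simulate_section(small_section_config(seed = 10))
  expect_false(identical(a$section$cells$x_px, c$section$cells$x_px))

  ea <- simulate_expression(a$section, small_expression_config(seed = 2))
  eb <- simulate_expression(b$section, small_expression_config(seed = 2))
  expect_identical(ea$section$expression@x, eb$section$expression@x)
  expect_identical(ea$truth$invasion_genes, eb$truth$invasion_genes)
})

test_that("requesting more vessels than fit raises a placement error", {
  cfg <- small_section_config(seed = 1, n_vessels = 200)
  expect_error(simulate_section(cfg), "placement error")
})

test_that("every generated cell's compartment matches its signed distance", {
  for (seed in 1:3) {
    gs <- simulate_section(small_section_config(seed = seed))
    d <- compute_distances(gs$section)
    expect_identical(d$compartment, gs$section$cells$compartment)
  }
})

test_that("EVT depth density decays at the configured scale", {
  # Monte-Carlo oracle: direct draws from the stated placement density
  # (depth ~ Exp(500) truncated at the decidua depth)
  cfg <- section_config(
    width_px = 3000, height_px = 4000, interface_amplitude_px = 100,
    interface_period_px = 1500, n_vessels = 0,
    cell_counts = c(EVT = 10000), evt_depth_decay_px = 500,
    evt_vessel_frac = 0, evt_subtype_props = c(iEVT = 1), seed = 2)
  gs <- simulate_section(cfg)
  d <- compute_distances(gs$section)
  depth <- d$d_interface_px
  got <- sum(depth >= 0 & depth < 500) / sum(depth >= 500 & depth < 1000)
  oracle <- withr::with_seed(99, {
    s <- stats::rexp(2e5, 1 / 500)
    s <- s[s < 2500]
    sum(s < 500) / sum(s >= 500 & s < 1000)
  })
  expect_equal(got, oracle, tolerance = 0.08)
})

test_that("zero slopes leave invasion genes independent of depth", {
  cfg <- section_config(width_px = 4000, height_px = 3000, n_vessels = 0,
                        cell_counts = c(EVT = 5000), evt_vessel_frac = 0,
                        evt_subtype_props = c(iEVT = 1), seed = 3)
  gs <- simulate_section(cfg)
  ge <- simulate_expression(gs$section,
                            expression_config(n_genes = 300,
                                              n_invasion_genes = 5,
                                              n_mimicry_genes = 5,
                                              invasion_slope_range = c(0, 0),
                                              seed = 4))
  d <- compute_distances(ge$section)
  g <- ge$truth$invasion_genes$gene[1]
  rho <- suppressWarnings(stats::cor.test(
    as.numeric(ge$section$expression[g, ]), d$d_interface_px,
    method = "spearman", exact = FALSE))$estimate
  expect_lt(abs(rho), 0.05)
})

test_that("a planted slope reproduces the expected fold change in counts", {
  # two EVT groups at depth 0 and 1000 px, slope 0.7 per 1000 px
  n <- 1500
  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(2 * n)),
    x_px = runif(2 * n, 0, 4000),
    y_px = rep(c(1000, 0), each = n),  # interface at y = 1000
    cell_type = "EVT", subtype = "iEVT", compartment = "maternal")
  sec <- flat_section(cells, y0 = 1000)
  ge <- simulate_expression(sec, expression_config(
    n_genes = 200, n_invasion_genes = 6, n_mimicry_genes = 5,
    invasion_slope_range = c(0.7, 0.7), invasion_prop_positive = 1,
    theta = 2, seed = 5))
  shallow <- cells$cell_id[cells$y_px == 1000]
  deep <- cells$cell_id[cells$y_px == 0]
  for (g in ge$truth$invasion_genes$gene[1:3]) {
    got <- mean(ge$section$expression[g, deep]) /
      mean(ge$section$expression[g, shallow])
    # oracle: direct NB simulation at the two depths
    oracle <- withr::with_seed(6, {
      mean(stats::rnbinom(2e4, mu = exp(log(8) + 0.7), size = 2)) /
        mean(stats::rnbinom(2e4, mu = exp(log(8)), size = 2))
    })
    expect_equal(got, oracle, tolerance = 0.12)
  }
})

test_that("local suppression scales invasion genes by exp(delta)", {
  # EVTs at one depth; half sit within 250 px of a DSC4 cell
  n <- 1200
  cells <- dplyr::bind_rows(
    tibble::tibble(cell_id = sprintf("near%04d", 1:n),
                   x_px = runif(n, 0, 50), y_px = runif(n, 450, 500),
                   cell_type = "EVT", subtype = "iEVT",
                   compartment = "maternal"),
    tibble::tibble(cell_id = sprintf("far%04d", 1:n),
                   x_px = runif(n, 3000, 3050), y_px = runif(n, 450, 500),
                   cell_type = "EVT", subtype = "iEVT",
                   compartment = "maternal"),
    tibble::tibble(cell_id = "dsc", x_px = 25, y_px = 475,
                   cell_type = "DSC", subtype = "DSC4",
                   compartment = "maternal"))
  sec <- flat_section(cells, y0 = 1000)
  ge <- simulate_expression(sec, expression_config(
    n_genes = 200, n_invasion_genes = 6, n_mimicry_genes = 5,
    invasion_slope_range = c(0, 0), suppression_delta = -1,
    suppression_radius_px = 250, theta = 2, seed = 6))
  near <- cells$cell_id[startsWith(cells$cell_id, "near")]
  far <- cells$cell_id[startsWith(cells$cell_id, "far")]
  expect_setequal(ge$truth$suppression$affected_cells, near)
  inv <- ge$truth$invasion_genes$gene
  ratio <- mean(as.matrix(ge$section$expression[inv, near])) /
    mean(as.matrix(ge$section$expression[inv, far]))
  expect_equal(ratio, exp(-1), tolerance = 0.12)
})

test_that("endothelial states are placed with ordered wall offsets", {
  gs <- simulate_section(small_section_config(seed = 12,
                                              cell_counts = c(EC = 400)))
  d <- compute_distances(gs$section)
  df <- dplyr::inner_join(gs$truth$ec_states, d, by = "cell_id")
  med <- tapply(abs(df$d_vessel_px), df$state, median)
  expect_lt(max(med[c("caEC", "R0")]), med[["R1"]])
  expect_lt(med[["R1"]], med[["R2"]])
})

test_that("GRN generation respects the sign mix and the seed", {
  g1 <- simulate_grn(sign_mix = c(evt_activation = 1, evt_repression = 0,
                                  sct_activation = 0, sct_repression = 0),
                     seed = 3)
  expect_true(all(g1$truth$edges$category == "evt_activation"))
  expect_true(all(g1$edges$coefficient > 0))

  g2 <- simulate_grn(seed = 4)
  g3 <- simulate_grn(seed = 4)
  expect_identical(g2$edges, g3$edges)

  expect_error(simulate_grn(sign_mix = c(evt_activation = 0.5,
                                         evt_repression = 0.5,
                                         sct_activation = 0.5,
                                         sct_repression = 0.5)),
               "sum to 1")
})

test_that("threshold-straddling coefficients split exactly at the filter", {
  g <- simulate_grn(n_edges = 100, n_below_threshold = 50, seed = 8)
  kept <- filter_grn_edges(g$edges, c_min = 0.1)
  # enumeration oracle: compare each coefficient to 0.1 directly
  oracle <- g$edges[abs(g$edges$coefficient) > 0.1, ]
  expect_identical(kept$tf, oracle$tf)
  expect_identical(kept$coefficient, oracle$coefficient)
  expect_identical(
    sort(kept$coefficient),
    sort(g$truth$edges$coefficient[g$truth$edges$above_threshold]))
})
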