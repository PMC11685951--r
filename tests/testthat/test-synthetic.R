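test_that("landscape generation is reproducible and seed-sensitive", {
  cfg <- synthetic_config(n_rows = 20, n_cols = 20, n_samples = 30, seed = 5)
  l1 <- make_landscape(cfg)
  l2 <- make_landscape(cfg)
  expect_identical(l1$truth$values, l2$truth$values)
  expect_identical(l1$stack$layers$dust$values, l2$stack$layers$dust$values)
  cfg2 <- synthetic_config(n_rows = 20, n_cols = 20, seed = 6)
  expect_false(identical(make_landscape(cfg2)$truth$values, l1$truth$values))
})

test_that("one block with no covariate effects gives a constant truth surface", {
  cfg <- synthetic_config(n_rows = 10, n_cols = 10, n_blocks = 1,
                          dust_effect = 0, noise_effect = 0,
                          within_cell_sd = 0, seed = 2)
  land <- make_landscape(cfg)
  expect_equal(length(unique(as.vector(land$truth$values))), 1)
})

test_that("the truth surface stays inside the plausible bioavailable range", {
  for (seed in c(1, 9, 33)) {
    land <- make_landscape(synthetic_config(n_rows = 30, n_cols = 30,
                                            seed = seed))
    expect_gte(min(land$truth$values), 0.703)
    expect_lte(max(land$truth$values), 0.88)
  }
})

test_that("noise-free sampling observes the truth exactly", {
  land <- make_landscape(synthetic_config(n_rows = 15, n_cols = 15, seed = 4))
  samp <- sample_sites(land, n = 50, within_cell_sd = 0)
  rc <- srisoscape:::cell_rowcol(land$truth$spec, samp$longitude,
                                 samp$latitude)
  expect_equal(samp$sr_ratio, land$truth$values[rc])
})

test_that("repeated draws at one cell centre on the truth (CLT check)", {
  land <- make_landscape(synthetic_config(n_rows = 1, n_cols = 1,
                                          n_blocks = 1, seed = 7))
  samp <- sample_sites(land, n = 1e4, within_cell_sd = 0.002, seed = 7)
  truth <- land$truth$values[1, 1]
  se <- 0.002 / sqrt(1e4)
  expect_lt(abs(mean(samp$sr_ratio) - truth), 3 * se)
})

test_that("an empty sample table fails downstream fitting cleanly", {
  land <- make_landscape(synthetic_config(n_rows = 10, n_cols = 10, seed = 3))
  samp <- sample_sites(land, n = 0)
  expect_equal(nrow(samp), 0)
  d <- extract_predictors(samp, land$stack)
  expect_error(srforest(d, samp$sr_ratio), "empty")
})

test_that("simulated individuals are reproducible and carry valid origins", {
  land <- make_landscape(synthetic_config(n_rows = 15, n_cols = 15, seed = 8))
  i1 <- simulate_individuals(land, m = 12, seed = 8, with_oxygen = TRUE)
  i2 <- simulate_individuals(land, m = 12, seed = 8, with_oxygen = TRUE)
  expect_identical(i1, i2)
  expect_true(all(i1$origin_row >= 1 & i1$origin_row <= 15))
  # the simulated carbonate values invert to the drawn water values
  w <- carb_vpdb_to_water(i1$d18o_carb_vpdb)$d18o_w_vsmow
  expect_equal(stats::sd(w - i1$true_d18o_w), 0.5, tolerance = 0.5)
})

test_that("noise-free tissue values point at cells with matching means", {
  land <- make_landscape(synthetic_config(n_rows = 8, n_cols = 8, seed = 9))
  ind <- simulate_individuals(land, m = 5, seed = 9, tissue_sd = 0)
  iso <- list(mean = land$truth,
              se = sr_grid(matrix(0.001, 8, 8), land$truth$spec))
  for (i in 1:5) {
    a <- assign_individual(sr_ratio = ind$sr87_sr86[i], sr_isoscape = iso)
    am <- which(a$posterior$values == max(a$posterior$values), arr.ind = TRUE)
    expect_equal(land$truth$values[am[1, 1], am[1, 2]], ind$sr87_sr86[i])
  }
})
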