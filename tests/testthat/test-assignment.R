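test_that("the three-stage d18O conversion reproduces the worked values", {
  out <- carb_vpdb_to_water(-4.0)
  expect_equal(out$d18o_carb_vsmow, 26.78636, tolerance = 1e-7)
  expect_equal(out$d18o_p_vsmow, 17.75063, tolerance = 1e-5)
  expect_equal(out$d18o_w_vsmow, -6.38403, tolerance = 1e-5)
  expect_equal(carb_vpdb_to_water(0)$d18o_w_vsmow, -0.160628,
               tolerance = 1e-5)
})

test_that("the conversion chain equals its symbolic affine composition", {
  co <- d18o_conversion_coefficients()
  expect_equal(unname(co["slope"]), 1.03091 * 0.98 * 1.54, tolerance = 1e-12)
  x <- seq(-20, 10, by = 0.25)
  w <- carb_vpdb_to_water(x)$d18o_w_vsmow
  expect_equal(w, co["slope"] * x + co["intercept"], tolerance = 1e-10,
               ignore_attr = TRUE)
  # exact inverse round-trip
  wat <- seq(-15, 5, by = 0.5)
  expect_equal(carb_vpdb_to_water(water_to_carb_vpdb(wat))$d18o_w_vsmow, wat,
               tolerance = 1e-10)
  expect_true(carb_vpdb_to_water(-25)$implausible)
})

test_that("the two-cell worked posterior reproduces the e^-8 likelihood ratio", {
  iso <- two_cell_isoscape()
  L <- likelihood_surface(0.710, iso$mean, iso$se)
  expect_equal(L$values[1, 2] / L$values[1, 1], exp(-8), tolerance = 1e-10)
  post <- posterior_surface(L)
  expect_equal(as.vector(post$posterior$values),
               c(1 / (1 + exp(-8)), exp(-8) / (1 + exp(-8))),
               tolerance = 1e-9)
  expect_lt(abs(post$posterior$values[1, 1] - 0.999665), 1e-6)
  expect_lt(abs(post$posterior$values[1, 2] - 0.000335), 1e-6)
  expect_equal(sum(post$posterior$values), 1, tolerance = 1e-9)
  # display surface is max-normalised
  expect_equal(max(post$display$values), 1)
})

test_that("likelihood surfaces behave under flat means and rescaled SDs", {
  spec <- local_spec(3, 3)
  flat <- list(mean = sr_grid(matrix(0.715, 3, 3), spec),
               se = sr_grid(matrix(0.004, 3, 3), spec))
  L <- likelihood_surface(0.715, flat$mean, flat$se)
  expect_equal(length(unique(as.vector(L$values))), 1)
  set.seed(23)
  mu <- matrix(runif(9, 0.705, 0.735), 3, 3)
  m1 <- list(mean = sr_grid(mu, spec), se = sr_grid(matrix(0.003, 3, 3), spec))
  m2 <- list(mean = sr_grid(mu, spec), se = sr_grid(matrix(0.006, 3, 3), spec))
  L1 <- likelihood_surface(0.72, m1$mean, m1$se)
  L2 <- likelihood_surface(0.72, m2$mean, m2$se)
  expect_equal(which.max(L1$values), which.max(L2$values))
  # degenerate: all SDs zero and no exact match
  zero <- sr_grid(matrix(0, 3, 3), spec)
  expect_error(likelihood_surface(0.9, m1$mean, zero), "degenerate")
})

test_that("posterior normalisation, priors and display behave as specified", {
  iso <- two_cell_isoscape()
  L <- likelihood_surface(0.710, iso$mean, iso$se)
  # positive scaling of the likelihood leaves the posterior unchanged
  L10 <- sr_grid(10 * L$values, L$spec)
  expect_equal(posterior_surface(L10)$posterior$values,
               posterior_surface(L)$posterior$values, tolerance = 1e-12)
  # prior masking cell 1 forces all mass to cell 2
  prior <- sr_grid(matrix(c(0, 1), 1, 2), L$spec)
  p <- posterior_surface(L, prior)
  expect_equal(as.vector(p$posterior$values), c(0, 1))
  # display of a (0.2, 0.8) posterior is (0.25, 1)
  L28 <- sr_grid(matrix(c(0.2, 0.8), 1, 2), L$spec)
  expect_equal(as.vector(posterior_surface(L28)$display$values), c(0.25, 1))
  # empty support
  zeroprior <- sr_grid(matrix(0, 1, 2), L$spec)
  expect_error(posterior_surface(L, zeroprior), "empty support")
})

test_that("credible regions honour mass targets and tie-breaks", {
  iso <- two_cell_isoscape()
  post <- posterior_surface(likelihood_surface(0.710, iso$mean, iso$se))
  expect_equal(as.vector(top_fraction_region(post, 0.95)$values), c(1, 0))
  expect_equal(as.vector(top_fraction_region(post, 1)$values), c(1, 1))
  expect_equal(as.vector(top_fraction_region(post, 0)$values), c(0, 0))
  # area-based region keeps the top-ranked fraction of valid cells
  expect_equal(as.vector(top_area_region(post, 0.5)$values), c(1, 0))
})

test_that("dual-isotope assignment multiplies likelihoods and commutes", {
  spec <- grid_spec(1, 4, 0, 0, 1, crs = "local")
  sr_iso <- list(mean = sr_grid(matrix(c(0.710, 0.710, 0.730, 0.730), 1, 4), spec),
                 se = sr_grid(matrix(0.002, 1, 4), spec))
  o_iso <- list(mean = sr_grid(matrix(c(-6, -2, -6, -2), 1, 4), spec),
                se = sr_grid(matrix(0.5, 1, 4), spec))
  carb <- water_to_carb_vpdb(-6)
  a <- assign_individual(sr_ratio = 0.710, sr_isoscape = sr_iso,
                         d18o_carb_vpdb = carb, o_isoscape = o_iso,
                         o_extra_sd = 0)
  # each isotope alone is ambiguous between two cells; only cell 1 matches both
  expect_equal(which.max(t(a$posterior$values)), 1)
  # hand product of normal densities, normalised
  Lsr <- dnorm(0.710, c(0.710, 0.710, 0.730, 0.730), 0.002)
  Lo <- dnorm(-6, c(-6, -2, -6, -2), 0.5)
  expect_equal(as.vector(a$posterior$values), Lsr * Lo / sum(Lsr * Lo),
               tolerance = 1e-9)
  expect_named(a$components, c("sr", "o"))
  # a flat oxygen surface leaves the Sr-only posterior unchanged
  o_flat <- list(mean = sr_grid(matrix(-6, 1, 4), spec),
                 se = sr_grid(matrix(0.5, 1, 4), spec))
  both <- assign_individual(sr_ratio = 0.710, sr_isoscape = sr_iso,
                            d18o_carb_vpdb = carb, o_isoscape = o_flat,
                            o_extra_sd = 0)
  sr_only <- assign_individual(sr_ratio = 0.710, sr_isoscape = sr_iso)
  expect_equal(both$posterior$values, sr_only$posterior$values,
               tolerance = 1e-12)
  # product commutes: swapping the component roles is bit-identical
  v1 <- a$components$sr$values * a$components$o$values
  v2 <- a$components$o$values * a$components$sr$values
  expect_identical(v1, v2)
})

test_that("dual-isotope support is the intersection of component supports", {
  spec <- grid_spec(1, 4, 0, 0, 1, crs = "local")
  sr_iso <- list(mean = sr_grid(matrix(c(0.710, 0.710, 0.730, NA), 1, 4), spec),
                 se = sr_grid(matrix(0.002, 1, 4), spec))
  o_iso <- list(mean = sr_grid(matrix(c(-6, NA, -6, -6), 1, 4), spec),
                se = sr_grid(matrix(0.5, 1, 4), spec))
  a <- assign_individual(sr_ratio = 0.710, sr_isoscape = sr_iso,
                         d18o_carb_vpdb = water_to_carb_vpdb(-6),
                         o_isoscape = o_iso)
  support <- as.vector(a$posterior$values) > 0
  expect_equal(support, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(assign_individual(), "at least one isotope")
})
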