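toy_model <- function() {
  cached("toy_mask_model", {
    set.seed(31)
    d <- data.frame(a = runif(40, 0, 1), b = runif(40, 10, 20),
                    lith = sample(c(1, 2, 5), 40, replace = TRUE))
    attr(d, "kinds") <- c(a = "continuous", b = "continuous",
                          lith = "categorical")
    srforest(d, 0.71 + 0.01 * d$a, n_trees = 30, seed = 31)
  })
}

toy_stack <- function(a, b, lith, spec = local_spec(4, 4)) {
  predictor_stack(list(a = sr_grid(a, spec), b = sr_grid(b, spec),
                       lith = sr_grid(lith, spec)),
                  c("continuous", "continuous", "categorical"))
}

test_that("a stack inside the training envelope is never masked", {
  m <- toy_model()
  row <- m$design[3, ]
  st <- toy_stack(matrix(row$a, 4, 4), matrix(row$b, 4, 4),
                  matrix(row$lith, 4, 4))
  msk <- strict_mask(st, m)
  expect_true(all(msk$values == 0))
})

test_that("out-of-range values mask exactly the constructed cells", {
  m <- toy_model()
  a <- matrix(0.5, 4, 4)
  a[, 3:4] <- max(m$design$a) + 1  # east half above the training max
  st <- toy_stack(a, matrix(15, 4, 4), matrix(1, 4, 4))
  msk <- strict_mask(st, m)
  expect_equal(sum(msk$values), 8)
  expect_true(all(msk$values[, 3:4] == 1))
  expect_true(all(msk$values[, 1:2] == 0))
  # below the minimum masks too
  b <- matrix(15, 4, 4); b[1, 1] <- min(m$design$b) - 0.001
  st2 <- toy_stack(matrix(0.5, 4, 4), b, matrix(1, 4, 4))
  expect_equal(sum(strict_mask(st2, m)$values), 1)
})

test_that("unseen categorical codes mask exactly those cells", {
  m <- toy_model()
  lith <- matrix(1, 4, 4)
  lith[c(2, 7, 13)] <- 99
  st <- toy_stack(matrix(0.5, 4, 4), matrix(15, 4, 4), lith)
  msk <- strict_mask(st, m)
  expect_equal(sum(msk$values), 3)
})

test_that("training rows are never strict-masked", {
  study <- small_study()
  msk <- strict_mask(study$land$stack, study$model)
  cells <- attr(study$design, "cells")
  # model trained on all samples; their cells carry in-range values
  expect_true(all(msk$values[cells] == 0))
})

test_that("MOP similarity matches a brute-force Mahalanobis oracle", {
  set.seed(44)
  n <- 25
  d <- data.frame(a = rnorm(n), b = rnorm(n) * 2 + 1)
  spec <- local_spec(3, 3)
  st <- predictor_stack(list(a = sr_grid(matrix(rnorm(9), 3, 3), spec),
                             b = sr_grid(matrix(rnorm(9, 1, 2), 3, 3), spec)),
                        "continuous")
  sim <- mop_similarity(st, d, fraction = 0.2)
  S <- stats::cov(cbind(d$a, d$b))
  k <- ceiling(0.2 * n)
  tab <- srisoscape:::stack_table(st)
  oracle <- vapply(seq_len(9), function(i) {
    d2 <- stats::mahalanobis(as.matrix(d), center = as.numeric(tab[i, ]),
                             cov = S)
    mean(sort(sqrt(d2))[1:k])
  }, numeric(1))
  expect_equal(as.vector(t(sim$values)), oracle, tolerance = 1e-10)
})

test_that("similarity is zero at a replicated training vector", {
  n <- 20
  set.seed(5)
  d <- data.frame(a = c(rep(0.3, 4), runif(n - 4)),
                  b = c(rep(1.0, 4), runif(n - 4)))
  # ceil(0.1 * 20) = 2 <= 4 replicates of the cell vector
  spec <- grid_spec(1, 1, 0, 0, 1, crs = "local")
  st <- predictor_stack(list(a = sr_grid(matrix(0.3), spec),
                             b = sr_grid(matrix(1.0), spec)), "continuous")
  sim <- mop_similarity(st, d, fraction = 0.1)
  expect_equal(as.numeric(sim$values), 0)
})

test_that("similarity grows monotonically away from the training centroid", {
  set.seed(6)
  n <- 40
  d <- data.frame(a = rnorm(n), b = 0.5 * rnorm(n) + 2)
  S <- stats::cov(cbind(d$a, d$b))
  eig <- eigen(S)$vectors[, 1]
  ctr <- colMeans(cbind(d$a, d$b))
  # start outside the training cloud: inside it, approaching individual
  # training points can shrink nearest-neighbour distances
  steps <- seq(3, 12, length.out = 9)
  spec <- grid_spec(1, 9, 0, 0, 1, crs = "local")
  st <- predictor_stack(
    list(a = sr_grid(matrix(ctr[1] + steps * eig[1], 1, 9), spec),
         b = sr_grid(matrix(ctr[2] + steps * eig[2], 1, 9), spec)),
    "continuous")
  sim <- mop_similarity(st, d)
  vals <- as.vector(sim$values)
  expect_true(all(diff(vals) >= -1e-10))
})

test_that("similarity is invariant to affine rescaling (full-rank case)", {
  set.seed(8)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  spec <- local_spec(3, 3)
  a_cells <- matrix(rnorm(9), 3, 3); b_cells <- matrix(rnorm(9), 3, 3)
  st1 <- predictor_stack(list(a = sr_grid(a_cells, spec),
                              b = sr_grid(b_cells, spec)), "continuous")
  s1 <- mop_similarity(st1, d)
  d2 <- data.frame(a = 2 * d$a, b = 2 * d$b)
  st2 <- predictor_stack(list(a = sr_grid(2 * a_cells, spec),
                              b = sr_grid(2 * b_cells, spec)), "continuous")
  s2 <- mop_similarity(st2, d2)
  expect_equal(s1$values, s2$values, tolerance = 1e-8)
})

test_that("too few training rows is an error", {
  d <- data.frame(a = rnorm(5), b = rnorm(5))
  spec <- grid_spec(1, 1, 0, 0, 1, crs = "local")
  st <- predictor_stack(list(a = sr_grid(matrix(0), spec),
                             b = sr_grid(matrix(0), spec)), "continuous")
  expect_error(mop_similarity(st, d), "at least 10")
})
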