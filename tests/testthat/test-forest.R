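make_toy_design <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(age = runif(n, 0, 3000), dust = rnorm(n), wet = rnorm(n))
  attr(d, "kinds") <- c(age = "continuous", dust = "continuous",
                        wet = "continuous")
  d
}

test_that("a fixed seed gives bit-identical in-bag counts and predictions", {
  d <- make_toy_design(50)
  y <- 0.71 + 1e-5 * d$age + rnorm(50, 0, 0.001)
  m1 <- srforest(d, y, n_trees = 100, seed = 5)
  m2 <- srforest(d, y, n_trees = 100, seed = 5)
  expect_identical(m1$inbag, m2$inbag)
  expect_identical(m1$tree_pred, m2$tree_pred)
  expect_identical(m1$oob_pred, m2$oob_pred)
  m3 <- srforest(d, y, n_trees = 100, seed = 6)
  expect_false(identical(m1$tree_pred, m3$tree_pred))
})

test_that("bootstrap in-bag counts sum to n for every tree", {
  m <- small_study()$model
  expect_true(all(rowSums(m$inbag) == length(m$response)))
})

test_that("OOB metrics match a hand-rolled loop oracle on a small fixture", {
  d <- make_toy_design(10, seed = 2)
  y <- 0.71 + 2e-5 * d$age + rnorm(10, 0, 0.002)
  m <- srforest(d, y, n_trees = 60, seed = 2)
  # oracle: average only trees where the sample was out of bag
  oob <- rep(NA_real_, 10)
  for (i in 1:10) {
    trees <- which(m$inbag[, i] == 0)
    if (length(trees) > 0) oob[i] <- mean(m$tree_pred[i, trees])
  }
  ok <- !is.na(oob)
  sse <- sum((y[ok] - oob[ok])^2)
  sst <- sum((y[ok] - mean(y[ok]))^2)
  expect_equal(m$oob_pred, oob)
  expect_equal(m$oob_r2, 1 - sse / sst)
  expect_equal(m$oob_rmse, sqrt(mean((y[ok] - oob[ok])^2)))
})

test_that("uninformative predictors give low OOB R2, strong signal high", {
  d <- make_toy_design(300, seed = 7)
  set.seed(7)
  y_noise <- rnorm(300, 0.71, 0.005)
  m_noise <- srforest(d, y_noise, n_trees = 200, seed = 7)
  expect_lte(m_noise$oob_r2, 0.1)
  set.seed(8)
  y_sig <- 0.71 + (d$age / 3000) * 0.05 + rnorm(300, 0, 0.002)
  m_sig <- srforest(d, y_sig, n_trees = 200, seed = 8)
  expect_gte(m_sig$oob_r2, 0.8)
})

test_that("predictions never leave the training response range", {
  study <- small_study()
  iso <- cached("small_iso", predict_isoscape(study$model, study$land$stack))
  mu <- iso$mean$values
  expect_gte(min(mu, na.rm = TRUE), min(study$model$response))
  expect_lte(max(mu, na.rm = TRUE), max(study$model$response))
})

test_that("a constant predictor field predicts that row's fitted value everywhere", {
  study <- small_study()
  row1 <- study$design[7, , drop = FALSE]
  spec <- local_spec(3, 3)
  layers <- lapply(as.list(row1), function(v) sr_grid(matrix(v, 3, 3), spec))
  st <- predictor_stack(layers, unname(attr(study$design, "kinds")[names(layers)]))
  iso <- predict_isoscape(study$model, st, se = FALSE)
  fitted_row <- predict(study$model, srisoscape:::subset_design(study$design, 7))
  expect_equal(unique(as.vector(iso$mean$values)), unname(fitted_row[1]))
})

test_that("a single-tree model's surface is the tree's piecewise-constant map", {
  d <- make_toy_design(40, seed = 3)
  y <- 0.71 + 1e-5 * d$age
  m1 <- srforest(d, y, n_trees = 1, seed = 3)
  pred <- predict(m1, d)
  tp <- predict(m1, d, per_tree = TRUE)
  expect_equal(as.numeric(pred), as.numeric(tp))
})

test_that("tuning returns the OOB-RMSE minimiser with deterministic tie-breaks", {
  d <- make_toy_design(80, seed = 4)
  y <- 0.71 + (d$age / 3000) * 0.03 + rnorm(80, 0, 0.002)
  grid <- expand.grid(mtry = 1:3, min_node_size = c(2, 5))
  out <- tune_srforest(d, y, grid, n_trees = 80, seed = 4)
  # exhaustive oracle: chosen config beats or ties every grid point
  expect_true(all(out$results$oob_rmse >=
                    out$results$oob_rmse[out$results$mtry == out$best$mtry &
                                         out$results$min_node_size ==
                                           out$best$min_node_size]))
  # singleton grid
  single <- tune_srforest(d, y, data.frame(mtry = 2, min_node_size = 5),
                          n_trees = 40, seed = 4)
  expect_equal(single$best$mtry, 2)
  expect_equal(single$best$min_node_size, 5)
  # constant response: every RMSE 0, smallest (mtry, node) wins
  const <- tune_srforest(d, rep(0.71, 80), grid, n_trees = 20, seed = 4)
  expect_lt(max(const$results$oob_rmse), 1e-12)
  expect_equal(const$best$mtry, 1)
  expect_equal(const$best$min_node_size, 2)
  # grid exceeding the number of predictors is a configuration error
  expect_error(tune_srforest(d, y, data.frame(mtry = 99, min_node_size = 2),
                             n_trees = 10, seed = 1), "configuration")
})

test_that("cross-validation covers constant responses and leave-one-out", {
  d <- make_toy_design(20, seed = 5)
  cv0 <- cross_validate(d, rep(0.71, 20), n_folds = 5, repeats = 1,
                        n_trees = 20, seed = 5)
  expect_lt(max(cv0$folds$rmse), 1e-12)
  loo <- cross_validate(d, 0.71 + 1e-5 * d$age, n_folds = 20, repeats = 1,
                        n_trees = 20, seed = 5)
  expect_equal(nrow(loo$folds), 20)
})

test_that("cross-validated RMSE is consistent with the OOB estimate", {
  study <- small_study()
  cv <- cached("small_cv",
               cross_validate(study$design, study$samples$sr_ratio,
                              n_folds = 5, repeats = 2, n_trees = 150,
                              seed = 11))
  expect_lt(abs(cv$rmse - study$model$oob_rmse), 0.2 * study$model$oob_rmse)
})

test_that("unseen categorical codes are withheld at prediction", {
  study <- small_study()
  nd <- study$design[1:3, ]
  attr(nd, "kinds") <- attr(study$design, "kinds")
  nd$lithology[2] <- 99
  p <- predict(study$model, nd)
  expect_true(is.na(p[2]))
  expect_false(any(is.na(p[c(1, 3)])))
  expect_equal(unname(attr(p, "withheld")), c(FALSE, TRUE, FALSE))
})
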