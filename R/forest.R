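# One-hot encoding of categorical predictors. The encoder freezes the
# category sets and continuous ranges seen at training time; categories not
# in the training set are strict extrapolation and predictions for such rows
# are withheld.

make_encoder <- function(design, kinds) {
  enc <- list(columns = names(design), kinds = kinds,
              levels = list(), ranges = list())
  for (nm in names(design)) {
    v <- design[[nm]]
    if (kinds[[nm]] == "categorical") {
      enc$levels[[nm]] <- sort(unique(v[!is.na(v)]))
    } else {
      enc$ranges[[nm]] <- range(v, na.rm = TRUE)
    }
  }
  enc
}

encode_design <- function(design, enc) {
  n <- nrow(design)
  cols <- list()
  unseen <- rep(FALSE, n)
  incomplete <- rep(FALSE, n)
  for (nm in enc$columns) {
    v <- design[[nm]]
    if (is.null(v)) stop("design lacks predictor '", nm, "'", call. = FALSE)
    incomplete <- incomplete | is.na(v)
    if (enc$kinds[[nm]] == "categorical") {
      levs <- enc$levels[[nm]]
      unseen <- unseen | (!is.na(v) & !(v %in% levs))
      for (lv in levs)
        cols[[paste0(nm, ".", lv)]] <- as.numeric(!is.na(v) & v == lv)
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  x <- as.data.frame(cols, optional = TRUE)
  # rows with a missing continuous value cannot be fed to the trees
  x[incomplete, ] <- 0
  list(x = x, unseen = unseen, incomplete = incomplete)
}

#' Fit a bagged regression-tree ensemble for isoscape prediction
#'
#' Fits a random forest to a predictor design and an isotope-ratio response,
#' retaining the per-tree bootstrap in-bag counts and the per-tree training
#' predictions needed for out-of-bag (OOB) error estimation and
#' infinitesimal-jackknife prediction variances. Bootstrap resampling is
#' with replacement, n draws of n, per tree. Categorical predictors are
#' one-hot encoded, which makes the strict-extrapolation rule (a category
#' unseen in training) explicit at prediction time.
#'
#' @param design predictor data.frame (`sr_design` or plain); its `"kinds"`
#'   attribute marks categorical columns, otherwise all columns are treated
#'   as continuous.
#' @param response numeric vector of 87Sr/86Sr values, one per design row.
#' @param n_trees number of trees (default 500).
#' @param mtry predictors sampled at each split (default 2, the tuned value
#'   for continental Sr isoscapes, capped at the number of encoded
#'   predictor columns).
#' @param min_node_size minimal terminal-node size (default 2); this is the
#'   "node size" hyperparameter of the tree grower.
#' @param seed integer seed; fixed seed gives bit-identical in-bag counts
#'   and predictions.
#' @return object of class `srforest` with components `forest` (the fitted
#'   engine), `inbag` (trees x samples bootstrap count matrix), `tree_pred`
#'   (samples x trees training predictions), `oob_pred`, `oob_r2`,
#'   `oob_rmse`, `encoder`, `design`, `response`, `config`.
#' @seealso [predict.srforest()], [ij_variance()], [cross_validate()],
#'   [tune_srforest()]
#' @export
srforest <- function(design, response, n_trees = 500, mtry = NULL,
                     min_node_size = 2, seed = 1) {
  design <- as.data.frame(design)
  if (nrow(design) == 0) stop("empty design", call. = FALSE)
  if (length(response) != nrow(design))
    stop("response length does not match design", call. = FALSE)
  if (any(is.na(design)))
    stop("design contains missing values; infill before fitting",
         call. = FALSE)
  if (any(is.na(response))) stop("response contains NA", call. = FALSE)
  kinds <- attr(design, "kinds")
  if (is.null(kinds))
    kinds <- stats::setNames(rep("continuous", ncol(design)), names(design))
  kinds <- kinds[names(design)]
  enc <- make_encoder(design, kinds)
  ex <- encode_design(design, enc)
  if (is.null(mtry)) mtry <- min(2L, ncol(ex$x))
  if (mtry < 1 || mtry > ncol(ex$x))
    stop("configuration error: mtry must be in [1, ", ncol(ex$x), "]",
         call. = FALSE)
  if (min_node_size < 1)
    stop("configuration error: min_node_size must be >= 1", call. = FALSE)
  fit <- ranger::ranger(x = ex$x, y = response, num.trees = n_trees,
                        mtry = mtry, min.node.size = min_node_size,
                        replace = TRUE, sample.fraction = 1,
                        keep.inbag = TRUE, oob.error = FALSE,
                        num.threads = 1, seed = seed)
  inbag <- do.call(rbind, fit$inbag.counts)  # trees x samples
  tree_pred <- stats::predict(fit, data = ex$x, predict.all = TRUE,
                              num.threads = 1)$predictions  # samples x trees
  oob_mask <- t(inbag) == 0                  # samples x trees
  n_oob <- rowSums(oob_mask)
  oob_pred <- ifelse(n_oob > 0,
                     rowSums(tree_pred * oob_mask) / pmax(n_oob, 1),
                     NA_real_)
  ok <- !is.na(oob_pred)
  sse <- sum((response[ok] - oob_pred[ok])^2)
  sst <- sum((response[ok] - mean(response[ok]))^2)
  oob_r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  oob_rmse <- sqrt(mean((response[ok] - oob_pred[ok])^2))
  structure(list(forest = fit, inbag = inbag, tree_pred = tree_pred,
                 oob_pred = oob_pred, oob_r2 = oob_r2, oob_rmse = oob_rmse,
                 encoder = enc, kinds = kinds, design = design,
                 response = response,
                 config = list(n_trees = n_trees, mtry = mtry,
                               min_node_size = min_node_size, seed = seed)),
            class = "srforest")
}

#' @export
print.srforest <- function(x, ...) {
  cat(sprintf("srforest: %d trees, mtry %d, node size %d, %d training samples\n",
              x$config$n_trees, x$config$mtry, x$config$min_node_size,
              length(x$response)))
  cat(sprintf("  OOB R2 %.3f, OOB RMSE %.5f\n", x$oob_r2, x$oob_rmse))
  invisible(x)
}

#' @export
summary.srforest <- function(object, ...) {
  res <- residuals(object)
  out <- list(config = object$config, n = length(object$response),
              oob_r2 = object$oob_r2, oob_rmse = object$oob_rmse,
              residual_quantiles = stats::quantile(res, c(0, .25, .5, .75, 1),
                                                   na.rm = TRUE),
              predictors = object$encoder$columns)
  class(out) <- "summary.srforest"
  out
}

#' @export
print.summary.srforest <- function(x, ...) {
  cat(sprintf("Bagged regression-tree isoscape model (%d trees)\n",
              x$config$n_trees))
  cat(sprintf("Training samples: %d; predictors: %s\n", x$n,
              paste(x$predictors, collapse = ", ")))
  cat(sprintf("OOB R2 %.3f, OOB RMSE %.5f\n", x$oob_r2, x$oob_rmse))
  cat("OOB residual quantiles:\n"); print(signif(x$residual_quantiles, 3))
  invisible(x)
}

#' Out-of-bag residuals of an srforest
#'
#' `residual_i = y_i -` OOB prediction for sample i (averaging only trees in
#' which i was out of bag). Samples with zero OOB trees are `NA`.
#' @param object an [srforest()].
#' @param ... unused.
#' @export
residuals.srforest <- function(object, ...) {
  object$response - object$oob_pred
}

# Row-subset a design while keeping its kinds attribute.
subset_design <- function(design, rows) {
  out <- design[rows, , drop = FALSE]
  attr(out, "kinds") <- attr(design, "kinds")
  out
}

# Per-tree predictions for already-encoded valid rows.
tree_predictions <- function(model, x_encoded) {
  stats::predict(model$forest, data = x_encoded, predict.all = TRUE,
                 num.threads = 1)$predictions
}

#' Predict isotope ratios for new predictor rows
#'
#' Rows with any missing predictor, or a categorical code unseen in
#' training, get `NA` (prediction withheld as strict extrapolation); the
#' logical attribute `"withheld"` marks them.
#'
#' @param object an [srforest()].
#' @param newdata data.frame with the model's predictor columns.
#' @param per_tree if `TRUE`, return the rows x trees matrix of per-tree
#'   predictions (valid rows only, attribute `"valid"` maps them back).
#' @param ... unused.
#' @return numeric vector of predictions (or a matrix if `per_tree`).
#' @export
predict.srforest <- function(object, newdata, per_tree = FALSE, ...) {
  ex <- encode_design(as.data.frame(newdata), object$encoder)
  valid <- !ex$incomplete & !ex$unseen
  if (per_tree) {
    tp <- tree_predictions(object, ex$x[valid, , drop = FALSE])
    attr(tp, "valid") <- valid
    return(tp)
  }
  out <- rep(NA_real_, nrow(newdata))
  if (any(valid)) {
    tp <- tree_predictions(object, ex$x[valid, , drop = FALSE])
    out[valid] <- rowMeans(tp)
  }
  attr(out, "withheld") <- !valid
  out
}

#' Tune mtry and node size by OOB RMSE
#'
#' Refits the forest at every grid point and returns the one minimising the
#' out-of-bag RMSE; ties are broken toward smaller `mtry`, then smaller
#' `min_node_size`.
#'
#' @param design,response as in [srforest()].
#' @param grid data.frame with columns `mtry` and `min_node_size`.
#' @param n_trees,seed forwarded to [srforest()] (the same seed is used for
#'   every grid point so comparisons share their bootstrap stream).
#' @return list with `best` (row of `grid`), `results` (grid plus
#'   `oob_rmse`, `oob_r2`).
#' @export
tune_srforest <- function(design, response, grid, n_trees = 500, seed = 1) {
  if (nrow(grid) == 0) stop("configuration error: empty tuning grid",
                            call. = FALSE)
  res <- grid
  res$oob_rmse <- NA_real_; res$oob_r2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- srforest(design, response, n_trees = n_trees,
                  mtry = grid$mtry[i], min_node_size = grid$min_node_size[i],
                  seed = seed)
    res$oob_rmse[i] <- m$oob_rmse; res$oob_r2[i] <- m$oob_r2
  }
  best <- res[order(res$oob_rmse, res$mtry, res$min_node_size), ][1, ]
  list(best = best[, c("mtry", "min_node_size")], results = res)
}

#' Repeated k-fold cross-validation
#'
#' Folds are random partitions (no spatial blocking), reshuffled each repeat
#' with seeds derived from `seed`. Per-fold R2 uses the test-set total sum
#' of squares; folds with zero test variance (e.g. singleton folds) report
#' `NA` R2 and are dropped from the aggregate mean.
#'
#' @param design,response as in [srforest()].
#' @param n_folds number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param n_trees,mtry,min_node_size,seed forwarded to [srforest()].
#' @return object of class `sr_cv`: list with `folds` (data.frame of repeat,
#'   fold, n_test, r2, rmse) and aggregate `r2`, `rmse`.
#' @export
cross_validate <- function(design, response, n_folds = 5, repeats = 10,
                           n_trees = 500, mtry = NULL, min_node_size = 2,
                           seed = 1) {
  n <- nrow(design)
  if (n < n_folds) stop("fewer samples than folds", call. = FALSE)
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed((seed + 1000L * r) %% .Machine$integer.max)
    fold_id <- sample(rep_len(seq_len(n_folds), n))
    for (k in seq_len(n_folds)) {
      test <- which(fold_id == k)
      train <- which(fold_id != k)
      m <- srforest(subset_design(design, train), response[train],
                    n_trees = n_trees, mtry = mtry,
                    min_node_size = min_node_size,
                    seed = seed + 37L * r + k)
      pred <- predict(m, subset_design(design, test))
      sse <- sum((response[test] - pred)^2)
      sst <- sum((response[test] - mean(response[test]))^2)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = k, n_test = length(test),
                   r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                   rmse = sqrt(mean((response[test] - pred)^2)))
    }
  }
  folds <- do.call(rbind, rows)
  out <- list(folds = folds, r2 = mean(folds$r2, na.rm = TRUE),
              rmse = mean(folds$rmse), n_folds = n_folds, repeats = repeats)
  class(out) <- "sr_cv"
  out
}

#' @export
print.sr_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repetition(s): mean R2 %.3f, mean RMSE %.5f\n",
              x$n_folds, x$repeats, x$r2, x$rmse))
  invisible(x)
}

#' Predict the isoscape mean and standard-error surfaces over a stack
#'
#' Per valid cell, the mean is the average of the per-tree predictions and
#' the standard error comes from the bias-corrected infinitesimal jackknife
#' for bagging ([ij_variance()]). Cells with any missing predictor, or a
#' categorical code unseen in training, are withheld (`NA` in both
#' surfaces).
#'
#' @param model an [srforest()].
#' @param stack a [predictor_stack()] whose layer names and kinds match the
#'   model's predictors.
#' @param se compute the standard-error surface (default `TRUE`).
#' @param bias_correction forwarded to the jackknife (default `TRUE`).
#' @param chunk cells processed per block (memory control).
#' @return object of class `sr_isoscape`: list with `mean` and `se`
#'   ([sr_grid()]s), `n_withheld`, and `config`.
#' @export
predict_isoscape <- function(model, stack, se = TRUE, bias_correction = TRUE,
                             chunk = 4096) {
  missing_layers <- setdiff(model$encoder$columns, names(stack$layers))
  if (length(missing_layers) > 0)
    stop("stack lacks predictor layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  tab <- stack_table(stack)[, model$encoder$columns, drop = FALSE]
  ex <- encode_design(tab, model$encoder)
  valid <- which(!ex$incomplete & !ex$unseen)
  ncell <- nrow(tab)
  mu <- rep(NA_real_, ncell)
  sg <- rep(NA_real_, ncell)
  n_trunc <- 0L
  for (start in seq(1, length(valid), by = chunk)) {
    idx <- valid[start:min(start + chunk - 1L, length(valid))]
    tp <- tree_predictions(model, ex$x[idx, , drop = FALSE])
    mu[idx] <- rowMeans(tp)
    if (se) {
      v <- ij_variance_trees(tp, model$inbag,
                             bias_correction = bias_correction)
      sg[idx] <- sqrt(v)
      n_trunc <- n_trunc + attr(v, "n_truncated")
    }
  }
  out <- list(mean = grid_from_vector(mu, stack$spec),
              se = if (se) grid_from_vector(sg, stack$spec) else NULL,
              n_withheld = ncell - length(valid),
              n_se_truncated = if (se) n_trunc else NA_integer_,
              config = model$config)
  class(out) <- "sr_isoscape"
  out
}

#' @export
print.sr_isoscape <- function(x, ...) {
  v <- x$mean$values
  cat(sprintf("sr_isoscape: %d x %d grid, %d cells withheld\n",
              nrow(v), ncol(v), x$n_withheld))
  cat(sprintf("  mean in [%.5f, %.5f]\n", min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  if (!is.null(x$se))
    cat(sprintf("  SE in [%.5f, %.5f] (%d variance truncations)\n",
                min(x$se$values, na.rm = TRUE), max(x$se$values, na.rm = TRUE),
                x$n_se_truncated))
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' Serialises the full model (trees, in-bag counts, encoder, config, seed)
#' so standard-error computation and assignment can run later.
#' @param model an [srforest()].
#' @param path archive path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_srforest <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_srforest
#' @export
load_srforest <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "srforest")) stop("not an srforest archive", call. = FALSE)
  m
}
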