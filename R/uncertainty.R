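# Infinitesimal jackknife for bagging.
#
# For a prediction point x with per-tree predictions t_b(x), b = 1..B, and
# bootstrap in-bag counts N_{b,i} (tree b, training sample i):
#
#   V_IJ(x)    = sum_i Cov_b[N_{b,i}, t_b(x)]^2
#   V_IJ-U(x)  = V_IJ(x) - (n / B^2) * sum_b (t_b(x) - tbar(x))^2
#
# with Cov_b the empirical covariance over trees using 1/B (population)
# normalisation. The bias correction removes Monte-Carlo noise from finite
# B and can overshoot for small ensembles, so the variance is truncated at
# zero; truncation events are counted.

#' Infinitesimal-jackknife variance from raw ensemble components
#'
#' Low-level entry point operating directly on a points x trees matrix of
#' per-tree predictions and the trees x samples bootstrap in-bag count
#' matrix; [ij_variance()] is the model-facing wrapper. Exposed so the
#' estimator can be checked against independent implementations.
#'
#' @param tpred numeric matrix, prediction points x trees.
#' @param inbag integer matrix, trees x training samples.
#' @param bias_correction apply the finite-B correction (default `TRUE`).
#' @return numeric vector of variances with attributes `raw` and
#'   `n_truncated`.
#' @export
ij_variance_trees <- function(tpred, inbag, bias_correction = TRUE) {
  tpred <- as.matrix(tpred)
  B <- ncol(tpred)
  if (B < 2) stop("infinitesimal jackknife needs at least 2 trees",
                  call. = FALSE)
  if (nrow(inbag) != B)
    stop("inbag matrix does not match the number of trees", call. = FALSE)
  n <- ncol(inbag)
  N <- t(inbag)                       # samples x trees
  Nc <- N - rowMeans(N)
  tc <- tpred - rowMeans(tpred)
  C <- tcrossprod(tc, Nc) / B         # points x samples: Cov_b[N_bi, t_b]
  raw <- rowSums(C^2)
  v <- raw
  if (bias_correction) v <- raw - (n / B^2) * rowSums(tc^2)
  truncated <- v < 0
  v[truncated] <- 0
  attr(v, "raw") <- raw
  attr(v, "n_truncated") <- sum(truncated)
  v
}

#' Infinitesimal-jackknife prediction variance
#'
#' Bias-corrected infinitesimal-jackknife variance of the bagged prediction
#' at new predictor rows, computed from the model's retained in-bag counts
#' and per-tree predictions. Negative bias-corrected values are truncated
#' at zero (the count of truncations is returned as an attribute).
#'
#' @param model an [srforest()] (fitted with retained in-bag counts).
#' @param newdata data.frame of predictor rows; rows that are incomplete or
#'   contain unseen categorical codes get `NA` variance.
#' @param bias_correction apply the finite-B bias correction (default
#'   `TRUE`).
#' @return numeric vector of variances (87Sr/86Sr squared units) with
#'   attributes `raw` (uncorrected values for the valid rows, in row order)
#'   and `n_truncated`.
#' @export
ij_variance <- function(model, newdata, bias_correction = TRUE) {
  ex <- encode_design(as.data.frame(newdata), model$encoder)
  valid <- !ex$incomplete & !ex$unseen
  out <- rep(NA_real_, nrow(newdata))
  raw <- rep(NA_real_, nrow(newdata))
  n_trunc <- 0L
  if (any(valid)) {
    tp <- tree_predictions(model, ex$x[valid, , drop = FALSE])
    v <- ij_variance_trees(tp, model$inbag, bias_correction = bias_correction)
    out[valid] <- v
    raw[valid] <- attr(v, "raw")
    n_trunc <- attr(v, "n_truncated")
  }
  attr(out, "raw") <- raw
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Standard-error surface of an isoscape model
#'
#' Applies [ij_variance()] to every valid cell of a predictor stack;
#' missing-predictor cells propagate as `NA`.
#'
#' @param model an [srforest()].
#' @param stack a [predictor_stack()] matching the model's predictors.
#' @param bias_correction,chunk as in [predict_isoscape()].
#' @return an [sr_grid()] of per-cell prediction standard errors.
#' @export
se_surface <- function(model, stack, bias_correction = TRUE, chunk = 4096) {
  iso <- predict_isoscape(model, stack, se = TRUE,
                          bias_correction = bias_correction, chunk = chunk)
  iso$se
}
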