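#' Fraction of residuals within a tolerance band
#'
#' @param residuals numeric residuals (`NA`s dropped).
#' @param tol half-width of the band (default 0.002, in 87Sr/86Sr units).
#' @return the share of residuals with `|r| <= tol`.
#' @export
residual_fraction <- function(residuals, tol = 0.002) {
  r <- residuals[!is.na(residuals)]
  mean(abs(r) <= tol)
}

#' OOB residual summary of a fitted isoscape model
#'
#' @param model an [srforest()].
#' @param tol band half-width for the reported fraction (default 0.002).
#' @return list with `residuals` (OOB residuals), `fraction` (share within
#'   `+/-tol`), `n_excluded` (samples with zero OOB trees, excluded with a
#'   warning).
#' @export
residual_summary <- function(model, tol = 0.002) {
  res <- residuals(model)
  n_excl <- sum(is.na(res))
  if (n_excl > 0)
    warning(n_excl, " sample(s) with zero OOB trees excluded", call. = FALSE)
  list(residuals = res, fraction = residual_fraction(res, tol),
       n_excluded = n_excl, tol = tol)
}

#' Binned spatial correlogram of residuals with a permutation envelope
#'
#' Great-circle pair distances are split into `n_bins` equal-count bins;
#' each bin reports a Moran-style correlation of residual pairs: the mean
#' centred cross-product of the paired residuals divided by the residual
#' variance. The null envelope (2.5/97.5 percentiles) comes from `n_perm`
#' random permutations of the residuals over the locations. Bins holding
#' fewer than 30 pairs are flagged. If all residuals are identical the
#' correlations are undefined and reported as `NA`.
#'
#' @param residuals numeric residuals, one per location.
#' @param coords two-column matrix/data.frame of longitude, latitude
#'   (decimal degrees WGS84).
#' @param n_bins number of distance bins (default 10).
#' @param n_perm permutations for the null envelope (default 199).
#' @param seed RNG seed for the permutations.
#' @return object of class `sr_correlogram`: data.frame with bin edges
#'   (km), per-bin correlation, pair counts, envelope bounds and a
#'   `few_pairs` flag.
#' @export
correlogram <- function(residuals, coords, n_bins = 10, n_perm = 199,
                        seed = 1) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (nrow(coords) != n) stop("coords do not match residuals", call. = FALSE)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  d_km <- geosphere::distHaversine(coords[i, , drop = FALSE],
                                   coords[j, , drop = FALSE]) / 1000
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- unique(stats::quantile(d_km, probs, names = FALSE))
  bin <- cut(d_km, breaks = edges, include.lowest = TRUE, labels = FALSE)
  n_bins_eff <- length(edges) - 1

  ec <- residuals - mean(residuals)
  denom <- mean(ec^2)
  bin_stat <- function(e_centred) {
    prod <- e_centred[i] * e_centred[j]
    as.vector(rowsum(prod, bin, reorder = TRUE)) /
      tabulate(bin, n_bins_eff) / denom
  }
  counts <- tabulate(bin, n_bins_eff)
  if (denom == 0) {
    obs <- rep(NA_real_, n_bins_eff)
    lower <- upper <- rep(NA_real_, n_bins_eff)
  } else {
    obs <- bin_stat(ec)
    set.seed(seed)
    perm <- matrix(NA_real_, n_perm, n_bins_eff)
    for (p in seq_len(n_perm)) perm[p, ] <- bin_stat(sample(ec))
    lower <- apply(perm, 2, stats::quantile, probs = 0.025)
    upper <- apply(perm, 2, stats::quantile, probs = 0.975)
  }
  out <- data.frame(bin = seq_len(n_bins_eff),
                    d_min_km = edges[-length(edges)], d_max_km = edges[-1],
                    correlation = obs, n_pairs = counts,
                    env_lower = lower, env_upper = upper,
                    few_pairs = counts < 30)
  class(out) <- c("sr_correlogram", "data.frame")
  out
}

#' @export
plot.sr_correlogram <- function(x, ...) {
  mid <- (x$d_min_km + x$d_max_km) / 2
  ylim <- range(c(x$correlation, x$env_lower, x$env_upper), na.rm = TRUE)
  graphics::plot(mid, x$correlation, type = "b", pch = 16, ylim = ylim,
                 xlab = "pair distance (km)",
                 ylab = "residual correlation", ...)
  graphics::lines(mid, x$env_lower, lty = 2)
  graphics::lines(mid, x$env_upper, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

# OOB mean squared error given per-tree predictions on (possibly permuted)
# training data.
oob_mse_from_trees <- function(tpred, inbag, response) {
  oob_mask <- t(inbag) == 0
  n_oob <- rowSums(oob_mask)
  pred <- rowSums(tpred * oob_mask) / pmax(n_oob, 1)
  ok <- n_oob > 0
  mean((response[ok] - pred[ok])^2)
}

#' Permutation importance of predictors
#'
#' Mean increase in OOB mean squared error when a predictor's training
#' values are permuted, averaged over `n_repeats` permutations (fixed
#' seed). One-hot groups of a categorical predictor are permuted together.
#'
#' @param model an [srforest()].
#' @param n_repeats permutations per predictor (default 5).
#' @param seed RNG seed.
#' @return data.frame of predictor, importance (OOB MSE increase), ranked
#'   decreasing.
#' @export
importance_permutation <- function(model, n_repeats = 5, seed = 1) {
  design <- model$design
  base <- oob_mse_from_trees(model$tree_pred, model$inbag, model$response)
  set.seed(seed)
  imp <- vapply(names(design), function(nm) {
    deltas <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      d <- design
      d[[nm]] <- sample(d[[nm]])
      ex <- encode_design(d, model$encoder)
      tp <- tree_predictions(model, ex$x)
      deltas[r] <- oob_mse_from_trees(tp, model$inbag, model$response) - base
    }
    mean(deltas)
  }, numeric(1))
  out <- data.frame(predictor = names(design), importance = unname(imp))
  out[order(-out$importance), ]
}

#' Partial dependence of the model on one predictor
#'
#' `PD(v)` is the mean model prediction over the training rows with the
#' chosen predictor forced to `v`. Values outside the training range are
#' computed but flagged.
#'
#' @param model an [srforest()].
#' @param predictor name of the predictor.
#' @param values evaluation points; default 25 equally spaced points over
#'   the training range (continuous) or the training category set.
#' @return data.frame of value, pd, out_of_range.
#' @export
partial_dependence <- function(model, predictor, values = NULL) {
  design <- model$design
  if (!predictor %in% names(design))
    stop("unknown predictor '", predictor, "'", call. = FALSE)
  kind <- model$kinds[[predictor]]
  if (is.null(values)) {
    values <- if (kind == "categorical") model$encoder$levels[[predictor]]
    else seq(model$encoder$ranges[[predictor]][1],
             model$encoder$ranges[[predictor]][2], length.out = 25)
  }
  oor <- if (kind == "categorical")
    !(values %in% model$encoder$levels[[predictor]])
  else values < model$encoder$ranges[[predictor]][1] |
    values > model$encoder$ranges[[predictor]][2]
  pd <- vapply(values, function(v) {
    d <- design
    d[[predictor]] <- v
    mean(predict(model, d), na.rm = TRUE)
  }, numeric(1))
  data.frame(value = values, pd = pd, out_of_range = oor)
}
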