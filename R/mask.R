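#' Strict-extrapolation mask
#'
#' A cell is strict extrapolation (masked, `TRUE`) when at least one
#' predictor's value there falls outside the range sampled at training:
#' below the training minimum or above the maximum for continuous layers, a
#' code unseen in training for categorical layers. Cells with any missing
#' predictor are masked too.
#'
#' @param stack a [predictor_stack()].
#' @param model an [srforest()] (its training ranges and category sets are
#'   used).
#' @return an [sr_grid()] with values 1 (masked) / 0 (inside the sampled
#'   range).
#' @export
strict_mask <- function(stack, model) {
  enc <- model$encoder
  tab <- stack_table(stack)
  masked <- rep(FALSE, nrow(tab))
  for (nm in enc$columns) {
    v <- tab[[nm]]
    if (is.null(v)) stop("stack lacks predictor layer '", nm, "'",
                         call. = FALSE)
    if (enc$kinds[[nm]] == "categorical") {
      masked <- masked | is.na(v) | !(v %in% enc$levels[[nm]])
    } else {
      rng <- enc$ranges[[nm]]
      masked <- masked | is.na(v) | v < rng[1] | v > rng[2]
    }
  }
  grid_from_vector(as.numeric(masked), stack$spec)
}

# Shrink a covariance toward its diagonal until it is numerically
# invertible (one-hot columns can be collinear).
shrink_covariance <- function(S, max_condition = 1e8) {
  target <- diag(diag(S), nrow = nrow(S))
  for (lambda in c(0, 1e-4, 1e-3, 1e-2, 1e-1, 0.5)) {
    Sl <- (1 - lambda) * S + lambda * target
    kap <- tryCatch(kappa(Sl, exact = TRUE), error = function(e) Inf)
    if (is.finite(kap) && kap <= max_condition)
      return(list(S = Sl, lambda = lambda))
  }
  stop("covariance is singular even after diagonal shrinkage; ",
       "drop constant or duplicated predictors", call. = FALSE)
}

#' Environmental-similarity (mobility-oriented parity) surface
#'
#' Per cell, the Mahalanobis distance from the cell's predictor vector to
#' each training row (using the training-set covariance, diagonal-shrunk if
#' ill-conditioned), summarised as the mean of the distances to the nearest
#' `fraction` of the sampled cloud (the `ceiling(fraction * n)` closest
#' reference points). Larger values mean greater environmental
#' dissimilarity from the calibration data. Categorical predictors enter
#' one-hot encoded; constant encoded columns are dropped (they carry no
#' distance information).
#'
#' @param stack a [predictor_stack()].
#' @param design the training design (`sr_design` or data.frame; `"kinds"`
#'   attribute marks categorical columns).
#' @param fraction reference fraction of the sampled cloud (default 0.10).
#' @param mask optional [sr_grid()] of cells to exclude (nonzero = exclude),
#'   typically the [strict_mask()]; excluded cells become `NA`.
#' @param chunk cells per processing block.
#' @return an [sr_grid()] of mean Mahalanobis distances (dimensionless).
#' @export
mop_similarity <- function(stack, design, fraction = 0.10, mask = NULL,
                           chunk = 4096) {
  design <- as.data.frame(design)
  n <- nrow(design)
  if (n < 10) stop("need at least 10 training rows", call. = FALSE)
  kinds <- attr(design, "kinds")
  if (is.null(kinds))
    kinds <- stats::setNames(rep("continuous", ncol(design)), names(design))
  enc <- make_encoder(design, kinds[names(design)])
  X <- as.matrix(encode_design(design, enc)$x)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all predictors constant", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  S <- stats::cov(X)
  sh <- shrink_covariance(S)
  R <- chol(sh$S)
  W <- backsolve(R, diag(ncol(X)))     # whitener: X %*% W has identity cov
  U <- X %*% W
  u2 <- rowSums(U^2)
  k <- ceiling(fraction * n)

  tab <- stack_table(stack)[, enc$columns, drop = FALSE]
  ex <- encode_design(tab, enc)
  cellX <- as.matrix(ex$x)[, keep, drop = FALSE]
  valid <- which(!ex$incomplete)
  if (!is.null(mask)) {
    mv <- as.vector(t(mask$values))
    valid <- setdiff(valid, which(is.na(mv) | mv != 0))
  }
  out <- rep(NA_real_, nrow(tab))
  for (start in seq(1, length(valid), by = chunk)) {
    idx <- valid[start:min(start + chunk - 1L, length(valid))]
    V <- cellX[idx, , drop = FALSE] %*% W
    d2 <- outer(rowSums(V^2), rep(1, n)) +
      outer(rep(1, length(idx)), u2) - 2 * tcrossprod(V, U)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    out[idx] <- apply(d, 1, function(row) mean(sort.int(row,
                                                        partial = k)[1:k]))
  }
  g <- grid_from_vector(out, stack$spec)
  attr(g, "fraction") <- fraction
  attr(g, "shrinkage_lambda") <- sh$lambda
  g
}
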