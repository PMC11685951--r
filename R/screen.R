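#' Collinearity screening of a predictor design
#'
#' Advisory diagnostics used when reducing a predictor set: pairwise Pearson
#' correlations and variance-inflation factors over the continuous columns.
#' Categorical columns are excluded. VIF for column j is `1 / (1 - R2_j)`
#' where `R2_j` comes from regressing column j on all other continuous
#' columns; for rank-deficient designs the dependent columns report `Inf`
#' rather than erroring.
#'
#' @param design an `sr_design` (or plain data.frame; then all numeric
#'   columns are treated as continuous).
#' @param r_threshold absolute-correlation threshold above which a pair is
#'   flagged (default 0.8).
#' @return object of class `sr_screen`: list with `pearson` (correlation
#'   matrix), `vif` (named vector), `flagged_pairs` (data.frame of var1,
#'   var2, r).
#' @export
screen_predictors <- function(design, r_threshold = 0.8) {
  kinds <- attr(design, "kinds")
  if (is.null(kinds))
    kinds <- stats::setNames(rep("continuous", ncol(design)), names(design))
  cont <- names(design)[kinds[names(design)] == "continuous"]
  if (length(cont) < 1)
    stop("no continuous columns to screen", call. = FALSE)
  x <- as.matrix(design[, cont, drop = FALSE])
  if (length(cont) == 1) {
    pearson <- matrix(1, 1, 1, dimnames = list(cont, cont))
    out <- list(pearson = pearson, vif = stats::setNames(numeric(0), NULL),
                flagged_pairs = data.frame(var1 = character(),
                                           var2 = character(), r = numeric()),
                r_threshold = r_threshold)
    class(out) <- "sr_screen"
    return(out)
  }
  pearson <- stats::cor(x)
  vif <- vapply(seq_along(cont), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    res <- fit$residuals
    tot <- sum((x[, j] - mean(x[, j]))^2)
    if (tot == 0) return(NA_real_)  # constant column
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- cont
  pairs <- which(upper.tri(pearson) & abs(pearson) > r_threshold,
                 arr.ind = TRUE)
  flagged <- data.frame(var1 = cont[pairs[, 1]], var2 = cont[pairs[, 2]],
                        r = pearson[pairs], stringsAsFactors = FALSE)
  out <- list(pearson = pearson, vif = vif, flagged_pairs = flagged,
              r_threshold = r_threshold)
  class(out) <- "sr_screen"
  out
}

#' @export
print.sr_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen over %d continuous predictors\n",
              nrow(x$pearson)))
  if (length(x$vif)) {
    cat("VIF:\n"); print(round(x$vif, 2))
  }
  if (nrow(x$flagged_pairs) > 0) {
    cat(sprintf("Pairs with |r| > %g:\n", x$r_threshold))
    print(x$flagged_pairs)
  } else cat(sprintf("No pairs with |r| > %g\n", x$r_threshold))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Correlation matrix and VIF as CSV, plus a flat text summary.
#' @param report an `sr_screen`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pearson, file.path(dir, "pearson.csv"))
  utils::write.csv(data.frame(predictor = names(report$vif),
                              vif = unname(report$vif)),
                   file.path(dir, "vif.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(dir)
}
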