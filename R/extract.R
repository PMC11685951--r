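#' Extract predictor values at sample locations, infilling missing cells
#'
#' Each sample receives one value per stack layer, taken from the cell its
#' coordinates fall in. Where a layer is missing at that cell, the value is
#' infilled: categorical layers take the value of the nearest non-missing
#' cell (distance between cell centers; great-circle on lon/lat grids,
#' Euclidean otherwise; ties broken by row-major cell index), continuous
#' layers take the arithmetic mean of the 5 nearest non-missing cells.
#'
#' @param samples an `sr_samples` table (see [read_samples()]).
#' @param stack a [predictor_stack()] whose extent contains every sample.
#' @param max_radius search radius for infill donors, in metres (lon/lat
#'   grids) or CRS units (projected); donors farther than this make the
#'   infill fail for that sample/layer (reported, value left `NA`).
#' @return a `data.frame` of class `sr_design`, rows aligned to `samples`,
#'   columns aligned to stack layers, with attributes `infill_log`
#'   (data.frame of row, column, method, n_donors, max_donor_distance) and
#'   `failures` (data.frame of row, column, reason), plus `kinds`.
#' @export
extract_predictors <- function(samples, stack, max_radius = Inf) {
  spec <- stack$spec
  rc <- cell_rowcol(spec, samples$longitude, samples$latitude)
  outside <- is.na(rc[, "row"])
  if (any(outside))
    stop("sample(s) outside the grid extent: ",
         paste(samples$sample_id[outside], collapse = ", "), call. = FALSE)
  n <- nrow(samples)
  design <- as.data.frame(matrix(NA_real_, n, length(stack$layers)))
  names(design) <- names(stack$layers)
  infill_log <- list(); failures <- list()

  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]]$values
    kind <- stack$kinds[[nm]]
    vals <- v[cbind(rc[, "row"], rc[, "col"])]
    miss <- which(is.na(vals))
    if (length(miss) > 0) {
      donors <- which(!is.na(t(v)))  # row-major cell indices of valid cells
      if (length(donors) == 0) {
        for (i in miss)
          failures[[length(failures) + 1L]] <-
            data.frame(row = i, column = nm, reason = "layer entirely missing")
        vals[miss] <- NA_real_
      } else {
        drc <- index_rowcol(spec, donors)
        dxy <- cell_centers(spec, drc[, "row"], drc[, "col"])
        need <- if (kind == "categorical") 1L else 5L
        for (i in miss) {
          ctr <- cell_centers(spec, rc[i, "row"], rc[i, "col"])
          d <- point_distances(spec, ctr[1, "x"], ctr[1, "y"], dxy)
          ord <- order(d, donors)  # ties broken by row-major cell index
          ok <- ord[d[ord] <= max_radius]
          if (length(ok) < need) {
            failures[[length(failures) + 1L]] <-
              data.frame(row = i, column = nm,
                         reason = sprintf("fewer than %d donors within radius",
                                          need))
            next
          }
          pick <- ok[seq_len(need)]
          dv <- v[cbind(drc[pick, "row"], drc[pick, "col"])]
          vals[i] <- if (kind == "categorical") dv[1] else mean(dv)
          infill_log[[length(infill_log) + 1L]] <-
            data.frame(row = i, column = nm,
                       method = if (kind == "categorical") "nearest_cell"
                                else "mean_5_nearest",
                       n_donors = need, max_donor_distance = max(d[pick]))
        }
      }
    }
    design[[nm]] <- vals
  }
  attr(design, "infill_log") <- if (length(infill_log))
    do.call(rbind, infill_log) else
    data.frame(row = integer(), column = character(), method = character(),
               n_donors = integer(), max_donor_distance = numeric())
  attr(design, "failures") <- if (length(failures))
    do.call(rbind, failures) else
    data.frame(row = integer(), column = character(), reason = character())
  attr(design, "kinds") <- stack$kinds
  attr(design, "cells") <- rc
  class(design) <- c("sr_design", "data.frame")
  design
}
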