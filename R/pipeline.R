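# End-to-end orchestration: simulate -> build isoscape -> assign origins.
# Each stage failure is re-raised with a stage tag so a run aborts with a
# clear message about where it died.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Write a synthetic dataset to disk
#'
#' Generates a landscape and writes it in the same formats the pipeline
#' reads: `predictors/*.asc`, `samples.csv`, `individuals.csv`,
#' `truth.asc` (and `truth_o.asc`), so synthetic runs exercise the real
#' I/O paths.
#'
#' @param out_dir output directory (created).
#' @param config a [synthetic_config()].
#' @param with_oxygen simulate d18O for the individuals (default `TRUE`).
#' @return the `sr_landscape`, invisibly.
#' @export
simulate_dataset <- function(out_dir, config = synthetic_config(),
                             with_oxygen = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  land <- make_landscape(config)
  write_stack(land$stack, file.path(out_dir, "predictors"))
  write_samples(sample_sites(land), file.path(out_dir, "samples.csv"))
  ind <- simulate_individuals(land, with_oxygen = with_oxygen)
  utils::write.csv(ind, file.path(out_dir, "individuals.csv"),
                   row.names = FALSE)
  write_ascii_grid(land$truth, file.path(out_dir, "truth.asc"))
  write_ascii_grid(land$truth_o, file.path(out_dir, "truth_o.asc"))
  invisible(land)
}

#' Build an isoscape from samples and predictor rasters
#'
#' Stage order: read samples, extract/infill predictors, collinearity
#' screen, hyperparameter tuning, fit, repeated k-fold cross-validation,
#' mean prediction, infinitesimal-jackknife standard errors,
#' strict-extrapolation mask and environmental-similarity surface, then
#' diagnostics. A holdout of `n_holdout` samples (chosen uniformly at
#' random with the run seed) is set aside before tuning and scored at the
#' end. The masked cells are removed (nodata) from the written mean/SE
#' surfaces.
#'
#' @param samples path to a samples CSV or an `sr_samples` table.
#' @param predictors path to a directory of `.asc` layers or a
#'   [predictor_stack()].
#' @param out_dir directory for artifacts, or `NULL` to skip writing.
#' @param n_trees trees per forest (default 500).
#' @param tune_grid data.frame of `mtry`, `min_node_size` candidates;
#'   `NULL` skips tuning and uses `mtry`/`min_node_size`.
#' @param mtry,min_node_size hyperparameters when not tuning (default 2
#'   and 2).
#' @param n_folds,cv_repeats cross-validation design (default 5 folds, 10
#'   repetitions).
#' @param n_holdout validation holdout size (default 20).
#' @param mop_fraction reference fraction for [mop_similarity()].
#' @param seed run seed; every random stage derives its stream from it.
#' @return list of class `sr_build`: `model`, `isoscape` (with masked
#'   cells removed), `mask`, `similarity`, `screen`, `cv`, `holdout`
#'   (r2/rmse), `diagnostics`, `run_info`.
#' @export
build_isoscape <- function(samples, predictors, out_dir = NULL,
                           n_trees = 500, tune_grid = NULL, mtry = 2,
                           min_node_size = 2, n_folds = 5, cv_repeats = 10,
                           n_holdout = 20, mop_fraction = 0.10, seed = 1) {
  if (is.character(predictors) && !dir.exists(predictors))
    stop("configuration error: predictor directory not found: ", predictors,
         call. = FALSE)
  if (is.character(samples) && !file.exists(samples))
    stop("configuration error: sample file not found: ", samples,
         call. = FALSE)
  stack <- run_stage("read_predictors",
                     if (is.character(predictors)) read_stack(predictors)
                     else predictors)
  samp <- run_stage("read_samples",
                    if (is.character(samples)) read_samples(samples)
                    else samples)
  design <- run_stage("extract", extract_predictors(samp, stack))
  screen <- run_stage("screen", screen_predictors(design))

  set.seed(seed)
  n <- nrow(design)
  holdout_idx <- if (n_holdout > 0 && n > n_holdout)
    sample.int(n, n_holdout) else integer(0)
  train_idx <- setdiff(seq_len(n), holdout_idx)
  d_train <- subset_design(design, train_idx)
  y_train <- samp$sr_ratio[train_idx]

  if (!is.null(tune_grid)) {
    tuned <- run_stage("tune", tune_srforest(d_train, y_train, tune_grid,
                                             n_trees = n_trees, seed = seed))
    mtry <- tuned$best$mtry; min_node_size <- tuned$best$min_node_size
  } else tuned <- NULL
  model <- run_stage("fit", srforest(d_train, y_train, n_trees = n_trees,
                                     mtry = mtry,
                                     min_node_size = min_node_size,
                                     seed = seed))
  cv <- run_stage("cross_validate",
                  cross_validate(d_train, y_train, n_folds = n_folds,
                                 repeats = cv_repeats, n_trees = n_trees,
                                 mtry = mtry, min_node_size = min_node_size,
                                 seed = seed))
  holdout <- NULL
  if (length(holdout_idx) > 0) {
    pred <- predict(model, subset_design(design, holdout_idx))
    yv <- samp$sr_ratio[holdout_idx]
    sst <- sum((yv - mean(yv))^2)
    holdout <- list(n = length(holdout_idx),
                    r2 = if (sst > 0) 1 - sum((yv - pred)^2) / sst
                         else NA_real_,
                    rmse = sqrt(mean((yv - pred)^2)))
  }
  iso <- run_stage("predict", predict_isoscape(model, stack, se = TRUE))
  mask <- run_stage("mask", strict_mask(stack, model))
  sim <- run_stage("similarity",
                   mop_similarity(stack, model$design,
                                  fraction = mop_fraction, mask = mask))
  # remove strict-extrapolation cells from the published surfaces
  mm <- mask$values != 0
  iso$mean$values[mm] <- NA_real_
  iso$se$values[mm] <- NA_real_

  diag <- run_stage("diagnostics", {
    rs <- residual_summary(model)
    coords <- cbind(samp$longitude, samp$latitude)[train_idx, , drop = FALSE]
    ok <- !is.na(rs$residuals)
    list(residuals = rs,
         correlogram = correlogram(rs$residuals[ok],
                                   coords[ok, , drop = FALSE],
                                   seed = seed),
         importance = importance_permutation(model, seed = seed))
  })

  run_info <- list(seed = seed, n_samples = n, n_train = length(train_idx),
                   n_holdout = length(holdout_idx), n_trees = n_trees,
                   mtry = mtry, min_node_size = min_node_size,
                   n_masked_cells = sum(mm),
                   oob_r2 = model$oob_r2, oob_rmse = model$oob_rmse)
  run_info$config_hash <- config_hash(run_info)

  out <- list(model = model, isoscape = iso, mask = mask, similarity = sim,
              screen = screen, tuning = tuned, cv = cv, holdout = holdout,
              diagnostics = diag, run_info = run_info)
  class(out) <- "sr_build"
  if (!is.null(out_dir)) write_build(out, out_dir)
  out
}

#' @export
print.sr_build <- function(x, ...) {
  cat("Isoscape build\n")
  print(x$model)
  print(x$cv)
  if (!is.null(x$holdout))
    cat(sprintf("  holdout (n=%d): R2 %.3f, RMSE %.5f\n", x$holdout$n,
                x$holdout$r2, x$holdout$rmse))
  cat(sprintf("  %d cells strict-masked\n", x$run_info$n_masked_cells))
  invisible(x)
}

write_build <- function(build, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(build$isoscape$mean, file.path(out_dir, "mean.asc"))
  write_ascii_grid(build$isoscape$se, file.path(out_dir, "se.asc"))
  write_ascii_grid(build$mask, file.path(out_dir, "mask.asc"),
                   kind = "categorical")
  write_ascii_grid(build$similarity, file.path(out_dir, "similarity.asc"))
  save_srforest(build$model, file.path(out_dir, "model.rds"))
  write_screen_report(build$screen, file.path(out_dir, "screen"))
  utils::write.csv(build$cv$folds, file.path(out_dir, "cv.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(residual = build$diagnostics$residuals$residuals),
                   file.path(out_dir, "residuals.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(build$diagnostics$correlogram),
                   file.path(out_dir, "correlogram.csv"), row.names = FALSE)
  utils::write.csv(build$diagnostics$importance,
                   file.path(out_dir, "importance.csv"), row.names = FALSE)
  jsonlite::write_json(build$run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read an isoscape (mean + SE) from a build directory
#'
#' @param dir directory holding `mean.asc` and `se.asc`.
#' @return list with `mean` and `se` [sr_grid()]s.
#' @export
read_isoscape <- function(dir) {
  list(mean = read_ascii_grid(file.path(dir, "mean.asc")),
       se = read_ascii_grid(file.path(dir, "se.asc")))
}

#' Read an individuals table
#'
#' Expected columns: `individual_id`, `sr87_sr86`, optional
#' `d18o_carb_vpdb`, `region_prior`, `sr_meas_sd`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path))
    stop("configuration error: individuals file not found: ", path,
         call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assign geographic origins for a table of individuals
#'
#' Per individual, a single-isotope (Sr) or dual-isotope (Sr + d18O)
#' continuous-surface assignment, depending on the data available. A
#' `region_prior` column naming an entry of `priors` restricts the support;
#' an unknown prior name fails that individual (recorded in the summary)
#' and the run continues.
#'
#' @param individuals data.frame (see [read_individuals()]) or CSV path.
#' @param sr_isoscape list with `mean`/`se` grids, an `sr_build`, or a
#'   build directory path.
#' @param o_isoscape optional list with `mean`/`se` grids of a
#'   precipitation d18O isoscape.
#' @param priors optional named list of region-prior [sr_grid()]s.
#' @param out_dir directory for per-individual rasters and the summary
#'   CSV, or `NULL`.
#' @param o_extra_sd additional d18O uncertainty (default 1 permil).
#' @param top_q credible-region mass for the reported region area
#'   (default 0.2).
#' @return data.frame summary (one row per individual: mode, argmax cell
#'   and coordinates, credible-region cell count, error message if any),
#'   with the per-individual `sr_assignment`s in attribute `"results"`.
#' @export
assign_origins <- function(individuals, sr_isoscape, o_isoscape = NULL,
                           priors = NULL, out_dir = NULL, o_extra_sd = 1,
                           top_q = 0.2) {
  if (is.character(individuals)) individuals <- read_individuals(individuals)
  if (is.character(sr_isoscape)) sr_isoscape <- read_isoscape(sr_isoscape)
  if (inherits(sr_isoscape, "sr_build")) sr_isoscape <- sr_isoscape$isoscape
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(individuals) == 0) {
    warning("no individuals to assign", call. = FALSE)
    return(data.frame())
  }
  rows <- list(); results <- list()
  for (i in seq_len(nrow(individuals))) {
    id <- as.character(individuals$individual_id[i])
    sr <- individuals$sr87_sr86[i]
    d18o <- if ("d18o_carb_vpdb" %in% names(individuals))
      individuals$d18o_carb_vpdb[i] else NA_real_
    sr_sd <- if ("sr_meas_sd" %in% names(individuals) &&
                 !is.na(individuals$sr_meas_sd[i]))
      individuals$sr_meas_sd[i] else 0
    prior_name <- if ("region_prior" %in% names(individuals))
      individuals$region_prior[i] else NA_character_
    if (is.null(o_isoscape)) d18o <- NA_real_  # Sr-only without an O isoscape
    res <- tryCatch({
      prior <- NULL
      if (!is.na(prior_name) && nzchar(prior_name)) {
        if (is.null(priors) || !prior_name %in% names(priors))
          stop("unknown region prior '", prior_name, "'", call. = FALSE)
        prior <- priors[[prior_name]]
      }
      assign_individual(sr_ratio = if (is.na(sr)) NULL else sr,
                        sr_isoscape = sr_isoscape,
                        d18o_carb_vpdb = if (is.na(d18o)) NULL else d18o,
                        o_isoscape = o_isoscape, prior = prior,
                        sr_extra_sd = sr_sd, o_extra_sd = o_extra_sd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(individual_id = id, mode = NA_character_,
                              argmax_row = NA_integer_,
                              argmax_col = NA_integer_,
                              argmax_lon = NA_real_, argmax_lat = NA_real_,
                              region_cells = NA_integer_,
                              error = conditionMessage(res))
      next
    }
    results[[id]] <- res
    mode <- paste(names(res$components), collapse = "+")
    p <- res$posterior$values
    am <- which(p == max(p), arr.ind = TRUE)[1, ]
    xy <- cell_centers(res$posterior$spec, am[1], am[2])
    region <- top_fraction_region(res, top_q)
    rows[[i]] <- data.frame(individual_id = id, mode = mode,
                            argmax_row = am[1], argmax_col = am[2],
                            argmax_lon = xy[1, "x"], argmax_lat = xy[1, "y"],
                            region_cells = sum(region$values),
                            error = NA_character_)
    if (!is.null(out_dir)) {
      write_ascii_grid(res$posterior,
                       file.path(out_dir, paste0("posterior_", id, ".asc")))
      write_ascii_grid(res$display,
                       file.path(out_dir, paste0("display_", id, ".asc")))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  attr(summary, "results") <- results
  summary
}
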