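# Shared fixtures. Everything is generated in code; the heavier fitted
# objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small projected grid for hand-constructed rasters.
local_spec <- function(nr = 5, nc = 5, cellsize = 1) {
  grid_spec(nr, nc, xll = 0, yll = 0, cellsize = cellsize, crs = "local")
}

# A small synthetic study: landscape, samples, design, fitted model.
small_study <- function() {
  cached("small_study", {
    cfg <- synthetic_config(n_rows = 50, n_cols = 50, n_samples = 180,
                            n_individuals = 30, seed = 11)
    land <- make_landscape(cfg)
    samp <- sample_sites(land)
    design <- extract_predictors(samp, land$stack)
    model <- srforest(design, samp$sr_ratio, n_trees = 150, seed = 11)
    list(config = cfg, land = land, samples = samp, design = design,
         model = model)
  })
}

# Write a samples CSV from a data.frame of raw column values.
write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independent brute-force infinitesimal-jackknife oracle: explicit loops
# over training samples and trees, population covariance.
ij_brute <- function(tpred, inbag, bias_correction = TRUE) {
  tpred <- as.matrix(tpred)
  B <- ncol(tpred)
  n <- ncol(inbag)
  out <- numeric(nrow(tpred))
  for (p in seq_len(nrow(tpred))) {
    t_b <- tpred[p, ]
    tbar <- mean(t_b)
    raw <- 0
    for (i in seq_len(n)) {
      N_i <- inbag[, i]
      cov_i <- mean(N_i * t_b) - mean(N_i) * tbar
      raw <- raw + cov_i^2
    }
    v <- raw
    if (bias_correction) v <- v - (n / B^2) * sum((t_b - tbar)^2)
    out[p] <- max(v, 0)
  }
  out
}

# A tiny two-cell Sr isoscape used by the worked assignment examples.
two_cell_isoscape <- function(mu = c(0.710, 0.730), sd = c(0.005, 0.005)) {
  spec <- grid_spec(1, 2, xll = 0, yll = 0, cellsize = 1, crs = "local")
  list(mean = sr_grid(matrix(mu, 1, 2), spec),
       se = sr_grid(matrix(sd, 1, 2), spec))
}
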