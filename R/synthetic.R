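#' Configuration of the synthetic landscape generator
#'
#' The generator emulates the statistical structure a bioavailable Sr
#' isoscape analysis assumes: a blocky "geology" (Voronoi terranes whose
#' age drives a spatially structured Sr mean field), smooth climate-like
#' covariates (dust, precipitation, elevation), a categorical lithology
#' layer, within-cell sampling noise, and tissue measurements drawn from
#' known origin cells.
#'
#' @param n_rows,n_cols grid size (default 200 x 200).
#' @param n_blocks number of Voronoi geology blocks (default 8).
#' @param smoothness Gaussian-blur length scale of the smooth covariates,
#'   in cells (default 12).
#' @param sr_block_range range the per-block Sr means span (default
#'   0.705-0.735; must stay inside the plausible bioavailable range
#'   0.703-0.88, which the truth surface is clipped to).
#' @param dust_effect,noise_effect coefficients of the dust term and the
#'   small-scale smooth noise in the truth surface, 87Sr/86Sr units per
#'   standardised-field unit (defaults 0.003 and 0.0015).
#' @param within_cell_sd within-cell sampling noise SD in 87Sr/86Sr units
#'   (default 0.002).
#' @param n_samples,n_individuals default sampling effort (800 sites, 100
#'   individuals).
#' @param seed root RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 200, n_cols = 200, n_blocks = 8,
                             smoothness = 12,
                             sr_block_range = c(0.705, 0.735),
                             dust_effect = 0.003, noise_effect = 0.0015,
                             within_cell_sd = 0.002, n_samples = 800,
                             n_individuals = 100, seed = 1) {
  stopifnot(within_cell_sd >= 0, n_blocks >= 1, dust_effect >= 0,
            noise_effect >= 0,
            sr_block_range[1] >= 0.703, sr_block_range[2] <= 0.88)
  structure(list(n_rows = n_rows, n_cols = n_cols, n_blocks = n_blocks,
                 smoothness = smoothness, sr_block_range = sr_block_range,
                 dust_effect = dust_effect, noise_effect = noise_effect,
                 within_cell_sd = within_cell_sd, n_samples = n_samples,
                 n_individuals = n_individuals, seed = seed),
            class = "synthetic_config")
}

# Smooth standardised Gaussian random field: white noise blurred with a
# separable Gaussian kernel (row-normalised, so edges are handled by
# renormalisation), then scaled to mean 0, sd 1.
gaussian_field <- function(n_rows, n_cols, scale) {
  blur_matrix <- function(n) {
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * scale^2))
    K / rowSums(K)
  }
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- blur_matrix(n_rows) %*% z %*% t(blur_matrix(n_cols))
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) return(f * 0)
  (f - mean(f)) / s
}

#' Generate a synthetic landscape with known Sr truth
#'
#' Layers: `terrane_age` (Voronoi blocks with per-block ages, Ma,
#' continuous), `dust`, `precipitation`, `elevation` (standardised smooth
#' fields), and `lithology` (categorical codes per block). The true Sr
#' surface is a monotone function of block age (per-block means spanning
#' `sr_block_range`) minus a dust term plus smooth small-scale noise,
#' clipped to the plausible bioavailable range [0.703, 0.88]. A smooth true
#' drinking-water d18O surface (permil VSMOW) is also generated for
#' dual-isotope simulations. Reproducible given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list of class `sr_landscape`: `stack` ([predictor_stack()]),
#'   `truth` ([sr_grid()] of true Sr means), `truth_o` ([sr_grid()] of true
#'   d18O water), `o_se` (flat d18O isoscape SE grid), `config`.
#' @export
make_landscape <- function(config = synthetic_config()) {
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols; k <- config$n_blocks
  spec <- grid_spec(nr, nc, xll = 10, yll = -10, cellsize = 0.05,
                    crs = "EPSG:4326")
  # Voronoi geology blocks in cell units
  ctr <- cbind(stats::runif(k, 1, nr), stats::runif(k, 1, nc))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2min <- matrix(Inf, nr, nc); block <- matrix(1L, nr, nc)
  for (b in seq_len(k)) {
    d2 <- (rows - ctr[b, 1])^2 + (cols - ctr[b, 2])^2
    upd <- d2 < d2min
    block[upd] <- b; d2min[upd] <- d2[upd]
  }
  ages_norm <- stats::runif(k)                       # 0 = young, 1 = Archaean
  lith_codes <- sample(1:5, k, replace = TRUE)
  dust <- gaussian_field(nr, nc, config$smoothness)
  precipitation <- gaussian_field(nr, nc, config$smoothness)
  elevation <- gaussian_field(nr, nc, config$smoothness)
  micro <- gaussian_field(nr, nc, max(2, config$smoothness / 4))
  lo <- config$sr_block_range[1]; hi <- config$sr_block_range[2]
  block_mean <- lo + (hi - lo) * ages_norm
  truth <- matrix(block_mean[block], nr, nc) -
    config$dust_effect * dust + config$noise_effect * micro
  truth <- pmin(pmax(truth, 0.703), 0.88)
  truth_o <- -4 + 2.5 * gaussian_field(nr, nc, config$smoothness)
  stack <- predictor_stack(
    list(terrane_age = sr_grid(matrix(ages_norm[block] * 3000, nr, nc), spec),
         dust = sr_grid(dust, spec),
         precipitation = sr_grid(precipitation, spec),
         elevation = sr_grid(elevation, spec),
         lithology = sr_grid(matrix(as.numeric(lith_codes[block]), nr, nc),
                             spec)),
    kinds = c("continuous", "continuous", "continuous", "continuous",
              "categorical"))
  structure(list(stack = stack, truth = sr_grid(truth, spec),
                 truth_o = sr_grid(truth_o, spec),
                 o_se = sr_grid(matrix(0.5, nr, nc), spec),
                 config = config),
            class = "sr_landscape")
}

#' Draw sample sites from a synthetic landscape
#'
#' `n` sites uniform over the grid cells, duplicates per cell allowed (the
#' analysis keeps co-located samples un-aggregated). Observed ratios are
#' the cell truth plus Normal within-cell noise.
#'
#' @param landscape an [make_landscape()] result.
#' @param n number of samples (default from the config).
#' @param within_cell_sd noise SD (default from the config).
#' @param seed RNG seed (default config seed + 1).
#' @return an `sr_samples` table (see [read_samples()]).
#' @export
sample_sites <- function(landscape, n = landscape$config$n_samples,
                         within_cell_sd = landscape$config$within_cell_sd,
                         seed = landscape$config$seed + 1) {
  spec <- landscape$truth$spec
  set.seed(seed)
  out <- if (n == 0) {
    data.frame(sample_id = character(), longitude = numeric(),
               latitude = numeric(), sr_ratio = numeric(),
               sample_type = character(), source = character(),
               reference = character(), stringsAsFactors = FALSE)
  } else {
    idx <- sample.int(spec$n_rows * spec$n_cols, n, replace = TRUE)
    rc <- index_rowcol(spec, idx)
    xy <- cell_centers(spec, rc[, "row"], rc[, "col"])
    truth <- landscape$truth$values[rc]
    data.frame(sample_id = sprintf("SYN%05d", seq_len(n)),
               longitude = xy[, "x"], latitude = xy[, "y"],
               sr_ratio = truth + stats::rnorm(n, 0, within_cell_sd),
               sample_type = sample(c("plant", "soil", "fauna"), n,
                                    replace = TRUE),
               source = sample(c("new", "published"), n, replace = TRUE,
                               prob = c(0.35, 0.65)),
               reference = "synthetic", stringsAsFactors = FALSE)
  }
  class(out) <- c("sr_samples", "data.frame")
  attr(out, "rejections") <- data.frame(row = integer(), reason = character())
  out
}

#' Simulate individuals with known origin cells
#'
#' Origin cells are drawn uniformly; tissue Sr is the origin-cell truth
#' plus Normal noise. With oxygen, a drinking-water d18O is drawn from the
#' true d18O surface and mapped back to enamel-carbonate VPDB by the exact
#' inverse of the three-stage conversion, so [carb_vpdb_to_water()]
#' recovers the simulated water value.
#'
#' @param landscape an [make_landscape()] result.
#' @param m number of individuals (default from the config).
#' @param seed RNG seed (default config seed + 2).
#' @param with_oxygen also simulate d18O (default `FALSE`).
#' @param tissue_sd tissue Sr noise SD (default the landscape's
#'   within-cell SD).
#' @param o_sd d18O water noise SD, permil (default 0.5).
#' @return data.frame of class `sr_individuals`: `individual_id`,
#'   `sr87_sr86`, `d18o_carb_vpdb` (NA without oxygen), `origin_row`,
#'   `origin_col`, `true_sr`, `true_d18o_w`.
#' @export
simulate_individuals <- function(landscape,
                                 m = landscape$config$n_individuals,
                                 seed = landscape$config$seed + 2,
                                 with_oxygen = FALSE,
                                 tissue_sd = landscape$config$within_cell_sd,
                                 o_sd = 0.5) {
  spec <- landscape$truth$spec
  set.seed(seed)
  idx <- sample.int(spec$n_rows * spec$n_cols, m, replace = TRUE)
  rc <- index_rowcol(spec, idx)
  true_sr <- landscape$truth$values[rc]
  sr <- true_sr + stats::rnorm(m, 0, tissue_sd)
  if (with_oxygen) {
    true_w <- landscape$truth_o$values[rc]
    w <- true_w + stats::rnorm(m, 0, o_sd)
    carb <- water_to_carb_vpdb(w)
  } else {
    true_w <- rep(NA_real_, m); carb <- rep(NA_real_, m)
  }
  out <- data.frame(individual_id = sprintf("IND%03d", seq_len(m)),
                    sr87_sr86 = sr, d18o_carb_vpdb = carb,
                    origin_row = rc[, "row"], origin_col = rc[, "col"],
                    true_sr = true_sr, true_d18o_w = true_w,
                    stringsAsFactors = FALSE)
  class(out) <- c("sr_individuals", "data.frame")
  out
}
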