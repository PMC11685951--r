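#' Convert enamel carbonate d18O (VPDB) to drinking-water d18O (VSMOW)
#'
#' Three-stage affine chain used for dual-isotope assignment:
#' carbonate VPDB -> carbonate VSMOW (`1.03091 x + 30.91`), carbonate
#' VSMOW -> phosphate VSMOW (`0.98 x - 8.5`), phosphate VSMOW -> drinking
#' water VSMOW (`1.54 x - 33.72`). All intermediates are returned. Inputs
#' outside [-20, +10] permil are implausible for tooth enamel and flagged.
#'
#' @param d18o_carb_vpdb numeric, permil on the VPDB scale.
#' @return data.frame with columns `d18o_carb_vpdb`, `d18o_carb_vsmow`,
#'   `d18o_p_vsmow`, `d18o_w_vsmow`, `implausible`.
#' @seealso [d18o_conversion_coefficients()] for the composite affine map,
#'   [water_to_carb_vpdb()] for the exact inverse.
#' @export
carb_vpdb_to_water <- function(d18o_carb_vpdb) {
  vsmow <- 1.03091 * d18o_carb_vpdb + 30.91
  p <- 0.98 * vsmow - 8.5
  w <- 1.54 * p - 33.72
  data.frame(d18o_carb_vpdb = d18o_carb_vpdb, d18o_carb_vsmow = vsmow,
             d18o_p_vsmow = p, d18o_w_vsmow = w,
             implausible = d18o_carb_vpdb < -20 | d18o_carb_vpdb > 10)
}

#' Composite coefficients of the three-stage d18O conversion
#'
#' The chain is affine, so it collapses to `w = slope * vpdb + intercept`.
#' @return named numeric vector with `slope` and `intercept`.
#' @export
d18o_conversion_coefficients <- function() {
  c(slope = 1.03091 * 0.98 * 1.54,
    intercept = (30.91 * 0.98 - 8.5) * 1.54 - 33.72)
}

#' Invert the carbonate-to-water d18O chain
#'
#' Exact affine inverse of [carb_vpdb_to_water()]; used by the synthetic
#' individual simulator so the forward conversion recovers the simulated
#' drinking-water value.
#'
#' @param d18o_w_vsmow numeric, permil VSMOW (drinking water).
#' @return numeric, permil VPDB (enamel carbonate).
#' @export
water_to_carb_vpdb <- function(d18o_w_vsmow) {
  p <- (d18o_w_vsmow + 33.72) / 1.54
  vsmow <- (p + 8.5) / 0.98
  (vsmow - 30.91) / 1.03091
}

#' Likelihood surface of a tissue isotope value over an isoscape
#'
#' Per valid cell `c`, the normal density of the measured value `y` with
#' mean `mu_c` and standard deviation `sqrt(sigma_c^2 + extra_sd^2)`.
#' Masked (`NA`) cells get likelihood 0.
#'
#' @param y measured isotope value.
#' @param mean_grid,se_grid aligned [sr_grid()]s of the isoscape mean and
#'   standard error.
#' @param extra_sd additional uncertainty combined in quadrature with the
#'   isoscape SE (default 0; e.g. 1 permil for converted d18O values).
#' @return an [sr_grid()] of likelihoods.
#' @export
likelihood_surface <- function(y, mean_grid, se_grid, extra_sd = 0) {
  if (!spec_equal(mean_grid$spec, se_grid$spec))
    stop("alignment error: mean and SE grids differ", call. = FALSE)
  if (extra_sd < 0) stop("extra_sd must be >= 0", call. = FALSE)
  mu <- mean_grid$values
  sd_tot <- sqrt(se_grid$values^2 + extra_sd^2)
  valid <- !is.na(mu) & !is.na(sd_tot)
  if (all(sd_tot[valid] == 0) && !any(mu[valid] == y))
    stop("degenerate likelihood: all cell SDs are zero and no cell mean ",
         "equals the measured value; supply extra_sd > 0", call. = FALSE)
  L <- matrix(0, nrow(mu), ncol(mu))
  pos <- valid & sd_tot > 0
  L[pos] <- stats::dnorm(y, mu[pos], sd_tot[pos])
  pt <- valid & sd_tot == 0
  L[pt] <- as.numeric(mu[pt] == y)
  sr_grid(L, mean_grid$spec)
}

#' Posterior origin surface from a likelihood surface
#'
#' `posterior_c` is proportional to `prior_c * L_c`, renormalised to sum to
#' 1 over the valid cells. The display surface divides each cell by the
#' maximum posterior (so its maximum is exactly 1), the convention used for
#' mapping relative probabilities of origin.
#'
#' @param likelihood an [sr_grid()] of likelihoods (e.g. from
#'   [likelihood_surface()]).
#' @param prior optional [sr_grid()] prior (a 0/1 region mask or any
#'   non-negative weights); `NULL` means uniform over valid cells.
#' @return object of class `sr_assignment`: list with `posterior`,
#'   `display` ([sr_grid()]s) and `components` (list of the input
#'   likelihood surfaces).
#' @export
posterior_surface <- function(likelihood, prior = NULL) {
  L <- likelihood$values
  if (!is.null(prior)) {
    if (!spec_equal(prior$spec, likelihood$spec))
      stop("alignment error: prior grid differs", call. = FALSE)
    p <- prior$values
    p[is.na(p)] <- 0
    if (any(p < 0)) stop("prior must be non-negative", call. = FALSE)
    L <- L * p
  }
  L[is.na(L)] <- 0
  total <- sum(L)
  if (total <= 0)
    stop("empty support: prior is zero everywhere the likelihood is positive",
         call. = FALSE)
  post <- L / total
  disp <- L / max(L)
  out <- list(posterior = sr_grid(post, likelihood$spec),
              display = sr_grid(disp, likelihood$spec),
              components = list(likelihood = likelihood))
  class(out) <- "sr_assignment"
  out
}

#' @export
print.sr_assignment <- function(x, ...) {
  p <- x$posterior$values
  top <- which(p == max(p), arr.ind = TRUE)[1, ]
  cat(sprintf("sr_assignment: posterior over %d cells, argmax at (row %d, col %d), max %.4g\n",
              sum(p > 0), top[1], top[2], max(p)))
  invisible(x)
}

#' Single- or dual-isotope geographic assignment of one individual
#'
#' Builds the per-isotope likelihood surfaces, multiplies them (raw
#' likelihoods, one final normalisation) and applies an optional region
#' prior. The d18O measurement is supplied on the enamel-carbonate VPDB
#' scale and converted to drinking water via [carb_vpdb_to_water()] before
#' comparison with a precipitation-water isoscape.
#'
#' @param sr_ratio tissue 87Sr/86Sr (or `NULL` for oxygen-only).
#' @param sr_isoscape list with `mean` and `se` [sr_grid()]s (an
#'   [predict_isoscape()] result works directly).
#' @param d18o_carb_vpdb optional enamel carbonate d18O, permil VPDB.
#' @param o_isoscape list with `mean` and `se` [sr_grid()]s of a
#'   precipitation-water d18O isoscape (required when `d18o_carb_vpdb` is
#'   given).
#' @param prior optional region-prior [sr_grid()].
#' @param sr_extra_sd additional 87Sr/86Sr uncertainty in quadrature
#'   (default 0).
#' @param o_extra_sd additional d18O uncertainty in quadrature (default 1
#'   permil, covering the conversion-equation errors).
#' @return an `sr_assignment`; `components` retains each isotope's
#'   likelihood surface.
#' @export
assign_individual <- function(sr_ratio = NULL, sr_isoscape = NULL,
                              d18o_carb_vpdb = NULL, o_isoscape = NULL,
                              prior = NULL, sr_extra_sd = 0, o_extra_sd = 1) {
  comps <- list()
  if (!is.null(sr_ratio)) {
    if (is.null(sr_isoscape)) stop("sr_isoscape required", call. = FALSE)
    comps$sr <- likelihood_surface(sr_ratio, sr_isoscape$mean,
                                   sr_isoscape$se, extra_sd = sr_extra_sd)
  }
  if (!is.null(d18o_carb_vpdb)) {
    if (is.null(o_isoscape))
      stop("o_isoscape required for dual-isotope assignment", call. = FALSE)
    w <- carb_vpdb_to_water(d18o_carb_vpdb)$d18o_w_vsmow
    comps$o <- likelihood_surface(w, o_isoscape$mean, o_isoscape$se,
                                  extra_sd = o_extra_sd)
  }
  if (length(comps) == 0)
    stop("at least one isotope measurement is required", call. = FALSE)
  joint <- comps[[1]]
  if (length(comps) > 1) {
    if (!spec_equal(comps[[1]]$spec, comps[[2]]$spec))
      stop("alignment error: isoscapes on different grids", call. = FALSE)
    v <- comps[[1]]$values * comps[[2]]$values
    v[is.na(v)] <- 0
    joint <- sr_grid(v, comps[[1]]$spec)
  }
  out <- posterior_surface(joint, prior = prior)
  out$components <- comps
  out
}

#' Top-ranked area region of a posterior surface
#'
#' The `area_fraction` share of valid cells with the highest posterior
#' (ties broken by row-major cell index). This is the region used by
#' area-based assignment quality assessment: rank cells by posterior and
#' keep the top fraction of the map, regardless of how much posterior mass
#' they hold.
#'
#' @param result an `sr_assignment` (or an [sr_grid()] posterior).
#' @param area_fraction fraction of valid (positive-support) cells to keep.
#' @return an [sr_grid()] with values 1 (inside) / 0.
#' @export
top_area_region <- function(result, area_fraction) {
  post <- if (inherits(result, "sr_assignment")) result$posterior else result
  p <- as.vector(t(post$values))
  p[is.na(p)] <- 0
  sel <- rep(FALSE, length(p))
  n_valid <- sum(p > 0)
  k <- ceiling(area_fraction * n_valid)
  if (k > 0) {
    ord <- order(-p, seq_along(p))
    keep <- ord[seq_len(min(k, n_valid))]
    sel[keep] <- TRUE
  }
  grid_from_vector(as.numeric(sel), post$spec)
}

#' Smallest credible region holding a given posterior mass
#'
#' Cells are added in decreasing posterior order (ties broken by row-major
#' cell index) until the accumulated mass reaches `q`.
#'
#' @param result an `sr_assignment` (or an [sr_grid()] posterior).
#' @param q target posterior mass in [0, 1].
#' @return an [sr_grid()] with values 1 (inside the region) / 0.
#' @export
top_fraction_region <- function(result, q) {
  post <- if (inherits(result, "sr_assignment")) result$posterior else result
  p <- as.vector(t(post$values))
  p[is.na(p)] <- 0
  sel <- rep(FALSE, length(p))
  if (q > 0) {
    ord <- order(-p, seq_along(p))
    cum <- cumsum(p[ord])
    k <- which(cum >= q - 1e-12)[1]
    if (is.na(k)) k <- sum(p > 0)
    keep <- ord[seq_len(k)]
    keep <- keep[p[keep] > 0]
    sel[keep] <- TRUE
  }
  grid_from_vector(as.numeric(sel), post$spec)
}
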