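#' Parameters of the depth-resolved orientation KDE
#'
#' @param bandwidth_depth Gaussian bandwidth along normalized depth
#'   (default 0.08).
#' @param bandwidth_angle Gaussian bandwidth along angle, degrees
#'   (default 6).
#' @param grid_depth number of depth grid points over [0, 1] (default 101).
#' @param grid_angle number of angle grid points over [-90, 90]
#'   (default 181; the two endpoints represent the same axial angle).
#' @return object of class `kde_params`.
#' @export
kde_params <- function(bandwidth_depth = 0.08, bandwidth_angle = 6,
                       grid_depth = 101, grid_angle = 181) {
  stopifnot(bandwidth_depth > 0, bandwidth_angle > 0,
            grid_depth >= 16, grid_angle >= 16)
  structure(list(bandwidth_depth = bandwidth_depth,
                 bandwidth_angle = bandwidth_angle,
                 grid_depth = as.integer(grid_depth),
                 grid_angle = as.integer(grid_angle)),
            class = "kde_params")
}

#' Depth-resolved orientation density (2D KDE with wrapped angles)
#'
#' Product-kernel Gaussian density estimate over (normalized depth, angle).
#' The depth dimension is linear on [0, 1]; each sample's depth kernel is
#' renormalized by its mass inside [0, 1] to correct edge loss. The angle
#' dimension is axial (180-degree periodic): samples are reduced to
#' (-90, 90] and their kernels summed over the replicas alpha + 180 k,
#' k in -2..2 (truncation error < 1e-12 for bandwidths up to 20 degrees).
#' The result is normalized to integrate to 1 over the domain.
#'
#' @param samples data frame with columns `z_n` and `alpha_deg` (as from
#'   [collect_samples()]); at least 2 rows.
#' @param params a [kde_params()] object.
#' @param weights optional non-negative sample weights (e.g. to weight each
#'   stack equally); defaults to uniform.
#' @return object of class `orientation_distribution`: list with `depth`
#'   (grid), `angle` (grid, -90..90 inclusive; the endpoints coincide
#'   axially), `density` (matrix grid_depth x grid_angle, probability per
#'   unit normalized depth per degree), `n`, `params`.
#' @export
kde2d_circular <- function(samples, params = kde_params(), weights = NULL) {
  n <- nrow(samples)
  if (n == 0) stop("no samples")
  if (n < 2) stop("need at least 2 samples")
  if (n < 50) warning("fewer than 50 samples: bandwidth choice unreliable")
  z <- pmin(pmax(samples$z_n, 0), 1)
  a <- wrap_axial(samples$alpha_deg)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  hz <- params$bandwidth_depth; ha <- params$bandwidth_angle
  zg <- seq(0, 1, length.out = params$grid_depth)
  ag <- seq(-90, 90, length.out = params$grid_angle)
  # depth kernels with per-sample edge renormalization over [0,1]
  edge <- stats::pnorm((1 - z) / hz) - stats::pnorm((0 - z) / hz)
  Kz <- outer(zg, z, function(g, s) stats::dnorm(g - s, sd = hz))
  Kz <- sweep(Kz, 2, edge, "/")
  # wrapped angle kernels
  Ka <- matrix(0, length(ag), n)
  for (k in -2:2)
    Ka <- Ka + outer(ag, a, function(g, s) stats::dnorm(g - s + 180 * k, sd = ha))
  dens <- (Kz * rep(w, each = length(zg))) %*% t(Ka)
  dens <- dens / kde_mass(zg, ag, dens)
  structure(list(depth = zg, angle = ag, density = dens, n = n,
                 params = params),
            class = "orientation_distribution")
}

# Trapezoidal integral of a density matrix over the (depth x angle) grid.
kde_mass <- function(zg, ag, dens) {
  wz <- trapezoid_weights(zg)
  wa <- trapezoid_weights(ag)
  as.numeric(wz %*% dens %*% wa)
}

trapezoid_weights <- function(g) {
  n <- length(g)
  h <- diff(g)
  w <- numeric(n)
  w[1] <- h[1] / 2; w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Octile curves of the conditional orientation distribution
#'
#' For each depth grid point, normalizes the conditional angle density and
#' computes the seven interior octiles (k/8 quantiles, k = 1..7). To respect
#' circularity, the conditional distribution is first centred at its
#' conditional axial circular mean; quantiles are computed on angles
#' unwrapped about that mean, so the curves remain continuous when the mean
#' orientation crosses +-90 degrees. Returned octiles are in the unwrapped
#' frame (mean - 90, mean + 90] and may therefore exceed +-90 where the
#' conditional mean is far from 0.
#'
#' @param dist an [kde2d_circular()] result.
#' @return list with `depth` (grid), `mean_deg` (conditional axial mean per
#'   depth), and `octiles` (matrix grid_depth x 7). Depths with ~zero
#'   conditional mass give NA rows.
#' @export
octile_curves <- function(dist) {
  zg <- dist$depth; ag <- dist$angle
  na <- length(ag) - 1L                 # drop the duplicate +90 endpoint
  aa <- ag[seq_len(na)]
  step <- ag[2] - ag[1]
  oct <- matrix(NA_real_, length(zg), 7)
  mu <- rep(NA_real_, length(zg))
  for (i in seq_along(zg)) {
    p <- dist$density[i, seq_len(na)]
    m <- sum(p) * step
    if (m < 1e-12) next
    # conditional axial circular mean from the gridded density
    d <- 2 * aa * pi / 180
    mu_i <- wrap_axial(0.5 * atan2(sum(p * sin(d)), sum(p * cos(d))) * 180 / pi)
    mu[i] <- mu_i
    # unwrap the periodic grid about the mean and sort
    u <- mu_i + wrap_axial(aa - mu_i)
    o <- order(u)
    u <- u[o]; pu <- p[o]
    # prepend the periodic left neighbour so the CDF spans the full period
    u <- c(u[1] - step, u)
    pu <- c(pu[length(pu)], pu)
    cdf <- cumsum((pu[-1] + pu[-length(pu)]) / 2 * diff(u))
    cdf <- c(0, cdf) / cdf[length(cdf)]
    oct[i, ] <- stats::approx(cdf, u, xout = (1:7) / 8, ties = "ordered")$y
  }
  list(depth = zg, mean_deg = mu, octiles = oct)
}

#' Per-stack dispersion percentiles at probe depths
#'
#' For each stack and each probe depth, computes the axial circular SD of
#' the angles whose normalized depth lies within `window_halfwidth` of the
#' probe depth; then summarises the per-stack SDs at each depth by their
#' 25th, 50th and 75th percentiles (linear interpolation between order
#' statistics, quantile type 7). Stacks with fewer than 2 samples in a
#' window are excluded from that row.
#'
#' @param samples data frame with `stack_id`, `z_n`, `alpha_deg`.
#' @param depths probe depths (default c(0.2, 0.4, 0.6, 0.8)).
#' @param window_halfwidth half-width of the depth window in normalized
#'   depth units (default 0.1).
#' @return data frame with one row per depth: `z_n`, `p25`, `p50`, `p75`,
#'   `iqr`, `n_stacks`.
#' @export
dispersion_table <- function(samples, depths = c(0.2, 0.4, 0.6, 0.8),
                             window_halfwidth = 0.1) {
  ids <- unique(samples$stack_id)
  if (length(ids) < 2) stop("need at least 2 stacks")
  rows <- lapply(depths, function(d) {
    sds <- vapply(ids, function(id) {
      a <- samples$alpha_deg[samples$stack_id == id &
                             abs(samples$z_n - d) <= window_halfwidth]
      if (length(a) < 2) NA_real_ else circular_sd(a)
    }, numeric(1))
    sds <- sds[is.finite(sds)]
    q <- if (length(sds)) stats::quantile(sds, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(z_n = d, p25 = q[1], p50 = q[2], p75 = q[3],
               iqr = q[3] - q[1], n_stacks = length(sds))
  })
  do.call(rbind, rows)
}

#' Per-stack circular SD profile
#'
#' Axial circular SD of one stack's angles in sliding depth windows;
#' convenience used by [summary.wall_orientation()] and recovery tests.
#'
#' @param samples data frame with `z_n`, `alpha_deg` (single stack or pooled).
#' @param depths probe depths.
#' @param window_halfwidth window half-width in normalized depth.
#' @return numeric vector of SDs (degrees), NA where fewer than 2 samples.
#' @export
circular_sd_profile <- function(samples, depths,
                                window_halfwidth = 0.1) {
  vapply(depths, function(d) {
    a <- samples$alpha_deg[abs(samples$z_n - d) <= window_halfwidth]
    if (length(a) < 2) NA_real_ else circular_sd(a)
  }, numeric(1))
}

#' Per-slice cell density profile
#'
#' Density (cells per 10^4 square micrometres) per slice: the number of
#' detected nuclei inside the slice's ROI divided by the ROI area. Counting
#' uses the clusters after area filtering but before the anisotropy filter —
#' density reflects all detected nuclei, whereas orientation uses the
#' stricter anisotropic subset. Slices with an invalid (zero-width) ROI are
#' omitted.
#'
#' @param counts data frame with `slice_index` and `count` (in-ROI detected
#'   nuclei per slice).
#' @param rois list of [effective_roi()] objects covering those slices.
#' @param lm_thickness_um muscle-layer thickness for normalized depth.
#' @return data frame: `slice_index`, `z_um`, `z_n`, `count`,
#'   `roi_area_um2`, `density_per_1e4um2`.
#' @export
cell_density_profile <- function(counts, rois, lm_thickness_um) {
  idx <- vapply(rois, function(r) r$slice_index, integer(1))
  rows <- lapply(rois, function(r) {
    if (!r$valid) return(NULL)
    cnt <- counts$count[match(r$slice_index, counts$slice_index)]
    if (is.na(cnt)) cnt <- 0
    data.frame(slice_index = r$slice_index, z_um = r$z_um,
               z_n = pmin(pmax(r$z_um / lm_thickness_um, 0), 1),
               count = cnt, roi_area_um2 = r$area_um2,
               density_per_1e4um2 = cnt / r$area_um2 * 1e4)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(slice_index = integer(0), z_um = numeric(0),
                      z_n = numeric(0), count = numeric(0),
                      roi_area_um2 = numeric(0),
                      density_per_1e4um2 = numeric(0)))
  do.call(rbind, rows)
}
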