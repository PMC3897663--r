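#' @export
print.wall_orientation <- function(x, ...) {
  cat("Depth-resolved wall orientation fit\n")
  cat(sprintf("  stacks: %d, orientation samples: %d\n",
              length(unique(x$samples$stack_id)), nrow(x$samples)))
  cat(sprintf("  pooled axial mean: %.1f deg, pooled circular SD: %.1f deg\n",
              axial_mean(x$samples$alpha_deg),
              circular_sd(x$samples$alpha_deg)))
  if (!is.null(x$dispersion)) {
    cat("  median per-stack circular SD by normalized depth:\n")
    cat(sprintf("    z_n = %.1f: %5.1f deg\n", x$dispersion$z_n,
                x$dispersion$p50), sep = "")
  }
  invisible(x)
}

#' Summarise a wall orientation fit
#'
#' Reports the pooled circular statistics, the per-depth circular SD profile,
#' the dispersion table across stacks and the range of cell densities.
#'
#' @param object a [fit_wall_orientation()] result.
#' @param ... unused.
#' @return object of class `summary.wall_orientation` (a list) with
#'   components `n_samples`, `n_stacks`, `pooled_mean_deg`, `pooled_sd_deg`,
#'   `sd_profile` (pooled circular SD at the probe depths), `dispersion`,
#'   `density_range` (cells per 10^4 um^2) and `counts` (filter-chain totals).
#' @export
summary.wall_orientation <- function(object, ...) {
  dens <- unlist(lapply(object$density, function(d) d$density_per_1e4um2))
  totals <- colSums(object$counts[, c("n_raw", "n_area", "n_roi", "n_aniso")])
  out <- list(n_samples = nrow(object$samples),
              n_stacks = length(unique(object$samples$stack_id)),
              pooled_mean_deg = axial_mean(object$samples$alpha_deg),
              pooled_sd_deg = circular_sd(object$samples$alpha_deg),
              sd_profile = stats::setNames(
                circular_sd_profile(object$samples, object$dispersion_depths,
                                    object$dispersion_window),
                sprintf("z_n=%.1f", object$dispersion_depths)),
              dispersion = object$dispersion,
              density_range = if (length(dens)) range(dens) else c(NA, NA),
              counts = totals)
  class(out) <- "summary.wall_orientation"
  out
}

#' @export
print.summary.wall_orientation <- function(x, ...) {
  cat("Wall orientation summary\n")
  cat(sprintf("  %d samples from %d stack(s)\n", x$n_samples, x$n_stacks))
  cat(sprintf("  pooled axial mean %.1f deg, circular SD %.1f deg\n",
              x$pooled_mean_deg, x$pooled_sd_deg))
  cat("  pooled circular SD profile (deg):\n")
  print(round(x$sd_profile, 1))
  if (!is.null(x$dispersion)) {
    cat("  per-stack SD percentiles (deg):\n")
    print(cbind(z_n = x$dispersion$z_n,
                round(x$dispersion[, c("p25", "p50", "p75")], 1)))
  }
  cat(sprintf("  cell density range: %.1f - %.1f cells per 1e4 um^2\n",
              x$density_range[1], x$density_range[2]))
  cat(sprintf("  filter chain: %d raw -> %d area -> %d ROI -> %d anisotropy\n",
              x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}

#' Evaluate the fitted orientation density
#'
#' Bilinear interpolation of the fitted (depth, angle) density surface.
#'
#' @param object a [fit_wall_orientation()] result.
#' @param newdata data frame with columns `z_n` (in [0, 1]) and `alpha_deg`.
#' @param ... unused.
#' @return numeric vector of density values (per unit normalized depth per
#'   degree).
#' @export
predict.wall_orientation <- function(object, newdata, ...) {
  zg <- object$kde$depth; ag <- object$kde$angle
  z <- pmin(pmax(newdata$z_n, 0), 1)
  a <- wrap_axial(newdata$alpha_deg)
  iz <- pmin(pmax(findInterval(z, zg), 1), length(zg) - 1)
  ia <- pmin(pmax(findInterval(a, ag), 1), length(ag) - 1)
  tz <- (z - zg[iz]) / (zg[iz + 1] - zg[iz])
  ta <- (a - ag[ia]) / (ag[ia + 1] - ag[ia])
  d <- object$kde$density
  d[cbind(iz, ia)] * (1 - tz) * (1 - ta) +
    d[cbind(iz + 1, ia)] * tz * (1 - ta) +
    d[cbind(iz, ia + 1)] * (1 - tz) * ta +
    d[cbind(iz + 1, ia + 1)] * tz * ta
}

#' Plot a wall orientation fit
#'
#' Draws the pooled (normalized depth x angle) density as an image with the
#' seven octile curves overlaid, and optionally the cell-density profile.
#'
#' @param x a [fit_wall_orientation()] result.
#' @param which `"kde"`, `"density"`, or `"both"` (default).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.wall_orientation <- function(x, which = c("both", "kde", "density"),
                                  ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "kde")) {
    graphics::image(x$kde$depth, x$kde$angle, x$kde$density,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "normalized depth", ylab = "angle (deg)",
                    main = "orientation density", ...)
    oc <- x$octiles$octiles
    for (k in 1:7)
      graphics::lines(x$octiles$depth, wrap_axial(oc[, k]), col = "white",
                      lwd = if (k == 4) 2 else 1)
  }
  if (which %in% c("both", "density")) {
    graphics::plot(NA, xlim = c(0, 1),
                   ylim = c(0, max(1, unlist(lapply(x$density, function(d)
                     d$density_per_1e4um2)))),
                   xlab = "normalized depth",
                   ylab = "cells per 1e4 um^2", main = "cell density")
    for (d in x$density)
      graphics::lines(d$z_n, d$density_per_1e4um2,
                      col = grDevices::grey(0.4, 0.5))
  }
  invisible(x)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic wall stack spec\n")
  cat(sprintf("  geometry: R = %g um, wall = %g um, field %d x %d px @ %g um, %d slices (dz = %g um)\n",
              x$outer_radius_um, x$wall_thickness_um,
              x$field_size_px[1], x$field_size_px[2], x$pixel_size_um,
              x$n_slices, x$slice_spacing_um))
  cat(sprintf("  nuclei: %g x %g x %g um, target %g cells/1e4 um^2, %.0f%% round\n",
              x$nucleus_long_axis_um, x$nucleus_short_axis_um,
              x$nucleus_depth_axis_um, x$target_density_cells_per_1e4um2,
              100 * x$round_nucleus_fraction))
  invisible(x)
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "ROI slice %d (z = %g um): w_c = %.2f, w_f = %.2f, w = %.2f um, area = %.0f um^2%s\n",
    x$slice_index, x$z_um, x$crosstalk_halfwidth_um, x$filling_halfwidth_um,
    x$effective_halfwidth_um, x$area_um2, if (x$valid) "" else " (invalid)"))
  invisible(x)
}
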