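#' Specification of a synthetic nucleus-stained wall stack
#'
#' Describes a cylindrical muscle wall imaged as flat optical sections:
#' elongated nucleus-like bright blobs whose in-plane orientation follows a
#' depth-dependent axial circular distribution, a fraction of round nuclei
#' (emulating foreshortened / urothelial cells that the anisotropy filter
#' must reject), small bright clutter ("dye particles") below the nucleus
#' area bounds, and photon/detector noise.
#'
#' Nucleus "axis" lengths are full extents: the default solid-ellipsoid
#' rendering uses semi-axes of axis/2, and the alternative Gaussian profile
#' uses standard deviation axis/4 so its +-2 sigma support spans the stated
#' axis. Overlapping bodies occlude rather than add (intensities combine by
#' maximum), and placement rejects any candidate whose center falls inside
#' an already placed nucleus. `target_density_cells_per_1e4um2` is the
#' expected per-slice detected areal density under the slice-wise counting
#' convention (a nucleus is counted once in every slice in which it is
#' segmented); `detection_span_um` is the depth extent over which a rendered
#' nucleus passes the default segmentation, and converts that target into a
#' volumetric placement rate.
#'
#' @param outer_radius_um outer radius of the tube (default 150).
#' @param wall_thickness_um muscle-layer thickness (default 55, near the
#'   median measured in rat ureter).
#' @param pixel_size_um lateral pixel size (default 0.5).
#' @param slice_spacing_um depth spacing between slices (default
#'   `pixel_size_um`).
#' @param field_size_px (ny, nx) image size in pixels (default 256 x 256).
#' @param n_slices number of slices (default covers the wall thickness).
#' @param nucleus_long_axis_um,nucleus_short_axis_um,nucleus_depth_axis_um
#'   nucleus extents in micrometres (defaults 12, 3, 3).
#' @param target_density_cells_per_1e4um2 target per-slice detected density
#'   (default 20).
#' @param detection_span_um depth extent over which a nucleus is segmented
#'   (default 2.0; calibrated once by simulation for the default rendering
#'   and segmentation parameters and then frozen).
#' @param orientation_field function mapping normalized depth (vector in
#'   [0, 1]) to `list(mu_deg, sigma_deg)`: the axial mean orientation and
#'   axial circular SD at that depth.
#' @param round_nucleus_fraction fraction of nuclei rendered round
#'   (default 0.1).
#' @param round_nucleus_diameter_um in-plane diameter of round nuclei
#'   (default 6, large enough to pass the area filter so rejection must come
#'   from the anisotropy criterion).
#' @param clutter_count_per_slice expected bright specks per slice
#'   (default 10).
#' @param clutter_area_um2 in-plane area of a speck (default 1.5, below the
#'   nucleus area lower bound).
#' @param nucleus_peak_intensity,background_level intensity units
#'   (defaults 500 and 100).
#' @param noise_model `list(gain, read_sd)` for Poisson shot noise on
#'   gain * signal plus additive Gaussian read noise, or `NULL` for a
#'   noiseless stack. Defaults give nucleus SNR of roughly 10.
#' @param hard_ellipsoid logical; render nuclei as uniform solid ellipsoids
#'   (default TRUE), or as anisotropic Gaussian intensity profiles when
#'   FALSE. Solid bodies keep a nucleus detectable over most of its
#'   physical depth extent, as real stained nuclei are.
#' @param seed integer RNG seed stored with the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(outer_radius_um = 150, wall_thickness_um = 55,
                           pixel_size_um = 0.5,
                           slice_spacing_um = pixel_size_um,
                           field_size_px = c(256, 256),
                           n_slices = floor(wall_thickness_um / slice_spacing_um) + 1,
                           nucleus_long_axis_um = 12,
                           nucleus_short_axis_um = 3,
                           nucleus_depth_axis_um = 3,
                           target_density_cells_per_1e4um2 = 20,
                           detection_span_um = 2.0,
                           orientation_field = function(z_n)
                             list(mu_deg = rep(0, length(z_n)),
                                  sigma_deg = rep(25, length(z_n))),
                           round_nucleus_fraction = 0.1,
                           round_nucleus_diameter_um = 6,
                           clutter_count_per_slice = 10,
                           clutter_area_um2 = 1.5,
                           nucleus_peak_intensity = 500,
                           background_level = 100,
                           noise_model = list(gain = 1, read_sd = 50),
                           hard_ellipsoid = TRUE,
                           seed = 1L) {
  stopifnot(wall_thickness_um > 0, wall_thickness_um < outer_radius_um,
            pixel_size_um > 0, slice_spacing_um > 0,
            length(field_size_px) == 2, all(field_size_px >= 8),
            n_slices >= 1,
            nucleus_long_axis_um > 0, nucleus_short_axis_um > 0,
            nucleus_depth_axis_um > 0,
            target_density_cells_per_1e4um2 >= 0, detection_span_um > 0,
            is.function(orientation_field),
            round_nucleus_fraction >= 0, round_nucleus_fraction <= 1,
            clutter_count_per_slice >= 0, clutter_area_um2 > 0,
            nucleus_peak_intensity > 0, background_level >= 0)
  structure(list(outer_radius_um = outer_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um,
                 field_size_px = as.integer(field_size_px),
                 n_slices = as.integer(n_slices),
                 nucleus_long_axis_um = nucleus_long_axis_um,
                 nucleus_short_axis_um = nucleus_short_axis_um,
                 nucleus_depth_axis_um = nucleus_depth_axis_um,
                 target_density_cells_per_1e4um2 = target_density_cells_per_1e4um2,
                 detection_span_um = detection_span_um,
                 orientation_field = orientation_field,
                 round_nucleus_fraction = round_nucleus_fraction,
                 round_nucleus_diameter_um = round_nucleus_diameter_um,
                 clutter_count_per_slice = clutter_count_per_slice,
                 clutter_area_um2 = clutter_area_um2,
                 nucleus_peak_intensity = nucleus_peak_intensity,
                 background_level = background_level,
                 noise_model = noise_model,
                 hard_ellipsoid = hard_ellipsoid,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Acquisition geometry implied by a synthetic spec
#' @param spec a [synthetic_spec()].
#' @return an [acquisition_geometry()] object.
#' @export
geometry_from_spec <- function(spec) {
  acquisition_geometry(spec$outer_radius_um, spec$wall_thickness_um,
                       spec$pixel_size_um, spec$slice_spacing_um,
                       spec$field_size_px, spec$n_slices)
}

#' Preset synthetic scenarios
#'
#' Named study conditions used throughout the package's validation:
#' \describe{
#'   \item{ureter_like}{longitudinal mean orientation (mu = 0) at every
#'     depth, with axial circular SD rising linearly from 25 degrees at the
#'     adventitial side to 32 degrees at the proprial side — the gradual
#'     dispersion pattern of the rat ureter muscle layer.}
#'   \item{intestine_like}{two-layer wall: longitudinal (mu = 0) for
#'     normalized depth < 0.5, circumferential (mu = 90) deeper, with
#'     sigma = 15 degrees in both layers.}
#'   \item{uniform_null}{axially uniform orientations (sigma = Inf), the
#'     no-structure null.}
#' }
#'
#' @param ... overrides passed on to [synthetic_spec()] (e.g.
#'   `field_size_px`, `seed`).
#' @return named list of `synthetic_spec` objects.
#' @export
preset_scenarios <- function(...) {
  list(
    ureter_like = synthetic_spec(
      orientation_field = function(z_n)
        list(mu_deg = rep(0, length(z_n)), sigma_deg = 25 + 7 * z_n), ...),
    intestine_like = synthetic_spec(
      orientation_field = function(z_n)
        list(mu_deg = ifelse(z_n < 0.5, 0, 90),
             sigma_deg = rep(15, length(z_n))), ...),
    uniform_null = synthetic_spec(
      orientation_field = function(z_n)
        list(mu_deg = rep(0, length(z_n)),
             sigma_deg = rep(Inf, length(z_n))), ...))
}

# Cross-sectional (y, z) area of the placeable shell region within the
# imaged box, by fine-grid quadrature; used to convert the volumetric
# placement rate into an expected nucleus count.
shell_cross_section_area <- function(spec, z_max, step = 0.25) {
  R <- spec$outer_radius_um; t <- spec$wall_thickness_um
  Ly <- spec$field_size_px[1] * spec$pixel_size_um
  y <- seq(-Ly / 2 + step / 2, Ly / 2, by = step)
  z <- seq(step / 2, z_max, by = step)
  r <- sqrt(outer((R - z)^2, y^2, "+"))
  sum(r >= R - t & r <= R) * step^2
}

#' Generate a synthetic image stack with ground truth
#'
#' Renders the scene described by a [synthetic_spec()]: nucleus centers and
#' orientations are placed in the cylindrical shell by rejection sampling —
#' orientations drawn from the spec's depth-dependent axial distribution,
#' and a candidate rejected when its center lies inside an already placed
#' nucleus's ellipsoid or vice versa (solid bodies may touch but not
#' interpenetrate; bounded at 10^4 attempts per nucleus). Nuclei are
#' rendered as solid ellipsoids (or anisotropic Gaussian profiles),
#' composited by maximum; clutter specks are added, and Poisson + Gaussian
#' noise is applied last. The same spec and seed give a bit-identical
#' stack.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional override of `spec$seed`.
#' @return list with `stack` (an `image_stack`: numeric array ny x nx x
#'   n_slices plus geometry) and `truth` (data frame, one row per rendered
#'   nucleus: `x_um`, `y_um` (lateral offset from the apex line), `z_um`
#'   (depth below the apex plane), `wall_depth_um`, `z_n`, `angle_deg` (NA
#'   for round nuclei), `sigma_deg`, `is_round`; the spec is attached as
#'   attribute `spec`).
#' @export
generate_stack <- function(spec, seed = NULL) {
  g <- geometry_from_spec(spec)
  ny <- g$field_size_px[1]; nx <- g$field_size_px[2]
  pix <- g$pixel_size_um
  Lx <- nx * pix; Ly <- ny * pix
  if (spec$nucleus_long_axis_um >= min(Lx, Ly))
    stop("nucleus axes larger than the field")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(if (is.null(seed)) spec$seed else seed)

  R <- spec$outer_radius_um; tw <- spec$wall_thickness_um
  z_max <- (g$n_slices - 1) * g$slice_spacing_um + spec$nucleus_depth_axis_um / 2
  rho_v <- spec$target_density_cells_per_1e4um2 / 1e4 / spec$detection_span_um
  vol <- shell_cross_section_area(spec, z_max) * Lx
  n_target <- stats::rpois(1, rho_v * vol)

  # nuclei are solid bodies: a candidate is rejected when its center lies
  # inside an already-placed nucleus's ellipsoid (or vice versa), which
  # permits near-contact without unphysical interpenetration
  al <- spec$nucleus_long_axis_um / 2
  as_ <- spec$nucleus_short_axis_um / 2
  ad <- spec$nucleus_depth_axis_um / 2
  ar <- spec$round_nucleus_diameter_um / 2
  centers <- matrix(NA_real_, n_target, 3)
  angle <- sig_used <- rep(NA_real_, n_target)
  is_round <- logical(n_target)
  cosv <- sinv <- sa <- sb <- numeric(n_target)
  n <- 0L
  for (j in seq_len(n_target)) {
    placed <- FALSE
    for (att in seq_len(1e4)) {
      x <- stats::runif(1, 0, Lx)
      y <- stats::runif(1, -Ly / 2, Ly / 2)
      z <- stats::runif(1, 0, z_max)
      wd <- R - sqrt((R - z)^2 + y^2)
      if (wd < 0 || wd > tw) next
      round_j <- stats::runif(1) < spec$round_nucleus_fraction
      fld <- spec$orientation_field(min(max(wd / tw, 0), 1))
      ang <- if (round_j) 0 else
        sample_axial_angle(1, fld$mu_deg[1], fld$sigma_deg[1])
      aj <- if (round_j) ar else al
      bj <- if (round_j) ar else as_
      if (n > 0L) {
        dx <- centers[1:n, 1] - x
        dy <- centers[1:n, 2] - y
        dz2 <- ((centers[1:n, 3] - z) / ad)^2
        # candidate center inside an existing nucleus
        u <- dx * cosv[1:n] + dy * sinv[1:n]
        v <- -dx * sinv[1:n] + dy * cosv[1:n]
        if (any((u / sa[1:n])^2 + (v / sb[1:n])^2 + dz2 < 1)) next
        # existing center inside the candidate
        cj <- cos(ang * pi / 180); sj <- sin(ang * pi / 180)
        u2 <- dx * cj + dy * sj
        v2 <- -dx * sj + dy * cj
        if (any((u2 / aj)^2 + (v2 / bj)^2 + dz2 < 1)) next
      }
      n <- n + 1L
      centers[n, ] <- c(x, y, z)
      is_round[n] <- round_j
      angle[n] <- if (round_j) NA_real_ else ang
      sig_used[n] <- fld$sigma_deg[1]
      cosv[n] <- cos(ang * pi / 180); sinv[n] <- sin(ang * pi / 180)
      sa[n] <- aj; sb[n] <- bj
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "nucleus placement failed: achieved density %.1f of target %.1f cells per 1e4 um2",
        n / vol * spec$detection_span_um * 1e4,
        spec$target_density_cells_per_1e4um2))
  }
  centers <- centers[seq_len(n), , drop = FALSE]
  is_round <- is_round[seq_len(n)]
  angle <- angle[seq_len(n)]
  sig_used <- sig_used[seq_len(n)]
  wall_depth <- R - sqrt((R - centers[, 3])^2 + centers[, 2]^2)
  z_n <- pmin(pmax(wall_depth / tw, 0), 1)

  sig <- array(0, dim = c(ny, nx, g$n_slices))
  for (j in seq_len(n)) {
    ax <- if (is_round[j])
      rep(spec$round_nucleus_diameter_um, 2) else
      c(spec$nucleus_long_axis_um, spec$nucleus_short_axis_um)
    p <- render_blob(dim(sig), g, centers[j, ], ifelse(is_round[j], 0, angle[j]),
                     sigma_long = ax[1] / 4, sigma_short = ax[2] / 4,
                     sigma_depth = spec$nucleus_depth_axis_um / 4,
                     peak = spec$nucleus_peak_intensity,
                     hard = spec$hard_ellipsoid)
    if (!is.null(p))   # solid bodies occlude, they do not sum
      sig[p$rows, p$cols, p$slices] <-
        pmax(sig[p$rows, p$cols, p$slices, drop = FALSE], p$vals)
  }
  n_clutter <- stats::rpois(1, spec$clutter_count_per_slice * g$n_slices)
  sc <- sqrt(spec$clutter_area_um2 / pi) / 2
  for (j in seq_len(n_clutter)) {
    ctr <- c(stats::runif(1, 0, Lx), stats::runif(1, -Ly / 2, Ly / 2),
             stats::runif(1, 0, (g$n_slices - 1) * g$slice_spacing_um))
    p <- render_blob(dim(sig), g, ctr, 0, sc, sc, sc,
                     peak = spec$nucleus_peak_intensity, hard = FALSE)
    if (!is.null(p))
      sig[p$rows, p$cols, p$slices] <-
        pmax(sig[p$rows, p$cols, p$slices, drop = FALSE], p$vals)
  }

  img <- sig + spec$background_level
  if (!is.null(spec$noise_model)) {
    gain <- spec$noise_model$gain
    img <- stats::rpois(length(img), gain * img) / gain +
      stats::rnorm(length(img), 0, spec$noise_model$read_sd)
    img <- array(pmax(img, 0), dim = dim(sig))
  }

  truth <- data.frame(x_um = centers[, 1], y_um = centers[, 2],
                      z_um = centers[, 3], wall_depth_um = wall_depth,
                      z_n = z_n, angle_deg = angle,
                      sigma_deg = sig_used, is_round = is_round)
  attr(truth, "spec") <- spec
  list(stack = image_stack(img, g), truth = truth)
}

# Render one anisotropic blob as a local intensity patch. Coordinates:
# voxel (r, c, s) sits at x = (c - 0.5) pix, y = (r - 0.5) pix - Ly/2,
# z = (s - 1) dz. Returns NULL when the blob misses the volume, otherwise
# list(rows, cols, slices, vals) for the caller to add in place.
render_blob <- function(dims, g, center, angle_deg, sigma_long, sigma_short,
                        sigma_depth, peak, hard = FALSE) {
  pix <- g$pixel_size_um
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  Ly <- ny * pix
  th <- angle_deg * pi / 180
  cut <- if (hard) 2 else 3
  hx <- cut * (sigma_long * abs(cos(th)) + sigma_short * abs(sin(th))) + pix
  hy <- cut * (sigma_long * abs(sin(th)) + sigma_short * abs(cos(th))) + pix
  cs <- max(1L, ceiling((center[1] - hx) / pix))
  ce <- min(nx, floor((center[1] + hx) / pix + 0.5))
  rs <- max(1L, ceiling((center[2] + Ly / 2 - hy) / pix))
  re <- min(ny, floor((center[2] + Ly / 2 + hy) / pix + 0.5))
  ss <- max(1L, ceiling(1 + (center[3] - cut * sigma_depth) / g$slice_spacing_um))
  se <- min(nz, floor(1 + (center[3] + cut * sigma_depth) / g$slice_spacing_um))
  if (cs > ce || rs > re || ss > se) return(NULL)
  xs <- (cs:ce - 0.5) * pix - center[1]
  ys <- (rs:re - 0.5) * pix - Ly / 2 - center[2]
  du <- outer(ys * sin(th), xs * cos(th), "+")   # along the long axis
  dv <- outer(ys * cos(th), -xs * sin(th), "+")  # along the short axis
  dz <- (ss:se - 1) * g$slice_spacing_um - center[3]
  vals <- array(0, dim = c(re - rs + 1L, ce - cs + 1L, se - ss + 1L))
  for (k in seq_along(dz)) {
    if (hard) {
      vals[, , k] <- peak * ((du / (2 * sigma_long))^2 +
        (dv / (2 * sigma_short))^2 + (dz[k] / (2 * sigma_depth))^2 <= 1)
    } else {
      vals[, , k] <- peak * exp(-(du^2 / (2 * sigma_long^2) +
        dv^2 / (2 * sigma_short^2) + dz[k]^2 / (2 * sigma_depth^2)))
    }
  }
  list(rows = rs:re, cols = cs:ce, slices = ss:se, vals = vals)
}
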