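#' Acquisition geometry of an image stack
#'
#' Describes how a stack of flat optical sections samples the curved wall of
#' a cylindrical organ. Slice 0 is the shallowest (adventitial-most) plane,
#' tangent to the outer surface apex; nominal depth of slice i is
#' `i * slice_spacing_um` below that apex. The longitudinal axis of the tube
#' runs along the image x-direction (matrix columns).
#'
#' @param outer_radius_um measured outer radius R of the tube (micrometres).
#' @param wall_thickness_um muscle-layer thickness t (micrometres), 0 < t < R.
#' @param pixel_size_um lateral pixel size (micrometres per pixel).
#' @param slice_spacing_um spacing between consecutive slices (micrometres).
#' @param field_size_px integer vector (ny, nx): image rows (lateral) and
#'   columns (longitudinal).
#' @param n_slices number of slices in the stack.
#' @return an object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(outer_radius_um, wall_thickness_um,
                                 pixel_size_um, slice_spacing_um,
                                 field_size_px, n_slices) {
  stopifnot(wall_thickness_um > 0, wall_thickness_um < outer_radius_um,
            pixel_size_um > 0, slice_spacing_um > 0,
            length(field_size_px) == 2, all(field_size_px >= 1),
            n_slices >= 1)
  structure(list(outer_radius_um = outer_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um,
                 field_size_px = as.integer(field_size_px),
                 n_slices = as.integer(n_slices)),
            class = "acquisition_geometry")
}

#' Crosstalk-limiting ROI half-width
#'
#' A flat plane at nominal depth `z` below the apex of a cylinder of radius
#' `R` cuts through tissue at shallower wall depths as it moves laterally off
#' the apex line: the wall depth of an in-plane point at lateral offset y is
#' `z_wall(y) = R - sqrt((R - z)^2 + y^2)`. The crosstalk half-width is the
#' lateral offset at which the wall depth has decreased by `delta_max`:
#' `w_c = sqrt((R - z + delta_max)^2 - (R - z)^2)`. Restricting analysis to
#' |y| <= w_c bounds depth crosstalk by `delta_max`. The half-width shrinks
#' with imaging depth and with decreasing radius.
#'
#' @param z nominal depth(s) below the outer-surface apex (micrometres),
#'   0 <= z <= R.
#' @param R outer radius (micrometres).
#' @param delta_max maximum tolerated wall-depth error (micrometres).
#' @return half-width(s) in micrometres (unclamped; the caller limits to the
#'   field half-width).
#' @export
crosstalk_halfwidth <- function(z, R, delta_max) {
  stopifnot(delta_max > 0)
  if (any(z < 0 | z > R)) stop("z must lie in [0, R]")
  sqrt((R - z + delta_max)^2 - (R - z)^2)
}

#' Tissue-filling ROI half-width
#'
#' The lateral offset at which the flat plane at depth `z` exits the outer
#' surface of the cylinder: `w_f = sqrt(z (2R - z))`. For |y| < w_f the plane
#' lies inside the tissue, so a band limited to this half-width is guaranteed
#' to be completely filled with muscle layer (for z not exceeding the wall
#' thickness), which makes per-area cell densities meaningful. It is 0 at
#' z = 0 (tangent plane) and grows with depth.
#'
#' @inheritParams crosstalk_halfwidth
#' @return half-width(s) in micrometres.
#' @export
filling_halfwidth <- function(z, R) {
  if (any(z < 0 | z > R)) stop("z must lie in [0, R]")
  sqrt(z * (2 * R - z))
}

#' Effective per-slice region of interest
#'
#' Combines the crosstalk and filling constraints with the physical field
#' half-width: `w = min(w_c, w_f, field half-width)`. The ROI is the band
#' |y| <= w around the apex line, running parallel to the longitudinal axis.
#' Slice 0 (z = 0, tangent plane) has w_f = 0 and is marked invalid.
#'
#' @param geometry an [acquisition_geometry()] object.
#' @param slice_index 0-based slice index.
#' @param delta_max crosstalk depth tolerance in micrometres (default 2).
#' @param apex_offset_px lateral offset of the apex line from the field
#'   centre, in pixels (default 0; mounting may decenter the vessel).
#' @return an object of class `roi_spec`: slice_index, z_um,
#'   crosstalk/filling/effective half-widths (micrometres), apex position
#'   (micrometres from image top edge), area_um2 and a validity flag.
#' @export
effective_roi <- function(geometry, slice_index, delta_max = 2,
                          apex_offset_px = 0) {
  stopifnot(slice_index >= 0, slice_index < geometry$n_slices)
  z <- slice_index * geometry$slice_spacing_um
  R <- geometry$outer_radius_um
  ny <- geometry$field_size_px[1]; nx <- geometry$field_size_px[2]
  half_field <- ny / 2 * geometry$pixel_size_um
  w_c <- crosstalk_halfwidth(z, R, delta_max)
  w_f <- filling_halfwidth(z, R)
  w <- min(w_c, w_f, half_field)
  len_x <- nx * geometry$pixel_size_um
  structure(list(slice_index = as.integer(slice_index), z_um = z,
                 crosstalk_halfwidth_um = w_c, filling_halfwidth_um = w_f,
                 effective_halfwidth_um = w,
                 apex_y_um = half_field + apex_offset_px * geometry$pixel_size_um,
                 length_x_um = len_x,
                 area_um2 = 2 * w * len_x,
                 valid = w > 0),
            class = "roi_spec")
}

#' Restrict clusters to the region of interest
#'
#' Retains clusters whose centroid lies within the ROI band (closed
#' boundary: a centroid at lateral offset exactly w is retained) and flags
#' membership in an `in_roi` column.
#'
#' @param clusters `nucleus_clusters` data frame for one slice.
#' @param roi an [effective_roi()] result for the same slice.
#' @return the retained clusters with `in_roi = TRUE`.
#' @export
apply_roi <- function(clusters, roi) {
  if (nrow(clusters) > 0 &&
      any(clusters$slice_index != roi$slice_index, na.rm = TRUE))
    stop("clusters do not belong to the ROI's slice")
  off <- abs(clusters$centroid_y_um - roi$apex_y_um)
  keep <- roi$valid & off <= roi$effective_halfwidth_um
  out <- clusters[keep, , drop = FALSE]
  if (nrow(out)) out$in_roi <- TRUE
  class(out) <- c("nucleus_clusters", "data.frame")
  out
}
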