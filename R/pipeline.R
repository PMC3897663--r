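#' Image stack container
#'
#' A 3D grayscale intensity volume plus its acquisition geometry. Slices are
#' ordered from the adventitial (outer) to the proprial (inner) side.
#'
#' @param data numeric array ny x nx x n_slices.
#' @param geometry an [acquisition_geometry()] matching the array.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, geometry) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(dim(data) == c(geometry$field_size_px, geometry$n_slices)))
    stop("array dimensions do not match geometry")
  structure(list(data = data, geometry = geometry), class = "image_stack")
}

#' Read a multi-page TIFF stack
#'
#' Pages are taken in file order as adventitial to proprial slices.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param geometry an [acquisition_geometry()]; its field size and slice
#'   count must match the file.
#' @param scale intensity multiplier applied to the [0, 1] values returned
#'   by the TIFF reader (default 65535, undoing 16-bit normalization).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, geometry, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (!is.matrix(pages[[i]]))
      stop(sprintf("page %d is not grayscale", i))
    if (!all(dim(pages[[i]]) == dim(pages[[1]])))
      stop(sprintf("page %d has a different size", i))
  }
  if (length(pages) != geometry$n_slices ||
      !all(dim(pages[[1]]) == geometry$field_size_px))
    stop("TIFF dimensions do not match the supplied geometry")
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(arr * scale, geometry)
}

#' Write a stack as multi-page 16-bit TIFF (plus optional JSON sidecar)
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param truth optional ground-truth data frame (from [generate_stack()]);
#'   written with the geometry to `<path>.json`.
#' @param scale intensity divisor mapping the data into [0, 1]
#'   (default 65535).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL, scale = 65535) {
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(s) pmin(pmax(stack$data[, , s] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (!is.null(truth)) {
    side <- list(geometry = unclass(stack$geometry),
                 ground_truth = truth[, setdiff(names(truth), "spec")])
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Process one stack: segmentation, ROI, orientation
#'
#' Runs the slice-wise stages on a stack: cellness filtering, thresholding,
#' clustering, area filtering, ROI restriction, moment tensors and the
#' anisotropy filter. Returns the per-cluster orientation samples, the
#' per-slice cell-density inputs and the filter-chain counts.
#'
#' @param stack an [image_stack()].
#' @param params a [cellness_params()].
#' @param delta_max ROI crosstalk tolerance in micrometres (default 2).
#' @param apex_offset_px lateral apex offset in pixels (default 0).
#' @param min_ratio anisotropy (eigenvalue-ratio) threshold (default 1.5).
#' @param lm_thickness_um muscle-layer thickness used for normalized depth;
#'   defaults to the geometry's wall thickness.
#' @param stack_id identifier carried into the samples (default "stack1").
#' @return list with `samples` (orientation samples data frame), `density`
#'   (per-slice [cell_density_profile()]), `counts` (per-slice filter-chain
#'   counts: raw, area-filtered, in-ROI, anisotropy-passed), `rois`,
#'   `clusters` (the retained, tensor-annotated clusters) and `clusters_all`
#'   (in-ROI clusters before the anisotropy filter, tensor-annotated).
#' @export
process_stack <- function(stack, params = cellness_params(), delta_max = 2,
                          apex_offset_px = 0, min_ratio = 1.5,
                          lm_thickness_um = NULL, stack_id = "stack1") {
  g <- stack$geometry
  if (is.null(lm_thickness_um)) lm_thickness_um <- g$wall_thickness_um
  if (lm_thickness_um <= 0) stop("lm_thickness_um must be > 0")
  n_slices <- g$n_slices
  rois <- vector("list", n_slices)
  kept <- vector("list", n_slices)
  kept_all <- vector("list", n_slices)
  counts <- data.frame(slice_index = seq_len(n_slices) - 1L,
                       n_raw = 0L, n_area = 0L, n_roi = 0L, n_aniso = 0L,
                       count = 0L)
  for (s in seq_len(n_slices)) {
    roi <- effective_roi(g, s - 1L, delta_max, apex_offset_px)
    rois[[s]] <- roi
    cmap <- cellness_filter(stack$data[, , s], params, g$pixel_size_um)
    thr <- if (isTRUE(params$otsu)) otsu_threshold(cmap) else params$threshold
    cl <- extract_clusters(binarize(cmap, thr), g$pixel_size_um,
                           params$connectivity, slice_index = s - 1L)
    counts$n_raw[s] <- nrow(cl)
    cl <- filter_by_area(cl, params$area_min_um2, params$area_max_um2)
    counts$n_area[s] <- nrow(cl)
    cl <- apply_roi(cl, roi)
    counts$n_roi[s] <- nrow(cl)
    counts$count[s] <- nrow(cl)   # density counts: post-area, in-ROI
    cl <- compute_tensors(cl, g$pixel_size_um)
    kept_all[[s]] <- cl
    ok <- !is.na(cl$lambda1) & anisotropy_ok(cl$lambda1, cl$lambda2, min_ratio) &
      !is.na(cl$angle_deg)
    cl <- cl[ok, , drop = FALSE]
    class(cl) <- c("nucleus_clusters", "data.frame")
    counts$n_aniso[s] <- nrow(cl)
    kept[[s]] <- cl
  }
  clusters <- do.call(rbind, kept)
  class(clusters) <- c("nucleus_clusters", "data.frame")
  clusters_all <- do.call(rbind, kept_all)
  class(clusters_all) <- c("nucleus_clusters", "data.frame")
  samples <- collect_samples(stats::setNames(list(clusters), stack_id),
                             stats::setNames(list(g), stack_id),
                             stats::setNames(list(lm_thickness_um), stack_id))
  density <- cell_density_profile(counts, rois, lm_thickness_um)
  list(samples = samples, density = density, counts = counts,
       rois = rois, clusters = clusters, clusters_all = clusters_all)
}

#' Fit the depth-resolved wall orientation model to one or more stacks
#'
#' The package's main entry point. Each stack is segmented slice by slice
#' (cellness filtering, thresholding, clustering, area filter), restricted
#' to the cylindrical-wall ROI, and each retained nucleus contributes an
#' orientation sample (angle vs normalized depth) after the anisotropy
#' filter. Samples are pooled across stacks (each stack weighted equally)
#' into a wrapped 2D kernel density estimate with octile curves, per-depth
#' circular SD profiles, a per-stack dispersion table and per-slice cell
#' density profiles.
#'
#' @param stacks an [image_stack()] or a (optionally named) list of them.
#' @param lm_thickness_um muscle-layer thickness(es) in micrometres, recycled
#'   across stacks; default: each stack's geometry wall thickness.
#' @param cellness a [cellness_params()].
#' @param kde a [kde_params()].
#' @param delta_max,apex_offset_px,min_ratio see [process_stack()].
#' @param dispersion_depths probe depths of the dispersion table.
#' @param dispersion_window window half-width for circular SDs.
#' @param equal_stack_weight logical; when TRUE (default) each stack
#'   contributes equal mass to the pooled KDE, otherwise raw samples pool
#'   with equal weight.
#' @return object of class `wall_orientation` with components `samples`,
#'   `kde`, `octiles`, `dispersion`, `density` (per stack), `counts`
#'   (filter-chain report per stack), `call`, plus the parameter objects.
#' @seealso [summary.wall_orientation()], [plot.wall_orientation()],
#'   [predict.wall_orientation()]
#' @export
fit_wall_orientation <- function(stacks, lm_thickness_um = NULL,
                                 cellness = cellness_params(),
                                 kde = kde_params(),
                                 delta_max = 2, apex_offset_px = 0,
                                 min_ratio = 1.5,
                                 dispersion_depths = c(0.2, 0.4, 0.6, 0.8),
                                 dispersion_window = 0.1,
                                 equal_stack_weight = TRUE) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (is.null(names(stacks)) || any(names(stacks) == ""))
    names(stacks) <- sprintf("stack%02d", seq_along(stacks))
  if (is.null(lm_thickness_um))
    lm_thickness_um <- vapply(stacks, function(s) s$geometry$wall_thickness_um,
                              numeric(1))
  lm_thickness_um <- rep_len(lm_thickness_um, length(stacks))
  runs <- lapply(seq_along(stacks), function(i)
    process_stack(stacks[[i]], params = cellness, delta_max = delta_max,
                  apex_offset_px = apex_offset_px, min_ratio = min_ratio,
                  lm_thickness_um = lm_thickness_um[i],
                  stack_id = names(stacks)[i]))
  names(runs) <- names(stacks)
  samples <- do.call(rbind, c(lapply(runs, `[[`, "samples"),
                              list(make.row.names = FALSE)))
  counts <- do.call(rbind, c(lapply(names(runs), function(id)
    cbind(stack_id = id, runs[[id]]$counts)), list(make.row.names = FALSE)))
  if (nrow(samples) < 2) stop("fewer than 2 orientation samples survived")
  weights <- if (equal_stack_weight) {
    tab <- table(samples$stack_id)
    1 / (length(tab) * as.numeric(tab[samples$stack_id]))
  } else NULL
  kde_fit <- kde2d_circular(samples, kde, weights)
  disp <- if (length(stacks) >= 2)
    dispersion_table(samples, dispersion_depths, dispersion_window) else NULL
  structure(list(samples = samples,
                 kde = kde_fit,
                 octiles = octile_curves(kde_fit),
                 dispersion = disp,
                 density = lapply(runs, `[[`, "density"),
                 counts = counts,
                 lm_thickness_um = stats::setNames(lm_thickness_um, names(stacks)),
                 cellness = cellness, kde_params = kde,
                 delta_max = delta_max, min_ratio = min_ratio,
                 dispersion_depths = dispersion_depths,
                 dispersion_window = dispersion_window,
                 call = match.call()),
            class = "wall_orientation")
}
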