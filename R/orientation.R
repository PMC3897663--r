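#' Second-moment (structure) tensor of a cluster
#'
#' The 2x2 second central moment matrix of the cluster's pixel coordinates in
#' micrometres, with uniform weight per pixel (population covariance). Axes:
#' x = longitudinal (image columns), y = lateral (image rows). The principal
#' eigenvector of this tensor gives the cluster's long-axis orientation.
#'
#' @param pixels integer matrix of (row, col) pixel coordinates, >= 2 pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @return 2x2 symmetric matrix with rows/cols (x, y), in square
#'   micrometres, with attribute `eigenvalues` = c(lambda1, lambda2),
#'   lambda1 >= lambda2 >= 0.
#' @export
moment_tensor <- function(pixels, pixel_size_um) {
  if (nrow(pixels) < 2) stop("cluster must have at least 2 pixels")
  x <- pixels[, 2] * pixel_size_um
  y <- pixels[, 1] * pixel_size_um
  cxx <- mean((x - mean(x))^2)
  cyy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  M <- matrix(c(cxx, cxy, cxy, cyy), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  attr(M, "eigenvalues") <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                                 decreasing = TRUE)
  M
}

#' Anisotropy filter for round nuclei
#'
#' A cluster passes when the ratio of its tensor eigenvalues lambda1/lambda2
#' exceeds `min_ratio` (default 1.5), excluding round-shaped nuclei whose
#' orientation is ill-defined (e.g. foreshortened transversely oriented
#' nuclei, urothelial cells). A degenerate lambda2 = 0 with lambda1 > 0
#' (a perfect line) passes.
#'
#' @param lambda1,lambda2 tensor eigenvalues, lambda1 >= lambda2 >= 0.
#' @param min_ratio eigenvalue-ratio threshold (default 1.5).
#' @return logical.
#' @export
anisotropy_ok <- function(lambda1, lambda2, min_ratio = 1.5) {
  ifelse(lambda2 == 0, lambda1 > 0, lambda1 / lambda2 > min_ratio)
}

#' Principal orientation angle of a cluster
#'
#' The angle alpha between the tensor's principal eigenvector and the
#' longitudinal (x) axis, reduced to the axial interval (-90, 90]. Positive
#' angles rotate from +x towards +y (increasing image row). Since the
#' eigenvector is defined up to sign, alpha is an orientation, not a
#' direction.
#'
#' @param tensor a [moment_tensor()] result.
#' @return angle in degrees in (-90, 90].
#' @export
principal_angle <- function(tensor) {
  ev <- attr(tensor, "eigenvalues")
  if (is.null(ev)) ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values,
                              decreasing = TRUE)
  if (ev[1] == ev[2]) stop("isotropic tensor: angle undefined")
  v <- eigen(tensor, symmetric = TRUE)$vectors[, 1]
  wrap_axial(atan2(v[2], v[1]) * 180 / pi)
}

# Closed-form half-angle solution for the 2x2 symmetric eigenproblem,
# used as an independent oracle for principal_angle in tests.
principal_angle_closed_form <- function(cxx, cyy, cxy) {
  wrap_axial(0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi)
}

#' Attach moment tensors, eigenvalues and angles to clusters
#'
#' Fills the tensor-derived columns of a `nucleus_clusters` data frame:
#' `lambda1`, `lambda2`, `ratio` (lambda1/lambda2, `Inf` for degenerate
#' clusters), and `angle_deg` (NA where the tensor is isotropic or the
#' cluster has a single pixel).
#'
#' @param clusters `nucleus_clusters` data frame.
#' @param pixel_size_um pixel size in micrometres.
#' @return the data frame with tensor columns added.
#' @export
compute_tensors <- function(clusters, pixel_size_um) {
  n <- nrow(clusters)
  l1 <- l2 <- ang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    px <- clusters$pixels[[i]]
    if (nrow(px) < 2) next
    M <- moment_tensor(px, pixel_size_um)
    ev <- attr(M, "eigenvalues")
    l1[i] <- ev[1]; l2[i] <- max(ev[2], 0)
    if (ev[1] > ev[2]) ang[i] <- principal_angle(M)
  }
  clusters$lambda1 <- l1
  clusters$lambda2 <- l2
  clusters$ratio <- ifelse(l2 == 0, ifelse(l1 > 0, Inf, NA_real_), l1 / l2)
  clusters$angle_deg <- ang
  clusters
}

#' Collect orientation samples across processed stacks
#'
#' Turns the surviving clusters of each stack (after area, ROI and
#' anisotropy filtering) into the unit records of the analysis: one sample
#' per cluster with depth, normalized depth and angle. Normalized depth is
#' the nominal slice depth divided by the stack's muscle-layer thickness,
#' clipped to [0, 1], so stacks with different wall thicknesses are
#' comparable.
#'
#' @param clusters_by_stack named list: stack id -> `nucleus_clusters` data
#'   frame with tensor columns (all filters applied).
#' @param geometry_by_stack named list of [acquisition_geometry()] objects.
#' @param lm_thickness_by_stack named numeric vector of muscle-layer
#'   thicknesses (micrometres), all > 0.
#' @return data frame with columns stack_id, slice_index, z_um, z_n,
#'   alpha_deg, ratio, area_um2.
#' @export
collect_samples <- function(clusters_by_stack, geometry_by_stack,
                            lm_thickness_by_stack) {
  if (any(unlist(lm_thickness_by_stack) <= 0))
    stop("lm_thickness must be > 0")
  out <- lapply(names(clusters_by_stack), function(id) {
    cl <- clusters_by_stack[[id]]
    if (nrow(cl) == 0) return(NULL)
    g <- geometry_by_stack[[id]]
    z <- cl$slice_index * g$slice_spacing_um
    data.frame(stack_id = id, slice_index = cl$slice_index, z_um = z,
               z_n = pmin(pmax(z / lm_thickness_by_stack[[id]], 0), 1),
               alpha_deg = cl$angle_deg, ratio = cl$ratio,
               area_um2 = cl$area_um2, row.names = NULL)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(stack_id = character(0), slice_index = integer(0),
                      z_um = numeric(0), z_n = numeric(0),
                      alpha_deg = numeric(0), ratio = numeric(0),
                      area_um2 = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
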