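#' Cellness filter parameters
#'
#' Parameters of the slice-wise nucleus enhancement and segmentation step.
#' The filter is the 2D bright-structure vesselness response of Frangi
#' applied at a single Gaussian-derivative scale matched to the nucleus
#' width, hence "cellness".
#'
#' @param sigma_kernel_um scale of the Gaussian derivative kernel in
#'   micrometres. A ridge of Gaussian cross-section sigma_r responds
#'   maximally (under gamma = 2 scale normalisation) at sqrt(2) * sigma_r;
#'   for nuclei about 3 um wide this gives the default of 1.0.
#' @param beta blobness weight of the vesselness response (unitless).
#'   Default 0.5, the conventional choice.
#' @param c structure/noise weight in intensity units. `NA` (default) sets it
#'   adaptively per slice to half the maximum Hessian norm, since a sensible
#'   value depends on the image intensity scale.
#' @param threshold cutoff on the per-slice max-normalised cellness map,
#'   in (0, 1). Default 0.35: high enough that out-of-focus halos do not
#'   bridge adjacent nuclei and that round (blobness-suppressed) nuclei
#'   stay below the cut. Use `otsu = TRUE` to derive it per slice instead.
#' @param otsu logical; when TRUE the threshold is computed per slice by
#'   Otsu's method on the cellness map (non-default alternative).
#' @param connectivity pixel connectivity for clustering, 4 or 8. Default 8
#'   so thin diagonal nucleus fragments do not split.
#' @param area_min_um2,area_max_um2 retained cluster area bounds in square
#'   micrometres. Defaults 8 and 120 bracket the elliptical cross-section
#'   estimate pi/4 * short * long for typical smooth-muscle nucleus axes.
#' @return an object of class `cellness_params` (a validated list).
#' @export
cellness_params <- function(sigma_kernel_um = 1.0, beta = 0.5, c = NA,
                            threshold = 0.35, otsu = FALSE, connectivity = 8,
                            area_min_um2 = 8, area_max_um2 = 120) {
  stopifnot(sigma_kernel_um > 0, beta > 0, is.na(c) || c > 0,
            threshold > 0, threshold < 1,
            connectivity %in% c(4, 8),
            area_min_um2 > 0, area_min_um2 < area_max_um2)
  structure(list(sigma_kernel_um = sigma_kernel_um, beta = beta, c = c,
                 threshold = threshold, otsu = otsu,
                 connectivity = as.integer(connectivity),
                 area_min_um2 = area_min_um2, area_max_um2 = area_max_um2),
            class = "cellness_params")
}

# 1D Gaussian and Gaussian-derivative kernels sampled at integer offsets.
# The smoothing kernel is normalised to unit sum; derivative kernels share
# its normalisation constant so that derivatives of a constant are exactly 0
# after the analytic forms cancel.
gaussian_kernels <- function(sigma_px) {
  m <- max(2L, ceiling(4 * sigma_px))
  x <- -m:m
  g <- exp(-x^2 / (2 * sigma_px^2))
  z <- sum(g)
  g2 <- (x^2 / sigma_px^4 - 1 / sigma_px^2) * g / z
  list(g0 = g / z,
       g1 = (-x / sigma_px^2) * g / z,   # odd: zero-sum by symmetry
       g2 = g2 - mean(g2),               # enforce exact zero DC response
       radius = m)
}

# Dense band matrix applying a 1D kernel along one axis with replicate
# (clamped-index) boundary handling; conv1d along rows is M %*% img.
conv_matrix <- function(n, kernel) {
  m <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (d in -m:m) {
    j <- pmin(pmax(i + d, 1L), n)
    idx <- cbind(i, j)
    M[idx] <- M[idx] + kernel[d + m + 1L]
  }
  M
}

# Scale-normalised Hessian of a slice via separable Gaussian derivatives
# (FFT correlation, replicate boundary). Rows of the slice run along the
# lateral (y) axis, columns along the longitudinal (x) axis. Returns
# gamma-normalised (sigma^2-scaled) Ixx, Iyy, Ixy. Equivalent to the
# explicit band-matrix construction in conv_matrix(), which the tests use
# as an independent oracle.
hessian2d <- function(slice, sigma_px) {
  k <- gaussian_kernels(sigma_px)
  s2 <- sigma_px^2
  f2 <- function(kernel_y, kernel_x)
    EBImage::filter2(slice, outer(kernel_y, kernel_x), boundary = "replicate")
  list(xx = s2 * f2(k$g0, k$g2),
       yy = s2 * f2(k$g2, k$g0),
       xy = s2 * f2(k$g1, k$g1))
}

#' Enhance elongated bright structures in a slice ("cellness" filtering)
#'
#' Computes the Hessian of the image at a single Gaussian-derivative scale
#' (with gamma normalisation), orders its eigenvalues by magnitude
#' |h1| <= |h2| per pixel, and evaluates the 2D Frangi response for bright
#' structures: 0 where h2 > 0, otherwise
#' `exp(-(h1/h2)^2 / (2 beta^2)) * (1 - exp(-(h1^2 + h2^2) / (2 c^2)))`.
#' The map is scaled to [0, 1] by its maximum (an all-zero response stays
#' all zero). Elongated bright nuclei produce ridge-like responses;
#' background and dark structures are suppressed.
#'
#' @param slice 2D numeric matrix; rows are the lateral (y) axis, columns the
#'   longitudinal (x) axis. All pixels must be finite.
#' @param params a [cellness_params()] object.
#' @param pixel_size_um pixel size in micrometres.
#' @return matrix of the same size with values in [0, 1].
#' @export
cellness_filter <- function(slice, params = cellness_params(),
                            pixel_size_um) {
  if (!is.matrix(slice) || length(slice) == 0) stop("slice must be a non-empty matrix")
  if (!all(is.finite(slice))) stop("slice contains non-finite pixels")
  H <- hessian2d(slice, params$sigma_kernel_um / pixel_size_um)
  # closed-form 2x2 symmetric eigenvalues, ordered |h1| <= |h2|
  half_tr <- (H$xx + H$yy) / 2
  disc <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
  e1 <- half_tr + disc
  e2 <- half_tr - disc
  big <- abs(e1) >= abs(e2)
  h2 <- ifelse(big, e1, e2)
  h1 <- ifelse(big, e2, e1)
  S2 <- h1^2 + h2^2
  # floor away float-level residuals (a constant image has zero Hessian)
  S2[S2 < (1e-9 * max(1, max(abs(slice))))^2] <- 0
  cpar <- params$c
  if (is.na(cpar)) cpar <- 0.5 * sqrt(max(S2))
  if (cpar == 0) return(matrix(0, nrow(slice), ncol(slice)))
  rb2 <- ifelse(h2 == 0, 0, (h1 / h2)^2)
  v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-S2 / (2 * cpar^2)))
  v[h2 > 0] <- 0
  mx <- max(v)
  if (mx > 0) v <- v / mx
  v
}

#' Threshold a cellness map into a binary nucleus mask
#'
#' @param cellness_map matrix in [0, 1] from [cellness_filter()].
#' @param threshold cutoff in (0, 1); pixels with cellness >= threshold are
#'   foreground.
#' @return logical matrix of the same size.
#' @export
binarize <- function(cellness_map, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  cellness_map >= threshold
}

# Merge 4-connected labels that touch diagonally, giving 8-connectivity.
merge_diagonal_labels <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  if (ny < 2 || nx < 2) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-ny, -nx]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-ny, -1]), as.vector(lab[-1, -nx])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0] <- relab[out[out > 0]]
  out
}

#' Extract connected clusters (candidate nuclei) from a binary mask
#'
#' Labels connected foreground components and summarises each as a candidate
#' nucleus cluster: pixel coordinates, area and centroid. Moment-tensor
#' fields (eigenvalues, angle) are filled in later by [compute_tensors()].
#'
#' @param mask logical matrix (a [binarize()] result).
#' @param pixel_size_um pixel size in micrometres.
#' @param connectivity 4 or 8.
#' @param slice_index integer slice index attached to each cluster.
#' @return a data frame of class `nucleus_clusters` with one row per cluster:
#'   `id`, `slice_index`, `n_px`, `area_um2`, `centroid_row`, `centroid_col`
#'   (pixel units), `centroid_x_um`, `centroid_y_um`, and a list column
#'   `pixels` of (row, col) integer matrices. Empty masks give zero rows.
#' @export
extract_clusters <- function(mask, pixel_size_um, connectivity = 8,
                             slice_index = NA_integer_) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0) return(empty_clusters())
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  labs <- lab[idx]
  o <- order(labs)
  rows <- rows[o]; cols <- cols[o]; labs <- labs[o]
  px <- lapply(split(seq_along(labs), labs),
               function(i) cbind(row = rows[i], col = cols[i]))
  n_px <- vapply(px, nrow, integer(1))
  crow <- vapply(px, function(p) mean(p[, 1]), numeric(1))
  ccol <- vapply(px, function(p) mean(p[, 2]), numeric(1))
  out <- data.frame(id = seq_along(px), slice_index = slice_index,
                    n_px = n_px, area_um2 = n_px * pixel_size_um^2,
                    centroid_row = crow, centroid_col = ccol,
                    centroid_x_um = (ccol - 0.5) * pixel_size_um,
                    centroid_y_um = (crow - 0.5) * pixel_size_um,
                    row.names = NULL)
  out$pixels <- unname(px)
  class(out) <- c("nucleus_clusters", "data.frame")
  out
}

empty_clusters <- function() {
  out <- data.frame(id = integer(0), slice_index = integer(0),
                    n_px = integer(0), area_um2 = numeric(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  out$pixels <- list()
  class(out) <- c("nucleus_clusters", "data.frame")
  out
}

#' Filter clusters by area
#'
#' Removes clusters that are too small (dye particles, debris) or too large
#' (adjacent cells erroneously merged into one cluster). Bounds are
#' inclusive.
#'
#' @param clusters a `nucleus_clusters` data frame.
#' @param area_min_um2,area_max_um2 inclusive area bounds in square
#'   micrometres.
#' @return the retained subset, same class.
#' @export
filter_by_area <- function(clusters, area_min_um2, area_max_um2) {
  stopifnot(area_min_um2 >= 0, area_min_um2 < area_max_um2)
  keep <- clusters$area_um2 >= area_min_um2 & clusters$area_um2 <= area_max_um2
  out <- clusters[keep, , drop = FALSE]
  class(out) <- c("nucleus_clusters", "data.frame")
  out
}

# Otsu threshold on a cellness map (optional alternative to the fixed cut).
otsu_threshold <- function(map, nbins = 256) {
  h <- tabulate(pmin(pmax(ceiling(map * nbins), 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) / nbins
}
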