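# Shared fixtures built in code.

# A slice with anisotropic Gaussian blobs at given centers/angles, built
# independently of the package's renderer (direct evaluation of the
# bivariate Gaussian), plus optional small specks.
make_blob_slice <- function(ny, nx, pixel_size, centers_px, angles_deg,
                            sigma_long_um = 3, sigma_short_um = 0.75,
                            peak = 1, speck_centers_px = NULL,
                            speck_sigma_um = 0.3) {
  xs <- matrix(rep(seq_len(nx), each = ny), ny) * pixel_size
  ys <- matrix(rep(seq_len(ny), nx), ny) * pixel_size
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centers_px))) {
    th <- angles_deg[i] * pi / 180
    dx <- xs - centers_px[i, 2] * pixel_size
    dy <- ys - centers_px[i, 1] * pixel_size
    du <- dx * cos(th) + dy * sin(th)
    dv <- -dx * sin(th) + dy * cos(th)
    img <- img + peak * exp(-du^2 / (2 * sigma_long_um^2) -
                              dv^2 / (2 * sigma_short_um^2))
  }
  if (!is.null(speck_centers_px)) {
    for (i in seq_len(nrow(speck_centers_px))) {
      dx <- xs - speck_centers_px[i, 2] * pixel_size
      dy <- ys - speck_centers_px[i, 1] * pixel_size
      img <- img + peak * exp(-(dx^2 + dy^2) / (2 * speck_sigma_um^2))
    }
  }
  img
}

# Segment a slice with the default chain and return tensor-annotated clusters.
segment_slice <- function(slice, pixel_size, params = cellness_params()) {
  cmap <- cellness_filter(slice, params, pixel_size)
  cl <- extract_clusters(binarize(cmap, params$threshold), pixel_size,
                         params$connectivity, slice_index = 0L)
  compute_tensors(cl, pixel_size)
}

# Random connected-ish pixel cluster (an integer-lattice ellipse with random
# orientation and axes), for tensor oracle checks.
random_cluster <- function(rng_n = 1) {
  repeat {
    a <- runif(1, 3, 12); b <- runif(1, 1, a)
    th <- runif(1, -pi / 2, pi / 2)
    m <- ceiling(a) + 1
    xs <- rep(-m:m, each = 2 * m + 1); ys <- rep(-m:m, 2 * m + 1)
    du <- xs * cos(th) + ys * sin(th)
    dv <- -xs * sin(th) + ys * cos(th)
    keep <- (du / a)^2 + (dv / b)^2 <= 1
    px <- cbind(row = ys[keep] + m + 1, col = xs[keep] + m + 1)
    if (nrow(px) < 3) next
    M <- moment_tensor(px, 0.5)
    ev <- attr(M, "eigenvalues")
    if (ev[1] - ev[2] > 1e-6) return(px)
  }
}

# Simulated multi-stack scenario runs are expensive; build them once per
# test session on demand.
.fixture_env <- new.env(parent = emptyenv())

# Validation problem size: 0.5 um pixels, 1 um slice spacing over a 55 um
# wall, and a long field along the tube axis so each depth window holds
# enough nuclei that per-stack circular-SD estimates are stable. Stacks are
# generated and processed one at a time and only the light-weight results
# (samples, counts, densities, slim clusters, ground truth) are retained.
ureter_bundle <- function(n_stacks = 12, seed_base = 100) {
  key <- sprintf("ureter_%d_%d", n_stacks, seed_base)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lapply(seq_len(n_stacks), function(i) {
      spec <- preset_scenarios(field_size_px = c(192, 2048),
                               slice_spacing_um = 1, n_slices = 56,
                               seed = seed_base + i)$ureter_like
      gs <- generate_stack(spec)
      run <- process_stack(gs$stack, stack_id = sprintf("s%02d", i))
      run$clusters$pixels <- NULL
      out <- list(truth = gs$truth, geometry = gs$stack$geometry,
                  samples = run$samples, counts = run$counts,
                  density = run$density, clusters = run$clusters)
      rm(gs, run); gc(verbose = FALSE)
      out
    })
  }
  .fixture_env[[key]]
}

pooled_samples <- function(bundle) {
  do.call(rbind, c(lapply(bundle, `[[`, "samples"),
                   list(make.row.names = FALSE)))
}

# Fraction of round ground-truth nuclei that leak an orientation sample:
# a round nucleus counts as leaked if any anisotropy-passing cluster sits
# within `radius` um of its center.
round_leakage <- function(bundle, radius = 2.5) {
  leak <- vapply(bundle, function(b) {
    tr <- b$truth
    cl <- b$clusters
    apex <- b$geometry$field_size_px[1] / 2 * b$geometry$pixel_size_um
    cz <- cl$slice_index * b$geometry$slice_spacing_um
    d2 <- outer(tr$x_um, cl$centroid_x_um, "-")^2 +
      outer(tr$y_um, cl$centroid_y_um - apex, "-")^2 +
      outer(tr$z_um, cz, "-")^2
    near <- apply(d2, 1, min) <= radius^2
    c(sum(near & tr$is_round), sum(tr$is_round))
  }, numeric(2))
  sum(leak[1, ]) / sum(leak[2, ])
}
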