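test_that("KDE integrates to one for arbitrary samples and bandwidths", {
  set.seed(15)
  for (i in 1:4) {
    n <- sample(60:500, 1)
    s <- data.frame(z_n = runif(n), alpha_deg = runif(n, -90, 90))
    p <- kde_params(bandwidth_depth = runif(1, 0.03, 0.2),
                    bandwidth_angle = runif(1, 2, 15))
    d <- kde2d_circular(s, p)
    expect_equal(tubeorient:::kde_mass(d$depth, d$angle, d$density), 1,
                 tolerance = 1e-3)
    expect_true(all(d$density >= 0))
    # axial periodicity: the -90 and +90 edges coincide
    expect_equal(d$density[, 1], d$density[, ncol(d$density)],
                 tolerance = 1e-10)
  }
})

test_that("angle wrapping is exact under 180-degree relabeling", {
  set.seed(16)
  s <- data.frame(z_n = runif(200), alpha_deg = runif(200, -90, 90))
  s2 <- s; s2$alpha_deg <- s$alpha_deg + 180
  expect_equal(kde2d_circular(s)$density, kde2d_circular(s2)$density,
               tolerance = 1e-12)
})

test_that("mass flows across the axial boundary", {
  s <- data.frame(z_n = runif(100), alpha_deg = rep(89, 100))
  d <- kde2d_circular(s)
  j <- which.min(abs(d$angle + 89))
  expect_gt(min(d$density[, j]), 0)
  # ridge at 0 when all samples are longitudinal
  s0 <- data.frame(z_n = runif(100), alpha_deg = rep(0, 100))
  d0 <- kde2d_circular(s0)
  marg <- colSums(d0$density)
  expect_equal(d0$angle[which.max(marg)], 0)
})

test_that("KDE input contracts", {
  expect_error(kde2d_circular(data.frame(z_n = numeric(0),
                                         alpha_deg = numeric(0))), "samples")
  expect_warning(kde2d_circular(data.frame(z_n = runif(10),
                                           alpha_deg = runif(10, -90, 90))),
                 "50 samples")
})

test_that("KDE angle marginal converges to the closed-form axial density", {
  set.seed(17)
  n <- 1e4
  s <- data.frame(z_n = runif(n), alpha_deg = sample_axial_angle(n, 0, 25))
  d <- kde2d_circular(s, kde_params(bandwidth_angle = 5))
  wz <- tubeorient:::trapezoid_weights(d$depth)
  marg <- as.numeric(wz %*% d$density)           # per-degree marginal
  truth <- tubeorient:::axial_vonmises_density(d$angle, 0, 25)
  wa <- tubeorient:::trapezoid_weights(d$angle)
  ise <- sum(wa * (marg - truth)^2)
  expect_lt(ise, 1e-4)
})

test_that("octiles: symmetry, uniform quantiles, non-crossing, coverage", {
  set.seed(18)
  n <- 1e4
  z <- runif(n)
  s <- data.frame(z_n = z, alpha_deg = sample_axial_angle(n, 0, 25 + 7 * z))
  d <- kde2d_circular(s)
  oc <- octile_curves(d)
  # symmetric unimodal conditional at 0: the median curve stays at 0
  expect_lt(max(abs(oc$octiles[, 4])), 2)
  # curves never cross
  expect_true(all(apply(oc$octiles, 1, function(r) all(diff(r) > 0))))
  # empirical coverage of each octile is k/8
  iz <- findInterval(s$z_n, d$depth + c(diff(d$depth) / 2, Inf)) + 1
  for (k in c(1, 2, 4, 6, 7)) {
    mu <- oc$mean_deg[iz]
    a_u <- mu + wrap_axial(s$alpha_deg - mu)
    cov_k <- mean(a_u <= oc$octiles[iz, k])
    expect_lt(abs(cov_k - k / 8), 0.02)
  }
  # near-uniform conditional: octiles near -67.5 .. 67.5 about the mean
  su <- data.frame(z_n = runif(5000), alpha_deg = sample_axial_angle(5000, 0, Inf))
  ocu <- octile_curves(kde2d_circular(su))
  ctr <- sweep(ocu$octiles, 1, ocu$mean_deg)
  for (k in 1:7)
    expect_lt(abs(mean(ctr[, k]) - (-90 + k * 22.5)), 4)
})

test_that("dispersion table percentiles follow the type-7 convention", {
  mk <- function(id, sd) data.frame(
    stack_id = id, z_n = runif(400),
    alpha_deg = sample_axial_angle(400, 0, sd))
  set.seed(19)
  s <- rbind(mk("a", 20), mk("b", 30), mk("c", 40))
  tab <- dispersion_table(s, depths = 0.5, window_halfwidth = 0.5)
  sds <- sapply(c("a", "b", "c"), function(id)
    circular_sd(s$alpha_deg[s$stack_id == id]))
  expect_equal(unlist(tab[, c("p25", "p50", "p75")], use.names = FALSE),
               unname(quantile(sds, c(0.25, 0.5, 0.75))))
  # constant per-stack SDs {20, 30, 40} interpolate to (25, 30, 35)
  expect_equal(unname(quantile(c(20, 30, 40), c(0.25, 0.5, 0.75))),
               c(25, 30, 35))
  # identical stacks: all percentiles equal; columns always monotone
  s2 <- rbind(mk("a", 25), mk("b", 25))
  s2$alpha_deg <- rep(s2$alpha_deg[1:400], 2)
  tab2 <- dispersion_table(s2, depths = 0.5, window_halfwidth = 0.5)
  expect_equal(tab2$p25, tab2$p75)
  expect_true(all(tab$p25 <= tab$p50 & tab$p50 <= tab$p75))
  expect_error(dispersion_table(mk("a", 20)), "2 stacks")
})

test_that("cell density arithmetic and invalid-ROI exclusion", {
  g <- acquisition_geometry(150, 55, 0.5, 1, c(256, 256), 56)
  rois <- lapply(c(0L, 10L, 20L), function(i) effective_roi(g, i))
  counts <- data.frame(slice_index = c(0L, 10L, 20L), count = c(5L, 10L, 0L))
  prof <- cell_density_profile(counts, rois, 55)
  expect_equal(nrow(prof), 2)               # slice 0 invalid, dropped
  expect_equal(prof$density_per_1e4um2,
               c(10, 0) / prof$roi_area_um2 * 1e4)
  # 10 clusters in a 5e3 um2 ROI -> 20 cells per 1e4 um2
  r <- rois[[2]]; r$area_um2 <- 5e3
  expect_equal(cell_density_profile(data.frame(slice_index = 10L, count = 10L),
                                    list(r), 55)$density_per_1e4um2, 20)
})
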