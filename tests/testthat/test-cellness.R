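test_that("constant images carry no cellness and offsets are invisible", {
  flat <- matrix(7, 32, 32)
  expect_equal(cellness_filter(flat, cellness_params(), 0.5),
               matrix(0, 32, 32))
  img <- make_blob_slice(48, 48, 0.5, cbind(24, 24), 20)
  expect_equal(cellness_filter(img, cellness_params(), 0.5),
               cellness_filter(img + 5, cellness_params(), 0.5))
  expect_error(cellness_filter(matrix(c(1, NA, 1, 1), 2), cellness_params(), 0.5),
               "finite")
})

test_that("cellness peaks at the center of a bright elongated blob", {
  # blob with 2 x 6 um axes (sigma 1.5 / 0.5 um) centered at (33, 41)
  img <- make_blob_slice(64, 64, 0.5, cbind(33, 41), -35,
                         sigma_long_um = 1.5, sigma_short_um = 0.5)
  cm <- cellness_filter(img, cellness_params(sigma_kernel_um = 1), 0.5)
  pk <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(33, 41))), 1)
})

test_that("dark structures on bright background give zero response", {
  img <- 1 - make_blob_slice(48, 48, 0.5, cbind(24, 24), 0)
  cm <- cellness_filter(img, cellness_params(), 0.5)
  expect_equal(cm[24, 20:28], rep(0, 9))  # along the dark core
})

test_that("cellness is exactly equivariant under 90-degree rotation", {
  set.seed(5)
  img <- make_blob_slice(40, 40, 0.5,
                         cbind(c(12, 28), c(15, 25)), c(30, -60)) +
    matrix(rnorm(1600, sd = 0.01), 40)
  p <- cellness_params()
  r1 <- cellness_filter(t(apply(img, 2, rev)), p, 0.5)
  r2 <- t(apply(cellness_filter(img, p, 0.5), 2, rev))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("FFT Hessian equals the explicit band-matrix convolution", {
  set.seed(20)
  img <- matrix(rnorm(48 * 80), 48)
  H <- tubeorient:::hessian2d(img, 2)
  k <- tubeorient:::gaussian_kernels(2)
  cm <- tubeorient:::conv_matrix
  expect_equal(H$xx, 4 * (cm(48, k$g0) %*% img %*% t(cm(80, k$g2))),
               tolerance = 1e-12)
  expect_equal(H$xy, 4 * (cm(48, k$g1) %*% img %*% t(cm(80, k$g1))),
               tolerance = 1e-12)
})

test_that("binarization thresholds are sharp and monotone", {
  expect_equal(sum(binarize(matrix(0, 8, 8), 0.5)), 0)
  m <- matrix(c(0.2, 0.8, 0.8, 0.2), 2)
  expect_equal(binarize(m, 0.5), m == 0.8)
  set.seed(6)
  cm <- matrix(runif(400), 20)
  counts <- sapply(seq(0.05, 0.95, by = 0.1), function(t) sum(binarize(cm, t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("connectivity controls diagonal merging and areas are conserved", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(extract_clusters(m, 0.5, connectivity = 8)), 1)
  expect_equal(nrow(extract_clusters(m, 0.5, connectivity = 4)), 2)
  sq <- matrix(FALSE, 7, 7); sq[3:5, 3:5] <- TRUE
  cl <- extract_clusters(sq, 0.5)
  expect_equal(cl$area_um2, 2.25)
  expect_equal(cl$centroid_row, 4)
  set.seed(7)
  for (i in 1:5) {
    rm <- matrix(runif(900) < 0.3, 30)
    for (conn in c(4, 8)) {
      cl <- extract_clusters(rm, 0.5, conn)
      expect_equal(sum(cl$area_um2), sum(rm) * 0.25)
      expect_equal(sum(cl$n_px), sum(rm))
    }
  }
})

test_that("label sets nest with connectivity: 8-conn never splits 4-conn", {
  set.seed(8)
  rm <- matrix(runif(400) < 0.4, 20)
  expect_lte(nrow(extract_clusters(rm, 0.5, 8)),
             nrow(extract_clusters(rm, 0.5, 4)))
})

test_that("area filtering keeps only in-range clusters", {
  cl <- extract_clusters(matrix(TRUE, 4, 4), 0.5)  # area 4 um2
  cl2 <- rbind(cl, cl, cl)
  cl2$area_um2 <- c(1, 20, 500)
  expect_equal(filter_by_area(cl2, 5, 100)$area_um2, 20)
  expect_equal(nrow(filter_by_area(cl2, 0, Inf)), 3)
})

test_that("nuclei survive the area filter and specks do not", {
  set.seed(9)
  centers <- matrix(numeric(0), 0, 2)
  while (nrow(centers) < 10) {     # distinct, non-touching nuclei
    cand <- c(sample(20:100, 1), sample(20:180, 1))
    if (nrow(centers) == 0 ||
        min(rowSums(sweep(centers, 2, cand)^2)) > 30^2)
      centers <- rbind(centers, cand)
  }
  specks <- cbind(sample(10:110, 15), sample(10:190, 15))
  img <- make_blob_slice(120, 200, 0.5, centers, runif(10, -90, 90),
                         speck_centers_px = specks)
  cl <- segment_slice(img, 0.5)
  kept <- filter_by_area(cl, 8, 120)
  # every kept cluster lies at a true nucleus; at least 9 of 10 recovered
  d2 <- function(c1, c2) outer(c1[, 1], c2[, 1], "-")^2 +
    outer(c1[, 2], c2[, 2], "-")^2
  near <- d2(cbind(kept$centroid_row, kept$centroid_col), centers) < 6^2
  expect_gte(sum(apply(near, 2, any)), 9)
  expect_true(all(apply(near, 1, any)))  # no speck survives
})

test_that("raising the threshold never increases retained clusters", {
  img <- make_blob_slice(80, 80, 0.5, cbind(c(20, 40, 60), c(30, 50, 20)),
                         c(0, 45, -70))
  cmap <- cellness_filter(img, cellness_params(), 0.5)
  n <- sapply(c(0.1, 0.3, 0.5, 0.7), function(t)
    nrow(extract_clusters(binarize(cmap, t), 0.5)))
  expect_true(all(diff(n) <= 0))
})
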