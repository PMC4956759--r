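cohort <- preprocess_cohort(small_phantom(6, seed = 12))

test_that("PCA bone masking recovers the simulated bone margin", {
  sim <- small_phantom(6, seed = 12)
  bm <- cohort$bone_mask
  agree <- total <- 0
  for (tr in sim$truth) {
    sel <- bm$origin$sample_id == tr$sample_id
    est <- bm$bone[sel]
    at <- cbind(bm$origin$row[sel], bm$origin$col[sel])
    informative <- tr$bone[at] | tr$tissue[at]
    agree <- agree + sum(est[informative] == tr$bone[at][informative])
    total <- total + sum(informative)
  }
  expect_gte(agree / total, 0.95)
  expect_gt(bm$var_explained, 0.05)
})

test_that("bone masking without a bone margin labels everything cartilage", {
  m <- cohort$mat
  expect_warning(bm <- bone_mask_pca(m, expect_bone = FALSE), "cartilage")
  expect_false(any(bm$bone))
})

test_that("PC1 scores are invariant (up to sign) to a constant offset", {
  m <- cohort$mat
  b1 <- bone_mask_pca(m)
  m2 <- spectrum_matrix(m$spectra + 0.37, m$axis, m$origin)
  b2 <- bone_mask_pca(m2)
  expect_equal(abs(b1$scores), abs(b2$scores), tolerance = 1e-8)
  expect_identical(b1$bone, b2$bone)
})

test_that("otsu threshold separates a clear bimodal sample", {
  set.seed(3)
  x <- c(rnorm(500, 0, 0.5), rnorm(200, 10, 0.5))
  thr <- otsu_threshold(x)
  expect_gt(thr, 2); expect_lt(thr, 8)
  expect_error(otsu_threshold(rep(1, 10)), "single-valued")
})

test_that("depth runs from 0 at the surface to 100 at the tidemark", {
  ax <- toy_axis(4)
  ab <- array(1, dim = c(70, 1, 4))
  tm <- matrix(FALSE, 70, 1); tm[10:59, 1] <- TRUE
  cube <- spectral_cube("D", ax, ab, tissue_mask = tm)
  dm <- compute_depth(cube)
  expect_equal(dm$depth[10, 1], 0)
  expect_equal(dm$depth[59, 1], 100)
  expect_equal(dm$surface_row[1], 10L)
  expect_equal(dm$tidemark_row[1], 59L)
  # columns with under 3 tissue pixels are excluded and reported
  tm2 <- cbind(tm, c(rep(FALSE, 68), TRUE, TRUE))
  cube2 <- spectral_cube("D2", ax, array(1, dim = c(70, 2, 4)),
                         tissue_mask = tm2)
  dm2 <- compute_depth(cube2)
  expect_equal(dm2$excluded_cols, 2L)
  expect_true(all(is.na(dm2$depth[, 2])))
  expect_error(compute_depth(spectral_cube("E", ax, array(1, dim = c(5, 1, 4)),
                                           tissue_mask = matrix(FALSE, 5, 1))),
               "no usable tissue")
})

test_that("estimated depth matches generator truth within one pixel", {
  sim <- small_phantom(6, seed = 12)
  for (k in seq_along(cohort$cubes)) {
    dm <- cohort$depthmaps[[k]]
    tr <- sim$truth[[k]]
    both <- !is.na(dm$depth) & !is.na(tr$depth)
    span <- tr$tidemark_row - tr$surface_row
    err_px <- abs(dm$depth[both] - tr$depth[both]) / 100 * span
    expect_lte(max(err_px), 1 + 1e-9)
  }
})

test_that("zones tile the tissue and pick the documented row counts", {
  ax <- toy_axis(4)
  ab <- array(1, dim = c(55, 1, 4))
  tm <- matrix(FALSE, 55, 1); tm[1:50, 1] <- TRUE
  cube <- spectral_cube("Z", ax, ab, tissue_mask = tm)
  dm <- compute_depth(cube)
  zones <- default_zones()
  full <- zone_pixels(cube, dm, zone_def("all", 0, 100))
  expect_equal(nrow(full$spectra), 50L)
  # 50-row column: d = 100*i/49, d <= 15 for i = 0..7, so 8 surface rows
  surf <- zone_pixels(cube, dm, zones$surface)
  expect_equal(nrow(surf$spectra), 8L)
  n_union <- length(unique(unlist(lapply(zones, function(z)
    zone_pixels(cube, dm, z)$origin$row))))
  expect_equal(n_union, 50L)
  expect_error(zone_pixels(cube, dm, zone_def("x", 99.5, 99.9)), "empty zone")
})

test_that("depth normalization is invariant to uniform vertical rescaling", {
  ax <- toy_axis(4)
  mk <- function(n_rows) {
    tm <- matrix(FALSE, n_rows + 4, 1); tm[3:(n_rows + 2), 1] <- TRUE
    compute_depth(spectral_cube("R", ax, array(1, dim = c(n_rows + 4, 1, 4)),
                                tissue_mask = tm))
  }
  d21 <- mk(21); d41 <- mk(41)
  # spans of 20 and 40 rows: every second row of the finer column matches
  f21 <- d21$depth[3:23, 1]
  f41 <- d41$depth[seq(3, 43, by = 2), 1]
  expect_equal(f21, f41, tolerance = 1e-12)
})

test_that("depth profiles bin by equal-width depth intervals", {
  d <- seq(0, 100, length.out = 201)
  pr <- depth_profile(rep(3.5, 201), d, n_bins = 10L)
  expect_equal(pr$mean, rep(3.5, 10))
  pr2 <- depth_profile(d, d, n_bins = 10L)
  expect_true(all(diff(pr2$mean) > 0))
  expect_equal(sum(pr2$n), 201L)
  # empty bins are NA with zero count
  pr3 <- depth_profile(c(1, 2), c(5, 95), n_bins = 4L)
  expect_true(is.na(pr3$mean[2]))
  expect_equal(pr3$n, c(1L, 0L, 0L, 1L))
  expect_error(depth_profile(1:5, 1:5, n_bins = 1L), "n_bins")
})

test_that("phantom proteoglycan profiles increase from surface to deep", {
  sim <- generate_phantom(phantom_config(
    n_samples = 1L, rows = 40L, cols = 10L, oarsi_grades = 1,
    thickness_jitter_rows = 0L, bad_pixel_rate = 0, seed = 6L))
  co <- preprocess_cohort(sim)
  reg <- region_registry()
  tmat <- combine_cubes(co$cubes, mask = "tissue")
  carb <- apply(tmat$spectra, 1, integrate_area, region = reg$carbohydrate,
                axis = tmat$axis)
  dm <- co$depthmaps[[1]]
  d <- dm$depth[cbind(tmat$origin$row, tmat$origin$col)]
  pr <- depth_profile(carb, d, n_bins = 8L)
  expect_gt(mean(tail(pr$mean, 3)), mean(head(pr$mean, 3)))
  expect_gt(cor(pr$bin, pr$mean, method = "spearman"), 0.8)
})
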