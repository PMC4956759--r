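test_that("quality filter rejects weak, saturated and noisy spectra", {
  ax <- default_axis()
  n <- length(ax)
  good <- gauss_spec(ax, 1655, 25, 0.8) + gauss_spec(ax, 1060, 25, 0.5)
  zero <- numeric(n)
  sat <- gauss_spec(ax, 1655, 25, 5)
  set.seed(1)
  noisy <- gauss_spec(ax, 1655, 25, 0.3) + rnorm(n, 0, 0.1)
  ab <- array(0, dim = c(4, 1, n))
  ab[1, 1, ] <- good; ab[2, 1, ] <- zero; ab[3, 1, ] <- sat
  ab[4, 1, ] <- noisy
  cube <- spectral_cube("Q", ax, ab)
  out <- quality_filter(cube)
  expect_identical(as.vector(out$cube$valid_mask), c(TRUE, FALSE, FALSE, FALSE))
  expect_setequal(out$report$reason, c("low_peak", "saturated", "low_snr"))
  # tissue mask shrinks with the valid mask
  expect_true(all(out$cube$tissue_mask <= out$cube$valid_mask))
})

test_that("noise-free phantom pixels pass the default quality thresholds", {
  sim <- generate_phantom(phantom_config(
    n_samples = 1L, rows = 20L, cols = 6L, oarsi_grades = 2,
    thickness_jitter_rows = 0L, noise_sd = 0, bad_pixel_rate = 0, seed = 3L))
  out <- quality_filter(sim$cubes[[1]])
  tr <- sim$truth[[1]]
  expect_true(all(out$cube$valid_mask[tr$tissue | tr$bone]))
})

test_that("simulated bad pixels are rejected at about their simulation rate", {
  fractions <- vapply(c(101L, 202L, 303L), function(seed) {
    sim <- generate_phantom(phantom_config(
      n_samples = 1L, rows = 64L, cols = 64L, bone_rows = 8L,
      thickness_jitter_rows = 0L, oarsi_grades = 2,
      bad_pixel_rate = 0.05, seed = seed))
    out <- quality_filter(sim$cubes[[1]])
    mean(!out$cube$valid_mask)
  }, 0)
  expect_true(all(fractions >= 0.03 & fractions <= 0.07))
})

test_that("EMSC inverts a known scale and linear baseline exactly", {
  ax <- default_axis()
  ref <- gauss_spec(ax, 1655, 25, 1) + gauss_spec(ax, 1060, 25, 0.6)
  w <- as.numeric(ax)
  s <- 2 * ref + 0.1 + 0.001 * w
  m <- toy_matrix(rbind(s, ref), ax)
  out <- emsc_correct(m, reference = ref)
  expect_lt(max(abs(out$corrected$spectra[1, ] - ref)), 1e-8)
  # the reference itself is a fixed point: b = 1, zero baseline
  expect_equal(out$b[2], 1, tolerance = 1e-10)
  expect_lt(max(abs(out$corrected$spectra[2, ] - ref)), 1e-10)
})

test_that("EMSC is scale-equivariant and flags degenerate scales", {
  ax <- default_axis()
  set.seed(4)
  ref <- gauss_spec(ax, 1655, 25, 1) + gauss_spec(ax, 1060, 20, 0.5)
  S <- rbind(1.3 * ref + 0.05, 0.6 * ref - 0.02 + 1e-4 * as.numeric(ax))
  out1 <- emsc_correct(toy_matrix(S, ax), reference = ref)
  out2 <- emsc_correct(toy_matrix(5 * S, ax), reference = ref)
  expect_equal(out1$corrected$spectra, out2$corrected$spectra,
               tolerance = 1e-9)
  # a spectrum orthogonal to the reference trend gets b ~ 0
  outd <- emsc_correct(toy_matrix(rbind(ref, -ref), ax), reference = ref)
  expect_true(outd$degenerate[2])
})

test_that("EMSC removes most multiplicative/additive between-pixel variance", {
  ax <- default_axis()
  reg <- region_registry()
  set.seed(7)
  mix <- gauss_spec(ax, 1655, 25, 1) + gauss_spec(ax, 1060, 25, 0.7)
  n <- 200
  scales <- runif(n, 0.7, 1.3)
  S <- t(vapply(seq_len(n), function(i) {
    scales[i] * mix + runif(1, -0.02, 0.05) +
      runif(1, -2e-5, 2e-5) * (as.numeric(ax) - 1375) + rnorm(length(ax), 0, 1e-4)
  }, numeric(length(ax))))
  m <- spectrum_matrix(S, ax, data.frame(sample_id = "V", row = seq_len(n),
                                         col = 1L))
  area <- function(M) apply(M, 1, integrate_area, region = reg$amide_I,
                            axis = ax)
  v_pre <- var(area(S))
  v_post <- var(area(emsc_correct(m)$corrected$spectra))
  expect_gt(v_pre / v_post, 5)
})

test_that("vector normalization yields unit rows and preserves direction", {
  set.seed(2)
  S <- matrix(abs(rnorm(5 * 213)) + 0.1, 5)
  m <- toy_matrix(S, default_axis())
  vn <- vector_normalize(m)
  expect_equal(unname(sqrt(rowSums(vn$spectra^2))), rep(1, 5),
               tolerance = 1e-12)
  cosine <- rowSums(vn$spectra * S) / sqrt(rowSums(S^2))
  expect_equal(unname(cosine), rep(1, 5), tolerance = 1e-12)
  # constant spectrum: closed form 1/sqrt(n)
  cm <- vector_normalize(toy_matrix(matrix(3, 1, 213), default_axis()))
  expect_equal(unname(cm$spectra[1, 1]), 1 / sqrt(213), tolerance = 1e-14)
  # idempotence
  expect_equal(vector_normalize(vn)$spectra, vn$spectra, tolerance = 1e-14)
  # zero row errors with the pixel named
  S[3, ] <- 0
  expect_error(vector_normalize(toy_matrix(S, default_axis())), "T1 \\(3, 1\\)")
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
  ax <- default_axis()
  w <- as.numeric(ax)
  a <- 0.003
  quad <- toy_matrix(rbind(a * w^2 + 2 * w + 5, -3 * w + 1), ax)
  d2 <- second_derivative(quad)
  expect_equal(unname(d2$spectra[1, ]), rep(2 * a, 213), tolerance = 1e-10)
  expect_equal(unname(d2$spectra[2, ]), rep(0, 213), tolerance = 1e-10)
})

test_that("Savitzky-Golay second derivative tracks an analytic sinusoid", {
  ax <- default_axis()
  w <- as.numeric(ax)
  s <- sin(2 * pi * w / 200)
  d2 <- second_derivative(matrix(s, 1), axis = ax)
  truth <- -(2 * pi / 200)^2 * sin(2 * pi * w / 200)
  interior <- 10:204
  expect_lt(max(abs(d2[1, interior] - truth[interior])) / max(abs(truth)),
            0.022)
})

test_that("second derivative commutes with scaling and kills linear terms", {
  ax <- default_axis()
  w <- as.numeric(ax)
  set.seed(5)
  s <- gauss_spec(ax, 1338, 12, 0.4) + gauss_spec(ax, 1550, 22, 1)
  d2 <- second_derivative(matrix(s, 1), axis = ax)
  d2k <- second_derivative(matrix(3 * s, 1), axis = ax)
  expect_equal(d2k, 3 * d2, tolerance = 1e-12)
  d2lin <- second_derivative(matrix(s + 0.5 - 0.002 * w, 1), axis = ax)
  expect_equal(d2lin, d2, tolerance = 1e-10)
})

test_that("second derivative settings are validated", {
  expect_error(sg_operator(default_axis(), window = 8L), "odd")
  expect_error(sg_operator(default_axis(), window = 3L, polyorder = 3L),
               "polyorder")
  expect_error(sg_operator(toy_axis(5), window = 9L), "larger than axis")
})

test_that("two-point baseline maps endpoints to zero and kills lines", {
  ax <- default_axis()
  w <- as.numeric(ax)
  reg <- region_registry()
  lin <- 0.4 + 0.003 * w
  out <- two_point_baseline(lin, reg$amide_II, ax)
  expect_equal(out$values, rep(0, length(out$values)), tolerance = 1e-12)
  out2 <- two_point_baseline(rep(5, length(w)), reg$ch2_side_chain, ax)
  expect_equal(out2$values, rep(0, length(out2$values)), tolerance = 1e-12)
  # a peak that is zero at the region endpoints passes through unchanged
  idx <- cartFTIR:::region_index(ax, reg$ch2_side_chain)
  tri <- numeric(length(w))
  mid <- idx[ceiling(length(idx) / 2)]
  tri[idx] <- 1 - abs(seq_along(idx) - ceiling(length(idx) / 2)) /
    (ceiling(length(idx) / 2) - 1)
  tri[tri < 0] <- 0
  out3 <- two_point_baseline(tri, reg$ch2_side_chain, ax)
  expect_equal(out3$values, tri[idx], tolerance = 1e-12)
  expect_error(two_point_baseline(lin, spectral_region("tiny", 1000, 1005),
                                  ax), "fewer than 3")
})
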