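test_that("trapezoidal areas match closed forms", {
  ax <- default_axis()
  reg60 <- spectral_region("r60", 1200, 1260)   # on-grid span? 1202..1258
  # use an exactly spanned region: points 1202..1258 cover 56 cm^-1
  s <- rep(1, 213)
  expect_equal(integrate_area(s, reg60, ax), 56)
  # a grid-aligned 60 cm^-1 region: constant 1 integrates to 60
  ax2 <- wn_axis(seq(1200, 1400, by = 4))
  expect_equal(integrate_area(rep(1, length(ax2)),
                              spectral_region("x", 1240, 1300), ax2), 60)
  # two-point baseline annihilates any linear spectrum
  lin <- 0.2 + 0.004 * as.numeric(ax)
  expect_equal(integrate_area(lin, reg60, ax, baseline = "two_point"), 0,
               tolerance = 1e-12)
  expect_error(integrate_area(s, spectral_region("p", 1200, 1203), ax),
               "fewer than 2")
})

test_that("trapezoid integral of a Gaussian band matches its closed form", {
  ax <- default_axis()
  A <- 1; sigma <- 10
  g <- gauss_spec(ax, 1200, sigma, A)
  wide <- spectral_region("w", 1100, 1300)      # +- 10 sigma
  est <- integrate_area(g, wide, ax)
  expect_equal(est, A * sigma * sqrt(2 * pi), tolerance = 0.005)
})

test_that("collagen integrity is a baseline-robust band-area ratio", {
  ax <- default_axis()
  reg <- region_registry()
  # symmetric triangular peaks of identical height and width in both regions
  w <- as.numeric(ax)
  tri <- function(center, half) pmax(0, 1 - abs(w - center) / half)
  s <- tri(1330, 28) + tri(1535, 28)
  expect_equal(collagen_integrity(s, ax), 1, tolerance = 1e-10)
  # halving the CH2 band halves the ratio
  s2 <- 0.5 * tri(1330, 28) + tri(1535, 28)
  expect_equal(collagen_integrity(s2, ax),
               0.5 * collagen_integrity(s, ax), tolerance = 1e-10)
  # invariant to any added global linear baseline
  s3 <- s + 0.8 - 0.003 * w
  expect_equal(collagen_integrity(s3, ax), collagen_integrity(s, ax),
               tolerance = 1e-9)
  # undefined when the amide II area is ~ 0
  expect_true(is.na(collagen_integrity(tri(1330, 28), ax)))
})

test_that("carbohydrate/amide I ratio is invariant to overall scaling", {
  ax <- default_axis()
  s <- gauss_spec(ax, 1655, 25, 1) + gauss_spec(ax, 1060, 25, 0.6)
  m <- toy_matrix(rbind(s, 4.2 * s), ax)
  pp <- pixel_params(m)
  expect_equal(pp$carb_over_amideI[1], pp$carb_over_amideI[2],
               tolerance = 1e-10)
  expect_equal(pp$amide_I_area[2], 4.2 * pp$amide_I_area[1],
               tolerance = 1e-10)
})

test_that("second-derivative peak values agree with a direct local fit", {
  ax <- default_axis()
  A <- 0.5; sigma <- 12; center <- 1202
  g <- gauss_spec(ax, center, sigma, A)
  d2 <- second_derivative(matrix(g, 1), axis = ax)
  got <- d2_peak(d2[1, ], center, ax)
  # oracle: independent quadratic-cubic least-squares fit of the exact
  # Gaussian over each 9-point window, minimized near the band centre
  w <- as.numeric(ax)
  oracle <- vapply(which(abs(w - center) <= 8), function(i) {
    win <- (i - 4):(i + 4)
    fit <- lm(y ~ poly(x, 3, raw = TRUE),
              data = data.frame(x = w[win] - w[i], y = g[win]))
    2 * coef(fit)[[3]]
  }, 0)
  expect_equal(got, -min(oracle), tolerance = 1e-8)
  # broad bands approach the analytic value A/sigma^2
  gb <- gauss_spec(ax, 1202, 60, 1)
  d2b <- second_derivative(matrix(gb, 1), axis = ax)
  expect_equal(d2_peak(d2b[1, ], 1202, ax), 1 / 60^2, tolerance = 0.02)
  # flat spectrum gives 0; doubling the amplitude doubles the value
  expect_equal(d2_peak(rep(0, 213), 1202, ax), 0)
  d2x2 <- second_derivative(matrix(2 * g, 1), axis = ax)
  expect_equal(d2_peak(d2x2[1, ], center, ax), 2 * got, tolerance = 1e-12)
  expect_error(d2_peak(d2[1, ], 5000, ax), "outside axis")
})

test_that("zone summaries average per-pixel parameters", {
  ax <- default_axis()
  s1 <- gauss_spec(ax, 1330, 15, 0.2) + gauss_spec(ax, 1535, 25, 1) +
    gauss_spec(ax, 1655, 25, 1)
  s2 <- gauss_spec(ax, 1330, 15, 0.4) + gauss_spec(ax, 1535, 25, 1) +
    gauss_spec(ax, 1655, 25, 1)
  m <- toy_matrix(rbind(s1, s2), ax)
  pp <- pixel_params(m)
  dm <- structure(list(depth = matrix(c(5, 10), 2, 1)), class = "depth_map")
  zs <- zone_summary(pp, dm, default_zones()$surface)
  expect_equal(zs$n_pixels, 2L)
  expect_equal(zs$collagen_integrity,
               mean(c(pp$collagen_integrity[1], pp$collagen_integrity[2])))
  # single-pixel zone reproduces that pixel
  dm1 <- structure(list(depth = matrix(c(5, 80), 2, 1)), class = "depth_map")
  zs1 <- zone_summary(pp, dm1, default_zones()$surface)
  expect_equal(zs1$amide_I_area, pp$amide_I_area[1])
  expect_error(zone_summary(pp, dm1, zone_def("x", 30, 40)), "empty zone")
})

test_that("surface integrity falls with grade across a phantom cohort", {
  sim <- small_phantom(6, seed = 31)
  co <- preprocess_cohort(sim)
  tmat <- combine_cubes(co$cubes, mask = "tissue")
  pp <- pixel_params(tmat)
  grades <- vapply(sim$cubes, function(x) x$metadata$oarsi_grade, 0)
  surf <- vapply(seq_along(co$cubes), function(k) {
    id <- co$cubes[[k]]$sample_id
    zone_summary(pp[pp$sample_id == id, ], co$depthmaps[[id]],
                 default_zones()$surface)$collagen_integrity
  }, 0)
  expect_lt(cor(grades, surf, method = "spearman"), 0)
})
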