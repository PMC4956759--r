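# internal band evaluator, reached through the package namespace for the
# mixture oracle below
eval_bands <- cartFTIR:::eval_bands

test_that("component library has the expected band structure", {
  ax <- default_axis()
  lib <- make_component_library(ax)
  reg <- region_registry()
  col <- eval_component(lib$collagen, ax)
  pg <- eval_component(lib$proteoglycan, ax)
  # collagen: amide I area exceeds its carbohydrate-region area
  a_amide <- integrate_area(col, reg$amide_I, ax)
  a_carb <- integrate_area(col, reg$carbohydrate, ax)
  expect_gt(a_amide, a_carb)
  # proteoglycan concentrates >= 70% of its area in the carbohydrate region
  frac <- integrate_area(pg, reg$carbohydrate, ax) /
    integrate_area(pg, reg$fingerprint, ax)
  expect_gte(frac, 0.7)
  # nonnegative everywhere
  for (comp in lib) expect_gte(min(eval_component(comp, ax)), 0)
})

test_that("noise-free phantoms are exact linear mixtures of the library", {
  sim <- generate_phantom(phantom_config(
    n_samples = 1L, rows = 20L, cols = 6L, bone_rows = 4L,
    thickness_jitter_rows = 0L, oarsi_grades = 1,
    noise_sd = 0, baseline_offset = c(0, 0), baseline_slope = c(0, 0),
    mult_scale = c(1, 1), bad_pixel_rate = 0, sample_scale_sd = 0,
    bio_variation_sd = 0, seed = 5L))
  cube <- sim$cubes[[1]]
  tr <- sim$truth[[1]]
  ax <- cube$axis
  lib <- make_component_library(ax)
  basis <- cbind(eval_bands(lib$collagen$bands, ax),
                 eval_bands(lib$collagen$integrity_bands, ax),
                 eval_bands(lib$proteoglycan$bands, ax))
  for (px in list(c(3, 2), c(10, 5), c(16, 1))) {
    s <- cube$absorbance[px[1], px[2], ]
    fit <- lsfit(basis, s, intercept = FALSE)
    expect_lt(max(abs(fit$residuals)), 1e-10)
    # recovered coefficients match the recorded ground truth
    expect_equal(unname(fit$coefficients[1]),
                 tr$conc_collagen[px[1], px[2]], tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[3]), tr$conc_pg[px[1], px[2]],
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[2] / fit$coefficients[1]),
                 tr$integrity[px[1], px[2]], tolerance = 1e-8)
  }
})

test_that("generation is deterministic given the seed", {
  a <- small_phantom(3, seed = 9)
  b <- small_phantom(3, seed = 9)
  expect_identical(a$cubes[[2]]$absorbance, b$cubes[[2]]$absorbance)
  expect_identical(a$truth[[3]]$depth, b$truth[[3]]$depth)
  c <- small_phantom(3, seed = 10)
  expect_false(identical(a$cubes[[2]]$absorbance, c$cubes[[2]]$absorbance))
})

test_that("surface proteoglycan is depleted and integrity lowered with grade", {
  mk <- function(grade, seed) generate_phantom(phantom_config(
    n_samples = 1L, rows = 30L, cols = 8L, oarsi_grades = grade,
    thickness_jitter_rows = 0L, bad_pixel_rate = 0, bio_variation_sd = 0,
    sample_scale_sd = 0, seed = seed))$truth[[1]]
  t1 <- mk(1, 3); t4 <- mk(4, 3)
  surf <- function(tr, m) mean(m[!is.na(tr$depth) & tr$depth <= 15])
  expect_lt(surf(t4, t4$conc_pg), surf(t1, t1$conc_pg))
  expect_lt(surf(t4, t4$integrity), surf(t1, t1$integrity))
  # grade ordering induces ordering of the ground truth across the scale
  grades <- c(1, 2, 3, 4, 4.5)
  pg_s <- vapply(grades, function(g) surf(mk(g, 3), mk(g, 3)$conc_pg), 0)
  in_s <- vapply(grades, function(g) surf(mk(g, 3), mk(g, 3)$integrity), 0)
  expect_true(all(diff(pg_s) < 0))
  expect_true(all(diff(in_s) < 0))
})

test_that("true depth is monotone down each column and erosion shifts the surface", {
  sim <- small_phantom(4, seed = 21)
  for (tr in sim$truth) {
    for (cc in seq_len(ncol(tr$depth))) {
      d <- tr$depth[!is.na(tr$depth[, cc]), cc]
      if (length(d) > 1) expect_true(all(diff(d) > 0))
    }
  }
  # grade 4.5 phantom loses its top cartilage rows but depth still starts at 0
  hi <- generate_phantom(phantom_config(
    n_samples = 1L, rows = 30L, cols = 6L, oarsi_grades = 4.5,
    thickness_jitter_rows = 0L, bad_pixel_rate = 0, seed = 2L))
  tr <- hi$truth[[1]]
  expect_gt(tr$surface_row, 1L)
  expect_equal(min(tr$depth, na.rm = TRUE), 0)
})

test_that("cohort manifest pools grades into the three OA groups", {
  man <- cohort_manifest(c(1.0, 2.5, 3.0, 3.5, 4.0, 4.5))
  expect_equal(man$group, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(cohort_manifest(c(1, 2.75)), "ungroupable")
  # default cohort matches the 10/9/9 design
  man28 <- cohort_manifest(default_cohort_grades())
  expect_equal(as.integer(table(man28$group)), c(10L, 9L, 9L))
})

test_that("phantom configuration rejects invalid settings", {
  expect_error(phantom_config(oarsi_grades = 0.5), "\\[1, 4.5\\]")
  expect_error(phantom_config(oarsi_grades = 2.2), "0.5")
  expect_error(phantom_config(bad_pixel_rate = 1), "bad_pixel_rate")
  expect_error(phantom_config(rows = 8, bone_rows = 5), "too small")
})

test_that("ground-truth sidecar CSV covers every tissue and bone pixel", {
  sim <- small_phantom(2, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, f)
  df <- read.csv(f)
  n_expected <- sum(vapply(sim$truth, function(tr)
    sum(tr$tissue | tr$bone | tr$bad_pixel), 0L))
  expect_equal(nrow(df), n_expected)
})
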