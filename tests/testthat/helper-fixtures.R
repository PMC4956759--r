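# Shared fixtures, all built in code at test time.

# tiny axis for toy spectra
toy_axis <- function(n = 3L, lo = 1000, step = 4) {
  wn_axis(seq(lo, by = step, length.out = n))
}

toy_origin <- function(n, sample_id = "T1") {
  data.frame(sample_id = sample_id, row = seq_len(n), col = 1L,
             stringsAsFactors = FALSE)
}

toy_matrix <- function(spectra, axis = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(axis)) axis <- toy_axis(ncol(spectra))
  spectrum_matrix(spectra, axis, toy_origin(nrow(spectra)))
}

# small-cohort phantom used by several module tests (fast: ~1 s)
small_phantom <- function(n_samples = 6L, seed = 42L, ...) {
  generate_phantom(phantom_config(
    n_samples = n_samples, rows = 36L, cols = 10L, bone_rows = 5L,
    thickness_jitter_rows = 4L,
    oarsi_grades = rep_len(c(1, 2, 3, 3.5, 4, 4.5), n_samples),
    seed = seed, ...))
}

# a deterministic spectrum with one Gaussian band
gauss_spec <- function(axis, center, sigma, amp = 1) {
  amp * exp(-(as.numeric(axis) - center)^2 / (2 * sigma^2))
}

# quality filter + EMSC + bone mask + depth, on a phantom cohort
preprocess_cohort <- function(sim, thresholds = quality_thresholds()) {
  cubes <- lapply(lapply(sim$cubes, quality_filter, thresholds = thresholds),
                  `[[`, "cube")
  mat <- combine_cubes(cubes, mask = "valid")
  em <- emsc_correct(mat)
  keep <- !em$degenerate
  mat <- spectrum_matrix(em$corrected$spectra[keep, , drop = FALSE],
                         mat$axis, mat$origin[keep, ])
  cubes <- set_cube_spectra(cubes, mat)
  bm <- bone_mask_pca(mat)
  cubes <- apply_bone_mask(cubes, bm)
  dms <- lapply(cubes, compute_depth)
  names(dms) <- vapply(cubes, `[[`, "", "sample_id")
  list(cubes = cubes, mat = mat, bone_mask = bm, depthmaps = dms)
}
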