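#' Gaussian band specification
#'
#' Component spectra of the phantom generator are sums of Gaussian bands.
#' Real FTIR bands are mixed Gauss/Lorentz profiles; Gaussians are used here
#' because they suffice for every downstream contract and their areas have a
#' closed form (`amplitude * width * sqrt(2*pi)`) usable as an oracle.
#'
#' @param center Band centre in cm^-1.
#' @param width Gaussian sigma in cm^-1 (> 0).
#' @param amplitude Peak absorbance, AU (>= 0).
#' @return A `band_spec`.
#' @export
band_spec <- function(center, width, amplitude) {
  stopifnot(width > 0, amplitude >= 0)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

eval_bands <- function(bands, axis) {
  axis <- as.numeric(axis)
  v <- numeric(length(axis))
  for (b in bands) {
    v <- v + b$amplitude * exp(-(axis - b$center)^2 / (2 * b$width^2))
  }
  v
}

#' Pure-component spectral library
#'
#' Builds the three pure components mixed by the phantom generator:
#' * `collagen` -- dominant amide I (1655 cm^-1) and amide II (1550) bands
#'   plus the minor collagen bands at 1338 (CH2 side chains, carried
#'   separately as the integrity band so collagen-network degradation can
#'   attenuate it) and 1202 cm^-1, an amide III shoulder and a weak C-O band.
#' * `proteoglycan` -- carbohydrate-residue bands concentrated in the
#'   985-1140 cm^-1 region (main band at 1060 cm^-1) plus a weak sulfate
#'   band.
#' * `bone_mineral_proxy` -- a strong, narrow phosphate band near
#'   1030 cm^-1 with carbonate and residual organic bands; its shape in the
#'   carbohydrate region is distinct from cartilage, which is what the
#'   PCA-based interface detection exploits.
#'
#' @param axis Axis the library will be evaluated on (used for validation).
#' @return Named list of components; each has `name`, `bands`, and for
#'   collagen additionally `integrity_bands` (the 1338 cm^-1 band).
#' @export
make_component_library <- function(axis = default_axis()) {
  lib <- list(
    collagen = list(
      name = "collagen",
      bands = list(
        band_spec(1655, 25, 1.00),   # amide I
        band_spec(1550, 22, 0.75),   # amide II
        band_spec(1238, 14, 0.20),   # amide III
        band_spec(1202, 10, 0.18),
        band_spec(1080, 20, 0.12)
      ),
      integrity_bands = list(band_spec(1338, 12, 0.25))
    ),
    proteoglycan = list(
      name = "proteoglycan",
      bands = list(
        band_spec(1060, 25, 1.00),
        band_spec(1120, 18, 0.45),
        band_spec(1000, 15, 0.25),
        band_spec(1230, 15, 0.12)    # sulfate
      ),
      integrity_bands = list()
    ),
    bone_mineral_proxy = list(
      name = "bone_mineral_proxy",
      bands = list(
        band_spec(1030, 14, 1.50),   # phosphate nu3
        band_spec(962, 10, 0.40),    # phosphate nu1
        band_spec(1415, 16, 0.35),   # carbonate
        band_spec(1655, 25, 0.25)    # residual organics
      ),
      integrity_bands = list()
    )
  )
  for (comp in lib) {
    v <- eval_bands(c(comp$bands, comp$integrity_bands), axis)
    if (any(v < 0)) stop("component ", comp$name, " negative on axis")
  }
  lib
}

#' Evaluate a component on an axis
#'
#' @param component An entry of [make_component_library()].
#' @param axis Wavenumber axis.
#' @param integrity Multiplier in `[0, 1]` applied to the integrity bands
#'   (the 1338 cm^-1 CH2 band for collagen); 1 = intact network.
#' @return Numeric vector of absorbance.
#' @export
eval_component <- function(component, axis, integrity = 1) {
  eval_bands(component$bands, axis) +
    integrity * eval_bands(component$integrity_bands, axis)
}

#' Default cohort grades
#'
#' 28 OARSI grades spread over the three analysis groups in the 10/9/9
#' shape of the emulated study: early OA (1.0-2.5, n = 10), intermediate OA
#' (3.0-3.5, n = 9), severe OA (4.0-4.5, n = 9). Grades start at 1.0 (the
#' OA threshold): arthroplasty cohorts contain no completely healthy tissue.
#'
#' @return Numeric vector of length 28.
#' @export
default_cohort_grades <- function() {
  c(rep(c(1.0, 1.5, 2.0, 2.5), 2L), 1.0, 2.5,   # group 1, n = 10
    rep(c(3.0, 3.5), 4L), 3.0,                   # group 2, n = 9
    rep(c(4.0, 4.5), 4L), 4.0)                   # group 3, n = 9
}

#' Phantom generator configuration
#'
#' Defines the simulated study conditions: a cohort of layered cartilage
#' sections (superficial to deep cartilage over a subchondral bone margin)
#' with depth-dependent composition, grade-dependent degradation, scatter
#' baselines, detector noise and occasional dead pixels.
#'
#' Depth profiles (d = normalized depth, 0 at the articular surface, 100 at
#' the tidemark): collagen decreases mildly with depth; proteoglycan
#' increases from surface to deep. Degradation with OARSI grade g:
#' * proteoglycan is multiplied by `exp(-pg_alpha * g * (1 - d/100))`
#'   (surface-weighted depletion); the default `pg_alpha = log(2)/3.5`
#'   halves surface PG at grade 4.5 relative to grade 1.0;
#' * the collagen integrity factor (amplitude of the 1338 cm^-1 band) falls
#'   linearly from 1.0 at grade 1 to 0.5 at grade 4.5 at the surface, with
#'   the decline attenuated towards the deep zone
#'   (`integrity_depth_floor` of the surface decline remains at d = 100);
#' * from grade 4.0 the top `lesion_per_grade * (g - 3.5)` fraction of
#'   cartilage rows is eroded (surface wear: those rows carry only
#'   background noise).
#'
#' All concentration scales are generator conventions; the emulated study
#' reports no absolute compositional magnitudes.
#'
#' @param n_samples Number of samples (default 28).
#' @param rows,cols Pixel grid size per sample.
#' @param bone_rows Rows of subchondral bone at the bottom of each image.
#' @param oarsi_grades Grades in `[1, 4.5]`, length `n_samples`.
#' @param pg_alpha,integrity_drop_per_grade,integrity_depth_floor,lesion_per_grade
#'   Degradation-model parameters (see Details).
#' @param noise_sd I.i.d. Gaussian detector noise, AU.
#' @param baseline_offset,baseline_slope Ranges (length-2) of the per-pixel
#'   additive linear baseline: offset in AU, slope in AU per cm^-1.
#' @param mult_scale Range of the per-pixel multiplicative scatter scale.
#' @param bad_pixel_rate Probability a pixel is replaced by low-signal
#'   detector noise (in `[0, 1)`).
#' @param sample_scale_sd Log-normal sd of a per-sample thickness-like
#'   concentration scale.
#' @param bio_variation_sd Log-normal sd of per-sample multiplicative
#'   jitter on the degradation parameters (`pg_alpha` and
#'   `integrity_drop_per_grade`): histopathological grade never determines
#'   composition exactly in real tissue, so samples of equal grade differ.
#' @param profile_variation_sd Log-normal sd of per-sample jitter on the
#'   compositional depth profiles (overall collagen level, proteoglycan
#'   offset and slope). Real cohorts vary in several independent spectral
#'   directions, not only along the degradation axis; without this the
#'   cohort collapses onto an unrealistically one-dimensional manifold.
#' @param integrity_sample_sd Additive per-sample offset (Gaussian sd) on
#'   the collagen integrity factor, independent of grade. Because the
#'   grade-driven integrity decline is surface-weighted while this noise
#'   is depth-uniform, the deep zone carries genuinely less grade
#'   information -- the composition of variability the grading literature
#'   describes.
#' @param thickness_jitter_rows Per-sample cartilage thickness varies
#'   uniformly within this many rows below the maximum.
#' @param water_vapor_amp Amplitude of optional sharp water-vapor lines in
#'   1500-1700 cm^-1 (default 0 = off).
#' @param axis Wavenumber axis.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_samples = 28L, rows = 60L, cols = 20L,
                           bone_rows = 6L,
                           oarsi_grades = default_cohort_grades(),
                           pg_alpha = log(2) / 3.5,
                           integrity_drop_per_grade = 0.5 / 3.5,
                           integrity_depth_floor = 0.15,
                           lesion_per_grade = 0.3,
                           noise_sd = 0.005,
                           baseline_offset = c(-0.02, 0.05),
                           baseline_slope = c(-2e-5, 2e-5),
                           mult_scale = c(0.7, 1.3),
                           bad_pixel_rate = 0.02,
                           sample_scale_sd = 0.05,
                           bio_variation_sd = 0.08,
                           profile_variation_sd = 0.15,
                           integrity_sample_sd = 0.05,
                           thickness_jitter_rows = 6L,
                           water_vapor_amp = 0,
                           axis = default_axis(),
                           seed = 1L) {
  oarsi_grades <- rep_len(oarsi_grades, n_samples)
  if (any(oarsi_grades < 1 | oarsi_grades > 4.5)) {
    stop("phantom grades must lie in [1, 4.5]")
  }
  if (!all(oarsi_grades %in% seq(1, 4.5, by = 0.5))) {
    stop("grades must be multiples of 0.5")
  }
  if (bad_pixel_rate < 0 || bad_pixel_rate >= 1) {
    stop("bad_pixel_rate must be in [0, 1)")
  }
  if (rows - bone_rows - thickness_jitter_rows < 3L) {
    stop("grid too small: need at least 3 cartilage rows and 1 bone row")
  }
  structure(list(n_samples = as.integer(n_samples), rows = as.integer(rows),
                 cols = as.integer(cols), bone_rows = as.integer(bone_rows),
                 oarsi_grades = oarsi_grades, pg_alpha = pg_alpha,
                 integrity_drop_per_grade = integrity_drop_per_grade,
                 integrity_depth_floor = integrity_depth_floor,
                 lesion_per_grade = lesion_per_grade, noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, mult_scale = mult_scale,
                 bad_pixel_rate = bad_pixel_rate,
                 sample_scale_sd = sample_scale_sd,
                 bio_variation_sd = bio_variation_sd,
                 profile_variation_sd = profile_variation_sd,
                 integrity_sample_sd = integrity_sample_sd,
                 thickness_jitter_rows = as.integer(thickness_jitter_rows),
                 water_vapor_amp = water_vapor_amp, axis = axis,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# depth profiles of true concentration (d in [0, 100])
collagen_conc <- function(d) 1.0 - 0.002 * d
pg_conc_base <- function(d) 0.25 + 0.75 * d / 100

pg_depletion <- function(d, grade, alpha) exp(-alpha * grade * (1 - d / 100))

integrity_factor <- function(d, grade, drop_per_grade, depth_floor) {
  w <- 1 - (1 - depth_floor) * d / 100
  1 - drop_per_grade * (grade - 1) * w
}

#' Generate a cohort of cartilage phantoms
#'
#' Each cube holds cartilage rows at the top (normalized depth d running
#' linearly from 0 at the top remaining tissue row to 100 at the tidemark)
#' over a bone margin at the bottom. Per-pixel absorbance is
#' `scale * sum_c conc_c(d, grade) * component_c + linear baseline + noise`;
#' with noise, baselines and bad pixels disabled every spectrum is an exact
#' nonnegative linear mixture of the library components. Bad pixels are
#' replaced by low-signal noise so the downstream quality filter has true
#' positives.
#'
#' @param config A [phantom_config()].
#' @return List with `cubes` (list of `spectral_cube`) and `truth` (per
#'   sample: logical `tissue`/`bone`/`bad_pixel` matrices, `depth` matrix
#'   (NA outside cartilage), `conc_collagen`, `conc_pg`, `integrity`
#'   matrices), plus `manifest` (see [cohort_manifest()]).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  axis <- cfg$axis
  nw <- length(axis)
  lib <- make_component_library(axis)
  col_base <- eval_bands(lib$collagen$bands, axis)
  col_integ <- eval_bands(lib$collagen$integrity_bands, axis)
  pg <- eval_bands(lib$proteoglycan$bands, axis)
  bone <- eval_bands(lib$bone_mineral_proxy$bands, axis)
  vapor <- if (cfg$water_vapor_amp > 0) {
    eval_bands(lapply(seq(1505, 1695, by = 10),
                      function(c0) band_spec(c0, 1.5, cfg$water_vapor_amp)),
               axis)
  } else NULL

  cubes <- vector("list", cfg$n_samples)
  truth <- vector("list", cfg$n_samples)
  for (k in seq_len(cfg$n_samples)) {
    grade <- cfg$oarsi_grades[[k]]
    id <- sprintf("S%02d", k)
    cart_max <- cfg$rows - cfg$bone_rows
    cart_rows <- cart_max - sample.int(cfg$thickness_jitter_rows + 1L, 1L) + 1L
    lesion_frac <- if (grade >= 4) cfg$lesion_per_grade * (grade - 3.5) else 0
    eroded <- round(lesion_frac * cart_rows)
    top <- 1L + eroded                     # first remaining tissue row
    tide <- cart_rows                      # tidemark row
    if (tide - top < 2L) stop("grid too small after erosion")
    s_scale <- exp(stats::rnorm(1L, 0, cfg$sample_scale_sd))
    alpha_k <- cfg$pg_alpha * exp(stats::rnorm(1L, 0, cfg$bio_variation_sd))
    drop_k <- cfg$integrity_drop_per_grade *
      exp(stats::rnorm(1L, 0, cfg$bio_variation_sd))
    # per-sample compositional individuality (see profile_variation_sd)
    col_k <- exp(stats::rnorm(1L, 0, cfg$profile_variation_sd / 2))
    pg_a0_k <- 0.25 * exp(stats::rnorm(1L, 0, cfg$profile_variation_sd))
    pg_a1_k <- 0.75 * exp(stats::rnorm(1L, 0, cfg$profile_variation_sd))
    int_off_k <- stats::rnorm(1L, 0, cfg$integrity_sample_sd)

    ab <- array(0, dim = c(cfg$rows, cfg$cols, nw))
    tissue <- matrix(FALSE, cfg$rows, cfg$cols)
    bonem <- matrix(FALSE, cfg$rows, cfg$cols)
    badm <- matrix(FALSE, cfg$rows, cfg$cols)
    depth <- matrix(NA_real_, cfg$rows, cfg$cols)
    c_col <- matrix(NA_real_, cfg$rows, cfg$cols)
    c_pg <- matrix(NA_real_, cfg$rows, cfg$cols)
    integ <- matrix(NA_real_, cfg$rows, cfg$cols)

    for (r in seq_len(cfg$rows)) {
      in_cart <- r >= top && r <= tide
      in_bone <- r > tide && r <= tide + cfg$bone_rows
      d <- if (in_cart) 100 * (r - top) / (tide - top) else NA_real_
      for (cc in seq_len(cfg$cols)) {
        bad <- stats::runif(1L) < cfg$bad_pixel_rate
        if (bad) {
          badm[r, cc] <- TRUE
          ab[r, cc, ] <- stats::rnorm(nw, 0.01, cfg$noise_sd + 0.003)
          next
        }
        if (in_cart) {
          tissue[r, cc] <- TRUE
          depth[r, cc] <- d
          ck <- s_scale * col_k * collagen_conc(d)
          pk <- s_scale * (pg_a0_k + pg_a1_k * d / 100) *
            pg_depletion(d, grade, alpha_k)
          ik <- max(integrity_factor(d, grade, drop_k,
                                     cfg$integrity_depth_floor) + int_off_k,
                    0.05)
          c_col[r, cc] <- ck; c_pg[r, cc] <- pk; integ[r, cc] <- ik
          mix <- ck * (col_base + ik * col_integ) + pk * pg
        } else if (in_bone) {
          bonem[r, cc] <- TRUE
          mix <- s_scale * (1.2 * bone + 0.15 * (col_base + col_integ))
        } else {
          # eroded surface / background: faint residue only
          ab[r, cc, ] <- stats::rnorm(nw, 0.005, cfg$noise_sd + 0.002)
          next
        }
        if (!is.null(vapor)) mix <- mix + vapor
        m <- stats::runif(1L, cfg$mult_scale[1L], cfg$mult_scale[2L])
        b0 <- stats::runif(1L, cfg$baseline_offset[1L], cfg$baseline_offset[2L])
        b1 <- stats::runif(1L, cfg$baseline_slope[1L], cfg$baseline_slope[2L])
        spec <- m * mix + b0 + b1 * (as.numeric(axis) - 1375)
        if (cfg$noise_sd > 0) spec <- spec + stats::rnorm(nw, 0, cfg$noise_sd)
        ab[r, cc, ] <- spec
      }
    }
    cubes[[k]] <- spectral_cube(id, axis, ab,
                                metadata = list(oarsi_grade = grade))
    truth[[k]] <- list(sample_id = id, tissue = tissue, bone = bonem,
                       bad_pixel = badm, depth = depth,
                       conc_collagen = c_col, conc_pg = c_pg,
                       integrity = integ, surface_row = top,
                       tidemark_row = tide, sample_scale = s_scale)
  }
  names(truth) <- vapply(cubes, `[[`, "", "sample_id")
  list(cubes = cubes, truth = truth, manifest = cohort_manifest(cubes))
}

#' Cohort manifest with OA groups
#'
#' Pools OARSI grades into the three analysis groups: group 1 (early OA,
#' grades 1.0-2.5), group 2 (intermediate OA, 3.0-3.5), group 3 (severe OA,
#' 4.0-4.5).
#'
#' @param cubes List of `spectral_cube` objects with `oarsi_grade` metadata,
#'   or a numeric vector of grades (then sample ids are generated).
#' @return Data frame with `sample_id`, `oarsi_grade`, `group`.
#' @export
cohort_manifest <- function(cubes) {
  if (is.numeric(cubes)) {
    grades <- cubes
    ids <- sprintf("S%02d", seq_along(grades))
  } else {
    grades <- vapply(cubes, function(x) {
      g <- x$metadata$oarsi_grade
      if (is.null(g)) stop("sample ", x$sample_id, " has no oarsi_grade")
      g
    }, 0)
    ids <- vapply(cubes, `[[`, "", "sample_id")
  }
  group <- ifelse(grades >= 1 & grades <= 2.5, 1L,
                  ifelse(grades >= 3 & grades <= 3.5, 2L,
                         ifelse(grades >= 4 & grades <= 4.5, 3L, NA_integer_)))
  if (anyNA(group)) {
    stop("ungroupable grade: ", paste(grades[is.na(group)], collapse = ", "))
  }
  data.frame(sample_id = ids, oarsi_grade = grades, group = group,
             stringsAsFactors = FALSE)
}

#' Write ground truth as a sidecar CSV
#'
#' @param truth The `truth` element returned by [generate_phantom()].
#' @param path Output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  rows <- lapply(truth, function(tr) {
    idx <- which(tr$tissue | tr$bone | tr$bad_pixel, arr.ind = TRUE)
    data.frame(sample_id = tr$sample_id, row = idx[, 1L], col = idx[, 2L],
               tissue = tr$tissue[idx], bone = tr$bone[idx],
               bad_pixel = tr$bad_pixel[idx], depth = tr$depth[idx],
               conc_collagen = tr$conc_collagen[idx],
               conc_pg = tr$conc_pg[idx], integrity = tr$integrity[idx],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
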