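#' Pipeline configuration
#'
#' Collects every tunable default of the analysis in one object. The
#' processing order is fixed: quality filter, scatter correction, then
#' per-branch vector normalization (clustering), second derivatives
#' (univariate and PLSR), and two-point baselines (inside the collagen
#' integrity parameter only).
#'
#' @param phantom A [phantom_config()] (the synthetic cohort to analyse),
#'   or NULL when `input_dir` is given.
#' @param input_dir Directory of cube container files (alternative to the
#'   synthetic cohort).
#' @param thresholds [quality_thresholds()].
#' @param emsc_order EMSC polynomial baseline order.
#' @param cluster_region Name (in [region_registry()]) of the clustering
#'   region; the carbohydrate region default is the one that best exposes
#'   the cartilage layering.
#' @param K,kmeans_iter K-means settings.
#' @param n_bins Depth-profile bins.
#' @param n_lv_max,cars_runs,cars_mc_ratio,cars_folds,cars_chains Regression settings.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param group_test_mode `"zone"` (Kruskal-Wallis per zone) or `"bin"`
#'   (per depth bin); both modes are available.
#' @param expect_bone Whether the sections include a bone margin.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(), input_dir = NULL,
                            thresholds = quality_thresholds(),
                            emsc_order = 2L, cluster_region = "carbohydrate",
                            K = 5L, kmeans_iter = 20L, n_bins = 20L,
                            n_lv_max = 20L, cars_runs = 50L,
                            cars_mc_ratio = 0.8, cars_folds = 5L,
                            cars_chains = 5L,
                            sg_window = 9L, sg_polyorder = 3L,
                            group_test_mode = c("zone", "bin"),
                            expect_bone = TRUE, seed = 1L) {
  structure(list(phantom = phantom, input_dir = input_dir,
                 thresholds = thresholds, emsc_order = emsc_order,
                 cluster_region = cluster_region, K = K,
                 kmeans_iter = kmeans_iter, n_bins = n_bins,
                 n_lv_max = n_lv_max, cars_runs = cars_runs,
                 cars_mc_ratio = cars_mc_ratio, cars_folds = cars_folds,
                 cars_chains = cars_chains,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 group_test_mode = match.arg(group_test_mode),
                 expect_bone = expect_bone, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()],
#' [phantom_config()] (under `phantom:`) and [quality_thresholds()]
#' (under `thresholds:`).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, as.list(y$phantom %||% list()))
  th <- do.call(quality_thresholds, as.list(y$thresholds %||% list()))
  rest <- y[setdiff(names(y), c("phantom", "thresholds"))]
  do.call(pipeline_config, c(list(phantom = ph, thresholds = th), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, on a synthetic cohort or a directory of cubes: quality
#' filtering, EMSC scatter correction, PCA bone segmentation, depth
#' mapping, combined K-means cluster imaging, per-pixel univariate
#' parameters with zonal summaries and depth profiles, the four grade
#' models (surface/deep x raw/second-derivative), and the cohort
#' statistics table. A rerun with the same configuration and seed is
#' bit-identical in all outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all tabular
#'   artifacts are written as CSV, cluster images as PNG, and a JSONL log
#'   of stage parameters is emitted.
#' @return A `cohort_result` list: `manifest`, `rejections`, `cluster`,
#'   `cluster_means`, `depthmaps`, `zone_summaries`, `profiles`, `models`
#'   (4 grade models), `statistics`, `diagnostics` (truth-based recovery
#'   metrics, synthetic cohorts only), `cubes` (corrected, masked).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }
  reg <- region_registry()

  # --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input_dir)) {
    files <- sort(list.files(config$input_dir, full.names = TRUE))
    cubes <- lapply(files, read_cube)
    note("load", n = length(cubes), dir = config$input_dir)
  } else {
    ph <- config$phantom
    ph$seed <- config$seed
    sim <- generate_phantom(ph)
    cubes <- sim$cubes
    truth <- sim$truth
    note("simulate", n = length(cubes), seed = config$seed)
  }
  manifest <- cohort_manifest(cubes)

  # --- preprocess ----------------------------------------------------------
  qf <- lapply(cubes, quality_filter, thresholds = config$thresholds)
  cubes <- lapply(qf, `[[`, "cube")
  rejections <- do.call(rbind, lapply(qf, `[[`, "report"))
  note("quality_filter", rejected = nrow(rejections))

  mat <- combine_cubes(cubes, mask = "valid")
  em <- emsc_correct(mat, baseline_order = config$emsc_order)
  if (any(em$degenerate)) {
    bad <- em$corrected$origin[em$degenerate, ]
    for (r in seq_len(nrow(bad))) {
      k <- match(bad$sample_id[r], manifest$sample_id)
      cubes[[k]]$valid_mask[bad$row[r], bad$col[r]] <- FALSE
      cubes[[k]]$tissue_mask[bad$row[r], bad$col[r]] <- FALSE
    }
  }
  keep <- !em$degenerate
  mat <- spectrum_matrix(em$corrected$spectra[keep, , drop = FALSE],
                         mat$axis, mat$origin[keep, ])
  cubes <- set_cube_spectra(cubes, mat)
  note("emsc", order = config$emsc_order, degenerate = sum(em$degenerate))

  # --- segmentation --------------------------------------------------------
  bm <- bone_mask_pca(mat, region = reg$carbohydrate,
                      expect_bone = config$expect_bone)
  cubes <- apply_bone_mask(cubes, bm)
  depthmaps <- lapply(cubes, compute_depth)
  names(depthmaps) <- manifest$sample_id
  note("segmentation", pc1_var = bm$var_explained)

  # --- clustering ----------------------------------------------------------
  tmat <- combine_cubes(cubes, mask = "tissue")
  vn <- vector_normalize(tmat)
  cl <- kmeans_combined(vn, region = reg[[config$cluster_region]],
                        K = config$K, n_iter = config$kmeans_iter,
                        seed = config$seed + 1L)
  cl_means <- cluster_mean_spectra(cl, vn)
  note("kmeans", K = config$K, region = config$cluster_region,
       inertia = cl$inertia)

  # --- univariate ----------------------------------------------------------
  params <- pixel_params(tmat, sg_window = config$sg_window,
                         sg_polyorder = config$sg_polyorder)
  zones <- default_zones()
  zsum <- list()
  profiles <- list()
  par_cols <- c("amide_I_area", "carbohydrate_area", "carb_over_amideI",
                "collagen_integrity", "d2_1202", "d2_1064")
  for (k in seq_along(cubes)) {
    id <- manifest$sample_id[k]
    pk <- params[params$sample_id == id, ]
    dm <- depthmaps[[id]]
    for (zn in zones[c("surface", "deep")]) {
      s <- zone_summary(pk, dm, zn)
      s$sample_id <- id
      zsum[[length(zsum) + 1L]] <- s
    }
    d <- dm$depth[cbind(pk$row, pk$col)]
    for (pm in par_cols) {
      pr <- depth_profile(pk[[pm]], d, config$n_bins)
      pr$sample_id <- id
      pr$parameter <- pm
      profiles[[length(profiles) + 1L]] <- pr
    }
  }
  zone_summaries <- do.call(rbind, zsum)
  profiles <- do.call(rbind, profiles)
  note("univariate", n_summaries = nrow(zone_summaries))

  # --- grade models --------------------------------------------------------
  specs <- expand.grid(zone = c("surface", "deep"),
                       representation = c("second_derivative",
                                          "raw_vector_normalized"),
                       stringsAsFactors = FALSE)
  models <- vector("list", nrow(specs))
  model_ok <- rep(TRUE, nrow(specs))
  for (i in seq_len(nrow(specs))) {
    res <- tryCatch(
      grade_model(cubes, depthmaps, zones[[specs$zone[i]]],
                  representation = specs$representation[i],
                  n_lv_max = config$n_lv_max, cars_runs = config$cars_runs,
                  cars_mc_ratio = config$cars_mc_ratio,
                  cars_folds = config$cars_folds,
                  cars_chains = config$cars_chains,
                  sg_window = config$sg_window,
                  sg_polyorder = config$sg_polyorder,
                  seed = config$seed + 10L + i),
      error = function(e) e)
    if (inherits(res, "error")) {
      model_ok[i] <- FALSE
      warning("grade model (", specs$zone[i], ", ",
              specs$representation[i], ") failed: ", conditionMessage(res))
      res <- NULL
    }
    models[i] <- list(res)
  }
  names(models) <- paste(specs$zone, specs$representation, sep = "_")
  note("grade_models", fitted = sum(model_ok))

  # --- statistics ----------------------------------------------------------
  statistics <- tryCatch(cohort_statistics(zone_summaries, manifest),
                         error = function(e) {
                           warning("statistics skipped: ",
                                   conditionMessage(e))
                           NULL
                         })
  note("statistics", mode = config$group_test_mode)

  # --- truth-based diagnostics (synthetic input only) ----------------------
  diagnostics <- if (!is.null(truth)) {
    pipeline_diagnostics(cubes, depthmaps, truth, bm, cl, cl_means, params,
                         manifest)
  } else NULL

  result <- list(manifest = manifest, rejections = rejections,
                 bone_mask = bm, cluster = cl, cluster_means = cl_means,
                 depthmaps = depthmaps, pixel_params = params,
                 zone_summaries = zone_summaries, profiles = profiles,
                 models = models, statistics = statistics,
                 diagnostics = diagnostics, cubes = cubes, truth = truth,
                 log = log, config = config)
  class(result) <- "cohort_result"
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

# recovery metrics against generator ground truth
pipeline_diagnostics <- function(cubes, depthmaps, truth, bm, cl, cl_means,
                                 params, manifest) {
  ids <- manifest$sample_id
  # bone mask agreement on pixels present in the PCA matrix
  agree <- total <- 0
  depth_err <- 0
  for (k in seq_along(cubes)) {
    tr <- truth[[ids[k]]]
    sel <- bm$origin$sample_id == ids[k]
    est_bone <- bm$bone[sel]
    true_bone <- tr$bone[cbind(bm$origin$row[sel], bm$origin$col[sel])]
    true_cart <- tr$tissue[cbind(bm$origin$row[sel], bm$origin$col[sel])]
    informative <- true_bone | true_cart
    agree <- agree + sum(est_bone[informative] == true_bone[informative])
    total <- total + sum(informative)
    # depth error in pixel units; columns whose true surface or tidemark
    # pixel was quality-rejected are excluded (there the depth scale is
    # necessarily re-based onto the observed tissue support)
    dm <- depthmaps[[ids[k]]]
    cube <- cubes[[k]]
    anchored <- vapply(seq_len(ncol(dm$depth)), function(cc) {
      cube$valid_mask[tr$surface_row, cc] &&
        cube$valid_mask[tr$tidemark_row, cc]
    }, NA)
    both <- !is.na(dm$depth) & !is.na(tr$depth) &
      matrix(anchored, nrow(dm$depth), ncol(dm$depth), byrow = TRUE)
    if (any(both)) {
      span <- (tr$tidemark_row - tr$surface_row)
      err <- abs(dm$depth[both] - tr$depth[both]) / 100 * span
      depth_err <- max(depth_err, max(err))
    }
  }
  # cluster with lowest carbohydrate-region mean absorbance
  reg <- region_registry()$carbohydrate
  idx <- region_index(cl_means$axis, reg)
  carb_level <- rowMeans(cl_means$mean_spectra[, idx, drop = FALSE])
  low_k <- which.min(carb_level)
  sel <- cl$labels == low_k
  d_low <- vapply(which(sel), function(i) {
    o <- cl$origin[i, ]
    depthmaps[[o$sample_id]]$depth[o$row, o$col]
  }, 0)
  list(bone_mask_agreement = agree / total, bone_mask_n = total,
       depth_max_error_px = depth_err,
       lowest_carb_cluster = low_k,
       lowest_carb_surface_fraction = mean(d_low < 33, na.rm = TRUE),
       lowest_carb_n = length(d_low))
}

#' Write pipeline artifacts
#'
#' CSV tables (manifest, rejection report, zone summaries, depth profiles,
#' per-model predictions, selected wavenumbers, statistics), per-sample
#' cluster PNG images, and a JSONL log of stage parameters.
#'
#' @param result A `cohort_result`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(result$manifest, "manifest.csv")
  w(result$rejections, "rejection_report.csv")
  w(result$zone_summaries, "zone_summaries.csv")
  w(result$profiles, "depth_profiles.csv")
  if (!is.null(result$statistics)) w(result$statistics, "statistics.csv")
  preds <- list(); sels <- list()
  for (nm in names(result$models)) {
    m <- result$models[[nm]]
    if (is.null(m)) next
    preds[[nm]] <- data.frame(model = nm, sample_id = result$manifest$sample_id,
                              reference = m$reference,
                              predicted = m$predictions,
                              stringsAsFactors = FALSE)
    sels[[nm]] <- data.frame(model = nm,
                             wavenumber = m$selected_wavenumbers,
                             stringsAsFactors = FALSE)
  }
  if (length(preds)) w(do.call(rbind, preds), "predictions.csv")
  if (length(sels)) w(do.call(rbind, sels), "selected_wavenumbers.csv")
  cl_assign <- cbind(result$cluster$origin,
                     cluster = result$cluster$labels)
  w(cl_assign, "cluster_assignments.csv")
  for (cube in result$cubes) {
    img <- render_cluster_image(result$cluster, cube)
    write_cluster_png(img, file.path(out_dir,
                                     paste0("cluster_", cube$sample_id,
                                            ".png")))
  }
  logf <- file.path(out_dir, "log.jsonl")
  writeLines(vapply(result$log, function(x) {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }, ""), logf)
  invisible(out_dir)
}
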