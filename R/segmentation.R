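#' Otsu threshold for a numeric vector
#'
#' Histogram-based threshold maximizing between-class variance, used to
#' split PC1 scores into bone and cartilage automatically (replacing manual
#' inspection of the score image, for reproducibility).
#'
#' @param x Numeric vector.
#' @param n_bins Histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) stop("cannot threshold a single-valued set")
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mid <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mid)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  # the criterion is flat across an empty gap: centre the threshold there
  best <- which(sb >= max(sb) - 1e-12 * abs(max(sb)))
  mean(mid[range(best)])
}

#' PCA-based bone/cartilage interface detection
#'
#' PCA is run jointly on the mean-centred carbohydrate-region spectra of
#' all samples; the first principal component contrasts the mineral
#' phosphate absorption of subchondral bone with the carbohydrate bands of
#' cartilage. PC1 scores are split by an automatic Otsu threshold (a manual
#' threshold can be supplied for parity with visual removal), and the side
#' containing the bottom image margin -- where the subchondral bone sits in
#' a surface-up section -- is labelled bone.
#'
#' @param mat Combined quality-filtered `spectrum_matrix` (full axis; the
#'   carbohydrate region is sliced internally).
#' @param region Region used for the PCA (default carbohydrate).
#' @param manual_threshold Optional numeric threshold on PC1 scores
#'   overriding Otsu.
#' @param expect_bone Set FALSE for sections with no bone margin: all
#'   pixels are labelled cartilage and a warning is emitted.
#' @return List: `bone` (logical per matrix row), `scores` (PC1),
#'   `threshold`, `var_explained` (PC1 variance fraction), `origin`.
#' @export
bone_mask_pca <- function(mat, region = region_registry()$carbohydrate,
                          manual_threshold = NULL, expect_bone = TRUE) {
  sub <- slice_region(mat, region)
  if (!expect_bone) {
    warning("no bone margin expected: all pixels labelled cartilage")
    return(list(bone = rep(FALSE, nrow(sub$spectra)), scores = NULL,
                threshold = NA_real_, var_explained = NA_real_,
                origin = mat$origin))
  }
  pc <- stats::prcomp(sub$spectra, center = TRUE, scale. = FALSE)
  ve <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  if (ve < 0.05) warning(sprintf("weak interface contrast: PC1 explains %.1f%% variance",
                                 100 * ve))
  scores <- pc$x[, 1L]
  thr <- if (is.null(manual_threshold)) otsu_threshold(scores) else
    manual_threshold
  side <- scores > thr
  if (all(side) || all(!side)) stop("single-class threshold: no interface found")
  # the bottom margin (largest row index per image column) identifies bone
  key <- paste(mat$origin$sample_id, mat$origin$col)
  bottom <- unlist(lapply(split(seq_len(nrow(mat$origin)), key),
                          function(i) i[which.max(mat$origin$row[i])]))
  frac_hi <- mean(side[bottom])
  bone <- if (frac_hi >= 0.5) side else !side
  list(bone = bone, scores = scores, threshold = thr, var_explained = ve,
       origin = mat$origin)
}

#' Apply a bone mask to cubes
#'
#' Updates each cube's tissue mask: tissue = valid AND not bone.
#'
#' @param cubes List of cubes.
#' @param bm Result of [bone_mask_pca()].
#' @return Updated list of cubes.
#' @export
apply_bone_mask <- function(cubes, bm) {
  ids <- vapply(cubes, `[[`, "", "sample_id")
  for (k in seq_along(cubes)) {
    cube <- cubes[[k]]
    tm <- cube$valid_mask
    sel <- which(bm$origin$sample_id == ids[[k]])
    bone_px <- sel[bm$bone[sel]]
    tm[cbind(bm$origin$row[bone_px], bm$origin$col[bone_px])] <- FALSE
    # pixels absent from the combined matrix (quality-rejected) are not tissue
    present <- matrix(FALSE, nrow(tm), ncol(tm))
    present[cbind(bm$origin$row[sel], bm$origin$col[sel])] <- TRUE
    cube$tissue_mask <- tm & present
    cubes[[k]] <- cube
  }
  cubes
}

#' Normalized depth map
#'
#' Per image column (sections are oriented articular-surface-up), the first
#' tissue pixel from the top is the articular surface (d = 0) and the last
#' tissue pixel before bone is the tidemark (d = 100); depth is linear in
#' the row index between them. Columns with fewer than 3 tissue pixels are
#' excluded and reported.
#'
#' @param cube A `spectral_cube` with final tissue mask.
#' @return Object of class `depth_map`: list with `depth` (matrix, NA
#'   outside usable tissue), `surface_row`, `tidemark_row` (per column, NA
#'   when excluded), `excluded_cols`.
#' @export
compute_depth <- function(cube) {
  tm <- cube$tissue_mask & cube$valid_mask
  nr <- nrow(tm); nc <- ncol(tm)
  depth <- matrix(NA_real_, nr, nc)
  surf <- rep(NA_integer_, nc)
  tide <- rep(NA_integer_, nc)
  excluded <- integer(0)
  for (cc in seq_len(nc)) {
    rows <- which(tm[, cc])
    if (length(rows) < 3L) {
      if (length(rows) > 0L) excluded <- c(excluded, cc)
      next
    }
    s <- rows[1L]; t <- rows[length(rows)]
    surf[cc] <- s; tide[cc] <- t
    depth[rows, cc] <- 100 * (rows - s) / (t - s)
  }
  if (all(is.na(surf))) stop("no usable tissue columns in ", cube$sample_id)
  structure(list(sample_id = cube$sample_id, depth = depth,
                 surface_row = surf, tidemark_row = tide,
                 excluded_cols = excluded),
            class = "depth_map")
}

#' Zone definition
#'
#' Standard zones in percent thickness from the articular surface towards
#' the tidemark: surface 0-15, middle 15-65, deep 65-100 (the middle zone
#' is the complement of the surface and deep bounds). Intervals are closed,
#' so shared boundaries belong to both adjacent zones.
#'
#' @param name Zone name.
#' @param lo_pct,hi_pct Bounds in percent, `0 <= lo < hi <= 100`.
#' @return A `zone_def`.
#' @export
zone_def <- function(name, lo_pct, hi_pct) {
  stopifnot(lo_pct >= 0, hi_pct <= 100, lo_pct < hi_pct)
  structure(list(name = name, lo_pct = lo_pct, hi_pct = hi_pct),
            class = "zone_def")
}

#' @rdname zone_def
#' @export
default_zones <- function() {
  list(surface = zone_def("surface", 0, 15),
       middle = zone_def("middle", 15, 65),
       deep = zone_def("deep", 65, 100))
}

#' Pixels of a depth zone
#'
#' @param cube A `spectral_cube` (corrected spectra).
#' @param dm Its [compute_depth()] map.
#' @param zone A [zone_def()].
#' @return A `spectrum_matrix` of the pixels with
#'   `lo_pct <= d <= hi_pct` (closed interval).
#' @export
zone_pixels <- function(cube, dm, zone) {
  sel <- !is.na(dm$depth) & dm$depth >= zone$lo_pct & dm$depth <= zone$hi_pct
  if (!any(sel)) stop("empty zone '", zone$name, "' in ", cube$sample_id)
  px <- which(sel, arr.ind = TRUE)
  flat <- matrix(cube$absorbance, ncol = length(cube$axis))
  spectrum_matrix(flat[which(sel), , drop = FALSE], cube$axis,
                  data.frame(sample_id = rep(cube$sample_id, nrow(px)),
                             row = px[, 1L], col = px[, 2L],
                             stringsAsFactors = FALSE))
}

#' Depth-wise profile of a per-pixel parameter
#'
#' Tissue pixels are binned by normalized depth into `n_bins` equal-width
#' bins over [0, 100]; the profile is the per-bin mean. Empty bins are
#' reported as NA with a zero count.
#'
#' @param values Numeric vector of the per-pixel parameter.
#' @param depth Numeric vector of matching depths (NA entries dropped).
#' @param n_bins Number of bins (default 20).
#' @return Data frame: `bin`, `d_lo`, `d_hi`, `mean`, `n`.
#' @export
depth_profile <- function(values, depth, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  keep <- !is.na(depth) & !is.na(values)
  values <- values[keep]; depth <- depth[keep]
  edges <- seq(0, 100, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(depth, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  mean_b <- tapply(values, factor(bin, levels = seq_len(n_bins)), mean)
  n_b <- tapply(values, factor(bin, levels = seq_len(n_bins)), length)
  n_b[is.na(n_b)] <- 0L
  data.frame(bin = seq_len(n_bins), d_lo = edges[-length(edges)],
             d_hi = edges[-1L], mean = as.numeric(mean_b),
             n = as.integer(n_b))
}
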