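#' K-means clustering of a combined spectral matrix
#'
#' Lloyd's algorithm on the vector-normalized spectra of all samples
#' combined, restricted to a spectral region (the carbohydrate region by
#' default, which best exposes the layered structure of cartilage).
#' Centroids are initialized as K distinct spectra drawn uniformly at
#' random (seeded) from the matrix; assignment (nearest centroid, Euclidean
#' distance) and update (class mean) alternate for exactly `n_iter`
#' iterations or until the labels stabilize, whichever comes first. An
#' emptied cluster is re-seeded from the point farthest from its assigned
#' centroid. The algorithm runs once per seed, as a single-shot analysis.
#'
#' @param mat Vector-normalized `spectrum_matrix`.
#' @param region Clustering region (a `spectral_region`).
#' @param K Number of clusters (default 5).
#' @param n_iter Maximum Lloyd iterations (default 20).
#' @param seed Integer seed for centroid initialization.
#' @return Object of class `cluster_result`: `K`, `region`, `centroids`
#'   (K x region width), `labels`, `inertia` (sum of squared distances to
#'   assigned centroids), `inertia_trace` (per iteration, nonincreasing),
#'   `n_iter_run`, `converged`, `origin`, `axis` (region axis), `seed`.
#' @export
kmeans_combined <- function(mat, region = region_registry()$carbohydrate,
                            K = 5L, n_iter = 20L, seed = 1L) {
  sub <- slice_region(mat, region)
  X <- sub$spectra
  n <- nrow(X)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of spectra")
  init <- withr::with_seed(seed, sample.int(n, K))
  cen <- X[init, , drop = FALSE]
  xsq <- rowSums(X^2)
  labels <- rep(0L, n)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    d2 <- outer(xsq, rowSums(cen^2), `+`) - 2 * X %*% t(cen)
    new_labels <- max.col(-d2, ties.method = "first")
    mind <- d2[cbind(seq_len(n), new_labels)]
    # re-seed empty clusters from the farthest point
    for (k in seq_len(K)) {
      if (!any(new_labels == k)) {
        far <- which.max(mind)
        new_labels[far] <- k
        mind[far] <- 0
      }
    }
    trace <- c(trace, max(sum(mind), 0))
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
    for (k in seq_len(K)) {
      cen[k, ] <- colMeans(X[labels == k, , drop = FALSE])
    }
  }
  d2 <- outer(xsq, rowSums(cen^2), `+`) - 2 * X %*% t(cen)
  inertia <- max(sum(d2[cbind(seq_len(n), labels)]), 0)
  structure(list(K = K, region = region, centroids = cen, labels = labels,
                 inertia = inertia, inertia_trace = trace,
                 n_iter_run = it, converged = converged, origin = sub$origin,
                 axis = sub$axis, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> K = %d on %s region, %d spectra, inertia %.4g (%d iterations%s)\n",
              x$K, x$region$name, length(x$labels), x$inertia, x$n_iter_run,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Per-cluster mean spectra
#'
#' Cluster means over the full fingerprint axis (not only the clustering
#' region), plus the Savitzky-Golay second derivative of each mean, as used
#' to interpret what distinguishes the clusters.
#'
#' @param result A `cluster_result`.
#' @param full_mat The full-axis `spectrum_matrix` the clustering was run
#'   on (same row order).
#' @return List: `mean_spectra` (K x n_wavenumbers), `d2` (second
#'   derivatives of the means), `n` (cluster sizes), `axis`.
#' @export
cluster_mean_spectra <- function(result, full_mat) {
  stopifnot(nrow(full_mat$spectra) == length(result$labels))
  K <- result$K
  means <- matrix(NA_real_, K, ncol(full_mat$spectra))
  n <- integer(K)
  for (k in seq_len(K)) {
    sel <- result$labels == k
    n[k] <- sum(sel)
    if (n[k] > 0L) means[k, ] <- colMeans(full_mat$spectra[sel, , drop = FALSE])
  }
  list(mean_spectra = means,
       d2 = second_derivative(means, axis = full_mat$axis),
       n = n, axis = full_mat$axis)
}

#' Render a per-sample cluster label image
#'
#' @param result A `cluster_result`.
#' @param cube The sample's `spectral_cube` (for image dimensions).
#' @return Integer matrix (rows x cols): cluster index 1..K, 0 for
#'   background/removed pixels (rendered black).
#' @export
render_cluster_image <- function(result, cube) {
  sel <- which(result$origin$sample_id == cube$sample_id)
  if (length(sel) == 0L) stop("unknown sample: ", cube$sample_id)
  img <- matrix(0L, nrow(cube$valid_mask), ncol(cube$valid_mask))
  img[cbind(result$origin$row[sel], result$origin$col[sel])] <-
    result$labels[sel]
  img
}

#' Write a cluster image as an indexed-colour PNG
#'
#' Fixed 5-colour palette plus black background for removed pixels.
#'
#' @param img Integer label matrix from [render_cluster_image()].
#' @param path Output path.
#' @param palette Colours for clusters 1..K.
#' @export
write_cluster_png <- function(img, path,
                              palette = c("#2ca02c", "#7f7f7f", "#1f77b4",
                                          "#d62728", "#ff7f0e", "#9467bd",
                                          "#8c564b", "#e377c2")) {
  K <- max(img)
  if (K > length(palette)) stop("palette too small")
  cols <- grDevices::col2rgb(c("#000000", palette[seq_len(max(K, 1L))])) / 255
  arr <- array(0, dim = c(nrow(img), ncol(img), 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(cols[ch, img + 1L], nrow(img), ncol(img))
  }
  png::writePNG(arr, path)
  invisible(path)
}
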