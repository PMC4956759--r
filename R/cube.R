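#' Hyperspectral FTIR cube
#'
#' A per-sample pixel grid of absorbance spectra on a shared wavenumber axis,
#' with masks tracking spectral quality control (`valid_mask`) and tissue
#' segmentation (`tissue_mask`, TRUE = articular cartilage, FALSE =
#' bone/background). After the masking stage the tissue mask is a subset of
#' the valid mask.
#'
#' @param sample_id Sample identifier.
#' @param axis A `wn_axis` (or numeric vector) of length `dim(absorbance)[3]`.
#' @param absorbance 3-D array rows x cols x wavenumbers, absorbance units.
#' @param pixel_size Pixel edge length in micrometres (default 21.6, the
#'   binned spatial resolution of the imaging setup emulated here).
#' @param valid_mask,tissue_mask Logical rows x cols matrices; default all
#'   TRUE (quality filtering and segmentation refine them).
#' @param metadata Named list; `oarsi_grade` (histopathological OA severity,
#'   0-6 in 0.5 steps) is consumed by the grade models. Samples with grade
#'   above 4.5 are rejected: cartilage is denuded from grade 5 on, so such
#'   sections carry no cartilage signal to analyse.
#' @return Object of class `spectral_cube`.
#' @export
spectral_cube <- function(sample_id, axis, absorbance, pixel_size = 21.6,
                          valid_mask = NULL, tissue_mask = NULL,
                          metadata = list()) {
  axis <- as_wn_axis(axis)
  if (length(dim(absorbance)) != 3L) stop("absorbance must be a 3-D array")
  if (dim(absorbance)[3L] != length(axis)) {
    stop("axis/absorbance length mismatch: axis has ", length(axis),
         " points, cube has ", dim(absorbance)[3L])
  }
  nr <- dim(absorbance)[1L]; nc <- dim(absorbance)[2L]
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nr, nc)
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nr, nc)
  stopifnot(identical(dim(valid_mask), c(nr, nc)),
            identical(dim(tissue_mask), c(nr, nc)))
  g <- metadata$oarsi_grade
  if (!is.null(g)) {
    if (!(g %in% seq(0, 6, by = 0.5))) {
      stop("oarsi_grade must be in {0, 0.5, ..., 6}")
    }
    if (g > 4.5) stop("sample ", sample_id, ": OARSI grade > 4.5 not usable ",
                      "(cartilage denuded)")
  }
  if (any(!is.finite(absorbance[array_mask_index(valid_mask, length(axis))]))) {
    stop("absorbance must be finite on valid pixels")
  }
  structure(list(sample_id = as.character(sample_id), axis = axis,
                 absorbance = absorbance, pixel_size = pixel_size,
                 valid_mask = valid_mask, tissue_mask = tissue_mask,
                 metadata = metadata),
            class = "spectral_cube")
}

# linear indices into a rows x cols x nw array for all wavenumbers of the
# pixels where mask is TRUE
array_mask_index <- function(mask, nw) {
  px <- which(mask)
  if (length(px) == 0L) return(integer(0))
  npix <- length(mask)
  as.vector(outer(px, (seq_len(nw) - 1L) * npix, `+`))
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf("<spectral_cube> %s: %d x %d pixels, %d wavenumbers, %d valid, %d tissue\n",
              x$sample_id, d[1L], d[2L], d[3L], sum(x$valid_mask),
              sum(x$tissue_mask)))
  if (!is.null(x$metadata$oarsi_grade)) {
    cat(sprintf("  OARSI grade %.1f\n", x$metadata$oarsi_grade))
  }
  invisible(x)
}

#' Matrix of pixel spectra
#'
#' A `spectrum_matrix` holds one spectrum per row together with the origin
#' of each row (`sample_id`, `row`, `col`), so that results computed on a
#' combined multi-sample matrix can be rendered back into per-sample images.
#'
#' @param spectra n_pixels x n_wavenumbers numeric matrix.
#' @param axis A `wn_axis` matching `ncol(spectra)`.
#' @param origin Data frame with columns `sample_id`, `row`, `col`; origins
#'   must be unique.
#' @return Object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(spectra, axis, origin) {
  axis <- as_wn_axis(axis)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(axis)) stop("axis/spectra width mismatch")
  stopifnot(is.data.frame(origin),
            all(c("sample_id", "row", "col") %in% names(origin)),
            nrow(origin) == nrow(spectra))
  key <- paste(origin$sample_id, origin$row, origin$col)
  if (anyDuplicated(key)) stop("duplicate pixel origins")
  rownames(spectra) <- NULL
  structure(list(spectra = spectra, axis = axis, origin = origin),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d spectra x %d wavenumbers, %d sample(s)\n",
              nrow(x$spectra), ncol(x$spectra),
              length(unique(x$origin$sample_id))))
  invisible(x)
}

#' Unfold a cube (or several) into a spectrum matrix
#'
#' @param x A `spectral_cube`.
#' @param mask Which pixels to keep: `"valid"` (passed quality control) or
#'   `"tissue"` (cartilage pixels; implies valid after the masking stage).
#' @return A `spectrum_matrix`.
#' @export
as_spectrum_matrix <- function(x, mask = c("valid", "tissue")) {
  mask <- match.arg(mask)
  m <- if (mask == "valid") x$valid_mask else x$tissue_mask & x$valid_mask
  px <- which(m, arr.ind = TRUE)
  nw <- length(x$axis)
  sp <- matrix(x$absorbance, ncol = nw)[which(m), , drop = FALSE]
  spectrum_matrix(sp, x$axis,
                  data.frame(sample_id = rep(x$sample_id, nrow(px)),
                             row = px[, 1L], col = px[, 2L],
                             stringsAsFactors = FALSE))
}

#' Combine several cubes into one large data matrix
#'
#' Stacks the selected pixels of all samples into a single matrix, the form
#' in which clustering and PCA are run jointly across the cohort.
#'
#' @param cubes List of `spectral_cube` objects sharing one axis.
#' @param mask Passed to [as_spectrum_matrix()].
#' @return A `spectrum_matrix`.
#' @export
combine_cubes <- function(cubes, mask = c("valid", "tissue")) {
  mask <- match.arg(mask)
  mats <- lapply(cubes, as_spectrum_matrix, mask = mask)
  ax <- mats[[1L]]$axis
  for (m in mats) {
    if (!isTRUE(all.equal(as.numeric(m$axis), as.numeric(ax)))) {
      stop("cubes do not share a wavenumber axis")
    }
  }
  spectrum_matrix(do.call(rbind, lapply(mats, `[[`, "spectra")), ax,
                  do.call(rbind, lapply(mats, `[[`, "origin")))
}

#' Write corrected spectra back into cubes
#'
#' Replaces, pixel by pixel, the absorbance of each origin in `mat` inside
#' the corresponding cube. Used after scatter correction so downstream
#' stages read corrected spectra from the cubes.
#'
#' @param cubes Named or unnamed list of cubes.
#' @param mat A `spectrum_matrix` on the same axis.
#' @return The updated list of cubes.
#' @export
set_cube_spectra <- function(cubes, mat) {
  ids <- vapply(cubes, `[[`, "", "sample_id")
  nw <- ncol(mat$spectra)
  for (k in seq_along(cubes)) {
    sel <- which(mat$origin$sample_id == ids[[k]])
    if (length(sel) == 0L) next
    cube <- cubes[[k]]
    npix <- nrow(cube$valid_mask) * ncol(cube$valid_mask)
    px <- (mat$origin$col[sel] - 1L) * nrow(cube$valid_mask) +
      mat$origin$row[sel]
    flat <- matrix(cube$absorbance, ncol = nw)
    flat[px, ] <- mat$spectra[sel, , drop = FALSE]
    cube$absorbance <- array(flat, dim = dim(cube$absorbance))
    cubes[[k]] <- cube
  }
  cubes
}
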