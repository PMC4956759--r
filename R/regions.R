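#' Spectral region
#'
#' A named closed wavenumber interval used for integration, clustering, or
#' PCA. An axis point w belongs to the region iff `lo <= w <= hi` (closed on
#' both sides), so adjacent regions such as amide I and amide II share their
#' common boundary point when it lies on the grid.
#'
#' @param name Region name.
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return An object of class `spectral_region`.
#' @export
spectral_region <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!(lo < hi)) stop("spectral region requires lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "spectral_region")
}

#' @export
print.spectral_region <- function(x, ...) {
  cat(sprintf("<spectral_region> %s: [%g, %g] cm^-1\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Registry of the standard cartilage FTIR regions
#'
#' Returns the named spectral regions used throughout the analysis:
#' the carbohydrate region (985-1140 cm^-1, proteoglycan carbohydrate
#' residues), the extended carbohydrate region (950-1400), amide II
#' (1485-1585) and amide I (1585-1720, protein backbone, dominated by
#' collagen in cartilage), the CH2 side-chain region (1300-1360, the band
#' around 1338 cm^-1 used for collagen integrity), and the full fingerprint
#' region (950-1800).
#'
#' Amide I and amide II are contiguous at 1585 cm^-1; because regions are
#' closed intervals, a grid point at exactly 1585 would be counted in both.
#'
#' @param overrides Optional named list of `c(lo, hi)` pairs (or
#'   `spectral_region` objects) replacing or extending the defaults, e.g.
#'   from a configuration file.
#' @return Named list of `spectral_region` objects.
#' @examples
#' region_registry()[["carbohydrate"]]
#' @export
region_registry <- function(overrides = NULL) {
  defs <- list(
    carbohydrate          = c(985, 1140),
    extended_carbohydrate = c(950, 1400),
    amide_II              = c(1485, 1585),
    amide_I               = c(1585, 1720),
    ch2_side_chain        = c(1300, 1360),
    fingerprint           = c(950, 1800)
  )
  reg <- lapply(names(defs), function(nm) {
    spectral_region(nm, defs[[nm]][1L], defs[[nm]][2L])
  })
  names(reg) <- names(defs)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      reg[[nm]] <- if (inherits(ov, "spectral_region")) ov else
        spectral_region(nm, ov[[1L]], ov[[2L]])
    }
  }
  reg
}

region_index <- function(axis, region) {
  axis <- as_wn_axis(axis)
  idx <- which(axis >= region$lo & axis <= region$hi)
  if (length(idx) == 0L) {
    stop(sprintf("region outside axis: %s [%g, %g]", region$name,
                 region$lo, region$hi))
  }
  idx
}

#' Restrict spectra to a spectral region
#'
#' Keeps exactly the axis points w with `region$lo <= w <= region$hi`
#' (closed interval), preserving axis order. Slicing is idempotent.
#'
#' @param x A `spectrum_matrix` or `spectral_cube`. A cube is first unfolded
#'   to a matrix of its valid pixels (see [as_spectrum_matrix()]).
#' @param region A `spectral_region`.
#' @return A `spectrum_matrix` on the restricted axis.
#' @export
slice_region <- function(x, region) UseMethod("slice_region")

#' @export
slice_region.spectrum_matrix <- function(x, region) {
  idx <- region_index(x$axis, region)
  spectrum_matrix(x$spectra[, idx, drop = FALSE], wn_axis(as.numeric(x$axis)[idx]),
                  x$origin)
}

#' @export
slice_region.spectral_cube <- function(x, region) {
  slice_region(as_spectrum_matrix(x), region)
}
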