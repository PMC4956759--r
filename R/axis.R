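#' Wavenumber axis
#'
#' Constructs a validated wavenumber axis for FTIR spectra. The axis is stored
#' in ascending order (renderers may flip it for the spectroscopic convention
#' of descending wavenumber) and must be uniformly spaced, as produced by an
#' FTIR spectrometer at a fixed spectral resolution.
#'
#' @param values Numeric vector of wavenumbers in cm^-1, strictly monotone.
#' @return A numeric vector of class `wn_axis` with a `spacing` attribute
#'   (the nominal step in cm^-1).
#' @examples
#' ax <- wn_axis(seq(950, by = 4, length.out = 213))
#' axis_spacing(ax)
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("axis needs at least two points")
  d <- diff(values)
  if (any(d <= 0)) {
    if (all(d < 0)) {
      values <- rev(values)
      d <- -rev(d)
    } else {
      stop("axis must be strictly monotone")
    }
  }
  spacing <- mean(d)
  if (max(abs(d - spacing)) > 1e-9 * abs(spacing)) {
    stop("axis spacing not uniform (relative tolerance 1e-9)")
  }
  structure(values, spacing = spacing, class = "wn_axis")
}

#' Default fingerprint-region axis
#'
#' The working axis of the pipeline: 213 points starting at 950 cm^-1 with a
#' 4 cm^-1 step, covering the fingerprint region analysed throughout
#' (950-1800 cm^-1). The grid origin is anchored at 950, so band positions
#' such as 1064 or 1338 cm^-1 need not fall exactly on a grid point; peak
#' lookups snap to the nearest grid point.
#'
#' @param lo,step,n Start (cm^-1), step (cm^-1) and number of points.
#' @return A `wn_axis`.
#' @export
default_axis <- function(lo = 950, step = 4, n = 213L) {
  wn_axis(seq(lo, by = step, length.out = n))
}

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d points, %.6g to %.6g cm^-1, step %.6g cm^-1\n",
              length(x), x[[1L]], x[[length(x)]], axis_spacing(x)))
  invisible(x)
}

#' @rdname wn_axis
#' @param axis A `wn_axis`.
#' @export
axis_spacing <- function(axis) attr(axis, "spacing")

as_wn_axis <- function(x) {
  if (inherits(x, "wn_axis")) x else wn_axis(x)
}
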