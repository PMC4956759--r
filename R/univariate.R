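#' Integrated band area
#'
#' Trapezoidal integral of a spectrum over the grid points of a region,
#' optionally after a two-point linear baseline correction within the
#' region. Units AU * cm^-1.
#'
#' @param spectrum Numeric vector on `axis`.
#' @param region A `spectral_region`.
#' @param axis A `wn_axis`.
#' @param baseline `"none"` or `"two_point"`.
#' @return Scalar area.
#' @export
integrate_area <- function(spectrum, region, axis,
                           baseline = c("none", "two_point")) {
  baseline <- match.arg(baseline)
  axis <- as_wn_axis(axis)
  if (baseline == "two_point") {
    seg <- two_point_baseline(spectrum, region, axis)
    trapz_int(seg$axis, seg$values)
  } else {
    idx <- region_index(axis, region)
    if (length(idx) < 2L) stop("region has fewer than 2 points")
    trapz_int(as.numeric(axis)[idx], spectrum[idx])
  }
}

trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Collagen integrity parameter
#'
#' Ratio of the baseline-corrected integrated CH2 side-chain band
#' (1300-1360 cm^-1, the band around 1338 cm^-1 arising from the collagen
#' triple helix) to the baseline-corrected amide II band (1485-1585 cm^-1).
#' Both regions receive a two-point linear baseline individually, which
#' makes the ratio invariant to any global linear baseline. The parameter
#' decreases as the collagen network is denatured.
#'
#' @inheritParams integrate_area
#' @param eps Denominators at or below this are undefined; `NA` is returned
#'   and the pixel should be excluded from summaries.
#' @return Scalar ratio, or `NA` when undefined.
#' @export
collagen_integrity <- function(spectrum, axis, eps = 1e-10) {
  reg <- region_registry()
  num <- integrate_area(spectrum, reg$ch2_side_chain, axis, "two_point")
  den <- integrate_area(spectrum, reg$amide_II, axis, "two_point")
  if (!is.finite(den) || den <= eps) return(NA_real_)
  num / den
}

#' Second-derivative peak value
#'
#' Locates the minimum of a second-derivative spectrum within
#' `center +- search_halfwidth` (band centres such as 1064 or 1202 cm^-1
#' need not fall on the grid) and returns its negation, so that larger
#' values mean more absorbing material.
#'
#' @param spectrum_d2 Second-derivative spectrum on `axis`.
#' @param center Peak position, cm^-1.
#' @param axis A `wn_axis`.
#' @param search_halfwidth Search half-window, cm^-1 (default 8).
#' @return Negated second derivative at the located minimum (AU/cm^-2).
#' @export
d2_peak <- function(spectrum_d2, center, axis, search_halfwidth = 8) {
  axis <- as_wn_axis(axis)
  idx <- which(axis >= center - search_halfwidth &
               axis <= center + search_halfwidth)
  if (length(idx) == 0L) stop("search window outside axis")
  -min(spectrum_d2[idx])
}

#' Per-pixel univariate parameters
#'
#' Computes, for every spectrum of a matrix, the six univariate parameters:
#' integrated amide I area (collagen content), integrated carbohydrate area
#' (proteoglycan content), their ratio (thickness-invariant PG estimate),
#' the collagen integrity ratio, and the negated second-derivative peaks at
#' 1202 cm^-1 (collagen) and 1064 cm^-1 (PG).
#'
#' @param mat `spectrum_matrix` of corrected spectra.
#' @param d2 Optional matching second-derivative matrix (computed when
#'   missing).
#' @param sg_window,sg_polyorder Savitzky-Golay settings when `d2` missing.
#' @return Data frame: origin columns plus `amide_I_area`,
#'   `carbohydrate_area`, `carb_over_amideI`, `collagen_integrity`,
#'   `d2_1202`, `d2_1064`.
#' @export
pixel_params <- function(mat, d2 = NULL, sg_window = 9L, sg_polyorder = 3L) {
  reg <- region_registry()
  axis <- mat$axis
  if (is.null(d2)) d2 <- second_derivative(mat, sg_window, sg_polyorder)
  ai <- apply(mat$spectra, 1L, integrate_area, region = reg$amide_I,
              axis = axis)
  ca <- apply(mat$spectra, 1L, integrate_area, region = reg$carbohydrate,
              axis = axis)
  ci <- apply(mat$spectra, 1L, collagen_integrity, axis = axis)
  p1202 <- apply(d2$spectra, 1L, d2_peak, center = 1202, axis = axis)
  p1064 <- apply(d2$spectra, 1L, d2_peak, center = 1064, axis = axis)
  ratio <- ifelse(abs(ai) > 1e-10, ca / ai, NA_real_)
  cbind(mat$origin,
        data.frame(amide_I_area = ai, carbohydrate_area = ca,
                   carb_over_amideI = ratio, collagen_integrity = ci,
                   d2_1202 = p1202, d2_1064 = p1064))
}

#' Zonal summary of univariate parameters
#'
#' Mean of each per-pixel parameter over the pixels of a depth zone.
#' Undefined (NA) ratios are excluded parameter-wise rather than imputed;
#' the pixel count reported is the zone size.
#'
#' @param params Data frame from [pixel_params()] for one sample.
#' @param dm The sample's [compute_depth()] map.
#' @param zone A [zone_def()].
#' @return One-row data frame of means plus `n_pixels`.
#' @export
zone_summary <- function(params, dm, zone) {
  d <- dm$depth[cbind(params$row, params$col)]
  sel <- !is.na(d) & d >= zone$lo_pct & d <= zone$hi_pct
  if (!any(sel)) stop("empty zone '", zone$name, "'")
  cols <- c("amide_I_area", "carbohydrate_area", "carb_over_amideI",
            "collagen_integrity", "d2_1202", "d2_1064")
  sub <- params[sel, cols, drop = FALSE]
  if (all(is.na(sub$collagen_integrity))) {
    stop("all pixels undefined in zone '", zone$name, "'")
  }
  out <- as.data.frame(lapply(sub, mean, na.rm = TRUE))
  out$n_pixels <- sum(sel)
  out$zone <- zone$name
  out
}
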