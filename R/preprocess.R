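#' Spectral quality thresholds
#'
#' Criteria for per-pixel quality control: minimum and maximum amide I peak
#' absorbance (too little material / detector saturation) and a minimum
#' signal-to-noise ratio. SNR is the amide I peak height divided by the
#' standard deviation of the linearly detrended signal in the
#' 1760-1800 cm^-1 window, a band free of matrix absorptions. A small noise
#' floor is added to the denominator so noise-free synthetic spectra give a
#' finite, very large SNR.
#'
#' @param min_peak,max_peak Amide I peak bounds, AU.
#' @param min_snr Minimum SNR (unitless).
#' @param noise_window `c(lo, hi)` of the noise-estimation window, cm^-1.
#' @return A `quality_thresholds` list.
#' @export
quality_thresholds <- function(min_peak = 0.1, max_peak = 2.0, min_snr = 10,
                               noise_window = c(1760, 1800)) {
  stopifnot(min_peak >= 0, min_peak < max_peak, min_snr > 0)
  structure(list(min_peak = min_peak, max_peak = max_peak, min_snr = min_snr,
                 noise_window = noise_window),
            class = "quality_thresholds")
}

#' Quality filter
#'
#' Marks poor-quality pixels invalid. A pixel fails if its amide I maximum
#' is below `min_peak`, above `max_peak`, or its SNR is below `min_snr`.
#' Failed pixels are removed from all downstream stages and render black in
#' cluster images.
#'
#' @param cube A `spectral_cube` (raw).
#' @param thresholds A [quality_thresholds()].
#' @return List with `cube` (valid_mask updated; tissue_mask intersected
#'   with it) and `report` (data frame of rejected pixels with reasons; an
#'   empty surviving set is allowed but visible in the report).
#' @export
quality_filter <- function(cube, thresholds = quality_thresholds()) {
  reg <- region_registry()
  ai <- region_index(cube$axis, reg$amide_I)
  nw_reg <- spectral_region("noise_window", thresholds$noise_window[1L],
                            thresholds$noise_window[2L])
  nz <- region_index(cube$axis, nw_reg)
  flat <- matrix(cube$absorbance, ncol = length(cube$axis))
  peak <- apply(flat[, ai, drop = FALSE], 1L, max)
  w <- as.numeric(cube$axis)[nz]
  # sd of residuals about a straight line fit in the noise window
  X <- cbind(1, w - mean(w))
  H <- X %*% solve(crossprod(X), t(X))
  res <- flat[, nz, drop = FALSE] - flat[, nz, drop = FALSE] %*% t(H)
  noise <- sqrt(rowSums(res^2) / (length(nz) - 2L))
  snr <- peak / (noise + 1e-8)

  fail_low <- peak < thresholds$min_peak
  fail_high <- peak > thresholds$max_peak
  fail_snr <- !fail_low & !fail_high & snr < thresholds$min_snr
  ok <- matrix(!(fail_low | fail_high | fail_snr),
               nrow = nrow(cube$valid_mask))
  rej <- which(!ok & cube$valid_mask, arr.ind = TRUE)
  lin <- which(!ok & cube$valid_mask)
  reason <- ifelse(fail_low[lin], "low_peak",
                   ifelse(fail_high[lin], "saturated", "low_snr"))
  report <- data.frame(sample_id = rep(cube$sample_id, nrow(rej)),
                       row = rej[, 1L], col = rej[, 2L], reason = reason,
                       peak = peak[lin], snr = snr[lin],
                       stringsAsFactors = FALSE)
  cube$valid_mask <- cube$valid_mask & ok
  cube$tissue_mask <- cube$tissue_mask & cube$valid_mask
  list(cube = cube, report = report)
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Scatter correction: each spectrum s is fitted by least squares as
#' `s ~ b * reference + polynomial baseline in wavenumber`, and corrected
#' as `(s - baseline) / b`. This removes the per-pixel multiplicative
#' scatter scale and smooth additive baselines; it is the documented,
#' non-iterative stand-in for a full resonant-Mie correction, sufficient
#' because all downstream contracts depend only on the removal of
#' multiplicative/additive artifacts. Correction is scale-equivariant
#' (correcting `k*s`, k > 0, gives the same output as correcting `s`) and
#' leaves the reference spectrum itself fixed.
#'
#' @param mat A `spectrum_matrix` of quality-passing spectra.
#' @param reference Reference spectrum; default the column mean of `mat`
#'   (cohort mean spectrum).
#' @param baseline_order Polynomial baseline order (default 2).
#' @param b_tol Fits with scale `b <= b_tol` are degenerate; those pixels
#'   are flagged instead of corrected.
#' @return List: `corrected` (`spectrum_matrix`), `b` (scales), `baseline`
#'   (coefficient matrix), `reference`, `degenerate` (logical; TRUE rows
#'   are returned uncorrected and must be dropped by the caller).
#' @export
emsc_correct <- function(mat, reference = NULL, baseline_order = 2L,
                         b_tol = 1e-6) {
  X <- mat$spectra
  if (is.null(reference)) reference <- colMeans(X)
  stopifnot(length(reference) == ncol(X))
  w <- as.numeric(mat$axis)
  ws <- (w - mean(w)) / (diff(range(w)) / 2)     # scaled to [-1, 1]
  P <- outer(ws, 0:baseline_order, `^`)
  D <- cbind(ref = reference, P)
  # least squares for all spectra at once: coef = (D'D)^-1 D' s
  coef <- t(solve(crossprod(D), crossprod(D, t(X))))
  b <- coef[, 1L]
  degenerate <- b <= b_tol
  baseline <- coef[, -1L, drop = FALSE] %*% t(P)
  corrected <- (X - baseline) / ifelse(degenerate, 1, b)
  corrected[degenerate, ] <- X[degenerate, ]
  list(corrected = spectrum_matrix(corrected, mat$axis, mat$origin),
       b = b, baseline = coef[, -1L, drop = FALSE], reference = reference,
       degenerate = degenerate)
}

#' Vector normalization
#'
#' Scales every spectrum to unit Euclidean norm, removing differences in
#' the amount of material (section thickness) so that clustering compares
#' only spectral shape.
#'
#' @param mat A `spectrum_matrix`.
#' @return A `spectrum_matrix` with unit-norm rows.
#' @export
vector_normalize <- function(mat) {
  n <- sqrt(rowSums(mat$spectra^2))
  zero <- n < .Machine$double.eps^0.5
  if (any(zero)) {
    o <- mat$origin[which(zero)[1L], ]
    stop(sprintf("zero-norm spectrum at %s (%d, %d)", o$sample_id, o$row,
                 o$col))
  }
  spectrum_matrix(mat$spectra / n, mat$axis, mat$origin)
}

#' Savitzky-Golay second-derivative operator
#'
#' Builds the dense matrix applying a Savitzky-Golay second derivative
#' (window `window`, polynomial order `polyorder`) to a spectrum sampled on
#' a uniform axis. Interior points use the central filter; the first and
#' last `(window-1)/2` points use the one-sided polynomial fits, so the
#' output has the same length as the input (no truncation).
#'
#' @param axis Uniform `wn_axis`.
#' @param window Odd window length (default 9 smoothing points).
#' @param polyorder Polynomial order (default 3), `window >= polyorder + 1`.
#' @param deriv Derivative order (default 2).
#' @return `n x n` matrix `Dm`; `x %*% t(Dm)` differentiates rows of `x`,
#'   in AU per cm^-1 to the power `deriv`.
#' @export
sg_operator <- function(axis, window = 9L, polyorder = 3L, deriv = 2L) {
  axis <- as_wn_axis(axis)
  n <- length(axis)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window < polyorder + 1L) stop("window must be >= polyorder + 1")
  if (window > n) stop("window larger than axis")
  FF <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv,
                               ts = axis_spacing(axis)))
  h <- (window + 1L) %/% 2L
  Dm <- matrix(0, n, n)
  for (r in seq_len(h - 1L)) Dm[r, seq_len(window)] <- FF[r, ]
  for (r in h:(n - h + 1L)) Dm[r, (r - h + 1L):(r + h - 1L)] <- FF[h, ]
  for (r in (n - h + 2L):n) Dm[r, (n - window + 1L):n] <- FF[window - (n - r), ]
  Dm
}

#' Row-wise Savitzky-Golay second derivative
#'
#' Second-derivative spectroscopy sharpens overlapping bands: an absorbance
#' band becomes a negative minimum at its centre. Output units are
#' AU/cm^-2. The operator is linear, so it commutes with scalar
#' multiplication and annihilates any added linear function of wavenumber.
#'
#' @param mat A `spectrum_matrix` (or plain matrix with `axis` given).
#' @param window,polyorder See [sg_operator()].
#' @param axis Required when `mat` is a plain matrix.
#' @return Same type as `mat`, containing second derivatives.
#' @export
second_derivative <- function(mat, window = 9L, polyorder = 3L, axis = NULL) {
  if (inherits(mat, "spectrum_matrix")) {
    Dm <- sg_operator(mat$axis, window, polyorder, 2L)
    spectrum_matrix(mat$spectra %*% t(Dm), mat$axis, mat$origin)
  } else {
    Dm <- sg_operator(as_wn_axis(axis), window, polyorder, 2L)
    mat %*% t(Dm)
  }
}

#' Two-point linear baseline correction
#'
#' Subtracts the straight line through the first and last points of the
#' regional segment of a spectrum, mapping both endpoints to exactly zero.
#' Used inside the collagen-integrity parameter, where the CH2 side-chain
#' and amide II regions are baseline-corrected individually.
#'
#' @param spectrum Numeric vector on `axis`.
#' @param region A `spectral_region`.
#' @param axis A `wn_axis`.
#' @return List: `values` (corrected segment), `axis` (segment wavenumbers).
#' @export
two_point_baseline <- function(spectrum, region, axis) {
  axis <- as_wn_axis(axis)
  idx <- region_index(axis, region)
  if (length(idx) < 3L) stop("region has fewer than 3 points")
  w <- as.numeric(axis)[idx]
  y <- spectrum[idx]
  n <- length(idx)
  base <- y[1L] + (y[n] - y[1L]) * (w - w[1L]) / (w[n] - w[1L])
  list(values = y - base, axis = w)
}
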