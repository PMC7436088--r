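#' An emission spectrum
#'
#' @param wavelengths nm, strictly increasing, at least 10 points.
#' @param intensities arbitrary units, non-negative, same length.
#' @return an `mp_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities) {
  if (length(wavelengths) != length(intensities))
    stopf("wavelengths and intensities must have equal length")
  if (length(wavelengths) < 10) stopf("a spectrum needs at least 10 points")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (any(intensities < 0)) stopf("negative intensities")
  structure(list(wavelength = as.numeric(wavelengths),
                 intensity = as.numeric(intensities)),
            class = "mp_spectrum")
}

#' Read a 2-column spectrum CSV (wavelength_nm, intensity)
#' @param path CSV file.
#' @return an `mp_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stopf("spectrum CSV needs two columns")
  emission_spectrum(df[[1]], df[[2]])
}

#' Dual-band I(N*)/I(T*) ratio of an emission spectrum
#'
#' Locates the N* (short-wavelength, polarity-sensitive) and T* (tautomer)
#' band maxima of an ESIPT emitter within two disjoint wavelength windows
#' after light smoothing (moving average, 5 points), and reports their
#' intensity ratio. If the T* window holds no local maximum distinct from
#' its edges — the protic-solvent situation where the two bands merge into
#' one — the result is flagged `single_band` and no ratio is reported.
#' Ties between equal maxima resolve to the shorter wavelength.
#'
#' The default windows bracket the observed N* emission span (475-551 nm
#' across solvents) and the confocal detection channels.
#'
#' @param spectrum an `mp_spectrum`.
#' @param window_N,window_T nm intervals `c(lo, hi)`, disjoint, overlapping
#'   the wavelength grid.
#' @param smooth_width moving-average width in grid points.
#' @return an `mp_band_ratio`: `lambda_N`, `I_N`, `lambda_T`, `I_T`,
#'   `ratio`, `single_band`.
#' @export
band_ratio <- function(spectrum, window_N = c(460, 540),
                       window_T = c(545, 650), smooth_width = 5) {
  stopifnot(inherits(spectrum, "mp_spectrum"))
  wl <- spectrum$wavelength
  in_N <- which(wl >= window_N[1] & wl <= window_N[2])
  in_T <- which(wl >= window_T[1] & wl <= window_T[2])
  if (length(in_N) == 0 || length(in_T) == 0)
    stopf("configuration error: a window lies outside the wavelength grid")
  if (window_N[2] >= window_T[1] && window_T[2] >= window_N[1])
    if (max(window_N[1], window_T[1]) <= min(window_N[2], window_T[2]))
      stopf("configuration error: windows must be disjoint")
  sm <- moving_average(spectrum$intensity, smooth_width)

  iN <- in_N[which.max(sm[in_N])]
  iT <- in_T[which.max(sm[in_T])]
  # T* must be a genuine interior maximum, not a shoulder at the window edge
  at_edge <- iT == in_T[1] || iT == in_T[length(in_T)]
  interior_max <- !at_edge &&
    sm[iT] >= sm[iT - 1] && sm[iT] >= sm[iT + 1] &&
    (sm[iT] > sm[iT - 1] || sm[iT] > sm[iT + 1])
  if (!interior_max) {
    return(structure(list(lambda_N = wl[iN], I_N = sm[iN],
                          lambda_T = NA_real_, I_T = NA_real_,
                          ratio = NA_real_, single_band = TRUE),
                     class = "mp_band_ratio"))
  }
  structure(list(lambda_N = wl[iN], I_N = sm[iN],
                 lambda_T = wl[iT], I_T = sm[iT],
                 ratio = sm[iN] / sm[iT], single_band = FALSE),
            class = "mp_band_ratio")
}

#' @export
print.mp_band_ratio <- function(x, ...) {
  if (x$single_band)
    cat(sprintf("Single emission band at %.0f nm (no resolved T* maximum)\n",
                x$lambda_N))
  else
    cat(sprintf("I(N*)/I(T*) = %.3f  (N* %.0f nm, T* %.0f nm)\n",
                x$ratio, x$lambda_N, x$lambda_T))
  invisible(x)
}

read_channel <- function(x) {
  if (is.character(x)) {
    ext <- tolower(tools::file_ext(x))
    x <- switch(ext,
      png = png::readPNG(x),
      tif = ,
      tiff = tiff::readTIFF(x),
      stopf("unsupported image format '.%s'", ext))
    if (length(dim(x)) == 3) x <- x[, , 1]  # first channel of RGB(A)
  }
  m <- as.matrix(x)
  if (any(m < 0)) stopf("negative pixel intensities")
  m
}

#' Pixelwise I(N*)/I(T*) ratio of a two-channel vesicle image
#'
#' The membrane mask is the set of pixels whose summed two-channel
#' intensity exceeds `threshold_fraction` of the image pair's maximum
#' summed intensity — a simple scheme that isolates the bright membrane
#' annulus of a vesicle. On the mask the per-pixel ratio `N/T` is computed
#' (pixels with zero T are excluded and counted) and averaged.
#'
#' @param ch_N,ch_T matrices of equal shape, or PNG/TIFF file paths; the
#'   N* channel (e.g. 477-527 nm emission) and T* channel (550-600 nm).
#' @param threshold_fraction mask threshold in `(0, 1)` (default 0.2).
#' @return list with `ratio_map` (matrix, `NA` off-mask), `mean_ratio`,
#'   `n_mask`, `n_zero_T`.
#' @export
image_band_ratio <- function(ch_N, ch_T, threshold_fraction = 0.2) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stopf("threshold_fraction must be in (0, 1)")
  N <- read_channel(ch_N); T_ <- read_channel(ch_T)
  if (!all(dim(N) == dim(T_))) stopf("channel images differ in shape")
  s <- N + T_
  mask <- s > threshold_fraction * max(s)
  if (!any(mask)) stopf("no signal: empty membrane mask")
  zeroT <- mask & T_ == 0
  use <- mask & T_ > 0
  if (!any(use)) stopf("no signal: all masked T* pixels are zero")
  rmap <- matrix(NA_real_, nrow(N), ncol(N))
  rmap[use] <- N[use] / T_[use]
  list(ratio_map = rmap, mean_ratio = mean(rmap[use]),
       n_mask = sum(mask), n_zero_T = sum(zeroT))
}
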