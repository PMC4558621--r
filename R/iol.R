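# Intraocular-length (axial-length) measurement from the composite A-scan of
# a dual-reference-arm scan: the foveal RPE reflection sits near the
# zero-delay line, the corneal reflection at optical-path separation d beyond
# it, and IOL = (delta_L_ref - d) / n with the whole-eye group index n.

#' Detect the foveal and corneal peaks in a composite A-scan
#'
#' Local maxima above `min_peak_ratio` times the median amplitude qualify.
#' The foveal peak is the strongest qualifying maximum within the retinal
#' portion of the window (first `retinal_frac` of samples); the corneal peak
#' is the strongest maximum at least `min_sep_px` beyond it. Both are refined
#' to subpixel by a parabolic fit.
#'
#' @param ascan A `composite_ascan` (see [render_composite_ascan()]) or a
#'   plain numeric amplitude vector plus `axial_spacing_air_um`.
#' @param retinal_frac Fraction of the window holding the retina.
#' @param min_peak_ratio Peak qualification threshold over the median.
#' @param min_sep_px Minimum fovea-to-cornea separation, samples.
#' @param axial_spacing_air_um Spacing when `ascan` is a bare vector.
#' @return List with `fovea_px`, `cornea_px` (subpixel sample positions) and
#'   `d_mm` (optical-path separation).
#' @export
detect_peaks <- function(ascan, retinal_frac = 0.4, min_peak_ratio = 5,
                         min_sep_px = 10, axial_spacing_air_um = NULL) {
  if (inherits(ascan, "composite_ascan")) {
    a <- ascan$amplitude
    sp <- ascan$axial_spacing_air_um
  } else {
    a <- as.numeric(ascan)
    sp <- axial_spacing_air_um
    if (is.null(sp)) stop("axial_spacing_air_um required for a bare vector")
  }
  n <- length(a)
  thr <- min_peak_ratio * stats::median(a)
  i <- 2:(n - 1)
  is_max <- a[i] > a[i - 1] & a[i] >= a[i + 1] & a[i] > thr
  peaks <- i[is_max]
  if (length(peaks) < 2)
    stop("no corneal signal: fewer than 2 qualifying peaks")
  retinal <- peaks[peaks <= retinal_frac * n]
  if (!length(retinal))
    stop("no foveal peak in the retinal portion of the window")
  fovea <- retinal[which.max(a[retinal])]
  beyond <- peaks[peaks > fovea + min_sep_px]
  if (!length(beyond))
    stop("no corneal signal beyond the foveal peak")
  cornea <- beyond[which.max(a[beyond])]
  refine <- function(p) p + parabolic_offset(a[p - 1], a[p], a[p + 1])
  fovea_px <- refine(fovea)
  cornea_px <- refine(cornea)
  list(fovea_px = fovea_px, cornea_px = cornea_px,
       d_mm = (cornea_px - fovea_px) * sp / 1000)
}

#' Intraocular length from the peak separation
#'
#' `IOL = (delta_L_ref - d) / n`: the reference-mirror offset minus the
#' measured optical-path separation between the foveal and corneal peaks,
#' scaled by the whole-eye group refractive index.
#'
#' @param d_mm Optical-path separation fovea to cornea, mm.
#' @param delta_L_ref Reference-mirror offset, mm.
#' @param n_index Group refractive index (>= 1).
#' @return IOL in mm (full precision; round to 3 decimals for presentation).
#' @export
compute_iol <- function(d_mm, delta_L_ref = 35, n_index = 1.3375) {
  stopifnot(n_index >= 1, delta_L_ref > 0)
  if (any(d_mm < 0)) stop("peak separation d must be >= 0")
  if (any(d_mm >= delta_L_ref))
    stop("peak separation d must be smaller than delta_L_ref")
  (delta_L_ref - d_mm) / n_index
}

#' Measure IOL from a composite A-scan
#'
#' Convenience wrapper: [detect_peaks()] then [compute_iol()] with the
#' geometry stored in the A-scan.
#'
#' @param ascan A `composite_ascan`.
#' @param ... Passed to [detect_peaks()].
#' @return List with `d_mm`, `iol_mm`, `fovea_px`, `cornea_px`.
#' @export
measure_iol <- function(ascan, ...) {
  stopifnot(inherits(ascan, "composite_ascan"))
  pk <- detect_peaks(ascan, ...)
  list(d_mm = pk$d_mm,
       iol_mm = compute_iol(pk$d_mm, ascan$delta_L_ref, ascan$n_index),
       fovea_px = pk$fovea_px, cornea_px = pk$cornea_px)
}
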