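# Inter-B-scan axial motion correction. Adjacent B-scans are compared through
# their laterally averaged axial profiles; the normalized cross-correlation
# peak gives the relative axial shift, refined to subpixel by parabolic
# interpolation. Shifts are chained (cumulative, referenced to the first
# B-scan) and applied as integer rolls so no interpolation blur is introduced.

#' Estimate the axial shift between two A-scan profiles
#'
#' Finds the integer lag in `[-max_shift, max_shift]` maximizing the Pearson
#' correlation between the overlapping parts of the profiles, then refines it
#' by a parabolic fit through the correlation peak. A positive result means
#' `b` is `a` shifted deeper.
#'
#' @param profile_a,profile_b Mean axial profiles of two adjacent B-scans
#'   (equal length, at least 3 samples).
#' @param max_shift Search half-range in pixels (>= 1).
#' @return Shift in pixels (float). If either profile has zero variance the
#'   estimate is 0 with attribute `flat = TRUE` and a warning.
#' @export
estimate_axial_shift <- function(profile_a, profile_b, max_shift = 8L) {
  n <- length(profile_a)
  stopifnot(length(profile_b) == n, n >= 3, max_shift >= 1)
  if (stats::var(profile_a) == 0 || stats::var(profile_b) == 0) {
    warning("constant profile: returning zero shift")
    return(structure(0, flat = TRUE))
  }
  max_shift <- min(as.integer(max_shift), n - 3L)
  lags <- seq(-max_shift, max_shift)
  ncc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- profile_a[1:(n - k)]; b <- profile_b[(1 + k):n]
    } else {
      a <- profile_a[(1 - k):n]; b <- profile_b[1:(n + k)]
    }
    if (stats::var(a) == 0 || stats::var(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  # ties broken toward the smaller |lag|
  ord <- order(-ncc, abs(lags))
  best <- ord[1]
  shift <- lags[best]
  # a perfect-correlation peak is an exact integer shift; refine only below it
  if (ncc[best] < 1 - 1e-12 && best > 1 && best < length(lags) &&
      is.finite(ncc[best - 1]) && is.finite(ncc[best + 1])) {
    shift <- shift + parabolic_offset(-ncc[best - 1], -ncc[best],
                                      -ncc[best + 1])
  }
  shift
}

#' Correct per-B-scan axial motion in a volume
#'
#' Estimates the shift between every adjacent B-scan pair from their mean
#' axial profiles, chains the estimates into a cumulative trace referenced to
#' the first B-scan, and rolls each B-scan by the negated rounded cumulative
#' shift. Vacated rows are filled with the volume's noise-floor median
#' (median of the top rows, above the retina).
#'
#' @param vol An `oct_volume` with at least 2 B-scans.
#' @param max_shift Per-pair search half-range, pixels.
#' @return List with `volume` (corrected `oct_volume`) and `trace`
#'   (cumulative subpixel shift estimates, first entry 0).
#' @export
correct_motion <- function(vol, max_shift = 8L) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity)
  nz <- d[1]; ny <- d[3]
  if (ny < 2) stop("motion correction needs at least 2 B-scans")
  profiles <- apply(vol$intensity, 3L, rowMeans)   # nz x ny
  rel <- numeric(ny - 1L)
  for (j in 2:ny) {
    rel[j - 1L] <- suppressWarnings(
      estimate_axial_shift(profiles[, j - 1L], profiles[, j], max_shift))
  }
  trace <- c(0, cumsum(rel))
  shifts <- -round(trace)
  if (any(abs(shifts) >= nz))
    stop("cumulative shift exceeds the axial extent of the volume")
  floor_med <- stats::median(vol$intensity[seq_len(min(8L, nz)), , ])
  out <- vol$intensity
  for (j in seq_len(ny)) {
    t <- shifts[j]
    if (t != 0) {
      page <- matrix(floor_med, nz, d[2])
      if (t > 0) page[(t + 1):nz, ] <- vol$intensity[1:(nz - t), , j]
      else page[1:(nz + t), ] <- vol$intensity[(1 - t):nz, , j]
      out[, , j] <- page
    }
  }
  corrected <- vol
  corrected$intensity <- out
  list(volume = corrected, trace = trace)
}
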