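# Choroidal-thickness mapping: fovea localization from the ILM pit, thickness
# measured along the local RPE normal by ray casting onto the CSI surface,
# the nine-sector 1/5/10 mm geographic summary, and the 1 mm nasal-temporal
# ring profile. All physical work happens in geometric um (axial pixel pitch
# divided by the tissue refractive index); laterality is normalized here so
# "nasal" always points toward the optic disc.

new_thickness_map <- function(ct, valid, fovea_xy, sx_mm, sy_mm, laterality) {
  structure(list(ct = ct, valid = valid, fovea_xy = fovea_xy,
                 lateral_spacing_x_mm = sx_mm, lateral_spacing_y_mm = sy_mm,
                 laterality = laterality), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d, %.0f%% valid, fovea (%.2f, %.2f) mm, %s\n",
              nrow(x$ct), ncol(x$ct), 100 * mean(x$valid),
              x$fovea_xy[1], x$fovea_xy[2], x$laterality))
  invisible(x)
}

#' Locate the fovea from the ILM pit
#'
#' The fovea is the centre of the deepest local depression of the inner
#' limiting membrane. The ILM depth map is Gaussian-smoothed at a fine scale
#' (sigma 0.25 mm) and a coarse-trend smooth (sigma 1.5 mm) is subtracted so
#' the overall posterior-pole curvature cancels (a quadratic surface is
#' invariant up to a constant under both smooths); the pit is the maximum of
#' this relative depth within the central `central_frac` of the scan, refined
#' as the centre of mass of the deepest 5% of pit pixels.
#'
#' @param ilm An ILM `surface_map` (at least 50% valid).
#' @param sx_mm,sy_mm Lateral spacings, mm.
#' @param axial_um_per_px Geometric um per axial pixel
#'   (air pitch / tissue index).
#' @param central_frac Central fraction of the scan searched for the pit.
#' @param min_pit_um Minimum relative pit depth; below it there is no pit.
#' @return `c(x_mm, y_mm)` in centred scanner-frame coordinates.
#' @export
locate_fovea <- function(ilm, sx_mm, sy_mm, axial_um_per_px,
                         central_frac = 0.6, min_pit_um = 5) {
  stopifnot(inherits(ilm, "surface_map"))
  if (mean(ilm$valid) < 0.5)
    stop("ILM surface is less than 50% valid")
  z <- ilm$z
  nx <- nrow(z); ny <- ncol(z)
  fine <- smooth_gauss_na(z, 0.25 / sx_mm, 0.25 / sy_mm)
  trend <- smooth_gauss_na(z, 1.5 / sx_mm, 1.5 / sy_mm)
  pitmap <- fine - trend
  cx <- seq_len(nx)[abs(seq_len(nx) - (nx + 1) / 2) <= central_frac * nx / 2]
  cy <- seq_len(ny)[abs(seq_len(ny) - (ny + 1) / 2) <= central_frac * ny / 2]
  central <- pitmap[cx, cy, drop = FALSE]
  if (!any(is.finite(central))) stop("no valid ILM in the central scan region")
  rng <- diff(range(central, na.rm = TRUE)) * axial_um_per_px
  if (!is.finite(rng) || rng < min_pit_um)
    stop("no foveal pit detected (flat ILM); supply the centre manually")
  q <- stats::quantile(central, 0.95, na.rm = TRUE)
  deep <- which(central >= q, arr.ind = TRUE)
  w <- central[deep] - q + 1e-9
  ix <- sum(cx[deep[, 1]] * w) / sum(w)
  iy <- sum(cy[deep[, 2]] * w) / sum(w)
  c((ix - (nx + 1) / 2) * sx_mm, (iy - (ny + 1) / 2) * sy_mm)
}

#' Choroidal thickness normal to the RPE
#'
#' At each valid lateral position the unit normal of the Gaussian-smoothed
#' RPE surface is computed in physical units and a ray is cast from the (raw)
#' RPE point along it; the thickness is the Euclidean distance to the first
#' crossing of the CSI surface (ray march at `step_px` axial pixels with
#' linear interpolation at the crossing). Cells whose ray leaves the grid or
#' finds no crossing within `max_ct_um` are invalid.
#'
#' @param rpe,csi `surface_map`s on the same grid (outer RPE and
#'   choroid-sclera interface; RPE above CSI wherever both valid).
#' @param sx_mm,sy_mm Lateral spacings, mm.
#' @param axial_um_per_px Geometric um per axial pixel.
#' @param laterality `"OD"` or `"OS"` carried into the map.
#' @param fovea_xy Fovea centre, mm (from [locate_fovea()]); may be set later.
#' @param smooth_sigma_mm Gaussian sigma for the normal-direction smoothing.
#' @param step_px Ray-march step, axial pixels.
#' @param max_ct_um Give up beyond this distance.
#' @return A `thickness_map` with CT in geometric um.
#' @export
thickness_normal <- function(rpe, csi, sx_mm, sy_mm, axial_um_per_px,
                             laterality = "OD", fovea_xy = c(0, 0),
                             smooth_sigma_mm = 0.2, step_px = 0.25,
                             max_ct_um = 1000) {
  stopifnot(inherits(rpe, "surface_map"), inherits(csi, "surface_map"),
            all(dim(rpe$z) == dim(csi$z)))
  nx <- nrow(rpe$z); ny <- ncol(rpe$z)
  dx_um <- sx_mm * 1000; dy_um <- sy_mm * 1000
  z_rpe <- rpe$z * axial_um_per_px
  z_csi <- csi$z * axial_um_per_px
  zs <- smooth_gauss_na(z_rpe, smooth_sigma_mm / sx_mm,
                        smooth_sigma_mm / sy_mm)
  # surface gradient (um per um) by centered differences
  gx <- matrix(NA_real_, nx, ny); gy <- gx
  if (nx >= 3) gx[2:(nx - 1), ] <- (zs[3:nx, ] - zs[1:(nx - 2), ]) / (2 * dx_um)
  if (nx >= 2) { gx[1, ] <- (zs[2, ] - zs[1, ]) / dx_um
                 gx[nx, ] <- (zs[nx, ] - zs[nx - 1, ]) / dx_um }
  if (nx == 1) gx[] <- 0
  if (ny >= 3) gy[, 2:(ny - 1)] <- (zs[, 3:ny] - zs[, 1:(ny - 2)]) / (2 * dy_um)
  if (ny >= 2) { gy[, 1] <- (zs[, 2] - zs[, 1]) / dy_um
                 gy[, ny] <- (zs[, ny] - zs[, ny - 1]) / dy_um }
  if (ny == 1) gy[] <- 0
  nrm <- sqrt(1 + gx^2 + gy^2)
  nxv <- -gx / nrm; nyv <- -gy / nrm; nzv <- 1 / nrm   # pointing deeper
  live <- which(rpe$valid & csi$valid & is.finite(z_rpe) & is.finite(nxv))
  ct <- matrix(NA_real_, nx, ny)
  if (length(live)) {
    ri <- (live - 1) %% nx + 1
    ci <- (live - 1) %/% nx + 1
    step_um <- step_px * axial_um_per_px
    t_prev <- rep(0, length(live))
    f_prev <- z_rpe[live] - bilinear_idx(z_csi, ri, ci)
    alive <- f_prev < 0           # below the CSI not yet reached
    result <- rep(NA_real_, length(live))
    # cells already at/below the CSI (zero thickness after ordering clamp)
    result[!alive & is.finite(f_prev)] <- 0
    t <- 0
    while (any(alive) && t < max_ct_um) {
      t <- t + step_um
      xi <- ri + t * nxv[live] / dx_um
      yi <- ci + t * nyv[live] / dy_um
      zz <- z_rpe[live] + t * nzv[live]
      f <- zz - bilinear_idx(z_csi, xi, yi)
      crossed <- alive & is.finite(f) & f >= 0
      if (any(crossed)) {
        frac <- -f_prev[crossed] / (f[crossed] - f_prev[crossed])
        result[crossed] <- t_prev[crossed] +
          frac * (t - t_prev[crossed])
        alive[crossed] <- FALSE
      }
      alive <- alive & is.finite(f)   # ray left the grid -> invalid
      f_prev <- f; t_prev[] <- t
    }
    ct[live] <- result
  }
  valid <- is.finite(ct) & ct > 0
  ct[!valid] <- NA_real_
  new_thickness_map(ct, valid, fovea_xy, sx_mm, sy_mm, laterality)
}

# Laterality-normalized fovea-centred coordinates: `u` is the signed
# horizontal offset with nasal negative / temporal positive, `s` vertical
# (superior positive). Scanner x is temporal-positive for OD, mirrored for OS.
anatomical_coords <- function(ctmap) {
  nx <- nrow(ctmap$ct); ny <- ncol(ctmap$ct)
  x <- lateral_axis(nx, ctmap$lateral_spacing_x_mm)
  y <- lateral_axis(ny, ctmap$lateral_spacing_y_mm)
  mirror <- if (ctmap$laterality == "OD") 1 else -1
  u <- matrix((x - ctmap$fovea_xy[1]) * mirror, nx, ny)
  s <- matrix(y - ctmap$fovea_xy[2], nx, ny, byrow = TRUE)
  list(u = u, s = s, r = sqrt(u^2 + s^2))
}

#' Nine-sector geographic summary of a thickness map
#'
#' Pixels are classified by fovea-centred radius into the central disk and the
#' inner/outer rings of the 1/5/10 mm grid (half-open bins) and by quadrant
#' with 45-degree diagonal boundaries; nasal/temporal follow laterality. The
#' mean CT over valid pixels is reported per sector; sectors with under
#' `min_valid_frac` of their in-grid area valid are flagged missing.
#'
#' @param ctmap A `thickness_map` with `fovea_xy` set.
#' @param diameters Ring diameters, mm (strictly increasing, default 1/5/10).
#' @param min_valid_frac Minimum valid-area fraction per sector.
#' @return Tibble with `sector`, `mean_ct_um`, `n_valid`, `n_pixels`,
#'   `valid_frac`, `missing` in the fixed sector order.
#' @export
sector_summary <- function(ctmap, diameters = c(1, 5, 10),
                           min_valid_frac = 0.25) {
  stopifnot(inherits(ctmap, "thickness_map"),
            length(diameters) == 3, all(diff(diameters) > 0))
  nx <- nrow(ctmap$ct); ny <- ncol(ctmap$ct)
  half_x <- nx * ctmap$lateral_spacing_x_mm / 2
  half_y <- ny * ctmap$lateral_spacing_y_mm / 2
  f <- ctmap$fovea_xy
  if (abs(f[1]) > half_x || abs(f[2]) > half_y)
    stop("fovea centre lies outside the scan grid")
  co <- anatomical_coords(ctmap)
  radii <- diameters / 2
  # half-open radial bins; pixels exactly on a 45-degree diagonal go to the
  # horizontal (nasal/temporal) quadrants
  ring <- ifelse(co$r < radii[1], "F",
                 ifelse(co$r < radii[2], "IM",
                        ifelse(co$r < radii[3], "OM", NA)))
  quad <- ifelse(abs(co$u) >= abs(co$s),
                 ifelse(co$u < 0, "N", "T"),
                 ifelse(co$s > 0, "S", "I"))
  lab <- ifelse(ring == "F", "Fovea", paste0(quad, ring))
  lab[is.na(ring)] <- NA
  res <- lapply(SECTOR_NAMES, function(sec) {
    inside <- !is.na(lab) & lab == sec
    n_pix <- sum(inside)
    ok <- inside & ctmap$valid
    n_valid <- sum(ok)
    vf <- if (n_pix > 0) n_valid / n_pix else 0
    miss <- n_pix == 0 || vf < min_valid_frac
    tibble::tibble(sector = sec,
                   mean_ct_um = if (miss) NA_real_ else mean(ctmap$ct[ok]),
                   n_valid = n_valid, n_pixels = n_pix,
                   valid_frac = vf, missing = miss)
  })
  out <- do.call(rbind, res)
  attr(out, "ring_diameters_mm") <- diameters
  out
}

#' Nasal-temporal ring profile at 1 mm resolution
#'
#' Eleven bins at signed horizontal offsets -5..+5 mm (negative nasal,
#' positive temporal): bin 0 is the foveal disk (r < 0.5 mm); nasal bin `-k`
#' averages valid pixels with `k-1 <= r < k` mm inside the nasal 90-degree
#' wedge centred on the horizontal meridian, temporal bins symmetrically.
#'
#' @param ctmap A `thickness_map` with `fovea_xy` set.
#' @return Tibble with `offset_mm`, `mean_ct_um`, `n`, `missing`.
#' @export
ring_profile <- function(ctmap) {
  stopifnot(inherits(ctmap, "thickness_map"))
  co <- anatomical_coords(ctmap)
  wedge_n <- abs(co$u) >= abs(co$s) & co$u < 0
  wedge_t <- abs(co$u) >= abs(co$s) & co$u > 0
  offsets <- -5:5
  rows <- lapply(offsets, function(k) {
    sel <- if (k == 0) co$r < 0.5
      else if (k < 0) wedge_n & co$r >= (-k - 1) & co$r < -k
      else wedge_t & co$r >= (k - 1) & co$r < k
    ok <- sel & ctmap$valid
    n <- sum(ok)
    tibble::tibble(offset_mm = k,
                   mean_ct_um = if (n > 0) mean(ctmap$ct[ok]) else NA_real_,
                   n = n, missing = n == 0)
  })
  do.call(rbind, rows)
}
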