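# Boundary segmentation by dynamic programming. Each boundary is the
# column-to-column path minimizing the sum of a signed vertical-gradient cost
# (dark-to-bright boundaries reward positive depth gradients, bright-to-dark
# negative ones) under a smoothness constraint on the inter-column step, with
# parabolic subpixel refinement of the gradient extremum along each column.

# Signed vertical gradient: centered differences inside, one-sided at borders.
depth_gradient <- function(img) {
  nz <- nrow(img)
  g <- img
  if (nz >= 3) g[2:(nz - 1), ] <- (img[3:nz, ] - img[1:(nz - 2), ]) / 2
  g[1, ] <- img[2, ] - img[1, ]
  g[nz, ] <- img[nz, ] - img[nz - 1, ]
  g
}

#' Segment a single boundary in a B-scan
#'
#' @param bscan 2D intensity matrix (axial rows x lateral columns).
#' @param band Axial search interval: either `c(lo, hi)` applied to every
#'   column or a `2 x ncol` matrix of per-column intervals (rows `lo`, `hi`).
#' @param polarity `"dark_to_bright"` (boundary where intensity steps up with
#'   depth) or `"bright_to_dark"`.
#' @param smoothness Maximum inter-column step of the path, pixels (>= 1).
#' @param refine_img Optional second image (same size) whose gradient is used
#'   for the subpixel refinement instead of `bscan`'s; the refinement searches
#'   the polarity extremum within 2 px of the integer path. Used to localize
#'   on the unbiased raw-intensity gradient after a robust log-domain search.
#' @return List with `z` (subpixel axial position per column), `z_int` (the
#'   integer dynamic-programming path), `strength` (signed gradient at the
#'   path) and `cost` (total path cost).
#' @export
segment_surface <- function(bscan, band,
                            polarity = c("dark_to_bright", "bright_to_dark"),
                            smoothness = 2L, refine_img = NULL) {
  polarity <- match.arg(polarity)
  nz <- nrow(bscan); nc <- ncol(bscan)
  stopifnot(smoothness >= 1)
  if (is.matrix(band)) {
    stopifnot(nrow(band) == 2, ncol(band) == nc)
    lo <- pmax(1L, floor(band[1, ])); hi <- pmin(nz, ceiling(band[2, ]))
  } else {
    stopifnot(length(band) == 2)
    lo <- rep(max(1L, floor(band[1])), nc)
    hi <- rep(min(nz, ceiling(band[2])), nc)
  }
  if (any(hi - lo < 2))
    stop("search band narrower than 3 px or outside the image")
  g <- depth_gradient(bscan)
  cost <- if (polarity == "dark_to_bright") -g else g
  rmin <- min(lo); rmax <- max(hi)
  nb <- rmax - rmin + 1L
  C <- cost[rmin:rmax, , drop = FALSE]
  rows <- seq.int(rmin, rmax)
  for (i in seq_len(nc)) C[rows < lo[i] | rows > hi[i], i] <- Inf
  s <- as.integer(smoothness)
  # offsets ordered so ties resolve toward the smaller |step|
  offs <- order(abs(seq(-s, s)))
  offs <- seq(-s, s)[offs]
  D <- matrix(Inf, nb, nc)
  P <- matrix(0L, nb, nc)
  D[, 1] <- C[, 1]
  for (i in 2:nc) {
    prev <- D[, i - 1L]
    best <- rep(Inf, nb)
    arg <- integer(nb)
    for (off in offs) {
      idx <- seq_len(nb) + off
      cand <- rep(Inf, nb)
      okr <- idx >= 1L & idx <= nb
      cand[okr] <- prev[idx[okr]]
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- off
    }
    D[, i] <- C[, i] + best
    P[, i] <- arg
  }
  path <- integer(nc)
  path[nc] <- which.min(D[, nc])
  for (i in nc:2) path[i - 1L] <- path[i] + P[path[i], i]
  z_int <- path + rmin - 1L
  # subpixel: snap to the gradient extremum within 2 px of the path, then fit
  # a parabola through the signed gradient around it
  gr <- if (is.null(refine_img)) g else depth_gradient(refine_img)
  z <- numeric(nc); strength <- numeric(nc)
  sgn <- if (polarity == "dark_to_bright") 1 else -1
  for (i in seq_len(nc)) {
    r <- z_int[i]
    strength[i] <- sgn * g[r, i]
    win <- max(2L, r - 2L):min(nz - 1L, r + 2L)
    r2 <- win[which.max(sgn * gr[win, i])]
    y <- sgn * gr[(r2 - 1):(r2 + 1), i]
    if (y[2] >= y[1] && y[2] >= y[3]) {
      z[i] <- r2 + parabolic_offset(y[1], y[2], y[3])
    } else {
      z[i] <- r
    }
  }
  list(z = z, z_int = z_int, strength = strength, cost = D[path[nc], nc])
}

new_surface_map <- function(boundary, z, valid) {
  structure(list(boundary = boundary, z = z, valid = valid),
            class = "surface_map")
}

#' Segment the ILM, outer RPE and choroid-sclera interface of a volume
#'
#' Per B-scan the image is log-transformed (fully developed speckle becomes
#' additive with uniform variance) and smoothed laterally (boxcar) and axially
#' (Gaussian, 1 px) before gradients are taken. The brightest
#' band per column marks the RPE; the ILM is the first dark-to-bright boundary
#' above it, the outer RPE the bright-to-dark edge at the bottom of the bright
#' band, and the CSI a dark-to-bright transition searched in a band
#' `csi_band_um` below the outer RPE. Columns whose peak intensity stays below
#' `noise_factor` times the noise-floor median are invalid; B-scans with fewer
#' than 50% valid columns are flagged entirely invalid. Each surface gets a
#' 3x3 median smoothing across the volume and the depth ordering
#' ILM <= RPE_outer <= CSI is enforced.
#'
#' @param vol A motion-corrected `oct_volume`.
#' @param csi_band_um Search band below the outer RPE for the CSI, um of air
#'   path `c(min, max)`.
#' @param smoothness Dynamic-programming step constraint, px per column.
#' @param lateral_smooth Boxcar width (columns) applied before gradients.
#' @param noise_factor Validity threshold multiplier over the noise floor.
#' @param strength_min Minimum signed log-gradient at the RPE and CSI paths
#'   for a column to count as converged.
#' @return List with `surface_map`s `ilm`, `rpe_outer`, `csi` (position
#'   matrices are A-lines x B-scans) and `bscan_valid` (logical per B-scan).
#' @export
segment_volume <- function(vol, csi_band_um = c(10, 600), smoothness = 2L,
                           lateral_smooth = 5L, noise_factor = 5,
                           strength_min = 0.08) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity); nz <- d[1]; nx <- d[2]; ny <- d[3]
  sp <- vol$axial_spacing_air_um
  band_px <- csi_band_um / sp
  rpe_band_px <- ceiling(30 / sp)
  noise_med <- stats::median(vol$intensity[seq_len(min(8L, nz)), , ])
  zi <- matrix(NA_real_, nx, ny)
  zr <- zi; zc <- zi
  valid <- matrix(FALSE, nx, ny)
  bscan_valid <- rep(TRUE, ny)
  eps <- max(noise_med * 0.5, 1e-4)
  axial_k <- gauss_kernel(1)
  for (j in seq_len(ny)) {
    sm_raw <- boxcar_cols(vol$intensity[, , j], lateral_smooth)
    peak <- apply(sm_raw, 2, max)
    col_ok <- peak > noise_factor * max(noise_med, 1e-9)
    if (!any(col_ok)) { bscan_valid[j] <- FALSE; next }
    logim <- log(vol$intensity[, , j] + eps)
    sm <- conv_cols_k(boxcar_cols(logim, lateral_smooth), axial_k)
    # narrow-support raw image for subpixel localization: less lateral smear
    # of sloped boundaries than the robust search image
    sm_fine <- boxcar_cols(vol$intensity[, , j], 3L)
    # RPE centre prior from a heavily smoothed image + wide median filter:
    # robust against isolated speckle columns where the scleral band wins
    coarse <- conv_cols_k(boxcar_cols(logim, 4L * lateral_smooth + 1L),
                          axial_k)
    rpe_c <- apply(coarse, 2, which.max)
    rpe_c <- round(stats::runmed(rpe_c, min(15L, nx - (1 - nx %% 2))))
    # ILM: dark-to-bright above the bright band
    ilm_band <- rbind(rep(2, nx), pmax(rpe_c - 6, 5))
    ilm <- segment_surface(sm, ilm_band, "dark_to_bright", smoothness,
                           refine_img = sm_fine)
    # outer RPE: bright-to-dark at the bottom of the bright band
    rpe_band <- rbind(pmax(rpe_c - 1, 2),
                      pmin(rpe_c + rpe_band_px + 8, nz - 1))
    rpe <- segment_surface(sm, rpe_band, "bright_to_dark", smoothness,
                           refine_img = sm_fine)
    # CSI: dark-to-bright below the outer RPE
    csi_band <- rbind(pmin(pmax(rpe$z + band_px[1], 2), nz - 4),
                      pmin(rpe$z + band_px[2], nz - 1))
    csi <- segment_surface(sm, csi_band, "dark_to_bright", smoothness,
                           refine_img = sm_fine)
    # weak-gradient columns did not converge on a real edge
    ok <- col_ok & (ilm_band[2, ] - ilm_band[1, ] >= 2) &
      rpe$strength > strength_min & csi$strength > strength_min
    zi[, j] <- ilm$z; zr[, j] <- rpe$z; zc[, j] <- csi$z
    valid[, j] <- ok
    if (mean(ok) < 0.5) bscan_valid[j] <- FALSE
  }
  valid <- valid & matrix(bscan_valid, nx, ny, byrow = TRUE)
  zi[!valid] <- NA_real_; zr[!valid] <- NA_real_; zc[!valid] <- NA_real_
  # enforce depth ordering, then smooth each surface
  zr <- pmax(zr, zi); zc <- pmax(zc, zr)
  zi <- median3x3(zi); zr <- median3x3(zr); zc <- median3x3(zc)
  zr <- pmax(zr, zi); zc <- pmax(zc, zr)
  list(ilm = new_surface_map("ILM", zi, valid),
       rpe_outer = new_surface_map("RPE_outer", zr, valid),
       csi = new_surface_map("CSI", zc, valid),
       bscan_valid = bscan_valid)
}

#' Discrepancy between two independent choroidal-thickness analyses
#'
#' Quantifies how far two thickness maps of the same eye disagree:
#' `|mean(a) - mean(b)|` over the joint valid mask, divided by the average of
#' the two means. Eyes whose discrepancy exceeds 0.15 are conventionally
#' excluded from cohort statistics (dual-operator quality rule).
#'
#' @param ct_a,ct_b `thickness_map`s on the same grid.
#' @param per_pixel If `TRUE`, use the mean absolute per-pixel relative
#'   difference instead of the map-mean rule.
#' @return Discrepancy fraction (>= 0).
#' @export
segmentation_discrepancy <- function(ct_a, ct_b, per_pixel = FALSE) {
  stopifnot(inherits(ct_a, "thickness_map"), inherits(ct_b, "thickness_map"),
            all(dim(ct_a$ct) == dim(ct_b$ct)))
  joint <- ct_a$valid & ct_b$valid
  if (!any(joint)) stop("thickness maps have disjoint valid masks")
  a <- ct_a$ct[joint]; b <- ct_b$ct[joint]
  if (per_pixel) {
    return(mean(abs(a - b) / ((a + b) / 2)))
  }
  ma <- mean(a); mb <- mean(b)
  abs(ma - mb) / ((ma + mb) / 2)
}
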