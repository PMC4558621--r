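#' Draw a ground-truth eye for synthetic OCT rendering
#'
#' Samples one eye from a group's parameter distributions: the nine sector
#' choroidal-thickness targets (independent normals, floored at 20 um), the
#' axial length (normal, clamped to 20-30 mm), a foveal-pit position jitter,
#' and a per-B-scan integer axial motion trace. The choroidal-thickness field
#' is a smooth 2D surface through the sector targets (see Details); its value
#' at the pit centre equals the drawn Fovea target exactly.
#'
#' @details The CT field is built in fovea-centred anatomical coordinates
#' (temporal positive): quadrant values are blended angularly with cosine
#' transitions of half-width 15 degrees at the 45-degree diagonals, and
#' radially by monotone cosine interpolation through the ring values at the
#' sector centroid radii (0, 1.5, 3.75 mm), held constant beyond the outer
#' centroid. The choroid-sclera interface lies at distance `ct` from the RPE
#' along the local RPE normal.
#'
#' @param group_params One group entry of a [cohort_spec()] (fields
#'   `sector_mean`, `sector_sd`, `iol_mean`, `iol_sd`; `n_eyes` and
#'   `refractive_range` are ignored here).
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param seed Integer seed; the returned truth is a deterministic function of
#'   it.
#' @param refractive_error Signed refractive error in diopters (<= 0), stored
#'   as metadata.
#' @param n_bscans Number of B-scans the motion trace must cover.
#' @param motion_amplitude_px Axial motion amplitude A; per-B-scan shifts are
#'   uniform integers in \[-A, A\] (first B-scan 0 by convention).
#' @param pit_depth_um,pit_radius_mm Foveal pit depth and Gaussian radius.
#' @param retina_um Retinal thickness (ILM to outer RPE), geometric um.
#' @param rpe_depth_um Geometric depth of the outer RPE at the fovea, um.
#' @param rpe_curv_um_mm2 Posterior-pole bowing of the RPE, um per mm^2.
#' @return An object of class `eye_truth`.
#' @export
make_eye_truth <- function(group_params, laterality = "OD", seed = 1L,
                           refractive_error = -1,
                           n_bscans = 64L, motion_amplitude_px = 4L,
                           pit_depth_um = 110, pit_radius_mm = 0.6,
                           retina_um = 300, rpe_depth_um = 450,
                           rpe_curv_um_mm2 = 8) {
  if (!laterality %in% c("OD", "OS"))
    stop("laterality must be 'OD' or 'OS'")
  stopifnot(all(group_params$sector_sd >= 0),
            all(group_params$sector_mean > 0))
  set.seed(as.integer(seed))
  sectors <- pmax(stats::rnorm(length(SECTOR_NAMES),
                               mean = group_params$sector_mean[SECTOR_NAMES],
                               sd = group_params$sector_sd[SECTOR_NAMES]), 20)
  names(sectors) <- SECTOR_NAMES
  iol <- min(30, max(20, stats::rnorm(1, group_params$iol_mean,
                                      group_params$iol_sd)))
  pit_xy <- stats::runif(2, -0.25, 0.25)
  A <- as.integer(motion_amplitude_px)
  trace <- c(0L, if (n_bscans > 1L)
    sample.int(2L * A + 1L, n_bscans - 1L, replace = TRUE) - A - 1L)
  structure(list(
    sectors = sectors, iol_true = iol,
    refractive_error = refractive_error, laterality = laterality,
    pit = list(x_mm = pit_xy[1], y_mm = pit_xy[2],
               depth_um = pit_depth_um, radius_mm = pit_radius_mm),
    retina_um = retina_um, rpe_depth_um = rpe_depth_um,
    rpe_curv_um_mm2 = rpe_curv_um_mm2,
    motion_trace = trace, n_bscans = as.integer(n_bscans),
    seed = as.integer(seed)
  ), class = "eye_truth")
}

# Cosine smoothstep on [0, 1].
cosine_step <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

# Angular blend of four quadrant values at angles a (radians, temporal = 0,
# superior = pi/2, nasal = +/-pi, inferior = -pi/2) with cosine transitions of
# half-width `half_deg` degrees around the 45-degree diagonals.
quadrant_blend <- function(a, v_nasal, v_sup, v_temp, v_inf,
                           half_deg = 15) {
  hw <- half_deg * pi / 180
  vals <- c(v_temp, v_sup, v_nasal, v_inf, v_temp)  # centres 0, 90, 180, 270, 360
  ang <- a %% (2 * pi)                              # [0, 2pi)
  k <- floor((ang + pi / 4) / (pi / 2))             # nearest centre index 0..4
  centre <- k * pi / 2
  dv <- ang - centre                                # (-pi/4, pi/4]
  base <- vals[k + 1]
  # neighbour across the closest diagonal
  nb <- ifelse(dv >= 0, vals[(k + 1) %% 4 + 1], vals[(k - 1) %% 4 + 1])
  d_edge <- pi / 4 - abs(dv)                        # distance to the diagonal
  w <- ifelse(d_edge >= hw, 0, 0.5 * (1 - cosine_step(d_edge / hw)))
  base * (1 - w) + nb * w
}

# Radial profile through ring values: flat at v0 across the foveal disk
# (r <= r0), cosine interpolation to the inner centroid at r1 and on to the
# outer centroid at r2, constant beyond. The plateau keeps the foveal-disk
# mean equal to the configured subfoveal value.
radial_blend <- function(r, v0, v1, v2, r0 = 0.5, r1 = 1.5, r2 = 3.75) {
  w1 <- cosine_step((r - r0) / (r1 - r0))
  w2 <- cosine_step((r - r1) / (r2 - r1))
  inner <- v0 + (v1 - v0) * w1
  outer <- v1 + (v2 - v1) * w2
  ifelse(r < r1, inner, ifelse(r < r2, outer, v2))
}

#' Evaluate the ground-truth choroidal-thickness field
#'
#' @param truth An [make_eye_truth()] object.
#' @param t_mm,s_mm Fovea-centred anatomical coordinates in mm (temporal
#'   positive, superior positive); recycled to a common length.
#' @return CT in geometric um (>= 20).
#' @export
ct_field <- function(truth, t_mm, s_mm) {
  se <- truth$sectors
  r <- sqrt(t_mm^2 + s_mm^2)
  a <- atan2(s_mm, t_mm)
  inner <- quadrant_blend(a, se["NIM"], se["SIM"], se["TIM"], se["IIM"])
  outer <- quadrant_blend(a, se["NOM"], se["SOM"], se["TOM"], se["IOM"])
  pmax(radial_blend(r, se[["Fovea"]], inner, outer), 20)
}

#' Evaluate the analytic ground-truth surfaces on a lateral grid
#'
#' Returns geometric depths (um, increasing into the eye) of the ILM, the
#' outer RPE and the choroid-sclera interface, plus the CT field, on the
#' requested scanner-frame grid. Scanner x is temporal-positive for OD eyes
#' and temporal-negative for OS eyes; the CT field is evaluated in anatomical
#' coordinates accordingly.
#'
#' @param truth An `eye_truth`.
#' @param x_mm,y_mm Scanner-frame lateral coordinate vectors (mm, centred).
#' @return List of matrices `ilm_um`, `rpe_um`, `csi_um`, `ct_um` with
#'   `length(x_mm)` rows and `length(y_mm)` columns.
#' @export
truth_surfaces <- function(truth, x_mm, y_mm) {
  nx <- length(x_mm); ny <- length(y_mm)
  X <- matrix(x_mm, nx, ny)
  Y <- matrix(y_mm, nx, ny, byrow = TRUE)
  dx <- X - truth$pit$x_mm
  dy <- Y - truth$pit$y_mm
  mirror <- if (truth$laterality == "OD") 1 else -1
  t_mm <- dx * mirror
  s_mm <- dy
  r2 <- dx^2 + dy^2
  rpe <- truth$rpe_depth_um + truth$rpe_curv_um_mm2 * r2
  pit <- truth$pit$depth_um *
    exp(-r2 / (2 * truth$pit$radius_mm^2))
  ilm <- rpe - truth$retina_um + pit
  ct <- matrix(ct_field(truth, as.vector(t_mm), as.vector(s_mm)), nx, ny)
  # local RPE tilt: dz/dx in um/um; CSI sits at normal distance ct
  gx <- 2 * truth$rpe_curv_um_mm2 * dx / 1000
  gy <- 2 * truth$rpe_curv_um_mm2 * dy / 1000
  cos_theta <- 1 / sqrt(1 + gx^2 + gy^2)
  csi <- rpe + ct / cos_theta
  list(ilm_um = ilm, rpe_um = rpe, csi_um = csi, ct_um = ct)
}
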