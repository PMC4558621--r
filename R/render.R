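# Amplitude-domain rendering of synthetic SD-OCT volumes. The axial profile is
# a piecewise-constant reflectivity model (vitreous / retina / bright RPE band
# / choroid / inner-sclera band / deep) with anti-aliased steps at the
# ground-truth boundary positions, blurred by the axial PSF, attenuated by the
# sensitivity roll-off, with optional multiplicative speckle and per-B-scan
# axial motion. Intensities are quantized to the 16-bit grid so that on-disk
# round trips are exact.

# Anti-aliased unit step: fraction of a pixel above the boundary at signed
# distance d (pixels).
aa_step <- function(d) pmin(pmax(d + 0.5, 0), 1)

# Convert a geometric depth (um) to a continuous 1-based axial pixel row.
geom_to_px <- function(z_um, params) {
  (params$axial_offset_air_um + z_um * params$tissue_index) /
    params$axial_spacing_air_um + 1
}

#' Render a synthetic OCT volume from a ground-truth eye
#'
#' @param truth An [make_eye_truth()] object.
#' @param params A [render_params()] list.
#' @param seed Integer seed for the speckle draw.
#' @return An `oct_volume`: list with `intensity` (array `[z, x, y]` in
#'   \[0, 1\]), spacings and metadata, plus the injected motion trace as the
#'   `motion_applied` field.
#' @export
render_volume <- function(truth, params = render_params(), seed = 1L) {
  nz <- params$n_axial; nx <- params$n_alines; ny <- params$n_bscans
  if (truth$n_bscans < ny)
    stop("eye_truth motion trace is shorter than the requested B-scan count")
  x_mm <- lateral_axis(nx, params$lateral_spacing_x_mm)
  y_mm <- lateral_axis(ny, params$lateral_spacing_y_mm)
  surf <- truth_surfaces(truth, x_mm, y_mm)
  px <- lapply(surf[c("ilm_um", "rpe_um", "csi_um")], geom_to_px,
               params = params)
  band_px <- params$rpe_band_um / params$axial_spacing_air_um
  scl_px <- params$sclera_band_um / params$axial_spacing_air_um
  psf_sigma_px <- params$psf_sigma_um / params$axial_spacing_air_um
  margin <- 3 * psf_sigma_px + 1
  motion <- if (params$motion_on) truth$motion_trace[seq_len(ny)] else
    integer(ny)
  deepest <- apply(px$csi_um + scl_px, 2, max) + abs(motion) + margin
  if (any(deepest > nz)) {
    stop(sprintf("eye exceeds the axial window in B-scan %d (deepest %.1f px of %d)",
                 which.max(deepest), max(deepest), nz))
  }
  lv <- params$levels
  zg <- matrix(seq_len(nz), nz, nx)
  kernel <- gauss_kernel(psf_sigma_px)
  rolloff <- sensitivity_rolloff((seq_len(nz) - 1) *
                                   params$axial_spacing_air_um / 1000,
                                 params$rolloff_6db_mm)
  vol <- array(0, c(nz, nx, ny))
  for (j in seq_len(ny)) {
    ilm <- matrix(px$ilm_um[, j], nz, nx, byrow = TRUE)
    rpe <- matrix(px$rpe_um[, j], nz, nx, byrow = TRUE)
    csi <- matrix(px$csi_um[, j], nz, nx, byrow = TRUE)
    refl <- lv[["vitreous"]] +
      (lv[["retina"]] - lv[["vitreous"]]) * aa_step(zg - ilm) +
      (lv[["rpe"]] - lv[["retina"]]) * aa_step(zg - (rpe - band_px)) +
      (lv[["choroid"]] - lv[["rpe"]]) * aa_step(zg - rpe) +
      (lv[["sclera"]] - lv[["choroid"]]) * aa_step(zg - csi) +
      (lv[["deep"]] - lv[["sclera"]]) * aa_step(zg - (csi + scl_px))
    vol[, , j] <- conv_cols_k(refl, kernel) * rolloff + params$noise_floor
  }
  set.seed(as.integer(seed))
  if (params$speckle_on)
    vol <- vol * stats::rexp(length(vol))
  # per-B-scan integer axial motion: positive shift moves content deeper
  for (j in seq_len(ny)) {
    t <- motion[j]
    if (t != 0) {
      page <- matrix(params$noise_floor, nz, nx)
      if (t > 0) page[(t + 1):nz, ] <- vol[1:(nz - t), , j]
      else page[1:(nz + t), ] <- vol[(1 - t):nz, , j]
      vol[, , j] <- page
    }
  }
  vol <- round(pmin(vol / params$saturation, 1) * 65535) / 65535
  new_oct_volume(vol, params, truth, seed, motion)
}

new_oct_volume <- function(intensity, params, truth = NULL, seed = NA_integer_,
                           motion = NULL, laterality = truth$laterality,
                           refractive_error = truth$refractive_error) {
  structure(list(
    intensity = intensity,
    axial_spacing_air_um = params$axial_spacing_air_um,
    axial_offset_air_um = params$axial_offset_air_um,
    lateral_spacing_x_mm = params$lateral_spacing_x_mm,
    lateral_spacing_y_mm = params$lateral_spacing_y_mm,
    tissue_index = params$tissue_index,
    laterality = laterality,
    refractive_error = refractive_error,
    seed = seed,
    motion_applied = motion,
    generator = "choromap synthetic renderer"
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> %d axial x %d A-lines x %d B-scans (%s, %+.2f D)\n",
              d[1], d[2], d[3], x$laterality, x$refractive_error))
  cat(sprintf("  axial %.2f um(air)/px, lateral %.3f x %.3f mm/px\n",
              x$axial_spacing_air_um, x$lateral_spacing_x_mm,
              x$lateral_spacing_y_mm))
  invisible(x)
}

#' Parameters for composite A-scan rendering
#'
#' The composite A-scan covers the full dual-reference-arm window: the foveal
#' retina near the zero-delay line and the corneal reflection further down.
#'
#' @param n_samples Samples in the window.
#' @param axial_spacing_air_um Air-path spacing per sample, um.
#' @param fovea_depth_mm Air-path depth of the foveal RPE peak.
#' @param fovea_amp,cornea_amp Peak amplitudes.
#' @param peak_sigma_um Gaussian peak sigma, um air.
#' @param noise_floor Background amplitude.
#' @return List of class `ascan_params`.
#' @export
ascan_params <- function(n_samples = 1024L, axial_spacing_air_um = 6,
                         fovea_depth_mm = 0.35, fovea_amp = 1,
                         cornea_amp = 0.6, peak_sigma_um = 12,
                         noise_floor = 0.002) {
  structure(list(n_samples = as.integer(n_samples),
                 axial_spacing_air_um = axial_spacing_air_um,
                 fovea_depth_mm = fovea_depth_mm, fovea_amp = fovea_amp,
                 cornea_amp = cornea_amp, peak_sigma_um = peak_sigma_um,
                 noise_floor = noise_floor), class = "ascan_params")
}

#' Render the composite A-scan of an eye
#'
#' Places the foveal RPE reflection near the zero-delay line and the corneal
#' reflection at optical-path separation `d = delta_L_ref - n_index * IOL`
#' beyond it, the geometry created by offsetting the two reference mirrors by
#' `delta_L_ref`.
#'
#' @param truth An `eye_truth` (its `iol_true` is used).
#' @param delta_L_ref Reference-mirror optical-path offset, mm.
#' @param n_index Whole-eye group refractive index.
#' @param params An [ascan_params()] list.
#' @return A `composite_ascan`: amplitude vector plus geometry metadata.
#' @export
render_composite_ascan <- function(truth, delta_L_ref = 35,
                                   n_index = 1.3375,
                                   params = ascan_params()) {
  stopifnot(delta_L_ref > 0, n_index >= 1)
  d_mm <- delta_L_ref - n_index * truth$iol_true
  if (d_mm <= 0)
    stop("cornea peak outside window: delta_L_ref must exceed n * IOL")
  sp <- params$axial_spacing_air_um
  fovea_px <- params$fovea_depth_mm * 1000 / sp + 1
  cornea_px <- fovea_px + d_mm * 1000 / sp
  if (cornea_px > params$n_samples - 2)
    stop(sprintf("cornea peak at sample %.1f outside the %d-sample window",
                 cornea_px, params$n_samples))
  z <- seq_len(params$n_samples)
  s_px <- params$peak_sigma_um / sp
  amp <- params$noise_floor +
    params$fovea_amp * exp(-(z - fovea_px)^2 / (2 * s_px^2)) +
    params$cornea_amp * exp(-(z - cornea_px)^2 / (2 * s_px^2))
  structure(list(amplitude = amp, axial_spacing_air_um = sp,
                 delta_L_ref = delta_L_ref, n_index = n_index,
                 true_d_mm = d_mm, true_iol_mm = truth$iol_true),
            class = "composite_ascan")
}

#' Generate a synthetic cohort of eyes with ground truth
#'
#' Draws `n_eyes` eyes per severity group from a [cohort_spec()]: for each eye
#' a ground truth, a rendered OCT volume, a composite A-scan, and a uniform
#' refractive error within the group's range. Laterality alternates OD/OS.
#'
#' @param spec A `cohort_spec`.
#' @param seed Base seed; every eye derives its own seed deterministically.
#' @param params A [render_params()] list.
#' @param delta_L_ref,n_index Composite A-scan geometry.
#' @param render Set `FALSE` to skip volume/A-scan rendering (truths only).
#' @return List of records: `eye_id`, `group`, `laterality`,
#'   `refractive_error`, `truth`, `volume`, `ascan`.
#' @export
generate_cohort <- function(spec, seed = 1L, params = render_params(),
                            delta_L_ref = 35, n_index = 1.3375,
                            render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- list()
  idx <- 0L
  for (grp in c("low", "moderate", "high")) {
    g <- spec[[grp]]
    if (g$n_eyes == 0) next
    for (i in seq_len(g$n_eyes)) {
      idx <- idx + 1L
      eye_seed <- derive_seed(seed, idx)
      set.seed(eye_seed)
      re <- stats::runif(1, g$refractive_range[1], g$refractive_range[2])
      laterality <- if (idx %% 2L == 1L) "OD" else "OS"
      truth <- make_eye_truth(g, laterality = laterality,
                              seed = derive_seed(eye_seed, 1L),
                              refractive_error = re,
                              n_bscans = params$n_bscans)
      vol <- NULL; ascan <- NULL
      if (render) {
        vol <- render_volume(truth, params, seed = derive_seed(eye_seed, 2L))
        ascan <- render_composite_ascan(truth, delta_L_ref, n_index)
      }
      records[[idx]] <- list(eye_id = sprintf("%s_%02d", grp, i), group = grp,
                             laterality = laterality, refractive_error = re,
                             truth = truth, volume = vol, ascan = ascan)
    }
  }
  records
}
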