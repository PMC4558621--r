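# End-to-end orchestration: motion correction -> segmentation -> fovea
# localization -> RPE-normal thickness mapping -> sector grid and ring
# profile, per eye and per cohort.

#' Process one eye: volume to thickness map, sectors and ring profile
#'
#' @param vol An `oct_volume` (raw; motion correction runs first).
#' @param ascan Optional `composite_ascan` for simultaneous IOL measurement.
#' @param max_shift Motion-correction search half-range, px.
#' @param dual_qc Re-segment with an alternate lateral smoothing width and
#'   compute the dual-analysis discrepancy (the 15% exclusion rule input).
#' @param fovea_xy Manual fovea override, mm (skips [locate_fovea()]).
#' @param surface_override Optional externally corrected surfaces: a list with
#'   any of `ilm`, `rpe_outer`, `csi` `surface_map`s replacing the automatic
#'   result (the programmatic stand-in for manual correction).
#' @param ... Passed to [segment_volume()].
#' @return List with `surfaces`, `ctmap`, `sectors`, `profile`, `fovea_xy`,
#'   `shift_trace`, `iol` (or NULL), `qc_discrepancy` (NA unless `dual_qc`).
#' @export
process_eye <- function(vol, ascan = NULL, max_shift = 8L, dual_qc = FALSE,
                        fovea_xy = NULL, surface_override = NULL, ...) {
  stopifnot(inherits(vol, "oct_volume"))
  mc <- correct_motion(vol, max_shift)
  surf <- segment_volume(mc$volume, ...)
  for (nm in intersect(names(surface_override), c("ilm", "rpe_outer", "csi")))
    surf[[nm]] <- surface_override[[nm]]
  axial_um_px <- vol$axial_spacing_air_um / vol$tissue_index
  sx <- vol$lateral_spacing_x_mm; sy <- vol$lateral_spacing_y_mm
  if (is.null(fovea_xy))
    fovea_xy <- locate_fovea(surf$ilm, sx, sy, axial_um_px)
  ctmap <- thickness_normal(surf$rpe_outer, surf$csi, sx, sy, axial_um_px,
                            laterality = vol$laterality,
                            fovea_xy = fovea_xy)
  qc <- NA_real_
  if (dual_qc) {
    surf2 <- segment_volume(mc$volume, lateral_smooth = 3L, ...)
    ct2 <- thickness_normal(surf2$rpe_outer, surf2$csi, sx, sy, axial_um_px,
                            laterality = vol$laterality, fovea_xy = fovea_xy)
    qc <- segmentation_discrepancy(ctmap, ct2)
  }
  iol <- if (!is.null(ascan)) measure_iol(ascan) else NULL
  list(surfaces = surf, ctmap = ctmap,
       sectors = sector_summary(ctmap), profile = ring_profile(ctmap),
       fovea_xy = fovea_xy, shift_trace = mc$trace, iol = iol,
       qc_discrepancy = qc)
}

#' Run the full pipeline over a generated cohort
#'
#' @param cohort A [generate_cohort()] record list (or any list of records
#'   with `volume`, `ascan`, `eye_id`, `laterality`, `refractive_error`).
#' @param qc_threshold Eyes whose dual-analysis discrepancy exceeds this are
#'   flagged `excluded` (only evaluated when `dual_qc = TRUE`).
#' @param dual_qc,... Passed to [process_eye()].
#' @param verbose Print one line per eye.
#' @return Tibble, one row per eye: identifiers, `group` (re-derived from the
#'   refractive error), measured `iol_mm`, the nine sector means, ring-profile
#'   bins as `ring_m5`..`ring_p5`, `qc_discrepancy` and `excluded`; the
#'   per-eye result objects are attached as the `results` attribute.
#' @export
run_cohort_pipeline <- function(cohort, qc_threshold = 0.15,
                                dual_qc = FALSE, verbose = FALSE, ...) {
  results <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    res <- process_eye(rec$volume, ascan = rec$ascan, dual_qc = dual_qc, ...)
    results[[i]] <- res
    sec <- stats::setNames(res$sectors$mean_ct_um, res$sectors$sector)
    prof <- res$profile$mean_ct_um
    names(prof) <- ifelse(res$profile$offset_mm < 0,
                          paste0("ring_m", -res$profile$offset_mm),
                          ifelse(res$profile$offset_mm > 0,
                                 paste0("ring_p", res$profile$offset_mm),
                                 "ring_0"))
    excluded <- dual_qc && is.finite(res$qc_discrepancy) &&
      res$qc_discrepancy > qc_threshold
    rows[[i]] <- tibble::tibble(
      eye_id = rec$eye_id, laterality = rec$laterality,
      refractive_error = rec$refractive_error,
      group = assign_group(rec$refractive_error),
      iol_mm = if (is.null(res$iol)) NA_real_ else res$iol$iol_mm,
      !!!as.list(sec), !!!as.list(prof),
      qc_discrepancy = res$qc_discrepancy, excluded = excluded)
    if (verbose)
      message(sprintf("processed %s (%s, %+.2f D)", rec$eye_id,
                      rec$laterality, rec$refractive_error))
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
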