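#' Named macular sectors of the 1/5/10 mm geographic grid
#'
#' Fixed ordering used throughout: central fovea, then the four inner-macula
#' quadrants (nasal, superior, temporal, inferior), then the four outer-macula
#' quadrants.
#' @export
SECTOR_NAMES <- c("Fovea", "NIM", "SIM", "TIM", "IIM",
                  "NOM", "SOM", "TOM", "IOM")

#' Rendering parameters for synthetic OCT volumes
#'
#' Defaults describe a desk-scale version of a 1050 nm SD-OCT macular scan:
#' 256 axial samples x 256 A-lines x 64 B-scans over ~10 x 5 mm, ~10 um axial
#' resolution in air, 6 dB sensitivity roll-off at 3 mm depth, fully developed
#' speckle and per-B-scan axial motion. The full clinical protocol
#' (512 A-lines x 256 B-scans) is available by overriding `n_alines` /
#' `n_bscans`.
#'
#' @param n_axial,n_alines,n_bscans Volume dimensions (axial samples, A-lines
#'   per B-scan, B-scans).
#' @param axial_spacing_air_um Axial sample spacing, um of air path per sample.
#' @param axial_offset_air_um Air-path depth of the geometric zero plane, um;
#'   shifts the whole eye down from the zero-delay line.
#' @param lateral_spacing_x_mm,lateral_spacing_y_mm Lateral sample spacings, mm.
#' @param tissue_index Group refractive index used to convert geometric tissue
#'   distance to air path inside retina/choroid (distinct from the whole-eye
#'   index used for axial-length biometry).
#' @param psf_sigma_um Axial point-spread sigma, um air (FWHM ~10 um gives
#'   sigma ~4.25 um).
#' @param levels Named reflectivity levels of the piecewise tissue model.
#' @param rpe_band_um,sclera_band_um Air-path widths of the bright RPE band and
#'   inner-sclera band, um.
#' @param speckle_on Multiply intensities by unit-mean exponential speckle.
#' @param rolloff_6db_mm Depth (mm air) at which sensitivity has dropped 6 dB.
#' @param noise_floor Additive background amplitude.
#' @param motion_on Apply the eye's per-B-scan axial motion trace.
#' @param saturation Amplitude mapped to full scale before 16-bit quantization.
#' @return A list of class `render_params`.
#' @export
render_params <- function(n_axial = 256L, n_alines = 256L, n_bscans = 64L,
                          axial_spacing_air_um = 8,
                          axial_offset_air_um = 200,
                          lateral_spacing_x_mm = 10 / 256,
                          lateral_spacing_y_mm = 5 / 64,
                          tissue_index = 1.38,
                          psf_sigma_um = 4.25,
                          levels = c(vitreous = 0.02, retina = 0.25,
                                     rpe = 1.0, choroid = 0.12,
                                     sclera = 0.45, deep = 0.05),
                          rpe_band_um = 30, sclera_band_um = 50,
                          speckle_on = TRUE, rolloff_6db_mm = 3,
                          noise_floor = 0.02, motion_on = TRUE,
                          saturation = 4) {
  stopifnot(n_axial > 0, n_alines > 0, n_bscans > 0,
            axial_spacing_air_um > 0, lateral_spacing_x_mm > 0,
            lateral_spacing_y_mm > 0, rolloff_6db_mm > 0,
            tissue_index >= 1, saturation > 0)
  structure(list(
    n_axial = as.integer(n_axial), n_alines = as.integer(n_alines),
    n_bscans = as.integer(n_bscans),
    axial_spacing_air_um = axial_spacing_air_um,
    axial_offset_air_um = axial_offset_air_um,
    lateral_spacing_x_mm = lateral_spacing_x_mm,
    lateral_spacing_y_mm = lateral_spacing_y_mm,
    tissue_index = tissue_index, psf_sigma_um = psf_sigma_um,
    levels = levels, rpe_band_um = rpe_band_um,
    sclera_band_um = sclera_band_um, speckle_on = isTRUE(speckle_on),
    rolloff_6db_mm = rolloff_6db_mm, noise_floor = noise_floor,
    motion_on = isTRUE(motion_on), saturation = saturation
  ), class = "render_params")
}

#' Depth-dependent sensitivity roll-off factor
#'
#' Spectrometer-based OCT loses sensitivity with depth; the amplitude factor
#' halves every `rolloff_6db_mm` of air-path depth (6 dB in intensity terms as
#' reported for such systems).
#'
#' @param depth_mm Air-path depth, mm.
#' @param rolloff_6db_mm Depth at which the factor is 0.5.
#' @return Multiplicative amplitude factor in (0, 1].
#' @export
sensitivity_rolloff <- function(depth_mm, rolloff_6db_mm = 3) {
  stopifnot(rolloff_6db_mm > 0)
  2^(-depth_mm / rolloff_6db_mm)
}

group_spec <- function(g, what) {
  req <- c("n_eyes", "sector_mean", "sector_sd", "iol_mean", "iol_sd",
           "refractive_range")
  miss <- setdiff(req, names(g))
  if (length(miss))
    stop(sprintf("cohort spec group '%s' missing fields: %s",
                 what, paste(miss, collapse = ", ")))
  g$sector_mean <- unlist(g$sector_mean)[SECTOR_NAMES]
  g$sector_sd <- unlist(g$sector_sd)[SECTOR_NAMES]
  g$refractive_range <- sort(unlist(g$refractive_range))
  if (anyNA(g$sector_mean) || anyNA(g$sector_sd))
    stop(sprintf("cohort spec group '%s': all nine sectors (%s) need mean and sd",
                 what, paste(SECTOR_NAMES, collapse = ", ")))
  if (g$n_eyes < 0) stop("n_eyes must be >= 0")
  if (any(g$sector_mean <= 0)) stop("sector CT means must be positive")
  if (any(g$sector_sd < 0) || g$iol_sd < 0) stop("SDs must be >= 0")
  if (any(g$refractive_range > 0))
    stop("refractive ranges must be myopic (<= 0 D)")
  g
}

#' Build a cohort specification
#'
#' A cohort spec holds, per myopia severity group (`low`, `moderate`, `high`),
#' the number of eyes, the nine per-sector choroidal-thickness means and SDs
#' (um), the axial-length mean and SD (mm), and the refractive-error sampling
#' range (diopters, myopic hence <= 0).
#'
#' @param low,moderate,high Per-group lists with fields `n_eyes`,
#'   `sector_mean`, `sector_sd` (named by [SECTOR_NAMES]), `iol_mean`,
#'   `iol_sd`, `refractive_range`.
#' @return A list of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the study-condition defaults.
#' @export
cohort_spec <- function(low, moderate, high) {
  structure(list(low = group_spec(low, "low"),
                 moderate = group_spec(moderate, "moderate"),
                 high = group_spec(high, "high")),
            class = "cohort_spec")
}

#' Default cohort specification (study conditions)
#'
#' Reads the packaged defaults file: 20 low-myopia, 10 moderate and 10 high
#' myopia eyes, sector CT means/SDs for the nasal/fovea/temporal sectors from
#' the published group table, axial-length group means/SDs, and uniform
#' refractive-error ranges per group. Superior/inferior sectors, which the
#' published table does not report, default to the mean of the same-ring nasal
#' and temporal values.
#'
#' @param path Optional path to a JSON cohort spec; defaults to the packaged
#'   file.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(path = system.file("extdata",
                                                   "cohort_defaults.json",
                                                   package = "choromap")) {
  if (!nzchar(path) || !file.exists(path)) stop("cohort defaults file not found")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(low = raw$low, moderate = raw$moderate, high = raw$high)
}
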