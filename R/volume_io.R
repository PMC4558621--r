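# On-disk formats: multi-page TIFF (one page per B-scan, 16-bit) with a JSON
# sidecar carrying physical spacings and provenance, and RFC-4180-style CSV
# tables. Raw files stay in the scanner frame; laterality normalization
# happens in the thickness-mapping stage.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an OCT volume to disk
#'
#' Writes one 16-bit TIFF page per B-scan plus a JSON sidecar with dimensions,
#' spacings, laterality, refractive error and provenance. Intensities must lie
#' in \[0, 1\]; they are stored on the 16-bit grid, so volumes produced by
#' [render_volume()] (already quantized) round-trip bit-identically.
#'
#' @param vol An `oct_volume`.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity)
  pages <- lapply(seq_len(d[3]),
                  function(j) matrix(vol$intensity[, , j], d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    n_axial = d[1], n_alines = d[2], n_bscans = d[3],
    axial_spacing_air_um = vol$axial_spacing_air_um,
    axial_offset_air_um = vol$axial_offset_air_um,
    lateral_spacing_x_mm = vol$lateral_spacing_x_mm,
    lateral_spacing_y_mm = vol$lateral_spacing_y_mm,
    tissue_index = vol$tissue_index,
    laterality = vol$laterality,
    refractive_error = vol$refractive_error,
    seed = vol$seed,
    generator = vol$generator
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return An `oct_volume`.
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) stop("volume TIFF not found: ", path)
  if (!file.exists(sc))
    stop("missing sidecar: expected metadata at ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  req <- c("n_axial", "n_alines", "n_bscans", "axial_spacing_air_um",
           "lateral_spacing_x_mm", "lateral_spacing_y_mm", "laterality")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("sidecar schema invalid, missing: ", paste(miss, collapse = ", "))
  if (meta$axial_spacing_air_um <= 0 || meta$lateral_spacing_x_mm <= 0 ||
      meta$lateral_spacing_y_mm <= 0)
    stop("sidecar spacing must be > 0")
  if (!meta$laterality %in% c("OD", "OS"))
    stop("sidecar laterality must be 'OD' or 'OS'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bscans ||
      nrow(pages[[1]]) != meta$n_axial || ncol(pages[[1]]) != meta$n_alines)
    stop(sprintf(
      "dimension mismatch between TIFF (%d x %d x %d) and sidecar (%d x %d x %d)",
      nrow(pages[[1]]), ncol(pages[[1]]), length(pages),
      meta$n_axial, meta$n_alines, meta$n_bscans))
  intensity <- array(unlist(pages), c(meta$n_axial, meta$n_alines,
                                      meta$n_bscans))
  prm <- list(axial_spacing_air_um = meta$axial_spacing_air_um,
              axial_offset_air_um = meta$axial_offset_air_um %||% 0,
              lateral_spacing_x_mm = meta$lateral_spacing_x_mm,
              lateral_spacing_y_mm = meta$lateral_spacing_y_mm,
              tissue_index = meta$tissue_index %||% 1.38)
  new_oct_volume(intensity, prm,
                 seed = meta$seed %||% NA_integer_,
                 laterality = meta$laterality,
                 refractive_error = meta$refractive_error %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a data frame for CSV with NaN written literally so invalid cells
# survive a round trip; doubles at full precision.
format_csv_df <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.nan(col)] <- "NaN"
      out[is.na(col) & !is.nan(col)] <- "NA"
      out
    } else col
  })
  df
}

#' Write / read a data table as CSV
#'
#' Plain RFC-4180-style CSV with a header row, `.` decimal separator and
#' UTF-8 encoding. Doubles are written at full precision and `NaN` cells are
#' preserved literally.
#'
#' @param df A data frame or tibble.
#' @param path Output path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_table <- function(df, path) {
  utils::write.csv(format_csv_df(as.data.frame(df)), path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    warning = function(w) stop("malformed CSV at ", path, ": ",
                               conditionMessage(w)),
    error = function(e) stop("malformed CSV at ", path, ": ",
                             conditionMessage(e)))
  tibble::as_tibble(df)
}

#' Write / read a thickness map in long format
#'
#' Columns `x_mm`, `y_mm`, `ct_um`, `valid`; invalid cells carry `NaN`
#' thickness. Positions are scanner-frame mm (centred axes).
#'
#' @param ctmap A `thickness_map` (see [thickness_normal()]).
#' @param path CSV path.
#' @return `path` invisibly; the reader returns a `thickness_map`.
#' @export
write_thickness_map <- function(ctmap, path) {
  stopifnot(inherits(ctmap, "thickness_map"))
  nx <- nrow(ctmap$ct); ny <- ncol(ctmap$ct)
  x <- lateral_axis(nx, ctmap$lateral_spacing_x_mm)
  y <- lateral_axis(ny, ctmap$lateral_spacing_y_mm)
  df <- data.frame(x_mm = rep(x, times = ny), y_mm = rep(y, each = nx),
                   ct_um = as.vector(ctmap$ct),
                   valid = as.vector(ctmap$valid))
  df$ct_um[!df$valid] <- NaN
  write_table(df, path)
  # sidecar keeps grid geometry and fovea so the map can be reconstructed
  jsonlite::write_json(list(
    nx = nx, ny = ny,
    lateral_spacing_x_mm = ctmap$lateral_spacing_x_mm,
    lateral_spacing_y_mm = ctmap$lateral_spacing_y_mm,
    fovea_x_mm = ctmap$fovea_xy[1], fovea_y_mm = ctmap$fovea_xy[2],
    laterality = ctmap$laterality
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  df <- read_table(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ct <- matrix(df$ct_um, meta$nx, meta$ny)
  valid <- matrix(df$valid, meta$nx, meta$ny)
  new_thickness_map(ct, valid,
                    c(meta$fovea_x_mm, meta$fovea_y_mm),
                    meta$lateral_spacing_x_mm, meta$lateral_spacing_y_mm,
                    meta$laterality)
}

#' Write sector summaries for a cohort, one row per eye
#'
#' Columns: `eye_id`, `group`, `laterality`, `refractive_error`, `iol_mm`,
#' then the nine sector means in the fixed order
#' Fovea, NIM, SIM, TIM, IIM, NOM, SOM, TOM, IOM.
#'
#' @param records A cohort results tibble (see [run_cohort_pipeline()]).
#' @param path CSV path.
#' @export
write_sector_table <- function(records, path) {
  cols <- c("eye_id", "group", "laterality", "refractive_error", "iol_mm",
            SECTOR_NAMES)
  keep <- intersect(cols, names(records))
  write_table(records[, keep, drop = FALSE], path)
}
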