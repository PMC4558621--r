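# Shared fixtures: small rendering configurations and hand-built geometry.
# Everything is generated in code; no binary fixtures.

# Desk-scale render params covering the full ~10 x 5 mm field with fewer
# samples, for fast end-to-end tests.
prm_small <- function(...) {
  args <- utils::modifyList(
    list(n_axial = 232L, n_alines = 96L, n_bscans = 16L,
         lateral_spacing_x_mm = 10 / 96, lateral_spacing_y_mm = 5 / 16),
    list(...))
  do.call(render_params, args)
}

# Group parameters with every sector at the same CT and zero spread.
const_group <- function(ct = 250, sd = 0, iol_mean = 24.5, iol_sd = 0) {
  list(sector_mean = stats::setNames(rep(ct, 9), SECTOR_NAMES),
       sector_sd = stats::setNames(rep(sd, 9), SECTOR_NAMES),
       iol_mean = iol_mean, iol_sd = iol_sd)
}

# Surface map from a position matrix (A-lines x B-scans), all valid.
surface_from_z <- function(z, boundary = "RPE_outer") {
  choromap:::new_surface_map(boundary, z, matrix(TRUE, nrow(z), ncol(z)))
}

# Thickness map straight from a CT matrix.
map_from_ct <- function(ct, sx = 0.05, sy = 0.05, fovea = c(0, 0),
                        laterality = "OD", valid = NULL) {
  if (is.null(valid)) valid <- is.finite(ct)
  choromap:::new_thickness_map(ct, valid, fovea, sx, sy, laterality)
}

# Brute-force minimum-cost smoothness-feasible path by exhaustive enumeration
# (oracle for the dynamic-programming search). Cost convention matches
# segment_surface: minimize the summed signed-gradient cost.
enumerate_min_path <- function(cost, smoothness) {
  nr <- nrow(cost); nc <- ncol(cost)
  offs <- seq(-smoothness, smoothness)
  grid <- as.matrix(expand.grid(rep(list(offs), nc - 1)))
  best_cost <- Inf; best_path <- NULL
  for (start in seq_len(nr)) {
    # cumulative rows: start + running sum of the per-column offsets
    cum <- grid %*% upper.tri(matrix(0, nc - 1, nc - 1), diag = TRUE)
    rows <- cbind(start, start + cum)
    feas <- rowSums(rows < 1 | rows > nr) == 0
    if (!any(feas)) next
    rows <- rows[feas, , drop = FALSE]
    tot <- rep(0, nrow(rows))
    for (j in seq_len(nc)) tot <- tot + cost[cbind(rows[, j], j)]
    k <- which.min(tot)
    if (tot[k] < best_cost) { best_cost <- tot[k]; best_path <- rows[k, ] }
  }
  list(cost = best_cost, path = best_path)
}

# Signed-gradient cost matrix as segment_surface builds it.
gradient_cost <- function(img, polarity) {
  g <- choromap:::depth_gradient(img)
  if (polarity == "dark_to_bright") -g else g
}
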