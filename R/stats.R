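# Cohort statistics: myopia severity grouping, per-group sector tables,
# classical two-sample comparisons and per-diopter reduction rates.

#' Assign a myopia severity group from the refractive error
#'
#' Magnitude `m = |D|`: low if `m <= 3`, moderate if `3 < m < 6`, high if
#' `m >= 6`. Only myopic (non-positive) errors are in scope.
#'
#' @param refractive_error Signed refractive error(s), diopters (<= 0).
#' @return Character vector of `"low"`, `"moderate"`, `"high"`.
#' @export
assign_group <- function(refractive_error) {
  if (any(refractive_error > 0))
    stop("hyperopic (positive) refractive error is out of scope")
  m <- abs(refractive_error)
  ifelse(m <= 3, "low", ifelse(m < 6, "moderate", "high"))
}

#' Classical two-sample Student's t-test
#'
#' Pooled-variance two-sample t with `n_a + n_b - 2` degrees of freedom and a
#' two-sided p-value (Welch's correction available by flag). Degenerate
#' zero-variance inputs are resolved explicitly: equal means give `t = 0,
#' p = 1`; unequal means give `p = 0` with a `degenerate` flag.
#'
#' @param sample_a,sample_b Numeric samples, each of length >= 2.
#' @param welch Use Welch's unequal-variance form instead.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
students_t <- function(sample_a, sample_b, welch = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2,
            all(is.finite(sample_a)), all(is.finite(sample_b)))
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, p = 1, df = length(sample_a) + length(sample_b) - 2,
                  degenerate = FALSE))
    return(list(t = Inf * sign(mean(sample_a) - mean(sample_b)), p = 0,
                df = length(sample_a) + length(sample_b) - 2,
                degenerate = TRUE))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Per-diopter reduction rate between two group means
#'
#' `(mean_a - mean_b) / diopter_span`; adjacent severity-group midpoints are
#' 3 D apart, the default span. Report CT rates in um/D at 2 decimals and IOL
#' rates in mm/D at 3 decimals.
#'
#' @param mean_a,mean_b Group means (thicker/shorter group first for a
#'   positive thinning rate).
#' @param diopter_span Diopter distance between the groups (> 0).
#' @return Rate per diopter (full precision).
#' @export
reduction_rate <- function(mean_a, mean_b, diopter_span = 3) {
  stopifnot(diopter_span > 0)
  (mean_a - mean_b) / diopter_span
}

#' Per-group sector statistics, pairwise tests and reduction rates
#'
#' @param records Cohort results tibble (one row per eye) as produced by
#'   [run_cohort_pipeline()]: columns `group`, `excluded`, `iol_mm` and the
#'   nine sector columns. Excluded eyes are dropped before any statistic.
#' @param diopter_span Span for the reduction rates, D.
#' @return List of tibbles: `summary` (group x variable mean/sd/n; sd missing
#'   for n < 2, cells missing for empty groups), `comparisons` (pairwise
#'   pooled t per variable) and `rates` (per-diopter reduction low->moderate
#'   and moderate->high for subfoveal CT and IOL).
#' @export
group_table <- function(records, diopter_span = 3) {
  stopifnot(is.data.frame(records), "group" %in% names(records))
  if ("excluded" %in% names(records)) records <- records[!records$excluded, ]
  if (!nrow(records)) stop("no non-excluded records")
  vars <- c(intersect(SECTOR_NAMES, names(records)),
            intersect("iol_mm", names(records)))
  groups <- c("low", "moderate", "high")
  summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]]
      x <- x[is.finite(x)]
      n <- length(x)
      tibble::tibble(group = g, variable = v,
                     mean = if (n) mean(x) else NA_real_,
                     sd = if (n >= 2) stats::sd(x) else NA_real_,
                     n = n, missing = n == 0)
    }))
  }))
  pairs <- list(c("low", "moderate"), c("moderate", "high"), c("low", "high"))
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(vars, function(v) {
      a <- records[[v]][records$group == p[1]]
      b <- records[[v]][records$group == p[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2)
        return(tibble::tibble(group_a = p[1], group_b = p[2], variable = v,
                              t = NA_real_, p = NA_real_, df = NA_real_))
      ht <- students_t(a, b)
      tibble::tibble(group_a = p[1], group_b = p[2], variable = v,
                     t = ht$t, p = ht$p, df = ht$df)
    }))
  }))
  gmean <- function(g, v) {
    s <- summary[summary$group == g & summary$variable == v, ]
    if (nrow(s)) s$mean else NA_real_
  }
  rate_vals <- c(
    reduction_rate(gmean("low", "Fovea"), gmean("moderate", "Fovea"),
                   diopter_span),
    reduction_rate(gmean("moderate", "Fovea"), gmean("high", "Fovea"),
                   diopter_span),
    if ("iol_mm" %in% vars)
      reduction_rate(gmean("moderate", "iol_mm"), gmean("low", "iol_mm"),
                     diopter_span) else NA_real_,
    if ("iol_mm" %in% vars)
      reduction_rate(gmean("high", "iol_mm"), gmean("moderate", "iol_mm"),
                     diopter_span) else NA_real_)
  rates <- tibble::tibble(
    variable = c("Fovea", "Fovea", "iol_mm", "iol_mm"),
    from = c("low", "moderate", "low", "moderate"),
    to = c("moderate", "high", "moderate", "high"),
    diopter_span = diopter_span,
    rate_per_D = rate_vals)
  list(summary = summary, comparisons = comparisons, rates = rates)
}

#' En-face fundus projection of a volume
#'
#' Maximum intensity over depth per lateral position (the OCT fundus image).
#'
#' @param vol An `oct_volume`.
#' @return Matrix A-lines x B-scans.
#' @export
fundus_projection <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  apply(vol$intensity, c(2L, 3L), max)
}

# Fixed CT colour scale: blue (thin) -> red (thick) over ct_range um.
ct_colour <- function(ct_um, ct_range = c(50, 350)) {
  ramp <- grDevices::colorRamp(c("#2c7bb6", "#abd9e9", "#ffffbf",
                                 "#fdae61", "#d7191c"))
  u <- pmin(pmax((ct_um - ct_range[1]) / diff(ct_range), 0), 1)
  ramp(u) / 255
}

#' Render a geographic CT map over the fundus projection
#'
#' Greyscale en-face maximum projection with the nine sector means coloured on
#' a fixed CT scale (blue 50 um to red 350 um) inside the 10 mm grid, plus a
#' colour scale bar along the right edge. Output is deterministic for fixed
#' input.
#'
#' @param ctmap A `thickness_map`.
#' @param sectors A [sector_summary()] tibble for the same map.
#' @param vol Optional `oct_volume` for the fundus background (mid-grey
#'   otherwise).
#' @param file Optional PNG path; written with [png::writePNG()].
#' @param alpha Overlay opacity of the sector colours.
#' @param ct_range Colour scale range, um.
#' @return RGB array (height x width x 3) invisibly.
#' @export
render_ct_map <- function(ctmap, sectors, vol = NULL, file = NULL,
                          alpha = 0.55, ct_range = c(50, 350)) {
  stopifnot(inherits(ctmap, "thickness_map"))
  nx <- nrow(ctmap$ct); ny <- ncol(ctmap$ct)
  bg <- if (!is.null(vol)) {
    f <- fundus_projection(vol)
    rng <- range(f)
    if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0 + 0.5
  } else matrix(0.5, nx, ny)
  img <- array(rep(t(bg), 3), c(ny, nx, 3))   # rows = B-scans for display
  co <- anatomical_coords(ctmap)
  radii <- c(0.5, 2.5, 5)
  ring <- ifelse(co$r < radii[1], "F",
                 ifelse(co$r < radii[2], "IM",
                        ifelse(co$r < radii[3], "OM", NA)))
  quad <- ifelse(abs(co$u) >= abs(co$s),
                 ifelse(co$u < 0, "N", "T"),
                 ifelse(co$s > 0, "S", "I"))
  lab <- ifelse(ring == "F", "Fovea", paste0(quad, ring))
  lab[is.na(ring)] <- NA
  for (k in seq_len(nrow(sectors))) {
    if (isTRUE(sectors$missing[k])) next
    sel <- which(!is.na(lab) & lab == sectors$sector[k], arr.ind = TRUE)
    if (!nrow(sel)) next
    colr <- ct_colour(sectors$mean_ct_um[k], ct_range)
    for (ch in 1:3) {
      idx <- cbind(sel[, 2], sel[, 1], ch)
      img[idx] <- (1 - alpha) * img[idx] + alpha * colr[ch]
    }
  }
  # scale bar: rightmost 3 columns sweep the colour range top (thick) to
  # bottom (thin)
  bar_vals <- seq(ct_range[2], ct_range[1], length.out = ny)
  bar <- ct_colour(bar_vals, ct_range)
  for (ch in 1:3) img[, (nx - 2):nx, ch] <- matrix(bar[, ch], ny, 3)
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}
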