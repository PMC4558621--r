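test_that("constant sector parameters give a constant CT field", {
  truth <- make_eye_truth(const_group(250, 0), seed = 1)
  tt <- seq(-5, 5, by = 0.25)
  ss <- seq(-2.5, 2.5, by = 0.25)
  vals <- ct_field(truth, rep(tt, times = length(ss)),
                   rep(ss, each = length(tt)))
  expect_equal(unname(vals), rep(250, length(vals)))
})

test_that("eye truth is a deterministic function of the seed", {
  g <- default_cohort_spec()$low
  a <- make_eye_truth(g, seed = 7)
  b <- make_eye_truth(g, seed = 7)
  expect_identical(a, b)
  c <- make_eye_truth(g, seed = 8)
  expect_false(identical(a$sectors, c$sectors))
})

test_that("invalid laterality is rejected", {
  expect_error(make_eye_truth(const_group(), laterality = "left"),
               "laterality")
})

test_that("subfoveal truth draws follow the configured sampling distribution", {
  g <- default_cohort_spec()$low
  draws <- vapply(seq_len(1000), function(s)
    make_eye_truth(g, seed = 10000 + s)$sectors[["Fovea"]], numeric(1))
  se <- g$sector_sd[["Fovea"]] / sqrt(length(draws))
  expect_lt(abs(mean(draws) - g$sector_mean[["Fovea"]]), 3 * se)
})

test_that("CT field at the pit centre equals the drawn Fovea value", {
  g <- default_cohort_spec()$moderate
  for (s in 1:5) {
    truth <- make_eye_truth(g, seed = s)
    expect_equal(unname(ct_field(truth, 0, 0)),
                 unname(truth$sectors[["Fovea"]]), tolerance = 1e-9)
  }
})

test_that("ground-truth surfaces are strictly ordered in depth", {
  g <- default_cohort_spec()$high
  x <- seq(-5, 5, length.out = 41); y <- seq(-2.5, 2.5, length.out = 21)
  for (s in 1:5) {
    surf <- truth_surfaces(make_eye_truth(g, seed = 100 + s), x, y)
    expect_true(all(surf$ilm_um < surf$rpe_um))
    expect_true(all(surf$rpe_um < surf$csi_um))
    expect_true(all(surf$ct_um > 0))
  }
})

test_that("rendered volumes are finite, nonnegative and in [0, 1]", {
  truth <- make_eye_truth(const_group(), seed = 3)
  vol <- render_volume(truth, prm_small(), seed = 3)
  expect_true(all(is.finite(vol$intensity)))
  expect_true(all(vol$intensity >= 0 & vol$intensity <= 1))
})

test_that("speckle- and motion-free renders segment to within a pixel of truth", {
  # full scan density: at coarser grids the surface median filter distorts
  # the sharply curved pit vertex
  prm <- render_params(speckle_on = FALSE, motion_on = FALSE)
  truth <- make_eye_truth(const_group(260, 0), seed = 5)
  vol <- render_volume(truth, prm, seed = 5)
  seg <- segment_volume(vol)
  x <- choromap:::lateral_axis(prm$n_alines, prm$lateral_spacing_x_mm)
  y <- choromap:::lateral_axis(prm$n_bscans, prm$lateral_spacing_y_mm)
  surf <- truth_surfaces(truth, x, y)
  to_px <- function(z) choromap:::geom_to_px(z, prm)
  for (pair in list(list("ilm", surf$ilm_um), list("rpe_outer", surf$rpe_um),
                    list("csi", surf$csi_um))) {
    err <- abs(seg[[pair[[1]]]]$z - to_px(pair[[2]]))
    expect_lt(max(err[seg[[pair[[1]]]]$valid], na.rm = TRUE), 1)
  }
})

test_that("depth attenuation halves the signal at the 6 dB roll-off depth", {
  expect_equal(sensitivity_rolloff(3, 3), 0.5)
  expect_equal(sensitivity_rolloff(0), 1)
  # render the same eye near the top of the window and 3 mm deeper
  base <- list(n_axial = 640L, n_alines = 32L, n_bscans = 4L,
               lateral_spacing_x_mm = 10 / 32, lateral_spacing_y_mm = 5 / 4,
               speckle_on = FALSE, motion_on = FALSE)
  prm1 <- do.call(render_params, c(base, axial_offset_air_um = 100))
  prm2 <- do.call(render_params, c(base, axial_offset_air_um = 100 + 3000))
  truth <- make_eye_truth(const_group(150, 0), seed = 9,
                          rpe_curv_um_mm2 = 0, pit_depth_um = 0)
  v1 <- render_volume(truth, prm1, seed = 1)
  v2 <- render_volume(truth, prm2, seed = 1)
  p1 <- max(v1$intensity[, 16, 2]) - prm1$noise_floor / prm1$saturation
  p2 <- max(v2$intensity[, 16, 2]) - prm2$noise_floor / prm2$saturation
  d1 <- (which.max(v1$intensity[, 16, 2]) - 1) * prm1$axial_spacing_air_um / 1000
  d2 <- (which.max(v2$intensity[, 16, 2]) - 1) * prm2$axial_spacing_air_um / 1000
  expected <- sensitivity_rolloff(d2) / sensitivity_rolloff(d1)
  expect_equal(p2 / p1, expected, tolerance = 0.05)
  expect_equal(expected, 0.5, tolerance = 0.01)
})

test_that("an all-zero motion trace renders identically to motion disabled", {
  truth <- make_eye_truth(const_group(), seed = 11)
  truth$motion_trace[] <- 0L
  prm_on <- prm_small(motion_on = TRUE)
  prm_off <- prm_small(motion_on = FALSE)
  v1 <- render_volume(truth, prm_on, seed = 4)
  v2 <- render_volume(truth, prm_off, seed = 4)
  expect_identical(v1$intensity, v2$intensity)
})

test_that("an eye too deep for the axial window errors with the B-scan named", {
  truth <- make_eye_truth(const_group(400, 0), seed = 2)
  prm <- prm_small(n_axial = 96L)
  expect_error(render_volume(truth, prm), "axial window in B-scan")
})

test_that("composite A-scan peak separation follows the mirror-offset geometry", {
  g <- const_group()
  for (s in 1:20) {
    truth <- make_eye_truth(g, seed = 200 + s)
    truth$iol_true <- runif(1, 23, 26)
    a <- render_composite_ascan(truth)
    pk <- detect_peaks(a)
    d_true <- 35 - 1.3375 * truth$iol_true
    expect_lt(abs(pk$d_mm - d_true), a$axial_spacing_air_um / 2 / 1000)
  }
})

test_that("a cornea peak near 4 mm lands where the geometry predicts", {
  truth <- make_eye_truth(const_group(), seed = 1)
  truth$iol_true <- (35 - 4) / 1.3375
  a <- render_composite_ascan(truth)
  pk <- detect_peaks(a)
  expect_equal(pk$d_mm, 4, tolerance = 1e-3)
})

test_that("a cornea peak outside the window is rejected", {
  truth <- make_eye_truth(const_group(), seed = 1)
  truth$iol_true <- 20            # d = 8.25 mm > 6.1 mm window
  expect_error(render_composite_ascan(truth), "outside the .*window")
  truth$iol_true <- 27            # n * IOL > delta_L_ref
  expect_error(render_composite_ascan(truth), "delta_L_ref")
})

test_that("generate_cohort honours group sizes, labels and seeds", {
  spec <- default_cohort_spec()
  coh <- generate_cohort(spec, seed = 3, render = FALSE)
  expect_length(coh, 40)
  expect_equal(sum(vapply(coh, function(r) r$group == "low", logical(1))), 20)
  for (r in coh) {
    expect_identical(r$group, assign_group(r$refractive_error))
    expect_s3_class(r$truth, "eye_truth")
  }
  coh2 <- generate_cohort(spec, seed = 3, render = FALSE)
  expect_identical(lapply(coh, `[[`, "truth"), lapply(coh2, `[[`, "truth"))
  coh3 <- generate_cohort(spec, seed = 4, render = FALSE)
  expect_false(identical(coh[[1]]$truth$sectors, coh3[[1]]$truth$sectors))
  empty <- spec
  empty$low$n_eyes <- 0L; empty$moderate$n_eyes <- 0L; empty$high$n_eyes <- 0L
  expect_length(generate_cohort(empty, seed = 1, render = FALSE), 0)
})
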