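axial_um <- 8 / 1.38   # geometric um per axial pixel at the default pitch

test_that("flat parallel surfaces give the vertical separation everywhere", {
  nx <- 40; ny <- 20
  rpe <- surface_from_z(matrix(100, nx, ny))
  csi <- surface_from_z(matrix(100 + 250 / axial_um, nx, ny), "CSI")
  m <- thickness_normal(rpe, csi, 0.05, 0.05, axial_um)
  expect_true(all(m$valid))
  expect_equal(max(abs(m$ct - 250)), 0, tolerance = 1e-6)
})

test_that("tilted parallel planes obey the cos-theta oblique distance", {
  nx <- 80; ny <- 40; sx <- 0.05; sy <- 0.05
  x_um <- choromap:::lateral_axis(nx, sx) * 1000
  slope <- tan(30 * pi / 180)
  v <- 200  # vertical separation, um
  z1 <- matrix(3000 + slope * x_um, nx, ny) / axial_um
  z2 <- z1 + v / axial_um
  m <- thickness_normal(surface_from_z(z1), surface_from_z(z2, "CSI"),
                        sx, sy, axial_um, smooth_sigma_mm = 0)
  interior <- m$ct[5:(nx - 4), ]
  expect_lt(max(abs(interior - v * cos(30 * pi / 180)), na.rm = TRUE), 1)
})

test_that("curved geometry matches a dense brute-force normal search", {
  nx <- 48; ny <- 32; sx <- 0.08; sy <- 0.08
  x_um <- choromap:::lateral_axis(nx, sx) * 1000
  y_um <- choromap:::lateral_axis(ny, sy) * 1000
  X <- matrix(x_um, nx, ny); Y <- matrix(y_um, nx, ny, byrow = TRUE)
  z1_um <- 3000 + 120 * sin(X / 900) + 80 * cos(Y / 700)
  z2_um <- z1_um + 220 + 60 * sin((X + Y) / 1100)
  m <- thickness_normal(surface_from_z(z1_um / axial_um),
                        surface_from_z(z2_um / axial_um, "CSI"),
                        sx, sy, axial_um, smooth_sigma_mm = 0)
  # independent oracle: own finite-difference normals + 0.01-px-step march
  # with its own bilinear interpolation
  interp <- function(zm, ri, ci) {
    if (ri < 1 || ri > nx || ci < 1 || ci > ny) return(NA_real_)
    r0 <- min(floor(ri), nx - 1); c0 <- min(floor(ci), ny - 1)
    fr <- ri - r0; fc <- ci - c0
    (1 - fr) * (1 - fc) * zm[r0, c0] + fr * (1 - fc) * zm[r0 + 1, c0] +
      (1 - fr) * fc * zm[r0, c0 + 1] + fr * fc * zm[r0 + 1, c0 + 1]
  }
  step <- 0.01 * axial_um
  for (cell in list(c(10, 10), c(24, 16), c(35, 25), c(15, 20))) {
    i <- cell[1]; j <- cell[2]
    gx <- (z1_um[i + 1, j] - z1_um[i - 1, j]) / (2 * sx * 1000)
    gy <- (z1_um[i, j + 1] - z1_um[i, j - 1]) / (2 * sy * 1000)
    nn <- sqrt(1 + gx^2 + gy^2)
    nvec <- c(-gx, -gy, 1) / nn
    t <- 0; found <- NA_real_
    repeat {
      t <- t + step
      if (t > 1000) break
      ri <- i + t * nvec[1] / (sx * 1000)
      ci <- j + t * nvec[2] / (sy * 1000)
      zc <- interp(z2_um, ri, ci)
      if (is.na(zc)) break
      if (z1_um[i, j] + t * nvec[3] >= zc) { found <- t; break }
    }
    expect_lt(abs(m$ct[i, j] - found), 1)
  }
})

test_that("rays with no interface crossing are marked invalid", {
  nx <- 20; ny <- 10
  rpe <- surface_from_z(matrix(50, nx, ny))
  csi <- surface_from_z(matrix(50 + 2000 / axial_um, nx, ny), "CSI")
  m <- thickness_normal(rpe, csi, 0.05, 0.05, axial_um, max_ct_um = 1000)
  expect_false(any(m$valid))
})

test_that("the foveal pit is located from the ILM depression", {
  nx <- 96; ny <- 48; sx <- 10 / 96; sy <- 5 / 48
  x <- choromap:::lateral_axis(nx, sx); y <- choromap:::lateral_axis(ny, sy)
  mk_ilm <- function(cx, cy, curv = 8) {
    X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
    r2 <- (X - cx)^2 + (Y - cy)^2
    z_um <- 1200 + curv * r2 + 110 * exp(-r2 / (2 * 0.6^2))
    surface_from_z(z_um / axial_um, "ILM")
  }
  f0 <- locate_fovea(mk_ilm(0, 0), sx, sy, axial_um)
  expect_lt(max(abs(f0)), max(sx, sy))
  f1 <- locate_fovea(mk_ilm(0.8, -0.4), sx, sy, axial_um)
  expect_lt(abs(f1[1] - 0.8), sx * 1.5)
  expect_lt(abs(f1[2] + 0.4), sy * 1.5)
  flat <- surface_from_z(matrix(200, nx, ny), "ILM")
  expect_error(locate_fovea(flat, sx, sy, axial_um), "no foveal pit")
})

test_that("sector means reduce to the constant on a constant map", {
  m <- map_from_ct(matrix(260, 220, 120), sx = 0.05, sy = 0.05)
  ss <- sector_summary(m)
  expect_identical(ss$sector, SECTOR_NAMES)
  expect_true(all(abs(ss$mean_ct_um - 260) < 1e-9))
  pr <- ring_profile(m)
  expect_equal(nrow(pr), 11)
  expect_true(all(abs(pr$mean_ct_um - 260) < 1e-9))
})

test_that("a radially symmetric map gives equal inner-quadrant means", {
  n <- 220
  ax <- choromap:::lateral_axis(n, 0.05)
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  m <- map_from_ct(150 + 20 * r, sx = 0.05, sy = 0.05)
  ss <- sector_summary(m)
  inner <- ss$mean_ct_um[ss$sector %in% c("NIM", "SIM", "TIM", "IIM")]
  expect_lt(diff(range(inner)), 1)
})

test_that("sector means match a brute-force per-pixel classification oracle", {
  nx <- 160; ny <- 90; sx <- 10 / 160; sy <- 5 / 90
  x <- choromap:::lateral_axis(nx, sx); y <- choromap:::lateral_axis(ny, sy)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  fovea <- c(0.18, -0.12)
  ct <- 200 + 8 * X + 5 * Y
  for (lat in c("OD", "OS")) {
    m <- map_from_ct(ct, sx, sy, fovea = fovea, laterality = lat)
    ss <- sector_summary(m)
    acc <- stats::setNames(vector("list", 9), SECTOR_NAMES)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      u <- (x[i] - fovea[1]) * (if (lat == "OD") 1 else -1)
      s <- y[j] - fovea[2]
      r <- sqrt(u^2 + s^2)
      if (r >= 5) next
      sec <- if (r < 0.5) "Fovea" else {
        quad <- if (abs(u) >= abs(s)) (if (u < 0) "N" else "T")
                else (if (s > 0) "S" else "I")
        paste0(quad, if (r < 2.5) "IM" else "OM")
      }
      acc[[sec]] <- c(acc[[sec]], ct[i, j])
    }
    for (sec in SECTOR_NAMES) {
      got <- ss$mean_ct_um[ss$sector == sec]
      if (is.null(acc[[sec]])) expect_true(is.na(got))
      else expect_equal(got, mean(acc[[sec]]), tolerance = 1e-12)
    }
  }
})

test_that("sectors partition the 10 mm disk and conserve the disk mean", {
  set.seed(5)
  nx <- 220; ny <- 110; sx <- 10 / 220; sy <- 5 / 110
  ct <- matrix(runif(nx * ny, 80, 350), nx, ny)
  m <- map_from_ct(ct, sx, sy, fovea = c(0.1, 0.05))
  ss <- sector_summary(m)
  co <- choromap:::anatomical_coords(m)
  in_disk <- co$r < 5
  expect_equal(sum(ss$n_pixels), sum(in_disk))       # exactly one sector each
  disk_mean <- mean(ct[in_disk])
  weighted <- sum(ss$mean_ct_um * ss$n_valid) / sum(ss$n_valid)
  expect_equal(weighted, disk_mean, tolerance = 1e-6)
})

test_that("OD and mirrored OS data agree on every named sector and ring bin", {
  set.seed(6)
  nx <- 200; ny <- 100; sx <- 10 / 200; sy <- 5 / 100
  ct <- matrix(runif(nx * ny, 80, 350), nx, ny)
  fovea <- c(0.3, -0.15)
  od <- map_from_ct(ct, sx, sy, fovea = fovea, laterality = "OD")
  os <- map_from_ct(ct[nx:1, ], sx, sy, fovea = c(-fovea[1], fovea[2]),
                    laterality = "OS")
  ss_od <- sector_summary(od); ss_os <- sector_summary(os)
  expect_equal(ss_od$mean_ct_um, ss_os$mean_ct_um, tolerance = 1e-12)
  expect_equal(ring_profile(od)$mean_ct_um, ring_profile(os)$mean_ct_um,
               tolerance = 1e-12)
})

test_that("a fovea outside the grid is rejected", {
  m <- map_from_ct(matrix(200, 40, 20), fovea = c(30, 0))
  expect_error(sector_summary(m), "outside")
})

test_that("empty ring bins are flagged missing rather than zero", {
  ct <- matrix(200, 30, 16)
  valid <- matrix(FALSE, 30, 16)
  valid[13:18, 7:10] <- TRUE     # only a central patch is valid
  m <- map_from_ct(ct, sx = 10 / 30, sy = 5 / 16, valid = valid)
  pr <- ring_profile(m)
  expect_true(any(pr$missing))
  expect_true(all(is.na(pr$mean_ct_um[pr$missing])))
})
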