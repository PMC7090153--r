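test_that("Du Bois BSA reproduces the reference value and the power law", {
  b <- compute_bsa(80, 176)
  expect_equal(b$m2, 1.96, tolerance = 0.005)
  expect_equal(compute_bsa(160, 176)$m2 / b$m2, 2^0.425, tolerance = 1e-12)
  expect_error(compute_bsa(0, 176), "positive")
  expect_error(compute_bsa(80, -1), "positive")
})

test_that("dose resampling is exact on identical grids, constants and ramps", {
  d <- array(runif(6 * 5 * 4, 0, 70), c(6, 5, 4))
  vol <- image_volume(d, c(2, 2, 2.5), units = "Gy")
  expect_identical(resample_dose(vol, vol)$data, vol$data)

  const <- image_volume(array(7, c(6, 5, 4)), c(2, 2, 2.5), units = "Gy")
  tgt <- image_volume(array(0, c(5, 4, 3)), c(2.3, 2.3, 3),
                      origin = c(0.7, 0.4, 0.2), units = "Gy")
  expect_true(all(abs(resample_dose(const, tgt)$data - 7) < 1e-12))

  # trilinear interpolation reproduces affine fields exactly (inside)
  g <- skinNTCP:::grid_coords(c(10, 10, 8), c(2, 2, 2.5))
  ramp <- outer(outer(2 * g$x, 0.5 * g$y, "+"), 0.25 * g$z, "+")
  src <- image_volume(ramp, c(2, 2, 2.5), units = "Gy")
  tg <- skinNTCP:::grid_coords(c(8, 8, 6), c(2, 2, 2.5),
                               origin = c(1.1, 0.9, 1.3))
  tgt2 <- image_volume(array(0, c(8, 8, 6)), c(2, 2, 2.5),
                       origin = c(1.1, 0.9, 1.3), units = "Gy")
  got <- resample_dose(src, tgt2)$data
  want <- outer(outer(2 * tg$x, 0.5 * tg$y, "+"), 0.25 * tg$z, "+")
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(resample_dose(src, image_volume(array(0, c(4, 4, 4)),
                                               c(2, 2, 2), origin = c(500, 0, 0),
                                               units = "Gy")),
               "disjoint")
})

test_that("DVH matches step constructions and a voxel-counting oracle", {
  mask <- binary_mask(array(TRUE, c(4, 4, 4)), c(2, 2, 2))
  vol_cm3 <- mask_volume_cm3(mask)
  uni <- compute_dvh(uniform_dose(mask, 10), mask, bin_width = 1)
  expect_equal(uni$volume[uni$edges == 0], vol_cm3)
  expect_equal(uni$volume[uni$edges == 5], vol_cm3)
  expect_equal(uni$volume[uni$edges == 10], 0)

  half <- array(0, c(4, 4, 4)); half[1:2, , ] <- 20
  dvh <- compute_dvh(image_volume(half, c(2, 2, 2), units = "Gy"), mask,
                     bin_width = 1)
  expect_equal(dvh$volume[dvh$edges == 10], vol_cm3 / 2)

  set.seed(5)
  rnd <- array(runif(64, 0, 30), c(4, 4, 4))
  dvh2 <- compute_dvh(image_volume(rnd, c(2, 2, 2), units = "Gy"), mask,
                      bin_width = 0.5)
  for (x in c(0.5, 7, 15.5, 29.5)) {
    expect_equal(dvh2$volume[abs(dvh2$edges - x) < 1e-9],
                 sum(rnd > x) * 8 / 1000)
  }
  expect_error(compute_dvh(uniform_dose(mask, 1),
                           binary_mask(array(FALSE, c(4, 4, 4)), c(2, 2, 2))),
               "empty")
})

test_that("uniform-dose sphere DSH is a step with near-analytic total area", {
  ph <- sphere_phantom(R_mm = 40, spacing = 2)
  h <- compute_dsh(uniform_dose(ph$truth, 30), ph$truth)
  expect_equal(h$area[1], 4 * pi * 16, tolerance = 0.05)
  expect_equal(dsh_value(h, 29), h$area[1])
  expect_equal(dsh_value(h, 31), 0)
})

test_that("zero dose puts all area in the 0 Gy bin and every S_x at 0", {
  ph <- sphere_phantom(R_mm = 20, spacing = 2)
  h <- normalize_dsh(compute_dsh(uniform_dose(ph$truth, 0), ph$truth),
                     compute_bsa(80, 176))
  m <- extract_metrics(h)
  expect_gt(h$area[1], 0)
  expect_true(all(m$S == 0))
})

test_that("axial dose gradient on a sphere follows the spherical-cap line", {
  ph <- sphere_phantom(R_mm = 40, spacing = 2)
  d <- dim(ph$truth$data)
  g <- skinNTCP:::grid_coords(d, ph$truth$spacing)
  ctr <- (d[3] - 1) * 2 / 2
  dmax <- 10
  dz <- array(rep(dmax * ((g$z - ctr) + 40) / 80, each = d[1] * d[2]), d)
  h <- compute_dsh(image_volume(dz, ph$truth$spacing, units = "Gy"), ph$truth)
  for (x in c(2, 5, 8)) {
    expect_equal(dsh_value(h, x) / h$area[1], 1 - x / dmax, tolerance = 0.03)
  }
})

test_that("face and shell estimators agree on smooth phantoms", {
  ph <- sphere_phantom(R_mm = 40, spacing = 2)
  d <- dim(ph$truth$data)
  g <- skinNTCP:::grid_coords(d, ph$truth$spacing)
  dz <- array(rep(10 * ((g$z - 47) + 40) / 80, each = d[1] * d[2]), d)
  dose <- image_volume(dz, ph$truth$spacing, units = "Gy")
  hf <- compute_dsh(dose, ph$truth)
  hs <- compute_dsh(dose, ph$truth, method = "shell")
  expect_equal(hs$area[1], hf$area[1], tolerance = 0.05)
  for (x in c(2, 5, 8)) {
    expect_equal(dsh_value(hs, x), dsh_value(hf, x), tolerance = 0.05)
  }
})

test_that("sphere surface error shrinks by about half from 4 mm to 2 mm voxels", {
  truth <- 4 * pi * 16
  err <- sapply(c(4, 2), function(h) {
    ph <- sphere_phantom(R_mm = 40, spacing = h)
    abs(compute_dsh(uniform_dose(ph$truth, 10), ph$truth)$area[1] - truth) /
      truth
  })
  expect_lt(err[2], 0.7 * err[1])
})

test_that("DSH is additive over disjoint bodies", {
  n <- 40
  a <- array(FALSE, c(n, n, 16)); a[4:12, 14:26, 4:12] <- TRUE
  b <- array(FALSE, c(n, n, 16)); b[26:36, 14:26, 4:12] <- TRUE
  sp <- c(2, 2, 2.5)
  set.seed(11)
  dose <- image_volume(array(runif(n * n * 16, 0, 40), c(n, n, 16)), sp,
                       units = "Gy")
  ha <- compute_dsh(dose, binary_mask(a, sp), bin_width = 1)
  hb <- compute_dsh(dose, binary_mask(b, sp), bin_width = 1)
  hu <- compute_dsh(dose, binary_mask(a | b, sp), bin_width = 1)
  xs <- c(0, 5, 10, 20, 35)
  expect_equal(vapply(xs, function(x) dsh_value(hu, x), numeric(1)),
               vapply(xs, function(x) dsh_value(ha, x) + dsh_value(hb, x),
                      numeric(1)),
               tolerance = 1e-9)
})

test_that("normalization is arithmetic, invertible and BSA-guarded", {
  h <- dsh(seq(0, 30, 0.5), seq(200, 0, length.out = 61), "absolute")
  rel <- normalize_dsh(h, 2e4)  # 2 m^2 in cm^2
  expect_equal(rel$area[1], 1.0)  # 200 cm2 / 2 m2 = 1%
  back <- rel$area / 100 * rel$bsa_cm2
  expect_equal(back, h$area, tolerance = 1e-12)
  expect_error(normalize_dsh(h, 0), "positive")
  expect_error(normalize_dsh(rel, 2e4), "absolute")
})

test_that("volumetric thorax phantoms give S_5Gy inside the population envelope", {
  meds <- sapply(1:4, function(i) {
    set.seed(400 + i)
    ph <- make_phantom(phantom_spec(shape = c(48L, 48L, 32L),
                                    spacing = c(4, 4, 5),
                                    semi_axes = c(70, 50, 40) * runif(1, 0.92, 1.08)))
    mod <- if (i %% 2 == 0) "photon" else "proton"
    dose <- make_dose(beam_spec(mod, prescribed_dose = 74), ph$truth)
    h <- normalize_dsh(compute_dsh(dose, ph$truth, bin_width = 0.5),
                       compute_bsa(80, 176))
    s_metric(extract_metrics(h), 5)
  })
  expect_gt(median(meds), 0.7)
  expect_lt(median(meds), 6.6)
})

test_that("metrics read steps, interpolate linearly and keep D_x monotone", {
  # all surface at exactly 20 Gy
  edges <- seq(0, 25, 0.1)
  area <- ifelse(edges < 20, 4, 0)
  step <- dsh(edges, area, "relative")
  m <- extract_metrics(step)
  expect_equal(s_metric(m, 19), 4)
  expect_equal(s_metric(m, 21), 0)

  # linear relative DSH from 4% at 0 Gy to 0% at 40 Gy: S_20 = 2%
  lin <- dsh(seq(0, 40, 0.1), seq(4, 0, length.out = 401), "relative")
  ml <- extract_metrics(lin)
  expect_equal(s_metric(ml, 20), 2, tolerance = 1e-9)
  expect_true(all(diff(ml$S) <= 1e-9))
  expect_true(all(diff(ml$D) <= 1e-9))
  expect_lte(ml$D2pct, 40)
  expect_error(extract_metrics(dsh(numeric(0), numeric(0), "relative")),
               "empty")
})

test_that("surface-weighted mean dose matches a face-list oracle", {
  ph <- sphere_phantom(R_mm = 30, spacing = 2)
  d <- dim(ph$truth$data)
  g <- skinNTCP:::grid_coords(d, ph$truth$spacing)
  dz <- array(rep(20 * g$z / max(g$z), each = d[1] * d[2]), d)
  dose <- image_volume(dz, ph$truth$spacing, units = "Gy")
  h <- normalize_dsh(compute_dsh(dose, ph$truth), compute_bsa(80, 176))
  m <- extract_metrics(h)
  bf <- skinNTCP:::boundary_faces(ph$truth, dose)
  oracle <- sum(bf$area_cm2 * bf$dose_gy) / sum(bf$area_cm2)
  expect_equal(m$Dmean, oracle, tolerance = 0.005)
})
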