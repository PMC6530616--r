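test_that("radiological depth is exact in uniform media", {
  g <- water_cube(side = 12, spacing = 0.5)
  src <- c(0, 0, 85)
  # 10 cm geometric path inside water from entry (z = 6) down to z = -4
  expect_equal(radiological_depth(g, src, c(0, 0, -4)), 10,
               tolerance = 1e-9)
  half <- g
  half$density[] <- 0.5
  expect_equal(radiological_depth(half, src, c(0, 0, -4)), 5,
               tolerance = 1e-9)
  expect_error(radiological_depth(g, src, c(0, 0, 50)), "outside")
})

test_that("radiological depth matches a midpoint-rule oracle", {
  base <- water_cube(side = 12, spacing = 0.4)
  two_layer <- make_hetero_phantom(base, c(-6, -6, 0), c(6, 6, 6), 0.3)
  src <- c(3, 2, 12)
  for (pt in list(c(0, 0, -4), c(-2, 1.5, -5.5), c(4, -3, 2))) {
    expect_lt(abs(radiological_depth(two_layer, src, pt) -
                    midpoint_radiological_depth(two_layer, src, pt,
                                                n = 1e4)),
              1e-3)
  }
  # oblique ray through the split cheese phantom
  cheese <- make_cheese_phantom(spacing = 0.5, split = TRUE)
  src2 <- c(0, -1, 20)
  pt2 <- c(-3, -1, 2)
  expect_lt(abs(radiological_depth(cheese, src2, pt2) -
                  midpoint_radiological_depth(cheese, src2, pt2, n = 1e4)),
            1e-3)
})

test_that("beam-frame coordinates follow the divergent geometry", {
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0)
  expect_equal(beam_frame_coords(c(0, 0, 0), beam, 85),
               c(x_iso = 0, y_iso = 0, source_distance = 85))
  # 2 cm lateral in the isocenter plane stays 2 cm after back-projection
  expect_equal(beam_frame_coords(c(2, 0, 0), beam, 85)[["x_iso"]], 2)
  expect_equal(beam_frame_coords(c(0, 1.5, 0), beam, 85)[["y_iso"]], 1.5)
  # upstream points project larger, downstream smaller
  up <- beam_frame_coords(c(2, 0, 10), beam, 85)
  expect_equal(up[["source_distance"]], 75)
  expect_equal(up[["x_iso"]], 2 * 85 / 75)

  # gantry 180 mirrors the vertical displacement of gantry 0
  b180 <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 180)
  expect_equal(beam_frame_coords(c(0, 0, 3), b180, 85)[["source_distance"]],
               beam_frame_coords(c(0, 0, -3), beam, 85)[["source_distance"]])
  expect_error(beam_frame_coords(c(0, 0, 85), beam, 85), "singular")
})

test_that("single-beam dose follows the factorized model", {
  m <- test_model()
  g <- water_cube(side = 10, spacing = 0.5)
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0, mu = 2)

  # zero MU gives an all-zero grid
  zero <- compute_beam_dose(g, modifyList(beam, list(mu = 0)), m)
  expect_true(all(zero$dose == 0))

  d1 <- compute_beam_dose(g, modifyList(beam, list(mu = 1)), m)
  d2 <- compute_beam_dose(g, beam, m)
  expect_equal(d2$dose, 2 * d1$dose)   # linearity in MU

  # spot checks against the all-R reference path (midpoint depth oracle)
  for (ijk in list(c(10, 10, 10), c(5, 10, 14), c(13, 11, 6))) {
    pt <- voxel_center(g, ijk)
    expect_equal(d2$dose[ijk[1], ijk[2], ijk[3]],
                 reference_point_dose(g, beam, m, pt),
                 tolerance = 2e-3)
  }
})

test_that("dose at the reference condition equals the calibration factor", {
  m <- synthesize_beam_model(output_cal = 0.4)
  # slab surface at SSD = SAD - reference depth: the reference voxel sits
  # at 1.5 cm depth on the central axis in the isocenter plane. An odd
  # voxel count along y puts a voxel center exactly on the beam axis,
  # where the 0.4 cm field is too narrow for off-center interpolation.
  g <- make_slab_phantom(20, 20.25, 10, spacing = 0.25)
  g$origin[3] <- 1.5 - 10   # top surface at z = +1.5, point at z = 0
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0, mu = 1)
  d <- compute_beam_dose(g, beam, m)
  got <- point_dose(d, poi(c(0, 0, 0)))
  expect_equal(got, 0.4, tolerance = 0.005)
})

test_that("no dose is deposited in air outside the phantom", {
  g <- make_cheese_phantom(diameter = 6, length = 4, spacing = 0.5)
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0, mu = 5)
  d <- compute_beam_dose(g, beam, test_model())
  # top corner voxel: air with zero upstream density along its ray
  expect_equal(d$dose[1, 4, 12], 0)
  expect_gt(d$dose[6, 4, 6], 0)
})

test_that("plan dose equals an explicit per-beam summation", {
  m <- test_model()
  g <- water_cube(side = 10, spacing = 0.5)   # 20^3 grid
  plan <- build_helical_plan(-0.4, 0.8, "normal")
  total <- compute_plan_dose(g, plan, m)
  acc <- array(0, g$dims)
  for (i in seq_len(nrow(plan$beams)))
    acc <- acc + compute_beam_dose(g, plan$beams[i, ], m)$dose
  expect_equal(total$dose, acc, tolerance = 1e-12)
})

test_that("plan dose is additive over plan partitions and MU-homogeneous", {
  m <- test_model()
  g <- water_cube(side = 10, spacing = 0.5)
  plan <- build_static_plan(-1, 2, 0.1, isocenter_interval = 0.2)
  whole <- compute_plan_dose(g, plan, m)

  first <- plan; first$beams <- plan$beams[1:5, ]
  rest <- plan; rest$beams <- plan$beams[6:10, ]
  expect_equal(whole$dose,
               compute_plan_dose(g, first, m)$dose +
                 compute_plan_dose(g, rest, m)$dose,
               tolerance = 1e-12)

  scaled <- plan; scaled$beams$mu <- 3 * plan$beams$mu
  expect_equal(compute_plan_dose(g, scaled, m)$dose, 3 * whole$dose,
               tolerance = 1e-12)
})

test_that("half-density medium doubles the effective depth", {
  m <- test_model()
  # odd y voxel count: a voxel center sits on the beam axis plane
  water <- make_slab_phantom(20, 20.25, 20, spacing = 0.25)  # surface z = +10
  lungy <- water; lungy$density[] <- 0.5
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0, mu = 1)
  dw <- compute_beam_dose(water, beam, m)
  dh <- compute_beam_dose(lungy, beam, m)
  # dose at geometric depth d in half-density equals water dose at d/2,
  # after removing the differing inverse-square factors
  for (d_geo in c(4, 8, 12)) {
    z_h <- 10 - d_geo
    z_w <- 10 - d_geo / 2
    ph <- point_dose(dh, poi(c(0, 0, z_h)))
    pw <- point_dose(dw, poi(c(0, 0, z_w)))
    inv <- ((85 - z_w) / (85 - z_h))^2
    expect_equal(ph, pw * inv, tolerance = 1e-3)
  }
})

test_that("off-field lateral dose is bounded by the OCR terminal value", {
  m <- test_model()
  g <- make_slab_phantom(70, 6, 6, spacing = 0.5)
  beam <- list(iso_x = 0, iso_y = 0, iso_z = 0, gantry_deg = 0, mu = 1)
  d <- compute_beam_dose(g, beam, m)
  central <- point_dose(d, poi(c(0, 0, 0)))
  far <- point_dose(d, poi(c(30, 0, 0)))
  terminal <- m$ocr_x$values[length(m$ocr_x$values)]
  expect_lte(far, terminal * central + 1e-12)
})

test_that("full-rotation helical dose is rotationally symmetric on the axis phantom", {
  m <- test_model()
  # working resolution: coarser grids alias the longitudinal beam comb
  g <- make_cheese_phantom(spacing = 0.25)
  plan <- build_helical_plan(-2.4, 4.8, "fine")
  d <- compute_plan_dose(g, plan, m)
  r <- 5
  doses <- vapply(seq(0, 315, by = 45), function(a) {
    th <- a * pi / 180
    point_dose(d, poi(c(r * sin(th), 0, r * cos(th)), 0.44))
  }, numeric(1))
  expect_lt((max(doses) - min(doses)) / mean(doses), 0.01)
})

test_that("central dose converges under angular refinement (8 vs 16 beams)", {
  m <- test_model()
  g <- make_cheese_phantom(spacing = 0.5)
  ctr <- poi(c(0, 0, 0), 0.44)
  d8 <- point_dose(compute_plan_dose(
    g, build_helical_plan(-2.4, 4.8, "normal", beams_per_rotation = 8), m),
    ctr)
  d16 <- point_dose(compute_plan_dose(
    g, build_helical_plan(-2.4, 4.8, "normal", beams_per_rotation = 16), m),
    ctr)
  expect_lt(abs(d16 - d8) / d8, 0.02)
})

test_that("output calibration is a fixed point of the reference workflow", {
  m <- test_model()
  g <- make_cheese_phantom(spacing = 0.5, split = TRUE)
  plan <- build_static_plan(-3, 6, 0.1)
  # chamber at 1.5 cm depth below the top of the upper half-cylinder
  ref <- poi(c(0, 0, 15 - 1.5), 0.44)
  cal <- calibrate_output(m, plan, g, ref, measured_dose = 1.33)
  expect_true(cal$calibrated)
  d <- compute_plan_dose(g, plan, cal)
  expect_equal(point_dose(d, ref), 1.33, tolerance = 1e-3)

  # calibration arithmetic: measured / calculated at unit output
  d1 <- compute_plan_dose(g, plan, m)
  d_cal <- point_dose(d1, ref)
  expect_equal(cal$output_cal, 1.33 / d_cal, tolerance = 1e-12)

  # measured equal to the uncalibrated calculation gives factor 1
  cal1 <- calibrate_output(m, plan, g, ref, measured_dose = d_cal)
  expect_equal(cal1$output_cal, 1)
  # point longitudinally outside every beam's field receives no dose
  expect_error(calibrate_output(m, plan, g, poi(c(0, 8, 0)), 1),
               "zero")
  expect_error(calibrate_output(m, plan, g, ref, -1), "positive")
})

test_that("point dose interpolates and averages like a chamber", {
  g <- water_cube(side = 4, spacing = 0.5)
  uni <- dose_grid(g, array(2.5, g$dims))
  expect_equal(point_dose(uni, poi(c(0, 0, 0))), 2.5)
  expect_equal(point_dose(uni, poi(c(0.3, -0.2, 0.7), 0.44)), 2.5)

  # dose linear in y: segment average equals the center value
  cy <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$spacing[2]
  lin <- dose_grid(g, array(rep(2 + cy, each = g$dims[1]), g$dims))
  expect_equal(point_dose(lin, poi(c(0, 0.25, 0), 1)), 2.25,
               tolerance = 1e-9)
  # averaging length 0 at a voxel center returns that voxel's dose
  ctr <- voxel_center(g, c(3, 4, 5))
  expect_equal(point_dose(lin, poi(ctr)), lin$dose[3, 4, 5])
  expect_error(point_dose(uni, poi(c(0, 1.9, 0), 1)), "outside")
})

test_that("percent differences and their summaries match convention", {
  expect_equal(percent_difference(1.70, 1.70), 0)
  expect_equal(percent_difference(1.0, 0.5), 100)
  expect_lt(percent_difference(0.92, 0.98), 0)
  expect_error(percent_difference(1, 0), "positive")

  s <- summarize_differences(c(0.10, -1.85, -2.50))
  expect_equal(round(s$mean, 2), -1.42)
  expect_equal(round(s$sd, 2), 1.35)

  s2 <- summarize_differences(c(-1.23, 3.48, 3.24))
  expect_equal(round(s2$mean, 2), 1.83)
  expect_equal(round(s2$sd, 2), 2.65)

  s3 <- summarize_differences(c(4.2, 4.2))
  expect_equal(s3$mean, 4.2)
  expect_equal(s3$sd, 0)
  expect_true(is.na(summarize_differences(1.5)$sd))
  expect_error(summarize_differences(numeric(0)), "non-empty")

  tab <- compare_point_doses(c("up", "center"), c(1.70, 0.96),
                             c(1.70, 0.98))
  expect_equal(tab$difference_pct[1], 0)
  expect_lt(tab$difference_pct[2], 0)
})
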