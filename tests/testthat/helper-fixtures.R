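# Shared fixtures and independent oracles for the test suite.

# default synthetic beam model (deterministic)
test_model <- function(...) synthesize_beam_model(...)

# small uniform water cube centered on the origin
water_cube <- function(side = 10, spacing = 0.5) {
  make_slab_phantom(width = side, length = side, height = side,
                    spacing = spacing)
}

# Independent oracle for the radiological depth: midpoint-rule line
# integral of the voxelized density sampled at n points along the segment.
midpoint_radiological_depth <- function(grid, source, point, n = 1e4) {
  t_mid <- (seq_len(n) - 0.5) / n
  seg <- matrix(point - source, nrow = n, ncol = 3, byrow = TRUE)
  pts <- matrix(source, nrow = n, ncol = 3, byrow = TRUE) + seg * t_mid
  idx <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  idx <- floor(idx) + 1
  inside <- idx >= 1 & sweep(idx, 2, grid$dims) <= 0
  ok <- rowSums(inside) == 3
  dens <- numeric(n)
  if (any(ok))
    dens[ok] <- grid$density[idx[ok, , drop = FALSE]]
  L <- sqrt(sum((point - source)^2))
  sum(dens) * L / n
}

# Independent R-side evaluation of the factorized dose formula at one
# world point, using the midpoint depth oracle and the exported curve
# evaluators (no shared code with the compiled kernel beyond the curves).
reference_point_dose <- function(grid, beam, model, point) {
  g <- beam$gantry_deg * pi / 180
  u <- c(sin(g), 0, cos(g))
  iso <- c(beam$iso_x, beam$iso_y, beam$iso_z)
  src <- iso + model$sad * u
  fc <- beam_frame_coords(point, beam, model$sad)
  d <- midpoint_radiological_depth(grid, src, point, n = 2e4)
  pf <- eval_pdd(model, d) / eval_pdd(model, model$reference_depth)
  beam$mu * model$output_cal * pf *
    eval_ocr(model, fc[["x_iso"]], fc[["y_iso"]]) *
    (model$sad / fc[["source_distance"]])^2
}

# world coordinates of voxel center (i, j, k) (1-based)
voxel_center <- function(grid, ijk) {
  grid$origin + (ijk - 0.5) * grid$spacing
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
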