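#' Absorbed dose on a voxel lattice
#'
#' Shares origin, spacing and dims with the [voxel_grid()] it was computed
#' on; `dose` holds the per-voxel absorbed dose in cGy.
#'
#' @param grid The [voxel_grid()] defining the lattice.
#' @param dose 3D numeric array of doses (cGy), `dim` equal to the grid's.
#' @param meta Optional list of provenance metadata (plan settings,
#'   calibration state).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose, meta = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(dose) || !identical(dim(dose), dim(grid$density)))
    stop("`dose` must be an array congruent with the phantom lattice")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose values must be finite and >= 0")
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, dose = dose, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid: %d x %d x %d voxels, max %.4g cGy>\n",
              x$dims[1], x$dims[2], x$dims[3], max(x$dose)))
  invisible(x)
}

#' Radiological depth along a source-to-point ray
#'
#' Density-weighted path length (water-equivalent cm) from `source` to
#' `point`, computed by exact Siddon-style voxel traversal. Only the
#' portion of the segment inside the grid contributes; a 10 cm geometric
#' path through unit-density water yields exactly 10 cm.
#'
#' @param grid A [voxel_grid()].
#' @param source Numeric length-3 world position of the source (cm).
#' @param point Numeric length-3 world position inside the grid (cm).
#' @return Water-equivalent depth (cm).
#' @export
radiological_depth <- function(grid, source, point) {
  stopifnot(inherits(grid, "voxel_grid"))
  source <- as.numeric(source); point <- as.numeric(point)
  if (length(source) != 3L || length(point) != 3L)
    stop("`source` and `point` must be length-3")
  if (!point_in_grid(grid, point))
    stop("`point` lies outside the grid")
  cpp_radiological_depth(as.numeric(grid$density), as.integer(grid$dims),
                         grid$origin, grid$spacing, source, point)
}

#' Beam-frame coordinates of a world point
#'
#' Rotates a point into the frame of a beam (rotation about IEC-Y by the
#' gantry angle around the beam's isocenter) and returns its off-axis
#' coordinates back-projected to the isocenter plane together with the
#' source distance measured along the beam axis. Lateral offsets are
#' multiplied by `sad / source_distance` (fan divergence), so a point 2 cm
#' lateral in the isocenter plane maps to `x_iso = 2` and the isocenter
#' itself to `(0, 0, sad)`.
#'
#' @param point Numeric length-3 world position (cm).
#' @param beam A one-row beam specification: list or data frame row with
#'   `iso_x`, `iso_y`, `iso_z`, `gantry_deg`.
#' @param sad Source-axis distance (cm).
#' @return Named numeric vector `(x_iso, y_iso, source_distance)`.
#' @export
beam_frame_coords <- function(point, beam, sad = 85) {
  point <- as.numeric(point)
  g <- beam$gantry_deg * pi / 180
  u <- c(sin(g), 0, cos(g))          # isocenter -> source direction
  e_x <- c(cos(g), 0, -sin(g))
  v <- point - c(beam$iso_x, beam$iso_y, beam$iso_z)
  z_axis <- sad - sum(v * u)
  if (z_axis <= 1e-9)
    stop("point at or behind the source: beam-frame projection is singular")
  proj <- sad / z_axis
  c(x_iso = sum(v * e_x) * proj, y_iso = v[2] * proj,
    source_distance = z_axis)
}

model_curve_args <- function(model) {
  list(pdd_pos = model$pdd$positions, pdd_val = model$pdd$values,
       ocrx_pos = model$ocr_x$positions, ocrx_val = model$ocr_x$values,
       ocry_pos = model$ocr_y$positions, ocry_val = model$ocr_y$values)
}

plan_dose_raw <- function(grid, beam_matrix, model) {
  cv <- model_curve_args(model)
  d <- cpp_plan_dose(as.numeric(grid$density), as.integer(grid$dims),
                     grid$origin, grid$spacing, beam_matrix,
                     model$sad, model$reference_depth, model$output_cal,
                     cv$pdd_pos, cv$pdd_val, cv$ocrx_pos, cv$ocrx_val,
                     cv$ocry_pos, cv$ocry_val)
  array(d, grid$dims)
}

beam_matrix_from <- function(beams) {
  as.matrix(beams[, c("iso_x", "iso_y", "iso_z", "gantry_deg", "mu")])
}

#' Dose of a single 400 x 4 mm beam on a voxel grid
#'
#' Factorized divergent-beam model: for each voxel center the dose is
#' `MU * output_cal * PDD(d_rad) / PDD(d_ref) * OCR_x(x_iso) *
#' OCR_y(y_iso) * (SAD / z)^2`, where `d_rad` is the Siddon radiological
#' depth from the source, the off-axis offsets are back-projected to the
#' isocenter plane, and `z` is the along-axis source distance (so the
#' inverse-square factor is 1 on the isocenter plane). Voxels of air with
#' zero upstream density receive no dose.
#'
#' An uncalibrated model (sentinel `output_cal = 1`) is permitted; the
#' result is then in relative units and flagged in the metadata.
#'
#' @param grid A [voxel_grid()].
#' @param beam A beam specification with `iso_x`, `iso_y`, `iso_z`,
#'   `gantry_deg`, `mu` (e.g. one row of a plan's `beams`).
#' @param model An [mvct_beam_model()].
#' @return A [dose_grid()] (cGy, or relative if uncalibrated).
#' @export
compute_beam_dose <- function(grid, beam, model) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(model, "mvct_beam_model"))
  if (beam$mu < 0) stop("beam mu must be >= 0")
  bm <- matrix(c(beam$iso_x, beam$iso_y, beam$iso_z,
                 beam$gantry_deg, beam$mu), nrow = 1L)
  dose_grid(grid, plan_dose_raw(grid, bm, model),
            meta = list(calibrated = model$calibrated))
}

#' Total dose of a scan plan (sum over its discrete beams)
#'
#' Element-wise sum of [compute_beam_dose()] over every beam of the plan,
#' accumulated in double precision in compiled code.
#'
#' @param grid A [voxel_grid()].
#' @param plan A `scan_plan` from [build_helical_plan()] or
#'   [build_static_plan()].
#' @param model An [mvct_beam_model()].
#' @return A [dose_grid()] with the plan settings in its metadata.
#' @export
compute_plan_dose <- function(grid, plan, model) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(plan, "scan_plan"),
            inherits(model, "mvct_beam_model"))
  if (nrow(plan$beams) == 0L) stop("plan has no beams")
  dose_grid(grid, plan_dose_raw(grid, beam_matrix_from(plan$beams), model),
            meta = list(mode = plan$mode, n_beams = nrow(plan$beams),
                        total_mu = plan$total_mu,
                        calibrated = model$calibrated))
}

#' Calibrate the beam output against a measured point dose
#'
#' Reproduces the reference-condition output calibration: the reference
#' plan (a 6 cm static scan at 0.1 cm/s, gantry 0, on the split
#' cylindrical phantom with the chamber at 1.5 cm depth) is computed with
#' `output_cal = 1` and the calibration factor is the ratio of the
#' measured dose to the calculated dose at the point of interest.
#' Recomputing the reference plan with the calibrated model reproduces the
#' measurement at the point.
#'
#' @param model An [mvct_beam_model()] (calibrated or not; the existing
#'   factor is ignored).
#' @param plan The reference `scan_plan`.
#' @param grid The reference phantom [voxel_grid()].
#' @param poi_ref A [poi()] at the measurement position (chamber-style
#'   averaging recommended).
#' @param measured_dose Measured dose at the point (cGy), > 0.
#' @return A copy of `model` with `output_cal = measured_dose / D_cal` and
#'   `calibrated = TRUE`.
#' @export
calibrate_output <- function(model, plan, grid, poi_ref, measured_dose) {
  stopifnot(inherits(model, "mvct_beam_model"), inherits(poi_ref, "poi"))
  if (!is.finite(measured_dose) || measured_dose <= 0)
    stop("measured_dose must be positive")
  unit_model <- model
  unit_model$output_cal <- 1
  unit_model$calibrated <- FALSE
  d_cal <- point_dose(compute_plan_dose(grid, plan, unit_model), poi_ref)
  if (d_cal <= 0)
    stop("calculated dose at the calibration point is zero; ",
         "the point lies outside the beam")
  model$output_cal <- measured_dose / d_cal
  model$calibrated <- TRUE
  model
}

# trilinear interpolation at world positions (matrix n x 3)
trilinear_sample <- function(dose, pts) {
  u <- sweep(sweep(pts, 2, dose$origin), 2, dose$spacing, "/") - 0.5
  lo <- floor(u)
  n <- dose$dims
  if (any(u < 0) || any(sweep(u, 2, n - 1) > 1e-9))
    stop("sample position outside the voxel-center hull of the lattice")
  lo <- pmin(pmax(lo, 0), matrix(rep(n - 2, each = nrow(u)), ncol = 3))
  f <- u - lo
  at <- function(dx, dy, dz)
    dose$dose[cbind(lo[, 1] + 1 + dx, lo[, 2] + 1 + dy, lo[, 3] + 1 + dz)]
  w <- function(d, k) if (d == 1) f[, k] else 1 - f[, k]
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    out <- out + at(dx, dy, dz) * w(dx, 1) * w(dy, 2) * w(dz, 3)
  out
}

#' Point dose with optional chamber-style longitudinal averaging
#'
#' With `averaging_length = 0`, the trilinear interpolation of the dose at
#' the position. Otherwise the mean of trilinear samples along a centered
#' IEC-Y segment of that length (at least 9 samples), emulating the
#' collector volume of a small ionization chamber.
#'
#' @param dose A [dose_grid()].
#' @param poi_ref A [poi()] whose position (and averaging segment) lies
#'   within the lattice.
#' @return Dose in cGy.
#' @export
point_dose <- function(dose, poi_ref) {
  stopifnot(inherits(dose, "dose_grid"), inherits(poi_ref, "poi"))
  p <- poi_ref$position
  len <- poi_ref$averaging_length
  if (len == 0) return(trilinear_sample(dose, matrix(p, nrow = 1L)))
  n_samples <- max(9L, 2L * ceiling(len / dose$spacing[2]) + 1L)
  offs <- seq(-len / 2, len / 2, length.out = n_samples)
  pts <- cbind(p[1], p[2] + offs, p[3])
  mean(trilinear_sample(dose, pts))
}

#' Percent difference of a calculated dose relative to a measurement
#'
#' `(calculated - measured) / measured * 100`; negative when the
#' calculation underestimates the measurement.
#'
#' @param calculated Calculated dose(s), cGy.
#' @param measured Measured dose(s), cGy, > 0.
#' @return Percent difference(s).
#' @export
percent_difference <- function(calculated, measured) {
  if (any(!is.finite(measured)) || any(measured <= 0))
    stop("measured dose must be positive")
  (calculated - measured) / measured * 100
}

#' Mean and standard deviation of point-dose differences
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of percent differences, as reported in commissioning summaries.
#' Unrounded values are returned; the print method rounds to 2 decimals
#' for display.
#'
#' @param differences Numeric vector of percent differences (>= 1 value;
#'   >= 2 for a standard deviation).
#' @return A list of class `difference_summary` with `mean`, `sd` and `n`.
#' @export
summarize_differences <- function(differences) {
  if (length(differences) == 0L)
    stop("`differences` must be non-empty")
  if (any(!is.finite(differences)))
    stop("`differences` must be finite")
  structure(list(mean = mean(differences),
                 sd = if (length(differences) >= 2L)
                   stats::sd(differences) else NA_real_,
                 n = length(differences)),
            class = "difference_summary")
}

#' @export
print.difference_summary <- function(x, ...) {
  cat(sprintf("difference summary (n = %d): %.2f +/- %.2f %%\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Tabulate calculated vs measured point doses
#'
#' Convenience table for commissioning reports: one row per point with the
#' calculated dose, the measured dose and their percent difference.
#'
#' @param names Character vector of point labels.
#' @param calculated,measured Dose vectors (cGy).
#' @return A data frame with columns `point`, `calculated_cGy`,
#'   `measured_cGy`, `difference_pct`.
#' @export
compare_point_doses <- function(names, calculated, measured) {
  data.frame(point = as.character(names),
             calculated_cGy = calculated,
             measured_cGy = measured,
             difference_pct = percent_difference(calculated, measured))
}
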