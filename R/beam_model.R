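#' MVCT single-field beam model
#'
#' Bundles the three commissioning curves of the 400 x 4 mm imaging field
#' (PDD, lateral OCR, longitudinal OCR) with the machine geometry and the
#' output calibration factor. The model is evaluated by [eval_pdd()] and
#' [eval_ocr()] and consumed by the dose engine.
#'
#' The PDD must cover at least depths 0--30 cm and the lateral OCR at least
#' -25..+25 cm so that the engine never relies on long extrapolations
#' inside a human-scale phantom. `output_cal = 1` with `calibrated = FALSE`
#' is the sentinel "uncalibrated" state; [calibrate_output()] fills in the
#' measured cGy/MU factor.
#'
#' @param pdd Depth [profile_curve()] (water-equivalent cm), normalized to
#'   maximum 1.
#' @param ocr_x Lateral off-center ratio [profile_curve()] at the profile
#'   measurement depth, normalized to central value 1.
#' @param ocr_y Longitudinal off-center ratio [profile_curve()], normalized
#'   to central value 1.
#' @param sad Source-axis distance (cm), 85 for this unit.
#' @param field_x Field width at the isocenter (cm), 40.
#' @param field_y Field length at the isocenter along the couch axis (cm), 0.4.
#' @param profile_depth Depth at which the OCRs were measured (cm), 1.5.
#' @param reference_depth Depth of the output calibration point (cm), 1.5.
#' @param output_cal Dose per monitor unit at the reference condition
#'   (cGy/MU); 1 before calibration.
#' @param calibrated Logical; whether `output_cal` is a measured value.
#' @param mu_per_minute Monitor units assigned to 60 s of irradiation time
#'   (MU); 40 for this unit. Exposed as a constant because the assignment
#'   is a bookkeeping convention, not a physical property.
#' @return An object of class `mvct_beam_model`.
#' @export
mvct_beam_model <- function(pdd, ocr_x, ocr_y,
                            sad = 85, field_x = 40, field_y = 0.4,
                            profile_depth = 1.5, reference_depth = 1.5,
                            output_cal = 1, calibrated = FALSE,
                            mu_per_minute = 40) {
  stopifnot(inherits(pdd, "profile_curve"),
            inherits(ocr_x, "profile_curve"),
            inherits(ocr_y, "profile_curve"))
  if (sad <= 0 || field_x <= 0 || field_y <= 0)
    stop("sad, field_x and field_y must be positive")
  if (output_cal <= 0)
    stop("output_cal must be positive")
  if (mu_per_minute <= 0)
    stop("mu_per_minute must be positive")
  if (min(pdd$positions) > 0 || max(pdd$positions) < 30)
    stop("PDD must cover at least the depth interval [0, 30] cm")
  if (min(ocr_x$positions) > -25 || max(ocr_x$positions) < 25)
    stop("OCR_x must cover at least [-25, +25] cm")
  structure(list(pdd = pdd, ocr_x = ocr_x, ocr_y = ocr_y,
                 sad = sad, field_x = field_x, field_y = field_y,
                 profile_depth = profile_depth,
                 reference_depth = reference_depth,
                 output_cal = output_cal, calibrated = calibrated,
                 mu_per_minute = mu_per_minute),
            class = "mvct_beam_model")
}

#' @export
print.mvct_beam_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<mvct_beam_model: %g x %g cm field, SAD %g cm, ref depth %g cm,\n",
    "  output_cal %.4g cGy/MU (%s), %g MU/min>\n"),
    x$field_x, x$field_y, x$sad, x$reference_depth, x$output_cal,
    if (x$calibrated) "calibrated" else "uncalibrated", x$mu_per_minute))
  invisible(x)
}

#' Evaluate the percentage depth dose
#'
#' Piecewise-linear interpolation between the PDD nodes, with clamped
#' extrapolation: depths beyond the last node return the last node's value,
#' depths before the first node the first node's value.
#'
#' @param model An [mvct_beam_model()].
#' @param depth Water-equivalent depth(s), cm, >= 0.
#' @return Relative dose value(s).
#' @export
eval_pdd <- function(model, depth) {
  stopifnot(inherits(model, "mvct_beam_model"))
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be finite and >= 0")
  interp_curve(model$pdd, depth)
}

#' Evaluate the off-center ratio at a 2D off-axis position
#'
#' Returns `ocr_x(x_off) * ocr_y(y_off)`, each factor piecewise-linearly
#' interpolated with clamped extrapolation. The two profiles are measured
#' independently; a separable 2D fluence is assumed. Offsets are expressed
#' in the isocenter plane; the dose engine performs the divergent
#' back-projection before calling this.
#'
#' @param model An [mvct_beam_model()].
#' @param x_off Lateral off-axis distance(s) at the isocenter plane (cm).
#' @param y_off Longitudinal off-axis distance(s) (cm).
#' @return Relative factor(s) >= 0.
#' @export
eval_ocr <- function(model, x_off, y_off) {
  stopifnot(inherits(model, "mvct_beam_model"))
  if (any(!is.finite(x_off)) || any(!is.finite(y_off)))
    stop("off-axis offsets must be finite")
  interp_curve(model$ocr_x, x_off) * interp_curve(model$ocr_y, y_off)
}

#' Generate a fully synthetic analytic MVCT beam model
#'
#' Stands in for film-measured commissioning curves so that the whole
#' pipeline can run without access to the machine. The PDD is an analytic
#' build-up/attenuation shape `(1 - exp(-k d / buildup_depth)) *
#' exp(-attenuation_coeff d)` sampled on a fixed 0--35 cm grid, with `k`
#' solved so the maximum falls exactly at `buildup_depth`; after
#' normalization the node at `buildup_depth` is exactly 1. Each OCR is a
#' flat top of half-width `field/2` with error-function penumbra of the
#' given sigma, normalized to central value 1; tail values below 1e-12 of
#' the central value are truncated to exact zero so the dose engine can
#' skip voxels with no off-axis weight.
#'
#' Identical parameters always produce identical curves (no randomness).
#'
#' @param buildup_depth Depth of dose maximum (cm).
#' @param attenuation_coeff Effective linear attenuation coefficient (1/cm)
#'   of the exponential falloff beyond the build-up region.
#' @param penumbra_sigma_x,penumbra_sigma_y Error-function penumbra scale
#'   (cm) of the lateral and longitudinal profiles.
#' @param output_cal Output calibration factor (cGy/MU); 1 leaves the model
#'   in the uncalibrated sentinel state.
#' @param sad,field_x,field_y,mu_per_minute Machine geometry constants,
#'   defaulting to the helical tomotherapy imaging field (SAD 85 cm,
#'   40 x 0.4 cm field, 40 MU per minute).
#' @return An [mvct_beam_model()] with `profile_depth` and
#'   `reference_depth` of 1.5 cm.
#' @export
synthesize_beam_model <- function(buildup_depth = 1.0,
                                  attenuation_coeff = 0.055,
                                  penumbra_sigma_x = 0.3,
                                  penumbra_sigma_y = 0.1,
                                  output_cal = 1,
                                  sad = 85, field_x = 40, field_y = 0.4,
                                  mu_per_minute = 40) {
  pars <- c(buildup_depth = buildup_depth,
            attenuation_coeff = attenuation_coeff,
            penumbra_sigma_x = penumbra_sigma_x,
            penumbra_sigma_y = penumbra_sigma_y,
            output_cal = output_cal)
  if (any(!is.finite(pars)) || any(pars <= 0))
    stop("all synthetic beam model parameters must be positive")
  mb <- attenuation_coeff * buildup_depth
  if (mb >= 1)
    stop("attenuation_coeff * buildup_depth must be < 1 for a build-up maximum")
  # choose k so that d/dd [(1 - exp(-k d / b)) exp(-mu d)] = 0 at d = b
  k <- stats::uniroot(function(k) k * exp(-k) / (1 - exp(-k)) - mb,
                      interval = c(1e-9, 700), tol = 1e-12)$root
  depths <- seq(0, 35, by = 0.1)
  if (!any(abs(depths - buildup_depth) < 1e-9))
    depths <- sort(c(depths, buildup_depth))
  pdd_vals <- (1 - exp(-k * depths / buildup_depth)) *
    exp(-attenuation_coeff * depths)
  pdd_vals <- pdd_vals / max(pdd_vals)
  pdd <- profile_curve(depths, pdd_vals, "depth")

  flat_top <- function(x, half_width, sigma) {
    v <- stats::pnorm((half_width - x) / sigma) +
      stats::pnorm((half_width + x) / sigma) - 1
    v <- pmax(v, 0)
    v <- v / v[which.min(abs(x))]
    v[v < 1e-12] <- 0
    v
  }
  xs <- seq(-30, 30, by = 0.1)
  ocr_x <- profile_curve(xs, flat_top(xs, field_x / 2, penumbra_sigma_x),
                         "x_offaxis")
  ys <- seq(-3, 3, by = 0.02)
  ocr_y <- profile_curve(ys, flat_top(ys, field_y / 2, penumbra_sigma_y),
                         "y_offaxis")

  mvct_beam_model(pdd, ocr_x, ocr_y, sad = sad, field_x = field_x,
                  field_y = field_y, profile_depth = 1.5,
                  reference_depth = 1.5, output_cal = output_cal,
                  calibrated = FALSE, mu_per_minute = mu_per_minute)
}

#' Check point-dose differences against a tolerance
#'
#' Implements the commissioning adjustment loop: after comparing calculated
#' and measured point doses, the beam model is perturbed until every
#' absolute percent difference is strictly below the tolerance (3% in
#' routine commissioning).
#'
#' @param differences Numeric vector of percent differences.
#' @param tol Tolerance in percent (> 0); the bound is strict.
#' @return A list with `pass` (logical) and `offending` (integer indices of
#'   differences with `|difference| >= tol`).
#' @export
within_tolerance <- function(differences, tol = 3) {
  if (length(differences) == 0L)
    stop("`differences` must be non-empty")
  if (!is.numeric(differences) || any(!is.finite(differences)))
    stop("`differences` must be finite numbers")
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("`tol` must be a single positive number")
  offending <- which(abs(differences) >= tol)
  list(pass = length(offending) == 0L, offending = offending)
}

#' Write / read a beam model as a single JSON document
#'
#' The document embeds the three curves and the scalar geometry and
#' calibration fields.
#'
#' @param model An [mvct_beam_model()].
#' @param path Destination / source path.
#' @return `write_beam_model` returns `path` invisibly; `read_beam_model`
#'   an [mvct_beam_model()].
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "mvct_beam_model"))
  doc <- list(
    curves = lapply(model[c("pdd", "ocr_x", "ocr_y")], function(cv)
      list(positions = cv$positions, values = cv$values,
           axis_label = cv$axis_label)),
    sad = model$sad, field_x = model$field_x, field_y = model$field_y,
    profile_depth = model$profile_depth,
    reference_depth = model$reference_depth,
    output_cal = model$output_cal, calibrated = model$calibrated,
    mu_per_minute = model$mu_per_minute)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- function(nm) profile_curve(doc$curves[[nm]]$positions,
                                   doc$curves[[nm]]$values,
                                   doc$curves[[nm]]$axis_label)
  mvct_beam_model(cv("pdd"), cv("ocr_x"), cv("ocr_y"),
                  sad = doc$sad, field_x = doc$field_x,
                  field_y = doc$field_y,
                  profile_depth = doc$profile_depth,
                  reference_depth = doc$reference_depth,
                  output_cal = doc$output_cal,
                  calibrated = isTRUE(doc$calibrated),
                  mu_per_minute = doc$mu_per_minute)
}
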