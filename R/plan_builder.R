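#' Scan pitch setting of the MVCT acquisition
#'
#' The unit offers three pitches, defined by the couch travel per gantry
#' rotation: fine 0.4 cm, normal 0.8 cm, coarse 1.2 cm, all with a 10 s
#' gantry period. When the helical delivery is discretized into
#' `beams_per_rotation` beams, consecutive isocenters are separated by
#' `couch_travel_per_rotation / beams_per_rotation` (0.05 / 0.10 / 0.15 cm
#' at the default 8 beams per rotation).
#'
#' @param name `"fine"`, `"normal"` or `"coarse"`.
#' @param beams_per_rotation Number of discrete beams per rotation.
#' @return An object of class `pitch_setting` with fields `name`,
#'   `couch_travel_per_rotation`, `isocenter_interval` and
#'   `period_per_rotation`.
#' @export
pitch_setting <- function(name = c("fine", "normal", "coarse"),
                          beams_per_rotation = 8L) {
  name <- match.arg(name)
  if (beams_per_rotation < 1L)
    stop("beams_per_rotation must be >= 1")
  travel <- c(fine = 0.4, normal = 0.8, coarse = 1.2)[[name]]
  structure(list(name = name,
                 couch_travel_per_rotation = travel,
                 isocenter_interval = travel / beams_per_rotation,
                 period_per_rotation = 10),
            class = "pitch_setting")
}

#' Irradiation time of a helical MVCT scan
#'
#' `scan_length / couch_travel_per_rotation * period_per_rotation`: e.g. a
#' 4.8 cm scan takes 120 / 60 / 40 s at fine / normal / coarse pitch.
#'
#' @param scan_length Scan length (cm), >= 0.
#' @param pitch A [pitch_setting()].
#' @return Irradiation time in seconds.
#' @export
irradiation_time <- function(scan_length, pitch) {
  stopifnot(inherits(pitch, "pitch_setting"))
  if (!is.finite(scan_length) || scan_length < 0)
    stop("scan_length must be finite and >= 0")
  scan_length / pitch$couch_travel_per_rotation * pitch$period_per_rotation
}

#' Convert irradiation time to monitor units
#'
#' The unit prescribes dose by irradiation time; the planning side by
#' monitor units. The two are linked by the bookkeeping convention that
#' 60 s corresponds to `mu_per_minute` MU (40 by default).
#'
#' @param time Irradiation time (s), >= 0.
#' @param mu_per_minute MU assigned to one minute of irradiation.
#' @return Monitor units.
#' @export
time_to_mu <- function(time, mu_per_minute = 40) {
  if (any(!is.finite(time)) || any(time < 0))
    stop("time must be finite and >= 0")
  if (mu_per_minute <= 0) stop("mu_per_minute must be positive")
  mu_per_minute * time / 60
}

new_scan_plan <- function(mode, beams, scan_start, scan_length, settings,
                          total_time, total_mu) {
  structure(c(list(mode = mode, beams = beams, scan_start = scan_start,
                   scan_length = scan_length, total_time = total_time,
                   total_mu = total_mu), settings),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan: %s, %d beams over %g cm, %g s, %.4g MU>\n",
              x$mode, nrow(x$beams), x$scan_length, x$total_time,
              x$total_mu))
  invisible(x)
}

#' Discretize a helical MVCT delivery into equally spaced beams
#'
#' The continuous helical delivery is approximated by `n =
#' round(scan_length / interval)` discrete 400 x 4 mm beams with
#' cell-centered isocenters on the rotation axis (beam i at `scan_start +
#' (i - 1/2) * interval`) and gantry angles advancing by `360 /
#' beams_per_rotation` per beam. The total MU, derived from the
#' irradiation time, is shared equally among the beams, which makes the
#' total invariant under angular refinement.
#'
#' @param scan_start Longitudinal start of the scan (cm, IEC-Y).
#' @param scan_length Scan length (cm), > 0.
#' @param pitch A [pitch_setting()] or pitch name.
#' @param beams_per_rotation Beams per rotation (positive integer); the
#'   gantry advances by `360 / beams_per_rotation` degrees per beam.
#' @param start_angle Gantry angle of the first beam (degrees). The unit
#'   does not expose the initial angle; 0 (beam entering from above) is the
#'   conventional choice.
#' @param rotation_sense +1 or -1, direction of gantry rotation.
#' @param mu_per_minute MU per minute of irradiation time.
#' @return A `scan_plan` whose `beams` data frame has columns `iso_x`,
#'   `iso_y`, `iso_z`, `gantry_deg`, `mu`.
#' @export
build_helical_plan <- function(scan_start, scan_length, pitch,
                               beams_per_rotation = 8L, start_angle = 0,
                               rotation_sense = 1, mu_per_minute = 40) {
  if (is.character(pitch)) pitch <- pitch_setting(pitch, beams_per_rotation)
  stopifnot(inherits(pitch, "pitch_setting"))
  if (!is.finite(scan_length) || scan_length <= 0)
    stop("scan_length must be positive")
  if (beams_per_rotation < 1L ||
      abs(beams_per_rotation - round(beams_per_rotation)) > 1e-9)
    stop("beams_per_rotation must be a positive integer")
  if (!rotation_sense %in% c(-1, 1))
    stop("rotation_sense must be +1 or -1")
  interval <- pitch$couch_travel_per_rotation / beams_per_rotation
  if (scan_length < interval)
    stop("scan_length shorter than one isocenter interval: degenerate plan")
  n_exact <- scan_length / interval
  n <- as.integer(round(n_exact))
  if (abs(n - n_exact) > 1e-9)
    warning(sprintf(
      "scan length %g cm is not a multiple of the %g cm interval; using %d beams",
      scan_length, interval, n))
  i <- seq_len(n)
  iso_y <- scan_start + (i - 0.5) * interval
  gantry <- (start_angle + rotation_sense * (i - 1) *
               (360 / beams_per_rotation)) %% 360
  total_time <- irradiation_time(scan_length, pitch)
  total_mu <- time_to_mu(total_time, mu_per_minute)
  beams <- data.frame(iso_x = 0, iso_y = iso_y, iso_z = 0,
                      gantry_deg = gantry, mu = total_mu / n)
  new_scan_plan("helical", beams, scan_start, scan_length,
                list(pitch = pitch, beams_per_rotation = beams_per_rotation,
                     mu_per_minute = mu_per_minute),
                total_time, total_mu)
}

#' Discretize a static-gantry MVCT delivery
#'
#' In a static plan the gantry is fixed while the couch moves; the
#' delivery is discretized into `n = round(scan_length / interval)` beams
#' at cell-centered isocenters, each carrying the MU of `interval /
#' couch_speed` seconds of irradiation. The output-calibration reference
#' scan (6 cm at 0.1 cm/s, gantry 0, 0.2 cm intervals) yields 30 beams of
#' 2 s each, 40 MU in total.
#'
#' @param scan_start Longitudinal start of the scan (cm, IEC-Y).
#' @param scan_length Scan length (cm), > 0.
#' @param couch_speed Couch speed (cm/s), > 0.
#' @param gantry_angle Fixed gantry angle (degrees).
#' @param isocenter_interval Spacing of the discrete isocenters (cm), > 0.
#' @param mu_per_minute MU per minute of irradiation time.
#' @return A `scan_plan`, as in [build_helical_plan()].
#' @export
build_static_plan <- function(scan_start, scan_length, couch_speed,
                              gantry_angle = 0, isocenter_interval = 0.2,
                              mu_per_minute = 40) {
  if (!is.finite(scan_length) || scan_length <= 0)
    stop("scan_length must be positive")
  if (couch_speed <= 0) stop("couch_speed must be positive")
  if (isocenter_interval <= 0) stop("isocenter_interval must be positive")
  if (scan_length < isocenter_interval)
    stop("scan_length shorter than one isocenter interval: degenerate plan")
  n_exact <- scan_length / isocenter_interval
  n <- as.integer(round(n_exact))
  if (abs(n - n_exact) > 1e-9)
    warning(sprintf(
      "scan length %g cm is not a multiple of the %g cm interval; using %d beams",
      scan_length, isocenter_interval, n))
  i <- seq_len(n)
  iso_y <- scan_start + (i - 0.5) * isocenter_interval
  beam_time <- isocenter_interval / couch_speed
  beam_mu <- time_to_mu(beam_time, mu_per_minute)
  beams <- data.frame(iso_x = 0, iso_y = iso_y, iso_z = 0,
                      gantry_deg = gantry_angle %% 360, mu = beam_mu)
  new_scan_plan("static", beams, scan_start, scan_length,
                list(couch_speed = couch_speed,
                     isocenter_interval = isocenter_interval,
                     mu_per_minute = mu_per_minute),
                scan_length / couch_speed, n * beam_mu)
}

#' Build a scan plan from a YAML configuration file
#'
#' Recognized keys: `mode` (`helical` or `static`), `scan_start_cm`,
#' `scan_length_cm`, `pitch` (helical), `beams_per_rotation` (helical,
#' default 8), `start_angle_deg` (helical, default 0), `rotation_sense`
#' (helical, default 1), `couch_speed_cm_s` (static),
#' `gantry_angle_deg` (static, default 0), `isocenter_interval_cm`
#' (static, default 0.2), `mu_per_minute` (default 40).
#'
#' @param path Path to the YAML file.
#' @return A `scan_plan`.
#' @export
read_plan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  get_or <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  mode <- match.arg(cfg$mode, c("helical", "static"))
  if (mode == "helical") {
    build_helical_plan(
      scan_start = cfg$scan_start_cm,
      scan_length = cfg$scan_length_cm,
      pitch = cfg$pitch,
      beams_per_rotation = get_or("beams_per_rotation", 8L),
      start_angle = get_or("start_angle_deg", 0),
      rotation_sense = get_or("rotation_sense", 1),
      mu_per_minute = get_or("mu_per_minute", 40))
  } else {
    build_static_plan(
      scan_start = cfg$scan_start_cm,
      scan_length = cfg$scan_length_cm,
      couch_speed = cfg$couch_speed_cm_s,
      gantry_angle = get_or("gantry_angle_deg", 0),
      isocenter_interval = get_or("isocenter_interval_cm", 0.2),
      mu_per_minute = get_or("mu_per_minute", 40))
  }
}

#' Write / read a scan plan as JSON
#'
#' Serializes the ordered beam list (isocenter, gantry angle, MU) together
#' with the settings block.
#'
#' @param plan A `scan_plan`.
#' @param path Destination / source path.
#' @return `write_plan_json` returns `path` invisibly; `read_plan_json` a
#'   `scan_plan`.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  doc <- unclass(plan)
  if (!is.null(doc$pitch)) doc$pitch <- unclass(doc$pitch)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  beams <- as.data.frame(doc$beams)
  settings <- doc[setdiff(names(doc),
                          c("mode", "beams", "scan_start", "scan_length",
                            "total_time", "total_mu"))]
  if (!is.null(settings$pitch))
    settings$pitch <- structure(as.list(settings$pitch),
                                class = "pitch_setting")
  new_scan_plan(doc$mode, beams, doc$scan_start, doc$scan_length,
                settings, doc$total_time, doc$total_mu)
}
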