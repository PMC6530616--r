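#' Relative dose profile curve
#'
#' A sampled one-dimensional relative dose curve: a percentage depth dose
#' (PDD) along the central axis, or an off-center ratio (OCR) across the
#' field in the lateral (`x_offaxis`) or longitudinal (`y_offaxis`)
#' direction. Positions are in cm and must be strictly increasing; values
#' are dimensionless relative dose and must be finite and non-negative.
#'
#' @param positions Numeric vector of strictly increasing positions (cm):
#'   depth for a PDD, off-axis distance for an OCR.
#' @param values Numeric vector of relative dose values (>= 0), same length
#'   as `positions`.
#' @param axis_label One of `"depth"`, `"x_offaxis"`, `"y_offaxis"`.
#' @return An object of class `profile_curve`.
#' @seealso [read_profile_csv()], [normalize_curve()]
#' @export
profile_curve <- function(positions, values,
                          axis_label = c("depth", "x_offaxis", "y_offaxis")) {
  axis_label <- match.arg(axis_label)
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("`positions` and `values` must have the same length")
  if (length(positions) < 2L)
    stop("a profile curve needs at least 2 nodes")
  if (!all(is.finite(positions)) || !all(is.finite(values)))
    stop("profile curve nodes must be finite")
  if (any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing")
  if (any(values < 0))
    stop("profile curve values must be >= 0")
  structure(list(positions = positions, values = values,
                 axis_label = axis_label),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve: %s, %d nodes, range [%g, %g] cm>\n",
              x$axis_label, length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Read a measured profile curve from a two-column CSV file
#'
#' Expects two numeric columns `position_cm,value`. A header line is
#' optional (detected when no field of the first non-comment line parses as
#' a number); lines starting with `#` and blank lines are ignored. Rows are
#' sorted by position and rows sharing a position are collapsed by
#' averaging their values. No normalization is applied; see
#' [normalize_curve()].
#'
#' @param path Path to the CSV file.
#' @param axis_label Axis of the curve, as in [profile_curve()].
#' @return A [profile_curve()].
#' @export
read_profile_csv <- function(path,
                             axis_label = c("depth", "x_offaxis", "y_offaxis")) {
  axis_label <- match.arg(axis_label)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no data rows in ", path)
  first_fields <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- all(is.na(suppressWarnings(as.numeric(first_fields))))
  if (has_header) lines <- lines[-1L]
  if (length(lines) < 2L)
    stop("fewer than 2 valid data rows in ", path)
  pos <- numeric(length(lines))
  val <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], ",", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop(sprintf("row %d of %s: expected two columns", i, path))
    p <- suppressWarnings(as.numeric(fields[[1L]]))
    v <- suppressWarnings(as.numeric(fields[[2L]]))
    if (is.na(p) || is.na(v))
      stop(sprintf("row %d of %s: non-numeric cell", i, path))
    pos[i] <- p
    val[i] <- v
  }
  # collapse duplicate positions by averaging, then sort ascending
  val <- as.numeric(tapply(val, pos, mean))
  pos <- sort(unique(pos))
  profile_curve(pos, val, axis_label)
}

#' Normalize a profile curve
#'
#' Depth curves are conventionally expressed relative to their maximum
#' (`mode = "max"`); off-center ratios relative to the central-axis value
#' (`mode = "central"`, the value interpolated at position 0).
#'
#' @param curve A [profile_curve()].
#' @param mode `"max"` or `"central"`.
#' @return A normalized [profile_curve()] whose maximum (resp. central
#'   value) equals 1. Normalization is idempotent.
#' @export
normalize_curve <- function(curve, mode = c("max", "central")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "profile_curve"))
  if (mode == "max") {
    ref <- max(curve$values)
  } else {
    if (min(curve$positions) > 0 || max(curve$positions) < 0)
      stop("central normalization requires position 0 within the curve range")
    ref <- stats::approx(curve$positions, curve$values, xout = 0,
                         rule = 2)$y
  }
  if (ref <= 0)
    stop("cannot normalize: reference value is zero")
  profile_curve(curve$positions, curve$values / ref, curve$axis_label)
}

# piecewise-linear evaluation with clamped extrapolation (node-exact)
interp_curve <- function(curve, x) {
  stats::approx(curve$positions, curve$values, xout = x, rule = 2)$y
}
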