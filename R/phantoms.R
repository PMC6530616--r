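#' Voxelized density grid
#'
#' A rectilinear lattice of relative mass density (water = 1, air = 0).
#' Coordinates follow the radiotherapy convention used throughout the
#' package: `y` is the couch-travel (longitudinal, IEC-Y) axis, `z` is
#' vertical (a gantry-0 beam travels along -z), and `x` completes a
#' right-handed frame. `origin` is the world position (cm) of the corner of
#' voxel (1,1,1); voxel centers sit at `origin + (i - 1/2) * spacing`.
#'
#' @param origin Numeric length-3, world position (cm) of the grid corner.
#' @param spacing Per-axis voxel size (cm), length 1 or 3, all > 0.
#' @param density 3D numeric array of relative densities in \[0, 3\];
#'   its `dim` gives the voxel counts.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, density) {
  origin <- as.numeric(origin)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive on all axes")
  if (!is.array(density) || length(dim(density)) != 3L)
    stop("`density` must be a 3D array")
  if (any(dim(density) < 1L)) stop("all grid dimensions must be >= 1")
  if (any(!is.finite(density)) || any(density < 0) || any(density > 3))
    stop("density values must lie in [0, 3]")
  structure(list(origin = origin, spacing = spacing,
                 dims = dim(density), density = density),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) cm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# voxel-center coordinates along axis k
axis_centers <- function(grid, k) {
  grid$origin[k] + (seq_len(grid$dims[k]) - 0.5) * grid$spacing[k]
}

grid_upper <- function(grid) grid$origin + grid$dims * grid$spacing

point_in_grid <- function(grid, p) {
  all(p >= grid$origin) && all(p <= grid_upper(grid))
}

# density array for a cylinder along IEC-Y: cross-section mask replicated
cylinder_density <- function(cx, cz, ny, radius, center = c(0, 0)) {
  inside <- outer((cx - center[1])^2, (cz - center[2])^2, "+") <= radius^2
  aperm(array(as.numeric(inside), c(length(cx), length(cz), ny)),
        c(1L, 3L, 2L))
}

#' Cylindrical water-equivalent "cheese" phantom
#'
#' A cylinder of water density aligned with the couch (IEC-Y) axis, its
#' axis through the grid center at `x = z = 0`; voxels outside the cylinder
#' are air (density 0). `split = TRUE` zeroes the lower half (below the
#' horizontal plane through the axis), emulating the half phantom used for
#' output calibration on the unit.
#'
#' @param diameter Cylinder diameter (cm), 30 for the standard phantom.
#' @param length Cylinder length along IEC-Y (cm), 18 for the standard
#'   phantom.
#' @param spacing Voxel size (cm); the default 0.25 resolves the 0.4 cm
#'   field length.
#' @param split Zero the lower half of the cylinder?
#' @return A [voxel_grid()] centered on the world origin.
#' @export
make_cheese_phantom <- function(diameter = 30, length = 18, spacing = 0.25,
                                split = FALSE) {
  if (diameter <= 0 || length <= 0 || spacing <= 0)
    stop("diameter, length and spacing must be positive")
  if (spacing > diameter || spacing > length)
    stop("spacing exceeds the phantom extent: degenerate grid")
  dims <- pmax(1L, as.integer(round(c(diameter, length, diameter) / spacing)))
  origin <- -dims * spacing / 2
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  density <- cylinder_density(cx, cz, dims[2], diameter / 2)
  if (split) density[, , cz < 0] <- 0
  voxel_grid(origin, spacing, density)
}

#' Homogeneous rectangular water slab phantom
#'
#' A density-1 box centered on the world origin, with `width` along x,
#' `length` along IEC-Y and `height` along z, optionally surrounded by an
#' air margin.
#'
#' @param width,length,height Box dimensions (cm); the 30 x 55 x 10 cm
#'   default matches the rectangular water-equivalent phantom used for
#'   depth-dose commissioning.
#' @param spacing Voxel size (cm).
#' @param margin Air margin (cm) added on every side of the box.
#' @return A [voxel_grid()].
#' @export
make_slab_phantom <- function(width = 30, length = 55, height = 10,
                              spacing = 0.25, margin = 0) {
  ext <- c(width, length, height)
  if (any(ext <= 0) || spacing <= 0 || margin < 0)
    stop("phantom dimensions and spacing must be positive")
  if (spacing > min(ext))
    stop("spacing exceeds the phantom extent: degenerate grid")
  dims <- pmax(1L, as.integer(round((ext + 2 * margin) / spacing)))
  origin <- -dims * spacing / 2
  inside <- lapply(1:3, function(k) {
    centers <- origin[k] + (seq_len(dims[k]) - 0.5) * spacing
    abs(centers) <= ext[k] / 2
  })
  density <- array(0, dims)
  density[inside[[1]], inside[[2]], inside[[3]]] <- 1
  voxel_grid(origin, spacing, density)
}

#' Replace the density inside an axis-aligned box region
#'
#' Copies the base grid and overwrites the density of every voxel whose
#' center falls inside the world-coordinate box `[lower, upper]`. Useful to
#' build heterogeneous test phantoms (e.g. a lung-like low-density insert
#' in a water slab). Disjoint inserts commute.
#'
#' @param base A [voxel_grid()].
#' @param lower,upper Numeric length-3 world coordinates (cm) of the box
#'   corners; must lie within the grid.
#' @param insert_density Relative density in \[0, 3\].
#' @return A modified copy of `base`.
#' @export
make_hetero_phantom <- function(base, lower, upper, insert_density) {
  stopifnot(inherits(base, "voxel_grid"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(lower > upper))
    stop("`lower` and `upper` must be length-3 with lower <= upper")
  if (!point_in_grid(base, lower) || !point_in_grid(base, upper))
    stop("insert region extends outside the grid")
  if (insert_density < 0 || insert_density > 3)
    stop("insert_density must lie in [0, 3]")
  sel <- lapply(1:3, function(k) {
    centers <- axis_centers(base, k)
    centers >= lower[k] & centers <= upper[k]
  })
  base$density[sel[[1]], sel[[2]], sel[[3]]] <- insert_density
  base
}

#' Named structure mask over a voxel grid
#'
#' Stores the linear voxel indices belonging to an organ or region of
#' interest, for organ-dose reporting and DVH computation.
#'
#' @param name Structure name.
#' @param voxels Integer vector of linear indices into the grid's density
#'   array (1-based).
#' @param dims Dimensions of the grid the mask belongs to.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, voxels, dims) {
  voxels <- sort(unique(as.integer(voxels)))
  nvox <- prod(dims)
  if (length(voxels) && (min(voxels) < 1L || max(voxels) > nvox))
    stop("mask indices outside the grid index space")
  structure(list(name = as.character(name), voxels = voxels,
                 dims = as.integer(dims)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask '%s': %d voxels>\n", x$name,
              length(x$voxels)))
  invisible(x)
}

#' Cylindrical structure mask aligned with IEC-Y
#'
#' Selects voxels whose centers fall inside a cylinder of the given radius
#' and half-length around `axis_point`, as a synthetic "organ" for
#' reporting workflows. An empty result is returned with a warning rather
#' than an error.
#'
#' @param grid A [voxel_grid()].
#' @param name Structure name.
#' @param axis_point Numeric length-3 center of the cylinder (cm).
#' @param radius Cylinder radius (cm), > 0.
#' @param half_length Half-length along IEC-Y (cm), > 0.
#' @return A [structure_mask()].
#' @export
add_cylinder_mask <- function(grid, name, axis_point, radius, half_length) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius <= 0 || half_length <= 0)
    stop("radius and half_length must be positive")
  axis_point <- as.numeric(axis_point)
  cx <- axis_centers(grid, 1); cy <- axis_centers(grid, 2)
  cz <- axis_centers(grid, 3)
  in_xz <- outer((cx - axis_point[1])^2, (cz - axis_point[3])^2, "+") <=
    radius^2
  in_y <- abs(cy - axis_point[2]) <= half_length
  member <- aperm(array(in_xz, c(grid$dims[1], grid$dims[3], grid$dims[2])),
                  c(1L, 3L, 2L))
  member[, !in_y, ] <- FALSE
  voxels <- which(member)
  if (length(voxels) == 0L)
    warning("cylinder mask '", name, "' selects no voxels")
  structure_mask(name, voxels, grid$dims)
}

#' Point of interest with chamber-style averaging geometry
#'
#' A measurement position, optionally with a longitudinal averaging length
#' emulating an ionization chamber's collector (0.44 cm for the A1SL-class
#' chamber used in tomotherapy dosimetry); `averaging_length = 0` is a pure
#' point sample.
#'
#' @param position Numeric length-3 world position (cm).
#' @param averaging_length Averaging segment length along IEC-Y (cm), >= 0.
#' @return An object of class `poi`.
#' @export
poi <- function(position, averaging_length = 0) {
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position)))
    stop("`position` must be a finite length-3 vector")
  if (averaging_length < 0)
    stop("`averaging_length` must be >= 0")
  structure(list(position = position, averaging_length = averaging_length),
            class = "poi")
}
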