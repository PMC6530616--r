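#' Write a density or dose raster as an ASCII-encoded NRRD file
#'
#' Minimal NRRD0004 writer: 3D double raster, `encoding: ascii`, with the
#' grid geometry in `space origin` / `space directions` and the content
#' kind (`density` or `dose`) recorded as a key-value pair. ASCII encoding
#' keeps the files text-only and portable at the cost of size; these
#' rasters are intended for exchange at phantom scale, not archival.
#'
#' @param x A [voxel_grid()] or [dose_grid()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    values <- x$density; content <- "density"
  } else if (inherits(x, "dose_grid")) {
    values <- x$dose; content <- "dose"
  } else stop("`x` must be a voxel_grid or dose_grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", x$dims[1], x$dims[2], x$dims[3]),
    "encoding: ascii",
    "space dimension: 3",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            x$origin[1], x$origin[2], x$origin[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    sprintf("mvctdose-content:=%s", content),
    ""), con)
  # x fastest (NRRD convention) == R column-major order of dim (nx, ny, nz)
  v <- as.numeric(values)
  chunk <- 8L
  idx <- seq(1L, length(v), by = chunk)
  writeLines(vapply(idx, function(i)
    paste(format(v[i:min(i + chunk - 1L, length(v))], digits = 17),
          collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an ASCII-encoded NRRD raster written by [write_nrrd()]
#'
#' @param path Source path.
#' @return A [voxel_grid()] (content `density`) or [dose_grid()] (content
#'   `dose`; returned on a reconstructed lattice).
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[[1L]], "NRRD"))
    stop(path, " is not an NRRD file")
  blank <- which(!nzchar(trimws(lines)))[1L]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header")
  header <- lines[2:(blank - 1L)]
  field <- function(name) {
    hit <- grep(paste0("^", name, ": "), header, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", name, ": "), "", hit[[1L]])
  }
  keyval <- function(key) {
    hit <- grep(paste0("^", key, ":="), header, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", key, ":="), "", hit[[1L]])
  }
  if (!identical(field("encoding"), "ascii"))
    stop("only ascii-encoded NRRD rasters are supported")
  dims <- as.integer(strsplit(trimws(field("sizes")), "\\s+")[[1L]])
  nums <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1L]])
  origin <- nums(field("space origin"))
  dirs <- regmatches(field("space directions"),
                     gregexpr("\\(([^)]*)\\)", field("space directions")))[[1L]]
  spacing <- vapply(seq_along(dirs), function(k) nums(dirs[[k]])[k],
                    numeric(1))
  data <- scan(text = paste(lines[(blank + 1L):length(lines)],
                            collapse = " "),
               quiet = TRUE)
  if (length(data) != prod(dims))
    stop("NRRD data length does not match sizes")
  arr <- array(data, dims)
  content <- keyval("mvctdose-content")
  if (identical(content, "dose")) {
    lattice <- voxel_grid(origin, spacing, array(0, dims))
    dose_grid(lattice, arr)
  } else {
    voxel_grid(origin, spacing, arr)
  }
}

#' Write / read structure masks as a JSON index list
#'
#' Masks are stored as 1-based linear voxel indices per structure name,
#' together with the lattice dimensions they refer to.
#'
#' @param masks A list of [structure_mask()] objects.
#' @param path Destination / source path.
#' @return `write_masks_json` returns `path` invisibly; `read_masks_json`
#'   a named list of [structure_mask()] objects.
#' @export
write_masks_json <- function(masks, path) {
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  dims <- masks[[1L]]$dims
  doc <- list(dims = dims,
              masks = stats::setNames(
                lapply(masks, function(m) m$voxels),
                vapply(masks, function(m) m$name, character(1))))
  jsonlite::write_json(doc, path, digits = NA)
  invisible(path)
}

#' @rdname write_masks_json
#' @export
read_masks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(doc$dims)
  out <- lapply(names(doc$masks), function(nm)
    structure_mask(nm, doc$masks[[nm]], dims))
  stats::setNames(out, names(doc$masks))
}
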