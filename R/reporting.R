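#' Fractionation scheme of a treatment course
#'
#' @param fraction_dose Prescribed dose per fraction (cGy), > 0.
#' @param n_fractions Number of fractions, >= 1.
#' @return An object of class `fractionation` with the derived
#'   `prescription_total = fraction_dose * n_fractions`.
#' @export
fractionation <- function(fraction_dose, n_fractions) {
  if (!is.finite(fraction_dose) || fraction_dose <= 0)
    stop("fraction_dose must be positive")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("n_fractions must be a positive integer")
  structure(list(fraction_dose = fraction_dose,
                 n_fractions = n_fractions,
                 prescription_total = fraction_dose * n_fractions),
            class = "fractionation")
}

#' Maximum dose over a structure
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on a congruent lattice.
#' @return Maximum voxel dose (cGy) over the mask members.
#' @export
organ_max <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (length(mask$voxels) == 0L)
    stop("mask '", mask$name, "' is empty")
  if (!identical(as.integer(mask$dims), as.integer(dose$dims)))
    stop("mask lattice is not congruent with the dose grid")
  max(dose$dose[mask$voxels])
}

#' Per-organ imaging-dose report
#'
#' Carries the maximum imaging dose per fraction and the derived totals:
#' `total_max = max_per_fraction * n_fractions` and
#' `percent_of_prescription = total_max / prescription_total * 100`.
#' Values are kept unrounded; the print method rounds to 2 decimals.
#'
#' @param organ Organ name.
#' @param max_per_fraction Maximum organ dose per imaging fraction (cGy),
#'   > 0.
#' @param fx A [fractionation()].
#' @return An object of class `organ_dose_report`.
#' @export
build_report <- function(organ, max_per_fraction, fx) {
  stopifnot(inherits(fx, "fractionation"))
  if (!is.finite(max_per_fraction) || max_per_fraction <= 0)
    stop("max_per_fraction must be positive")
  total <- max_per_fraction * fx$n_fractions
  structure(list(organ = as.character(organ),
                 max_per_fraction = max_per_fraction,
                 total_max = total,
                 percent_of_prescription =
                   total / fx$prescription_total * 100,
                 fraction_dose = fx$fraction_dose,
                 n_fractions = fx$n_fractions),
            class = "organ_dose_report")
}

#' @export
print.organ_dose_report <- function(x, ...) {
  cat(sprintf("%s: %.2f cGy/fx, total %.2f cGy (%.2f%% of prescription)\n",
              x$organ, x$max_per_fraction, x$total_max,
              x$percent_of_prescription))
  invisible(x)
}

#' Organ-dose reports as a data frame
#'
#' @param reports A list of [build_report()] objects.
#' @return A data frame with columns `organ`, `fraction_dose_cGy`,
#'   `n_fractions`, `max_per_fx_cGy`, `total_max_cGy`,
#'   `percent_of_prescription`.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "organ_dose_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r)
    data.frame(organ = r$organ,
               fraction_dose_cGy = r$fraction_dose,
               n_fractions = r$n_fractions,
               max_per_fx_cGy = r$max_per_fraction,
               total_max_cGy = r$total_max,
               percent_of_prescription = r$percent_of_prescription)))
}

#' Table-level averages of organ-dose reports
#'
#' Arithmetic means of the display-rounded (2-decimal) total maximum doses
#' and percentages, themselves rounded to 2 decimals — the convention used
#' when averaging a published organ-dose table whose cells are printed to
#' 2 decimals.
#'
#' @param reports A non-empty list of [build_report()] objects, or a data
#'   frame with columns `total_max_cGy` and `percent_of_prescription`.
#' @return A list with `mean_total` (cGy), `mean_percent` (%) and `n`.
#' @export
summarize_reports <- function(reports) {
  if (is.data.frame(reports)) {
    totals <- reports$total_max_cGy
    percents <- reports$percent_of_prescription
  } else {
    if (inherits(reports, "organ_dose_report")) reports <- list(reports)
    totals <- vapply(reports, function(r) r$total_max, numeric(1))
    percents <- vapply(reports, function(r) r$percent_of_prescription,
                       numeric(1))
  }
  if (length(totals) == 0L) stop("no reports to summarize")
  list(mean_total = round(mean(round(totals, 2)), 2),
       mean_percent = round(mean(round(percents, 2)), 2),
       n = length(totals))
}

#' Cumulative dose-volume histogram of a structure
#'
#' Volume fraction of the structure receiving at least each dose level,
#' evaluated at bin edges from 0 up to just past the maximum dose. The
#' curve is monotone non-increasing, equals 1 at dose 0, and its last
#' nonzero edge lies within one bin width of the structure maximum.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()].
#' @param bin_width Dose bin width (cGy), > 0.
#' @return A data frame with columns `dose_cGy` and `volume_fraction`.
#' @export
compute_dvh <- function(dose, mask, bin_width) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (length(mask$voxels) == 0L) stop("mask '", mask$name, "' is empty")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  d <- dose$dose[mask$voxels]
  edges <- seq(0, by = bin_width,
               length.out = floor(max(d) / bin_width) + 2L)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  data.frame(dose_cGy = edges, volume_fraction = frac)
}

#' Write organ-dose reports or a DVH to CSV
#'
#' `write_report_csv` mirrors the columns of a clinical organ-dose summary
#' table; `write_dvh_csv` writes the two-column cumulative DVH.
#'
#' @param reports A list of [build_report()] objects.
#' @param dvh A data frame from [compute_dvh()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  utils::write.csv(report_table(reports), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(dvh, path, row.names = FALSE)
  invisible(path)
}
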