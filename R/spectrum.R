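#' Processed 1D NMR spectrum
#'
#' Container for a frequency-domain, phased and baseline-corrected 1D proton
#' spectrum. The ppm axis is always stored in descending order (the NMR
#' display convention); constructors reorder ascending input and permute the
#' intensities consistently.
#'
#' @param sample_id Sample identifier.
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#'   Units are arbitrary: all quantitative outputs are ratios against a
#'   calibration standard.
#' @param weight_mg Tissue mass in mg; `NULL` for standard solutions.
#' @param group_label Optional group: `"sporadic"`, `"SDHx"`, `"VHL"` or
#'   `"reference"`.
#' @param spectrometer_mhz Proton frequency in MHz (default 500.13).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(sample_id, ppm, intensity, weight_mg = NULL,
                       group_label = NULL, spectrometer_mhz = 500.13) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stopf("ppm and intensity lengths differ (%d vs %d)",
          length(ppm), length(intensity))
  if (length(ppm) < 2) stopf("a spectrum needs at least 2 points")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stopf("ppm axis must be strictly monotone")
  if (d[1] > 0) { # ascending input: normalize to descending
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  if (!is.null(weight_mg)) {
    weight_mg <- as.numeric(weight_mg)
    if (!is.finite(weight_mg) || weight_mg <= 0)
      stopf("weight_mg must be positive (got %s)", format(weight_mg))
  }
  if (!is.finite(spectrometer_mhz) || spectrometer_mhz <= 0)
    stopf("spectrometer_mhz must be positive")
  structure(
    list(sample_id = as.character(sample_id), ppm = ppm,
         intensity = intensity, weight_mg = weight_mg,
         group_label = if (is.null(group_label)) NULL else
           as.character(group_label),
         spectrometer_mhz = spectrometer_mhz),
    class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s: %d points, %.3f..%.3f ppm",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  if (!is.null(x$weight_mg)) cat(sprintf(", %.2f mg", x$weight_mg))
  if (!is.null(x$group_label)) cat(sprintf(", group=%s", x$group_label))
  cat("\n")
  invisible(x)
}

#' Named ppm integration window
#'
#' @param name Window name.
#' @param ppm_low,ppm_high Window bounds in ppm, `ppm_low < ppm_high`.
#' @param n_protons Number of protons contributing to the window (>= 1).
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, ppm_low, ppm_high, n_protons = 1L) {
  if (!(ppm_low < ppm_high)) stopf("region '%s': ppm_low must be < ppm_high", name)
  if (n_protons < 1) stopf("region '%s': n_protons must be >= 1", name)
  structure(list(name = as.character(name), ppm_low = as.numeric(ppm_low),
                 ppm_high = as.numeric(ppm_high),
                 n_protons = as.integer(n_protons)),
            class = "region_def")
}

#' External calibration standard
#'
#' A standard solution of known amount scanned under the same analytical
#' conditions as the tissue samples, used for PULCON-style absolute
#' quantification. The default is the 19.3 nmol lactate standard whose methyl
#' doublet at 1.33 ppm serves as the reference signal.
#'
#' @param spectrum A [spectrum1d] of the standard (no tissue weight).
#' @param amount_nmol Known amount in nmol (> 0).
#' @param reference_region [region_def] of the reference signal; default is
#'   the lactate methyl doublet window 1.31-1.35 ppm with 3 protons.
#' @return An object of class `calibration_standard`.
#' @export
calibration_standard <- function(spectrum, amount_nmol = 19.3,
                                 reference_region =
                                   region_def("lactate_ch3", 1.31, 1.35, 3L)) {
  stopifnot(inherits(spectrum, "spectrum1d"), inherits(reference_region, "region_def"))
  if (amount_nmol <= 0) stopf("amount_nmol must be positive")
  rng <- range(spectrum$ppm)
  if (reference_region$ppm_low < rng[1] || reference_region$ppm_high > rng[2])
    stopf("reference region [%g, %g] outside spectrum range [%g, %g]",
          reference_region$ppm_low, reference_region$ppm_high, rng[1], rng[2])
  structure(list(spectrum = spectrum, amount_nmol = amount_nmol,
                 reference_region = reference_region),
            class = "calibration_standard")
}

#' Extract the points of a spectrum inside a ppm window
#'
#' The window is a closed interval: points equal to either bound (within a
#' small floating-point tolerance) are included. Output order follows the
#' spectrum's descending storage order.
#'
#' @param s A [spectrum1d].
#' @param r A [region_def].
#' @return List with elements `ppm` and `intensity`.
#' @export
slice_region <- function(s, r) {
  stopifnot(inherits(s, "spectrum1d"), inherits(r, "region_def"))
  tol <- 1e-8 * max(1, abs(r$ppm_low), abs(r$ppm_high))
  keep <- s$ppm >= r$ppm_low - tol & s$ppm <= r$ppm_high + tol
  if (sum(keep) < 2)
    stopf("region '%s' [%g, %g] covers fewer than 2 points of spectrum '%s'",
          r$name, r$ppm_low, r$ppm_high, s$sample_id)
  list(ppm = s$ppm[keep], intensity = s$intensity[keep])
}
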