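#' Default quantitation panel
#'
#' The fixed ppm integration windows of the assay: succinate 2.39-2.43 (4H),
#' glutamate gamma-CH2 2.32-2.38 (2H), glutathione cysteinyl 2.93-2.98 (2H),
#' the pooled ATP/ADP/AMP complex 6.07-6.11 (1H), the epinephrine N-methyl
#' singlet 2.73-2.77 (3H) and the catechol aromatic position-5 proton
#' 6.89-6.93 (1H, carries epinephrine + norepinephrine). Also carries the
#' dopamine check positions (triplets at 2.85 and 3.22 ppm), the
#' total-integral normalization range 1-8.65 ppm, and the candidate
#' signal-free noise windows used by the detection limit. Proton counts
#' follow standard assignment tables and every window is overridable.
#'
#' @return Named list with `regions` (list of [region_def]), `dopamine_ppm`,
#'   `total_range`, `noise_windows`, and `feature_order` (the fixed
#'   four-metabolite column order of the chemometric matrix).
#' @export
panel_defaults <- function() {
  list(
    regions = list(
      succinate   = region_def("succinate",   2.39, 2.43, 4L),
      glutamate   = region_def("glutamate",   2.32, 2.38, 2L),
      glutathione = region_def("glutathione", 2.93, 2.98, 2L),
      atp_adp_amp = region_def("atp_adp_amp", 6.07, 6.11, 1L),
      epinephrine = region_def("epinephrine", 2.73, 2.77, 3L),
      catechol_aromatic = region_def("catechol_aromatic", 6.89, 6.93, 1L)
    ),
    dopamine_ppm = c(2.85, 3.22),
    dopamine_halfwidth = 0.02,
    total_range = c(1.0, 8.65),
    noise_windows = list(c(9.5, 10.0), c(0.5, 0.7)),
    feature_order = c("succinate", "glutathione", "glutamate", "atp_adp_amp")
  )
}

#' Integrate a spectral region
#'
#' Trapezoidal integral of the intensity over the closed ppm window. With
#' `baseline = "linear"` the chord joining the window's endpoint intensities
#' is subtracted first.
#'
#' @param s A [spectrum1d].
#' @param r A [region_def].
#' @param baseline `"none"` (default: spectra arrive baseline-corrected) or
#'   `"linear"`.
#' @return Area in intensity x ppm units.
#' @export
integrate_region <- function(s, r, baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  sl <- slice_region(s, r)
  y <- sl$intensity
  if (baseline == "linear") {
    o <- order(sl$ppm)
    x <- sl$ppm[o]; yy <- y[o]
    n <- length(x)
    chord <- yy[1] + (yy[n] - yy[1]) * (x - x[1]) / (x[n] - x[1])
    return(trapz(x, yy - chord))
  }
  trapz(sl$ppm, y)
}

#' Calibrate against the external standard
#'
#' PULCON-style calibration: the reference integral divided by (reference
#' protons x known amount) yields the spectrometer's area response per proton
#' per nmol under the acquisition conditions shared by standard and samples.
#'
#' @param standard A [calibration_standard].
#' @param baseline Baseline mode passed to [integrate_region].
#' @return An object of class `calibration_factor` with field
#'   `area_per_proton_per_nmol`.
#' @export
calibrate <- function(standard, baseline = "none") {
  stopifnot(inherits(standard, "calibration_standard"))
  a <- integrate_region(standard$spectrum, standard$reference_region, baseline)
  f <- a / (standard$reference_region$n_protons * standard$amount_nmol)
  if (!is.finite(f) || f <= 0)
    stopf("non-positive reference integral (%g): calibration failed", a)
  structure(list(area_per_proton_per_nmol = f), class = "calibration_factor")
}

#' Estimate the noise level of a spectrum
#'
#' Standard deviation of the intensities in the first configured signal-free
#' window fully covered by the spectrum; if none is covered, falls back to
#' 1.4826 x the median absolute deviation of the flattest decile of the
#' spectrum (the decile of lowest local variability).
#'
#' @param s A [spectrum1d].
#' @param noise_windows List of `c(lo, hi)` ppm candidate windows.
#' @return Noise standard deviation estimate.
#' @export
noise_sd_estimate <- function(s, noise_windows = panel_defaults()$noise_windows) {
  rng <- range(s$ppm)
  for (w in noise_windows) {
    if (w[1] >= rng[1] && w[2] <= rng[2]) {
      keep <- s$ppm >= w[1] & s$ppm <= w[2]
      if (sum(keep) >= 10) return(stats::sd(s$intensity[keep]))
    }
  }
  # fallback: MAD of the flattest decile by rolling absolute difference
  d <- abs(diff(s$intensity))
  d <- c(d[1], d)
  flat <- s$intensity[d <= stats::quantile(d, 0.1)]
  stats::mad(flat)
}

#' Detection-limit decision for a region
#'
#' A region is called above detection when its integrated area exceeds three
#' times (noise standard deviation x window width) -- a conventional
#' 3-sigma-style rule.
#'
#' @param s A [spectrum1d].
#' @param r A [region_def].
#' @param noise_sd Optional externally supplied noise SD; estimated from the
#'   spectrum when `NULL`.
#' @param baseline Baseline mode for the area.
#' @return `TRUE` when above detection.
#' @export
detect_limit <- function(s, r, noise_sd = NULL, baseline = "none") {
  if (is.null(noise_sd)) noise_sd <- noise_sd_estimate(s)
  area <- integrate_region(s, r, baseline)
  width <- r$ppm_high - r$ppm_low
  area > 3 * noise_sd * width
}

#' Quantify one metabolite in one spectrum
#'
#' `concentration = area / (n_protons x calibration factor x weight_mg)`
#' (nmol/mg). Concentrations whose region fails the detection limit are
#' reported as 0 and flagged.
#'
#' @param s A [spectrum1d] with a tissue weight.
#' @param r A [region_def].
#' @param f A `calibration_factor` from [calibrate].
#' @param baseline Baseline mode.
#' @param apply_detection Apply the detection-limit rule (default `TRUE`).
#' @param noise_sd Optional noise SD override for the detection rule.
#' @return List with `concentration` (nmol/mg) and `below_detection` flag.
#' @export
quantify_metabolite <- function(s, r, f, baseline = "none",
                                apply_detection = TRUE, noise_sd = NULL) {
  stopifnot(inherits(f, "calibration_factor"))
  if (is.null(s$weight_mg))
    stopf("spectrum '%s' has no tissue weight; cannot express nmol/mg",
          s$sample_id)
  area <- integrate_region(s, r, baseline)
  conc <- area / (r$n_protons * f$area_per_proton_per_nmol * s$weight_mg)
  below <- FALSE
  if (apply_detection && !detect_limit(s, r, noise_sd, baseline)) {
    conc <- 0
    below <- TRUE
  }
  conc <- max(conc, 0)
  list(concentration = conc, below_detection = below)
}

#' Quantify the catecholamines of one spectrum
#'
#' Epinephrine (E) is read from the N-methyl window (3H). The catechol
#' aromatic position-5 window (1H) carries epinephrine plus norepinephrine
#' (T); norepinephrine is obtained by subtraction, `NE = max(T - E, 0)`
#' (noise can push E above T; negative differences clip to zero with a
#' warning). The dopamine flag is `TRUE` only when the local signal exceeds
#' the detection limit at both 2.85 and 3.22 ppm, the positions of the
#' dopamine side-chain triplets.
#'
#' @param s A [spectrum1d] tissue spectrum.
#' @param panel Panel as from [panel_defaults()].
#' @param f A `calibration_factor`.
#' @param baseline Baseline mode.
#' @return List with `epinephrine`, `norepinephrine` (nmol/mg),
#'   `epinephrine_below`, `norepinephrine_below`, `dopamine_flag`.
#' @export
quantify_catecholamines <- function(s, panel = panel_defaults(), f,
                                    baseline = "none") {
  nsd <- noise_sd_estimate(s, panel$noise_windows)
  qe <- quantify_metabolite(s, panel$regions$epinephrine, f, baseline,
                            noise_sd = nsd)
  qt <- quantify_metabolite(s, panel$regions$catechol_aromatic, f, baseline,
                            noise_sd = nsd)
  e <- qe$concentration
  t_sum <- qt$concentration
  ne <- t_sum - e
  if (ne < 0 && !qt$below_detection) {
    warning(sprintf(
      "sample '%s': epinephrine exceeds the aromatic total (%.3g > %.3g); norepinephrine clipped to 0",
      s$sample_id, e, t_sum))
  }
  ne <- max(ne, 0)
  ne_below <- qt$below_detection || (ne == 0 && t_sum <= e)
  hw <- panel$dopamine_halfwidth
  dopa <- vapply(panel$dopamine_ppm, function(ctr) {
    r <- region_def(sprintf("dopamine_%g", ctr), ctr - hw, ctr + hw, 2L)
    detect_limit(s, r, noise_sd = nsd, baseline = baseline)
  }, logical(1))
  list(epinephrine = e, norepinephrine = ne,
       epinephrine_below = qe$below_detection,
       norepinephrine_below = ne_below,
       dopamine_flag = all(dopa))
}

#' Quantify a whole cohort
#'
#' Calibrates once against the standard, then quantifies the four-metabolite
#' panel and the catecholamines in every tissue spectrum. Per-sample
#' failures are collected and reported; the run continues.
#'
#' @param spectra List of tissue [spectrum1d] objects (each with a weight).
#' @param standard A [calibration_standard].
#' @param panel Panel as from [panel_defaults()].
#' @param baseline Baseline mode.
#' @param feature_scaling `"none"` (absolute nmol/mg, default) or
#'   `"total_integral"`: an alternative chemometric feature mode dividing
#'   each region area by the sample's total integral over the 1-8.65 ppm
#'   range (dimensionless relative features, not concentrations).
#' @return List with `quant` (data frame: sample_id, group, weight_mg, the
#'   six concentrations, detection flags, dopamine_flag), `features`
#'   (samples x 4 matrix in the fixed panel order), and `failures` (named
#'   list of error messages).
#' @export
quantify_cohort <- function(spectra, standard, panel = panel_defaults(),
                            baseline = "none",
                            feature_scaling = c("none", "total_integral")) {
  feature_scaling <- match.arg(feature_scaling)
  f <- calibrate(standard, baseline)
  mets <- panel$feature_order
  rows <- list()
  failures <- list()
  for (s in spectra) {
    res <- tryCatch({
      nsd <- noise_sd_estimate(s, panel$noise_windows)
      row <- list(sample_id = s$sample_id,
                  group = s$group_label %||% NA_character_,
                  weight_mg = s$weight_mg)
      flags <- character()
      for (met in mets) {
        q <- quantify_metabolite(s, panel$regions[[met]], f, baseline,
                                 noise_sd = nsd)
        row[[met]] <- q$concentration
        if (q$below_detection) flags <- c(flags, met)
      }
      cat_q <- quantify_catecholamines(s, panel, f, baseline)
      row$epinephrine <- cat_q$epinephrine
      row$norepinephrine <- cat_q$norepinephrine
      if (cat_q$epinephrine_below) flags <- c(flags, "epinephrine")
      if (cat_q$norepinephrine_below) flags <- c(flags, "norepinephrine")
      row$dopamine_flag <- cat_q$dopamine_flag
      if (feature_scaling == "total_integral") {
        tot <- integrate_region(
          s, region_def("total", panel$total_range[1], panel$total_range[2]),
          baseline)
        if (tot <= 0) stopf("non-positive total integral")
        for (met in mets) {
          a <- integrate_region(s, panel$regions[[met]], baseline)
          row[[paste0(met, "_rel")]] <- a / tot
        }
      }
      row$flags <- paste(flags, collapse = ";")
      as.data.frame(row, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s$sample_id]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  quant <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), group = character(),
               weight_mg = numeric())
  feat_cols <- if (feature_scaling == "total_integral")
    paste0(mets, "_rel") else mets
  features <- if (nrow(quant))
    as.matrix(quant[, feat_cols, drop = FALSE]) else
      matrix(numeric(), 0, length(mets))
  colnames(features) <- mets
  if (nrow(quant)) rownames(features) <- quant$sample_id
  list(quant = quant, features = features, failures = failures)
}
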