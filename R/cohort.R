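#' Cohort specification for the synthetic generator
#'
#' Encodes the group structure and per-group concentration distributions that
#' the generator emulates: 10 apparently sporadic, 12 SDHx and 6 VHL tumors,
#' with panel-metabolite medians and ranges (nmol/mg) matching the published
#' cohort table, the catecholamine detection pattern (epinephrine present in
#' 2/10 sporadic and 1/12 SDHx samples, never in VHL; norepinephrine in
#' 9/10, 9/12 and 6/6), and acquisition-like nuisance parameters (intensity
#' noise, Lorentzian linewidth, ppm grid). Tissue spectra contain no lactate
#' and no lipid signals by construction; dopamine defaults to absent.
#'
#' @param n Named integer vector of group sizes.
#' @param concentrations Named list (per metabolite) of 3x3 matrices or data
#'   frames with rows `sporadic`, `SDHx`, `VHL` and columns `median`, `min`,
#'   `max` (nmol/mg). Defaults encode the published table plus the
#'   catecholamine medians/ranges.
#' @param presence Named list of per-group detection probabilities for
#'   metabolites that are present only in a fraction of samples.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param linewidth_hz Lorentzian full width at half maximum in Hz.
#' @param grid List with `ppm_min`, `ppm_max`, `step` (ppm).
#' @param weight_range_mg Tissue weight bounds in mg (uniform draw).
#' @param spectrometer_mhz Proton frequency in MHz.
#' @param seed RNG seed for full reproducibility.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(sporadic = 10L, SDHx = 12L, VHL = 6L),
                        concentrations = default_concentrations(),
                        presence = default_presence(),
                        noise_sd = 1.0,
                        linewidth_hz = 1.5,
                        grid = list(ppm_min = 0.5, ppm_max = 9.0, step = 5e-4),
                        weight_range_mg = c(15, 20),
                        spectrometer_mhz = 500.13,
                        seed = 1L) {
  stopifnot(all(n >= 0), !is.null(names(n)))
  for (met in names(concentrations)) {
    cc <- concentrations[[met]]
    if (!all(cc[, "min"] <= cc[, "median"] & cc[, "median"] <= cc[, "max"]))
      stopf("%s: need min <= median <= max in every group", met)
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (linewidth_hz <= 0) stopf("linewidth_hz must be > 0")
  structure(list(n = n, concentrations = concentrations, presence = presence,
                 noise_sd = noise_sd, linewidth_hz = linewidth_hz,
                 grid = grid, weight_range_mg = weight_range_mg,
                 spectrometer_mhz = spectrometer_mhz, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_concentrations <- function() {
  m <- function(...) {
    x <- matrix(c(...), nrow = 3, byrow = TRUE,
                dimnames = list(c("sporadic", "SDHx", "VHL"),
                                c("median", "min", "max")))
    x
  }
  list(
    succinate    = m(0.03, 0, 0.06,    3.6, 0.9, 9.07,   0.06, 0.03, 0.12),
    glutathione  = m(0.04, 0.03, 0.22, 0.15, 0.05, 0.39, 0.32, 0.17, 0.43),
    glutamate    = m(1.36, 0.23, 2.55, 0.67, 0.13, 1.52, 1.49, 0.88, 2.18),
    atp_adp_amp  = m(0.10, 0.03, 0.18, 0.05, 0, 0.21,    0.16, 0.06, 0.29),
    # catecholamines: value distribution when present (see `presence`);
    # epinephrine params are the median and span of the three detected values
    epinephrine  = m(1.04, 0.93, 1.98, 1.04, 0.93, 1.98, 1.04, 0.93, 1.98),
    norepinephrine = m(0.90, 0, 4.60,  0.87, 0, 2.40,    1.80, 0.26, 4.53),
    dopamine     = m(0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
}

#' @rdname cohort_spec
#' @export
default_presence <- function() {
  list(
    epinephrine    = c(sporadic = 2 / 10, SDHx = 1 / 12, VHL = 0),
    norepinephrine = c(sporadic = 9 / 10, SDHx = 9 / 12, VHL = 1),
    dopamine       = c(sporadic = 0, SDHx = 0, VHL = 0)
  )
}

#' Draw concentrations from a median-matched scaled Beta law
#'
#' The published table reports only medians and ranges, so the generator uses
#' a Beta distribution rescaled to `[min, max]` with shape alpha fixed at 2
#' and beta solved numerically so the distribution median equals the target
#' median. A degenerate range (`min == max`) returns the constant.
#'
#' @param median,min,max Target median and support bounds (`min <= median <=
#'   max`).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws in `[min, max]`. Uses the current RNG
#'   state; seed externally for reproducibility.
#' @export
draw_concentration <- function(median, min, max, n = 1L) {
  if (!(min <= median && median <= max))
    stopf("median %g outside range [%g, %g]", median, min, max)
  if (min == max) return(rep(min, n))
  q <- (median - min) / (max - min)
  if (q <= 0 || q >= 1)
    stopf("median must lie strictly inside (min, max) for a non-degenerate range")
  b <- solve_beta_for_median(q)
  min + (max - min) * stats::rbeta(n, shape1 = 2, shape2 = b)
}

# Solve qbeta(0.5, 2, b) == q for b; the median of Beta(2, b) is strictly
# decreasing in b from 1 (b -> 0) to 0 (b -> Inf).
solve_beta_for_median <- function(q) {
  f <- function(logb) suppressWarnings(stats::qbeta(0.5, 2, exp(logb))) - q
  r <- stats::uniroot(f, lower = log(1e-8), upper = log(1e8), tol = 1e-13)
  exp(r$root)
}

#' Render a synthetic tissue spectrum from true concentrations
#'
#' The noise-free intensity is the sum over metabolites of
#' `concentration x weight x` (area-normalized Lorentzian lines of the
#' configured FWHM, one comb per resonance, areas in proton equivalents),
#' plus i.i.d. Gaussian noise. Deterministic given `seed`.
#'
#' @param truth Named list or one-row data frame with the per-metabolite true
#'   concentrations (nmol/mg), plus `weight_mg`, `sample_id`, `group`.
#' @param signatures Line lists as from [default_signatures()].
#' @param grid List with `ppm_min`, `ppm_max`, `step`; the step must be at
#'   most 0.002 ppm.
#' @param noise_sd Gaussian noise standard deviation.
#' @param linewidth_hz Lorentzian FWHM in Hz.
#' @param seed RNG seed for the noise.
#' @param spectrometer_mhz Proton frequency in MHz.
#' @return A [spectrum1d] with descending ppm axis.
#' @export
render_spectrum <- function(truth, signatures = default_signatures(),
                            grid = list(ppm_min = 0.5, ppm_max = 9.0, step = 5e-4),
                            noise_sd = 0, linewidth_hz = 1.5, seed = 1L,
                            spectrometer_mhz = 500.13) {
  if (grid$step > 0.002)
    stopf("grid step %g ppm too coarse (max 0.002 ppm)", grid$step)
  ppm <- seq(grid$ppm_min, grid$ppm_max, by = grid$step)
  fwhm_ppm <- linewidth_hz / spectrometer_mhz
  y <- numeric(length(ppm))
  weight <- truth$weight_mg %||% 1
  for (met in names(signatures)) {
    conc <- truth[[met]]
    if (is.null(conc) || is.na(conc) || conc <= 0) next
    amount <- conc * weight  # nmol rendered
    lines <- signatures[[met]]
    for (j in seq_len(nrow(lines))) {
      comb <- multiplet_comb(lines$center_ppm[j], lines$multiplicity[j],
                             lines$J_hz[j], spectrometer_mhz)
      for (k in seq_len(nrow(comb))) {
        y <- y + amount * lines$rel_area[j] * comb$w[k] *
          lorentzian(ppm, comb$ppm[k], fwhm_ppm)
      }
    }
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  spectrum1d(sample_id = truth$sample_id %||% "synthetic",
             ppm = ppm, intensity = y,
             weight_mg = truth$weight_mg,
             group_label = truth$group,
             spectrometer_mhz = spectrometer_mhz)
}

#' Render the lactate calibration standard
#'
#' A lactate-only spectrum (methyl doublet at 1.33 ppm, 3 protons) of the
#' stated amount, bundled with its reference integration window.
#'
#' @inheritParams render_spectrum
#' @param amount_nmol Amount of lactate in the standard (default 19.3 nmol).
#' @return A [calibration_standard].
#' @export
make_reference_standard <- function(amount_nmol = 19.3,
                                    grid = list(ppm_min = 0.5, ppm_max = 9.0,
                                                step = 5e-4),
                                    noise_sd = 0, linewidth_hz = 1.5,
                                    seed = 1L, spectrometer_mhz = 500.13) {
  truth <- list(lactate = amount_nmol, weight_mg = NULL,
                sample_id = "lactate_standard", group = "reference")
  sig <- default_signatures()["lactate"]
  s <- render_spectrum(truth, sig, grid, noise_sd, linewidth_hz, seed,
                       spectrometer_mhz)
  calibration_standard(s, amount_nmol = amount_nmol)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-sample tissue weights (uniform over the configured range),
#' per-sample true concentrations from the median-matched Beta laws,
#' Bernoulli presence for the catecholamines, renders one spectrum per
#' sample, and renders the lactate calibration standard. All randomness
#' derives from `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @return List with `spectra` (list of [spectrum1d]), `truth` (data frame of
#'   per-sample true concentrations, one row per sample), and `standard` (a
#'   [calibration_standard]).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mets <- names(spec$concentrations)
  groups <- names(spec$n)
  truth <- with_seed(spec$seed, {
    rows <- list()
    idx <- 0L
    for (g in groups) {
      ng <- spec$n[[g]]
      if (ng < 1) next
      for (i in seq_len(ng)) {
        idx <- idx + 1L
        row <- list(sample_id = sprintf("%s_%02d", g, i), group = g,
                    weight_mg = stats::runif(1, spec$weight_range_mg[1],
                                             spec$weight_range_mg[2]))
        for (met in mets) {
          cc <- spec$concentrations[[met]]
          pres <- spec$presence[[met]]
          present <- if (is.null(pres)) TRUE else
            stats::runif(1) < pres[[g]]
          row[[met]] <- if (!present) 0 else
            draw_concentration(cc[g, "median"], cc[g, "min"], cc[g, "max"])
        }
        rows[[idx]] <- as.data.frame(row, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  spectra <- lapply(seq_len(nrow(truth)), function(i) {
    render_spectrum(as.list(truth[i, ]), default_signatures(), spec$grid,
                    spec$noise_sd, spec$linewidth_hz,
                    seed = derive_seed(spec$seed, truth$sample_id[i]),
                    spectrometer_mhz = spec$spectrometer_mhz)
  })
  standard <- make_reference_standard(
    amount_nmol = 19.3, grid = spec$grid, noise_sd = spec$noise_sd,
    linewidth_hz = spec$linewidth_hz,
    seed = derive_seed(spec$seed, "reference_standard"),
    spectrometer_mhz = spec$spectrometer_mhz)
  list(spectra = spectra, truth = truth, standard = standard)
}

#' Read/write a cohort specification as YAML
#'
#' @param path YAML file path.
#' @param spec A [cohort_spec].
#' @return `read_cohort_spec` returns a [cohort_spec].
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  conc <- default_concentrations()
  if (!is.null(y$concentrations)) {
    for (met in names(y$concentrations)) {
      for (g in names(y$concentrations[[met]])) {
        v <- as.numeric(y$concentrations[[met]][[g]])
        conc[[met]][g, ] <- v
      }
    }
  }
  pres <- default_presence()
  if (!is.null(y$presence)) {
    for (met in names(y$presence))
      pres[[met]][names(y$presence[[met]])] <- as.numeric(y$presence[[met]])
  }
  defaults <- cohort_spec()
  n <- defaults$n
  if (!is.null(y$n)) {
    n <- unlist(y$n)[names(y$n)]
    storage.mode(n) <- "integer"
  }
  cohort_spec(
    n = n, concentrations = conc, presence = pres,
    noise_sd = y$noise_sd %||% defaults$noise_sd,
    linewidth_hz = y$linewidth_hz %||% defaults$linewidth_hz,
    grid = y$grid %||% defaults$grid,
    weight_range_mg = unlist(y$weight_range_mg %||% defaults$weight_range_mg),
    spectrometer_mhz = y$spectrometer_mhz %||% defaults$spectrometer_mhz,
    seed = y$seed %||% defaults$seed)
}

#' @rdname read_cohort_spec
#' @export
write_cohort_spec <- function(spec, path) {
  conc <- lapply(spec$concentrations, function(m) {
    out <- list()
    for (g in rownames(m)) out[[g]] <- as.numeric(m[g, ])
    out
  })
  pres <- lapply(spec$presence, as.list)
  yaml::write_yaml(list(n = as.list(spec$n), concentrations = conc,
                        presence = pres, noise_sd = spec$noise_sd,
                        linewidth_hz = spec$linewidth_hz, grid = spec$grid,
                        weight_range_mg = as.numeric(spec$weight_range_mg),
                        spectrometer_mhz = spec$spectrometer_mhz,
                        seed = spec$seed), path)
  invisible(path)
}
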