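# Shared fixtures built in code.

# Fine grid restricted to the aliphatic region: fast unit-test rendering.
fast_grid <- function() list(ppm_min = 0.5, ppm_max = 3.5, step = 5e-4)

default_grid <- function() list(ppm_min = 0.5, ppm_max = 9.0, step = 5e-4)

# Closed-form fraction of a unit Lorentzian (FWHM fwhm, center c) in [lo, hi].
lz_mass <- function(c, fwhm, lo, hi) {
  g <- fwhm / 2
  (atan((hi - c) / g) - atan((lo - c) / g)) / pi
}

# In-window mass of the lactate methyl doublet (J = 6.9 Hz) for the default
# reference window, computed independently of the package renderer.
lactate_window_mass <- function(fwhm_ppm, mhz = 500.13,
                                lo = 1.31, hi = 1.35) {
  half_split <- 6.9 / mhz / 2
  (lz_mass(1.33 - half_split, fwhm_ppm, lo, hi) +
     lz_mass(1.33 + half_split, fwhm_ppm, lo, hi)) / 2
}

# Minimal truth record for render_spectrum.
make_truth <- function(..., weight_mg = 15, sample_id = "t1",
                       group = "sporadic") {
  c(list(...), list(weight_mg = weight_mg, sample_id = sample_id,
                    group = group))
}

# A small, fast cohort: default distributions, fewer grid points via the
# default step but the standard group sizes (28 samples).
small_cohort <- function(seed = 1L, noise_sd = 1.0) {
  cohort_spec(seed = seed, noise_sd = noise_sd)
}

# Tiny linearly separable two-class feature matrix.
separable_xy <- function(n_per = 6L, p = 3L, gap = 10, seed = 42L) {
  withr_seed <- function(code) { set.seed(seed); code }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = gap), n_per, p))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}
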