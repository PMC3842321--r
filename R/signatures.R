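#' Default metabolite resonance signatures
#'
#' Line lists used by the synthetic spectrum renderer. Each signature is a
#' data frame with one row per resonance: `center_ppm`, `rel_area` (area per
#' molecule, in proton equivalents), `multiplicity` and `J_hz`. Multiplets
#' are rendered as binomial-weighted line combs split by `J / spectrometer
#' frequency`. Positions are the standard assignment-table shifts the
#' quantitation windows target: succinate methylene singlet at 2.41 ppm (4H),
#' glutamate gamma-CH2 at 2.35 and beta-CH2 at 2.08 ppm (2H each),
#' glutathione cysteinyl CH2 at 2.95 ppm (2H) plus glutamyl lines at
#' 2.16/2.55 ppm, the pooled ATP/ADP/AMP complex via its ribose H1' doublet
#' at 6.09 ppm (1H) and purine lines at 8.25/8.45 ppm, epinephrine N-CH3
#' singlet at 2.75 ppm (3H) with catechol aromatic lines at 6.86/6.91/6.96
#' ppm (the 6.91 ppm line standing for the ring position-5 proton),
#' norepinephrine sharing the aromatic lines but lacking the 2.75 ppm
#' singlet, dopamine side-chain triplets at 2.85 and 3.22 ppm, and the
#' lactate methyl doublet at 1.33 ppm (3H, J = 6.9 Hz).
#'
#' @return Named list of signature data frames.
#' @export
default_signatures <- function() {
  sig <- function(...) {
    df <- data.frame(...)
    names(df) <- c("center_ppm", "rel_area", "multiplicity", "J_hz")
    stopifnot(all(df$center_ppm >= 0 & df$center_ppm <= 10), all(df$rel_area > 0))
    df
  }
  aromatic <- rbind(
    c(6.86, 1, 2, 8.0),
    c(6.91, 1, 2, 8.0),   # ring position-5 proton: quantitation line
    c(6.96, 1, 1, 0))
  list(
    succinate = sig(2.41, 4, 1, 0),
    glutamate = sig(c(2.35, 2.08), c(2, 2), c(3, 3), c(7.0, 7.0)),
    glutathione = sig(c(2.95, 2.16, 2.55), c(2, 2, 2), c(2, 3, 2),
                      c(7.0, 7.0, 7.0)),
    atp_adp_amp = sig(c(6.09, 8.25, 8.45), c(1, 1, 1), c(2, 1, 1),
                      c(5.5, 0, 0)),
    epinephrine = sig(c(2.75, aromatic[, 1]), c(3, aromatic[, 2]),
                      c(1, aromatic[, 3]), c(0, aromatic[, 4])),
    norepinephrine = sig(aromatic[, 1], aromatic[, 2], aromatic[, 3],
                         aromatic[, 4]),
    dopamine = sig(c(2.85, 3.22, 6.89), c(2, 2, 1), c(3, 3, 1),
                   c(7.4, 7.4, 0)),
    lactate = sig(1.33, 3, 2, 6.9)
  )
}

# Positions and binomial weights of a first-order multiplet comb.
# Returns data.frame(ppm, w) with sum(w) == 1.
multiplet_comb <- function(center_ppm, multiplicity, J_hz, mhz) {
  m <- as.integer(multiplicity)
  if (m <= 1 || J_hz == 0)
    return(data.frame(ppm = center_ppm, w = 1))
  k <- 0:(m - 1)
  w <- choose(m - 1, k) / 2^(m - 1)
  dppm <- (k - (m - 1) / 2) * J_hz / mhz
  data.frame(ppm = center_ppm + dppm, w = w)
}

# Area-normalized Lorentzian density on the ppm axis. fwhm in ppm.
lorentzian <- function(ppm, center, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((ppm - center)^2 + g^2)
}

# Fraction of a unit-area Lorentzian centered at `center` lying inside
# [lo, hi] (closed form via the arctangent CDF).
lorentzian_mass <- function(center, fwhm, lo, hi) {
  g <- fwhm / 2
  (atan((hi - center) / g) - atan((lo - center) / g)) / pi
}
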