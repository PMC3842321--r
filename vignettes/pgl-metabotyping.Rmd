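---
title: "Metabotyping paragangliomas from HRMAS NMR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabotyping paragangliomas from HRMAS NMR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pglmetabo)
```

## The problem

Paragangliomas and pheochromocytomas (PGLs/PHEOs) with germline *SDHx*
mutations lose succinate dehydrogenase activity: succinate accumulates as an
oncometabolite, glutamate drops, and the catecholamine secretory profile is
immature (no epinephrine). *VHL*-related tumors instead show elevated
glutathione (GSH) and energy phosphorylated compounds (ATP/ADP/AMP). ¹H
high-resolution magic-angle-spinning (HRMAS) NMR of intact tissue measures
these metabolites simultaneously in a ~15–20 mg sample, so a small metabolite
panel can classify tumors into sporadic / *SDHx* / *VHL* metabotypes.

`pglmetabo` implements that analysis as a pipeline over *processed*
frequency-domain spectra (phased and baseline-corrected; raw FID processing
is out of scope), in five stages: spectrum I/O, synthetic cohort generation,
region-integration quantification, PLS-DA chemometrics under Monte-Carlo
cross-validation, and univariate statistics.

## Quantification model

Each metabolite is quantified by the trapezoidal integral of its fixed ppm
window (closed interval):

| window | ppm | protons |
|---|---|---|
| succinate (CH₂)₂ | 2.39–2.43 | 4 |
| glutamate γ-CH₂ | 2.32–2.38 | 2 |
| glutathione cysteinyl CH₂ | 2.93–2.98 | 2 |
| ATP/ADP/AMP ribose H1′ | 6.07–6.11 | 1 |
| epinephrine N-CH₃ | 2.73–2.77 | 3 |
| catechol aromatic H5 | 6.89–6.93 | 1 |

Absolute concentrations use PULCON-style external calibration: a 19.3 nmol
lactate standard scanned under matched conditions gives a calibration factor
`f = A_ref / (3 × 19.3)` (area per proton per nmol), and

$$ c = \frac{A}{n_H \, f \, w} \quad \text{[nmol/mg]}, $$

with `w` the tissue weight in mg. Quantifying the standard against itself
returns 19.3 nmol exactly, which the tests assert to floating-point.

Two normalizations appear in the assay's description — weight/standard
calibration and division by the total integral over 1–8.65 ppm — but they
cannot be combined into a single nmol/mg formula. This package takes
absolute calibration as the concentration path (only it yields nmol/mg) and
exposes total-integral normalization as an alternative *feature-scaling* mode
for the chemometric matrix (`quantify_cohort(feature_scaling =
"total_integral")`, off by default).

**Catecholamines.** Epinephrine (E) comes from the N-CH₃ window; the
aromatic H5 window carries epinephrine plus norepinephrine (T), and
`NE = max(T − E, 0)`. Noise can push E above T, so negative differences clip
to zero with a warning. The exact bounds of the aromatic H5 sub-window are
not part of the assay's published description; `[6.89, 6.93]` inside the
stated 6.85–6.98 complex is this package's documented, overridable default.
Proton counts per window likewise follow standard assignment tables and are
config-overridable. Dopamine is never quantified — its signature (triplets
at 2.85 and 3.22 ppm) only sets a detection flag when *both* positions
exceed the detection limit, which makes the flag robust to one-sided
spill-over from the epinephrine N-CH₃ or GSH lines.

**Detection limit.** The assay reports "not measurable" without a criterion,
so the package uses a conventional 3σ-style rule: a region is above
detection when its area exceeds `3 × (noise SD × window width)`. Noise SD is
estimated from a signal-free window (9.5–10 ppm when the grid covers it,
else 0.5–0.7 ppm; otherwise a MAD fallback over the flattest decile).
Below-detection concentrations are reported as 0 and flagged, never dropped.

**Baseline.** Default `none` — region integrals are taken directly on
corrected spectra; a linear endpoint-chord subtraction is available by flag.

## The synthetic cohort: what it emulates, and what a green test means

The original 28-sample cohort is not deposited, so the generator is the
package's stated world: 10 sporadic, 12 *SDHx* (the published cohort's 5
*SDHB* + 7 *SDHD*, pooled as *SDHx* throughout), 6 *VHL*; tissue weights
uniform in 15–20 mg; per-group panel concentrations matching the published
medians and ranges. Since only median and range are reported, any bounded
law matching both is admissible; the generator uses a Beta distribution
scaled to `[min, max]` with α fixed at 2 and β solved numerically so the
distribution median hits the target (bounded support is the deciding
property; a degenerate range returns the constant).

Spectra are rendered as sums of area-normalized Lorentzian lines (default
FWHM 1.5 Hz ≈ 0.003 ppm at 500.13 MHz), multiplets as binomial-weighted
combs split by `J/ν₀`, on a 0.5–9.0 ppm grid at 0.0005 ppm spacing (~17k
points — fast, yet window integrals capture >99% of in-window line mass),
plus i.i.d. Gaussian noise (default SD 1.0, which puts even the smallest
panel signals at SNR ≫ 100). Design choices worth stating:

* Tissue spectra contain **no lactate and no lipid** lines: the assay treats
  their absence as a tissue-quality marker, and the generator renders
  quality-passing tissue.
* Catecholamine presence is Bernoulli per group, mirroring the published
  detection pattern (epinephrine 2/10 sporadic, 1/12 *SDHx*, 0/6 *VHL*;
  norepinephrine 9/10, 9/12, 6/6). Epinephrine's value-when-present is drawn
  with median 1.04 and range 0.93–1.98 nmol/mg — the median and span of the
  three published detected values, the only information available.
  Norepinephrine uses the published per-group medians/ranges. The source
  prints catecholamines in nmol/ml but panel metabolites in nmol/mg; the
  generator and quantifier treat both as nmol/mg and record the discrepancy
  here.
* ATP/ADP/AMP is one pooled species (the assay quantifies the pooled
  spectral complex), and dopamine defaults to absent in all groups.

What a green test does **not** establish: the generator makes no attempt at
FID-domain realism — no phase/baseline artifacts, no macromolecular humps,
no shimming variation, no J-coupling quantum effects, no peak-position pH
shifts. Recovery and classification results on synthetic cohorts validate
the *pipeline machinery*, not the assay's clinical performance. Conversely,
the printed-metric checks (`paper_metrics_check()`) are exact reproductions
of the published confusion-derived percentages and involve no simulation.

## PLS-DA and Monte-Carlo cross-validation

Classes are dummy-coded (one 1/0 column per class, columns mean-centered)
and a PLS2 model is extracted by NIPALS: per component, iterate
`w ∝ Xᵀu`, `t = Xw`, `q = Yᵀt/tᵀt`, `u = Yq` to convergence (tolerance
1e-10, max 500 iterations), then deflate `X` by `tpᵀ` and `Y` by `tqᵀ`;
compact coefficients `B = W(PᵀW)⁻¹Qᵀ`. Predictions add the training dummy
means and take the column argmax, with exact ties broken to the
alphabetically first class. Components beyond the data rank truncate with a
warning rather than fail.

Defaults, and why:

* **Two components** — the published models are explicitly two-component. An
  optional leave-one-out Q² selector (`select_ncomp()`) is provided because
  cross-validation was said to choose the component count without stating
  the rule.
* **Unit-variance scaling** — the original analysis used chemometric
  software whose default is autoscaling; the choice is config-exposed
  (`pareto`, `none`) since it is not actually stated.
* **MCCV: 500 iterations, stratified 1/3 test fraction** — the source says
  only "extensive" Monte-Carlo resampling; both knobs are config-exposed.
  Preprocessing parameters are always estimated on the training split only.
* **Pooled confusion** — predictions accumulate into one aggregated matrix
  ("a confusion matrix", singular), from which Se/Sp/PPV/NPV/accuracy are
  computed; undefined ratios are `NA`, never 0. Carrier metrics collapse the
  3-class matrix over {SDHx, VHL}. Percentages round to the nearest integer,
  halves away from zero — the rule consistent with every published value.

A behavioural note measured during development (seeds 1–5, default
generator): pooled SDHx-vs-sporadic MCCV accuracy is 0.93–1.00 per seed,
0.98 pooled over seeds. Under unit-variance scaling an *SDHx* sample drawn
with low succinate but sporadic-like glutamate/GSH/ATP can cross the
boundary — the same failure mode as the single misclassified *SDHD* case in
the published 2-class model. This is a property of the stated model, not a
defect, and the package does not tune it away.

The published per-sample "correctly identified" counts may derive from
fitted-model classification rather than pooled CV; `paper_metrics_check()`
therefore consumes the printed counts as-is, and the carrier collapse of the
3-class counts assumes the one misclassified *VHL* case was predicted
sporadic — the only assignment consistent with the printed 94% carrier
sensitivity.

## Univariate layer

`mann_whitney()` computes U from rank sums with average ranks for ties; the
exact null distribution comes from the standard counting recursion
(tie-free), or full enumeration of all `C(m+n, m)` labelings when tied and
`m+n ≤ 14`; otherwise a normal approximation with tie and continuity
corrections. Two-sided exact p is `min(1, 2 × the smaller tail including
the observed U)`; two-sided throughout, as is conventional for these group
comparisons. At the cohort's (10, 12) group sizes, complete separation gives
`p = 2/C(22,10) ≈ 3.1e-6`, matching the printed succinate p-value at printed
precision. Spearman correlations are Pearson correlations of average ranks;
the published table prints unsigned magnitudes while describing some
correlations as negative, so the package always stores the signed value and
renders `|R|` only behind an explicit flag.

## Numerical choices and degenerate inputs

* ppm windows are closed intervals with a 1e-8 relative tolerance at the
  endpoints; spectra are stored descending (NMR convention) and readers
  normalize order.
* TSV round-trips write 12 significant digits; the JCAMP-DX dialect is the
  minimal uncompressed `(X++(Y..Y))` form only.
* The Beta median solver brackets β in `[1e-8, 1e8]` on the log scale
  (uniroot, tol 1e-13); a target median equal to a bound of a non-degenerate
  range is rejected (unreachable for α = 2).
* Rendering grids coarser than 0.002 ppm are rejected (lineshapes would be
  undersampled); zero-variance features drop with a warning under
  unit-variance scaling; rank-0 PCA input errors.
* All randomness flows from explicit seeds; the pipeline derives per-stage
  seeds from the global seed by a deterministic string hash, so stages can
  be rerun independently and reports are bit-reproducible.

## Known limitations

* The generator's concentration law (median-matched Beta) is one admissible
  choice among many; higher moments of the real cohort are unknown.
* Cross-metabolite spill-over is limited to Lorentzian tails of the modelled
  lines; real spectra contain many unmodelled resonances, so real-data
  quantification would be biased where the panel windows overlap them.
* The aromatic H5 window and per-window proton counts are documented
  defaults, not published values.
* Catecholamine units inherit the source's nmol/ml-vs-nmol/mg ambiguity.
* Exact Mann-Whitney with ties beyond `m+n = 14` falls back to the
  asymptotic approximation.
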