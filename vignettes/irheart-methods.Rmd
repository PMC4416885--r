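---
title: "Stain-free FT-IR histology: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-free FT-IR histology: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irheart)
```

## What the package computes

`irheart` classifies every pixel of a mid-infrared hyperspectral image of an
unstained endomyocardial biopsy section into one of five histologic classes —
myocardium, endocardium, fibrosis in the endocardial or myocardial
compartment, and lymphocytes — using only the tissue's vibrational spectrum,
and derives from the class map a sample-level rejection call (lymphocyte
burden, foci, encroachment on myocardium). This vignette explains the model,
its assumptions, the tunable parameters, what the synthetic phantom does and
does not emulate, and the design choices made where the design was genuinely
open.

## The classification model

Each kept pixel is reduced to a vector of spectral metrics
$x = (x_1, \dots, x_M)$ and classified by a weighted naive-Bayes rule

$$ P(c \mid x) \;\propto\; \pi_c \prod_{m} f_{cm}(x_m)^{\,w_m}, $$

computed in the log domain and normalized per pixel.

**Likelihood family.** $f_{cm}$ is a univariate Gaussian with the class
sample mean and standard deviation (floored at $10^{-6}$ so that degenerate,
noise-free training classes remain usable). The protocol this realizes
specifies per-metric likelihoods without fixing their functional form;
Gaussian is the natural default for ratio metrics averaged over many bands,
and a Laplace-smoothed 64-bin histogram estimator is available behind
`likelihood = "histogram"` for visibly non-Gaussian metrics.

**Metric weights.** Metrics may "have different weights" according to their
discriminative power. We make that measurable and reproducible: each metric's
exponent is $w_m = \max(\mathrm{AUC}_m - 0.5,\, 0)$, where $\mathrm{AUC}_m$
is the metric's best one-vs-rest ROC area over the five classes on the
training data, normalized so the mean exponent is 1. A metric carrying no
information ($\mathrm{AUC} = 0.5$) is effectively dropped; `weights =
"uniform"` restores the unweighted product. When one metric is selected for
several classes, its single exponent uses the best AUC across classes — the
model has one weight per metric, while scores are per (metric, class).

**Priors** default to uniform. Class abundances in a biopsy section are
determined by where the bioptome cut, not by a population frequency worth
encoding; `priors` can be overridden.

**Unclassified rule.** A pixel is assigned its argmax-posterior class only if
that posterior reaches `posterior_threshold` (default 0.5, chosen so an
Unclassified category exists as it does in practice — a posterior below 0.5
means no class is more likely than all alternatives combined). Pixels whose
amide I absorbance fails the mask, or whose every metric is undefined, are
likewise code 0. Ties in the argmax are broken toward the lowest class code,
deterministically.

**Metric selection.** Before fitting, every (metric, class) pair is scored by
rank-statistic AUC and by the minimum achievable thresholding error; the
union over classes of each class's top `k_per_class` metrics (default 5) by
AUC enters the model. Ties break by lower minimum error, then name order, so
refits are bit-identical. Undefined metric values (vanishing denominators)
are dropped from that pixel's likelihood product rather than imputed —
equivalent to a likelihood of 1 — so a single degenerate band never vetoes a
pixel.

## Preprocessing

* **Amide-I mask, threshold 0.30 AU (raw).** All cells and extracellular
  matrix contain protein, so pixels without amide I absorbance are
  non-tissue. The comparison is inclusive (≥ 0.30, reading the stated
  "minimum absorbance value" as the minimum acceptable value) and is made on
  *raw* absorbance: normalizing first would erase the very thickness signal
  the threshold uses.
* **Two-point baseline.** For each anchor pair the chord through the
  spectrum's values at the two anchors is subtracted between them; anchors
  are fixed per run. The published protocol fixes the anchor *points* but
  does not print them; our defaults are (900, 1800) cm⁻¹ for the fingerprint
  region and (2800, 3600) cm⁻¹ for the amide A region, recorded in the run
  config and overridable (including per-metric, by passing custom anchors).
  The correction is exact on linear drift and idempotent per pair.
* **Amide I normalization** divides by the windowed peak height at
  1652 cm⁻¹, making every ratio metric exactly scale-invariant; pixels whose
  corrected amide I height is non-positive cannot be normalized and are
  carried as unclassified, never dropped from the raster, so rendered images
  stay aligned.
* **Named wavenumbers** resolve to the nearest stored band (no
  interpolation): the 2 cm⁻¹ step is far below the ≥ 12 cm⁻¹ band widths.
* **Peak heights** are windowed maxima over ± 6 cm⁻¹ (config `half_window`),
  tolerating a couple of bands of calibration jitter rather than trusting a
  single stored band.

## The metric library

The default library is exactly the 27 published definitions: 21 peak-height
ratio pairs, 3 area-to-height rows and 3 center-of-gravity rows. The full
217-parameter space is not published; `default_metric_library(expand = TRUE)`
appends height ratios of every annotated band to amide I as a documented step
toward it. 1236 vs 1239 cm⁻¹ (and 1027 vs 1032 cm⁻¹) are treated as distinct
band positions as printed.

The center-of-gravity rows list four wavenumbers ("Left bound, Right bound,
CG 1, CG 2") whose semantics are not defined where they are printed. Two
readings are coherent, and both are implemented:

* **default (`cog_mode = "window"`):** the CG is computed over [CG 1, CG 2]
  with the local chord anchored at [Left, Right] — the outer bounds set the
  baseline, the inner bounds the analysis window;
* **alternative (`cog_mode = "normalized"`):** the CG is computed over
  [Left, Right] and mapped linearly so CG 1 → 0, CG 2 → 1.

The default was chosen because its output stays in wavenumber units, like
every other table entry. Inside CG weights, negative baseline-corrected
values are clipped at zero so the weighted mean stays inside its interval.

## The phantom generator

No biopsy data are deposited with the method, so the simulator is the test
substrate. It emulates the *statistical structure the classifier assumes*:

* **Per-class spectra** are sums of Gaussian bands at the annotated positions
  (1027, 1065, 1155, 1163, 1204, 1236, 1389, 1405, 1452, 1543, 1652,
  3300 cm⁻¹, plus a zero-height paraffin band at 1464 cm⁻¹), anchored at
  amide I = 1.0. Fingerprint bands default to 25 cm⁻¹ FWHM and amide A to
  120 cm⁻¹, chosen to resemble tissue spectra; line shapes are configurable
  (Lorentzian available). The per-class heights are simulator constants:
  only their *orderings* are anchored to observation (amide III / collagen
  elevated in fibrosis and endocardium over myocardium; glycogen elevated in
  myocardium and depressed at fibrosis; lymphocytes separated from muscle at
  1236 cm⁻¹); the absolute values were fixed once and shipped in
  `inst/extdata/class_library.json`.
* **Layout.** The layered-biopsy layout places an endocardium band along one
  edge, fibrosis-endocardium beneath it, a myocardium bulk with elliptical
  fibrosis patches and circular lymphocyte foci (count and radius
  configurable, emulating foci of infiltrate), inside a non-tissue frame of
  near-zero absorbance that the amide mask removes. Foci are kept disjoint
  where the raster allows it (so ground truth has the requested component
  count); on rasters too small for disjoint placement, contact is allowed
  after enough failed attempts rather than failing the simulation.
* **Pixel physics.** spectrum = thickness × class model + linear baseline +
  i.i.d. Gaussian noise. Thickness is uniform on [0.7, 1.3] (±30%, the
  variation amide-I normalization exists to remove); the baseline slope is
  N(0, 2 × 10⁻⁵ AU/cm⁻¹), a drift of a few percent of amide I across the
  stored range, removed exactly by the two-point correction. Boundary pixels
  at class interfaces are convex mixtures of the two adjacent class spectra
  (Beer–Lambert additivity, standard for thin sections) with the dominant
  fraction uniform on [0.5, 1], recorded in the ground truth. All randomness
  flows from one seed; equal specs give bit-identical phantoms.
* **Noise calibration.** The acquisition spec is SNR ≥ 500:1, measured here
  as amide I height over the peak-to-peak (max − min) noise in the
  signal-free 1800–2000 cm⁻¹ window. The expected range of the ~101 i.i.d.
  Gaussian samples in that window is ≈ 5.0 σ, so the default per-band σ is
  `1 / (snr × 7)`: the factor 7 places the 5th percentile of the measured
  ratio near 1.17 × the target, i.e. ≥ 95% of draws meet the spec with
  margin. This is an order-statistics calibration, not a fitted constant.
* **Residual paraffin.** De-paraffinization leaves a sharp CH-bending band at
  1464 cm⁻¹; `paraffin_contaminate()` injects it (default FWHM 12 cm⁻¹ —
  crystalline paraffin bands are much sharper than tissue bands). The QC
  score measures the 1464 cm⁻¹ height above a local chord anchored at 1452
  and 1476 cm⁻¹ (clipped at zero), normalized by amide I. The tight local
  chord is what isolates the narrow paraffin band from the broad overlapping
  1452 cm⁻¹ tissue band: clean tissue scores ≈ 0, and an injected band of
  height *h* is recovered at 0.9375 *h* (the chord keeps
  $1 - 2^{-4}$ of a band whose anchors sit one FWHM out). The score is a QC
  number, not a gate.

**What the phantom does *not* emulate** — and hence what passing tests do not
show about real data: Mie and resonant-Mie scattering, the dispersion
artifacts of reflective low-emissivity substrates (the protocol explicitly
forgoes rigorous distortion corrections), correlated detector noise (real
FT-IR noise is band-correlated; the classifier only consumes band ratios, so
i.i.d. noise is a documented simplification), per-region refocus effects in
stitched mosaics, and any morphological realism beyond layered compartments
with foci. Synthetic Pd values near 1 say the *pipeline* is correct and
well-conditioned at the stated SNR, not that patient tissue separates this
cleanly.

## Evaluation conventions

* ROC curves sweep the class posterior over kept, truth-labeled pixels, one
  vertex per unique score, with exact (0,0) and (1,1) endpoints and
  trapezoidal AUC. Labeled pixels whose posterior is undefined enter the
  sweep at score −∞, counting as misses or true negatives at every
  threshold — the unclassified mechanism is not allowed to flatter Pd.
  Posterior (not a raw discriminant) is the swept score.
* Pd at fixed Pfa interpolates linearly between vertices (at a vertical
  segment, the upper point is used).
* Confusion tables are column-normalized percent with an Unclassified
  predicted row; each truth column sums to 100.
* The rejection call uses 8-connectivity for foci and encroachment,
  `min_size = 4` pixels per focus and a negligible-burden threshold of 0.1%
  of tissue pixels; none of these constants are published, all are exposed in
  the call.
* Two independent AUC implementations coexist deliberately: the
  rank-statistic AUC used for metric scoring and the trapezoid AUC of the
  ROC module agree to 10⁻⁹ on identical input, which the tests assert.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 200 × 200 phantoms
(40,000 pixels, 1601 bands) for the held-out detection analog — large enough
that every class has hundreds to thousands of labeled pixels — and 40–64
pixel rasters for unit-level checks. Training on one realization and
evaluating on an independent one (different seeds) keeps the Pd estimates
honest about generalization across the generator's randomness.

Numerical conventions collected in one place: band areas use the trapezoid
rule above the endpoint chord; file I/O is a single documented ENVI dialect
(band-sequential, 32-bit little-endian floats, ascending in-memory axis
regardless of on-disk order; readers reject other interleaves); stitching
resolves overlap by last-tile-wins and zero-fills uncovered pixels for the
mask to remove; binning averages k × k blocks, drops trailing remainders with
a provenance note, and is applied to raw absorbance with the mask re-derived
afterwards; model JSON is written at full precision (17 significant digits)
so serialization round-trips are exact.

## Known limitations

Endocardium-vs-fibrosis confusion is intrinsic: their band structure differs
less than any other class pair, and thin endocardial bands are mostly
boundary pixels — the same pattern that limits endocardium accuracy on real
sections. Mixed pixels carry their dominant class as ground truth, so pixel
accuracy at class interfaces is bounded by the mixing model, not by the
classifier. The sample-level grade beyond a binary rejected/not-rejected call
(ISHLT numeric grading, antibody-mediated rejection, Quilty lesions) is out
of scope.
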