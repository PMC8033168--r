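---
title: "Methods: segmentation, spectral classification and cross-modal PLS in ramanxome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, spectral classification and cross-modal PLS in ramanxome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `ramanxome`, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design choices made where several defensible options existed.

## The measurement model

A hyperspectral Raman map is a `height × width` grid of pixel spectra over
one live cell, each spectrum an intensity vector on a shared wavenumber
axis (cm⁻¹). Two conditions are compared: non-activated B cells (`D0`) and
cells 96 h after cytokine activation (`D4`). The biology of interest is
nuclear: activation remodels chromatin and transcription, which shifts
nucleic-acid bands in the fingerprint region — most prominently the
786 cm⁻¹ band (cytosine ring / DNA backbone), whose intensity drops in
activated cells while the neighbouring 752 cm⁻¹ band is stable. The
752/786 intensity ratio is therefore a one-number activation readout, and
the full spectrum supports multivariate classification.

## Segmentation: common k-means

Pixel spectra of *all* maps are pooled and clustered jointly ("common"
k-means, `k = 10` by default), so a cluster means the same biochemical
class in every cell. We use Lloyd's algorithm with squared Euclidean
distance, k-means++ seeding, and `n_init = 10` restarts keeping the best
inertia; the within-cluster sum of squares is asserted non-increasing at
every iteration. Clustering is deterministic given the seed. Spectra are
clustered raw (no normalisation), with vector normalisation available as a
flag-like preprocessing step the caller can apply.

For large pools `common_kmeans(subsample = n)` fits the restarts on a
random pixel subset and then polishes with full-data Lloyd iterations, so
the returned centroids are still exact means of their full-data members.
This mirrors common practice when hundreds of thousands of spectra are
clustered, and it is what keeps the test-suite cohorts fast.

Cluster → compartment assignment uses two centroid band scores, each
baseline-referenced against a quiet band (1780–1800 cm⁻¹ by default):

* **cell signal** (default band 1420–1480 cm⁻¹, the CH₂ deformation band
  present in both nucleus and cytoplasm): clusters below 25% of the
  maximum signal are background;
* **nucleic-acid marker** (786 ± 4 cm⁻¹): the remaining clusters are split
  into nucleus (high marker) and cytoplasm (low marker).

The nucleus/cytoplasm split defaults to the *largest gap* in the sorted
marker scores rather than a fixed top-tercile count. With a data-driven
number of clusters per compartment a fixed count misassigns clusters
whenever k-means happens to spend, say, four of ten clusters on nuclei; the
gap rule adapts and is what makes 100% pixel accuracy on noiseless cohorts
attainable. A fixed count (`n_nucleus`, `method = "count"`) and a manual
`override` map remain available.

Per map, the nucleus, cytoplasm and background member-pixel spectra are
averaged; the whole-cell spectrum is recomputed over the union of nucleus
and cytoplasm pixels (equivalently, the pixel-count-weighted mean of the
two compartment means — not the unweighted average, which would distort
cells with small nuclei).

**QC rule.** Maps with no nucleus or no cytoplasm pixels are discarded, as
are maps whose nucleus is too small: we interpret "nucleus size" as the
equivalent-circle diameter `2·pixel_size·sqrt(A_px/π)` and discard strictly
below 3 µm (100 pixels at 0.2 µm ≈ 2.26 µm → discarded; 200 pixels ≈
3.19 µm → retained). A caliper or connected-component diameter would be a
defensible alternative; the equivalent diameter is insensitive to mask
raggedness at the noise levels we target.

**Background subtraction** is three steps: (1) subtract from every
compartment spectrum (including the background itself) its offset, the mean
intensity in the 1780–1840 cm⁻¹ band; (2) smooth the offset-corrected
background with a Savitzky–Golay filter, order 2, frame length 99; (3)
subtract the smoothed background from nucleus, cytoplasm and whole-cell
spectra. A Savitzky–Golay filter of order `p` reproduces degree-≤`p`
polynomials exactly, so a polynomial background passes through step 2
unchanged at interior channels — the property the unit tests pin down to
1e-9. Edge channels are handled by the filter's full-frame polynomial fits.
The default axis (600–1800 cm⁻¹ at 1 cm⁻¹, 1201 channels) covers the
fingerprint bands and comfortably exceeds the 99-channel frame; since the
offset band extends past the axis end, the offset uses the intersection
(1780–1800 cm⁻¹, 21 channels) and errors only when the intersection is
empty. The retained spectral range is a package choice: acquisition
commonly focuses via the C–H stretch region (2700–3000 cm⁻¹), but the
analysis is fingerprint-only by default and the axis is configurable.

## Spectral classification

* **Peak intensities** are windowed means (± 4 cm⁻¹) on background-
  corrected spectra, with no additional local baseline; the peak-ratio test
  is a two-sided Welch t-test on per-cell 752/786 ratios (cells with a
  nonpositive denominator are excluded with a warning).
* **PCA** is mean-centred with no scaling; 9 components are retained by
  default. Loadings follow the sign convention that the largest-magnitude
  element is positive. Per-component two-sided Welch t-tests compare D0 and
  D4 scores, unadjusted by default (Holm optional): with 9 components the
  per-test level is the quantity of interest, mirroring how per-PC tests
  are usually read in chemometrics. Welch rather than pooled-variance was
  chosen because the activation effect changes spectral variance as well as
  means.
* **LDA** is the Fisher discriminant on the selected PC scores (default
  1–9; restricting to t-test-significant components is available):
  `w ∝ S_w⁻¹(μ_D4 − μ_D0)`, scaled so the pooled within-class variance of
  the LD scores is 1, with the decision threshold at the midpoint of the
  projected class means (equal priors — class sizes are nearly balanced in
  the designs we target). A near-singular within-class scatter falls back
  to a small ridge with a warning. The discriminant is back-projected to
  the wavenumber axis as the coefficient-weighted sum of PC loadings, which
  is how band-level interpretation ("which peaks separate the states") is
  done.
* **Leave-one-out** refits the LDA per fold; the PCA is fit once on all
  cells by default, with `strict_loo = TRUE` refitting PCA inside every
  fold. Fixing the PCA is standard chemometrics practice and changes
  nothing on well-separated data; the strict variant is the conservative
  option for marginal effect sizes. D4 is the positive class for
  sensitivity/specificity.

## Cross-modal PLS

Bulk RNA-seq gives 3 replicates per condition; Raman gives tens of single
cells. Cells are therefore randomly partitioned into three balanced
pseudo-replicates per condition (sizes within one cell, e.g. 58 → 20/19/19)
and their PC-score vectors averaged, giving six Raman "samples" matched to
the six RNA samples by index order within condition — the replicates are
exchangeable, so the pairing is arbitrary and recorded via the seed.

Counts are transformed to `log2(1 + count)` and centred per transcript
using training-sample means only (no unit-variance scaling, preserving
magnitude structure; autoscaling is a caller-side option). The PLS2 model
is fit by NIPALS with deflation of both blocks; the coefficient matrix
`β` maps centred features to centred responses, and `A = 2` latent
components is the default — with six samples a leave-one-out fold has five,
leaving at most four estimable components, and two is the largest count
that is stable in every fold. Leave-one-out prediction holds each sample
out in turn, refits on the rest (centering recomputed on the training fold
only), predicts the held-out PC-score vector, and converts it to an LD
score and a D0/D4 group call via the spectral-stage discriminant.

VIP is computed on the full six-sample model (per-fold VIP with rank
aggregation is a straightforward caller-side variant), with
`mean(VIP²) = 1` as a built-in identity check. Responses are the retained
PC scores (9 by default).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
the optics:

* **Spectra** are sums of Gaussian peaks per compartment on the default
  axis. The nucleus carries the 752/786 cm⁻¹ doublet (amplitudes 8 and 10),
  plus backbone, CH₂ and amide bands; the cytoplasm carries
  protein/lipid-dominated bands with a weak residual doublet; the
  background is a broad low-frequency hump plus a water-bending band, so
  background subtraction is non-trivial. A shared, slowly varying additive
  baseline is applied to all pixels.
* **The condition effect** multiplies the nucleus 786 cm⁻¹ amplitude by
  0.8 in D4, reproducing a raised 752/786 ratio in activated cells.
* **Geometry**: disk cells with concentric disk nuclei (kidney-shaped
  nuclei available via an eccentricity parameter, off by default, as such
  nuclei occur but are a minority); per-map radius jitter (± 8%) and
  sub-pixel centre jitter, clamped to the grid. The default grid is
  75 × 75 px at 0.2 µm (15 × 15 µm).
* **Noise**: i.i.d. additive Gaussian per channel. With the default
  `noise_sd = 1` the per-pixel SNR at the 786 peak is ≈ 10. A small
  per-map log-normal intensity factor (sd 0.02) emulates focus/laser drift
  between cells; it is deliberately independent of `noise_sd`, so a
  zero-noise cohort is still pixelwise exact within each map while the
  pooled cohort contains enough distinct spectra for k = 10 clustering to
  be well-posed.
* **Counts** are negative binomial with common dispersion (default 0.1;
  `dispersion = 0` gives deterministic rounded means). A designated
  informative subset has `log2(1 + count)` means that are exactly affine in
  the per-sample PC-score targets through a planted coefficient matrix
  `B_true`. Coefficient directions are isotropic in target units — so the
  dominant, condition-separating score axes dominate the link, as they do
  when transcription drives biochemistry — and each informative row is
  rescaled to a guaranteed planted effect (log2 feature sd uniform in
  0.75–1.5 × `effect_scale`, default `effect_scale = 1.5`): an
  "informative" transcript with a near-zero coefficient would carry the
  label without any recoverable signal, which would make ground-truth
  recovery metrics meaningless rather than hard.

What the generator does **not** emulate: confocal point-spread bleed-through
of cytoplasm into nuclear pixels (real nuclear spectra are never pure),
Poisson/shot-noise statistics, cosmic-ray spikes, wavenumber calibration
drift, and any RNA-seq read-level artefacts (library size, GC bias — counts
only). Passing tests therefore demonstrate correctness of the algorithms
under the stated statistical model, not robustness to those instrument
effects.

## Numerical choices and degenerate inputs

* k-means errors when `k` exceeds the number of distinct spectra (the
  k-means++ seeding detects this); empty clusters during Lloyd iterations
  are re-seeded at the worst-fit point.
* Welch tests on zero-variance groups return statistic 0 / p = 1 when the
  groups are identical and ±∞ / p = 0 when constant but different.
* NIPALS stops early if the feature block is exhausted before `A`
  components (`A_used` records the count); `A = 0` predicts the training
  mean. Convergence tolerance 1e-12, 500 iterations.
* Doubles in the map container are written as `%.17g`, making write∘read
  bit-exact; 15-significant-digit writers do not round-trip.
* Map files are validated against their headers (channel count, pixel
  count), and all readers reject non-finite values.

## Problem sizes in the test suite

Tests run on sizes chosen to exercise every code path at desk scale: unit
cohorts of 4 + 4 to 15 + 15 cells on 24 × 24 px grids; the acceptance
surface uses 10 + 10 cells on 40 × 40 px grids for segmentation recovery
and 50 + 50 cells on 24 × 24 px grids for the classifier and cross-modal
stages, with 2000-transcript × 6-sample count matrices (30 informative),
clustering with `subsample = 8000`. Grid and cohort sizes scale the
compute, not the science: per-pixel SNR, the 0.8 effect, the QC rule and
the replicate structure are held at the defaults above.

## Known limitations

* The nucleus/cytoplasm marker rule assumes the nucleic-acid band is the
  discriminating feature; cell types whose compartments differ elsewhere
  need a different `nucleic_band`/`signal_band` configuration.
* With three pseudo-replicates per condition the PLS fit has four degrees
  of freedom; the model is intentionally low-rank (`A = 2`) and its
  leave-one-out validation is a sanity check, not a generalisation
  estimate.
* VIP ranks transcripts by contribution to the *fitted correspondence*;
  on real data it inherits any confounding between condition and batch.
* The report's SVG scatter is intentionally minimal (no axes/legends); the
  underlying TSVs are the quantitative record.
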