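# ramanxome

Label-free single-cell phenotyping from hyperspectral Raman maps, and its
linear correspondence with the transcriptome.

`ramanxome` is an R package for studies that image single B cells with
confocal Raman microscopy (a grid of pixel spectra per cell, intensity vs
wavenumber in cm⁻¹) across two activation states — non-activated (`D0`) and
cytokine-activated (`D4`) — and ask two questions:

1. **Can the activation state be read out label-free from the spectra?**
   The pipeline segments each map into nucleus / cytoplasm / background by
   *common k-means* (one k-means over the pooled pixel spectra of all maps,
   so cluster identities are shared across cells), extracts per-cell
   compartment mean spectra, removes coverslip/buffer background with a
   three-step Savitzky–Golay correction, and discriminates D0 from D4 by a
   nucleic-acid peak ratio (752/786 cm⁻¹), PCA with per-component Welch
   tests, and a Fisher linear discriminant on the PC scores with
   leave-one-out validation.
2. **Which transcripts track the Raman phenotype?** A PLS2 regression
   `R = β·T` predicts per-sample Raman PC-score vectors `R` from
   log-transformed transcript read counts `T` (cells are randomly grouped
   into three pseudo-replicates per condition to match the bulk RNA-seq
   replicate structure), validated leave-one-out, and transcripts are
   ranked by Variable Importance in Projection (VIP),
   `VIP_j = sqrt( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a )`,
   whose squared mean over transcripts is 1 by construction.

A first-class synthetic-data module generates Raman cohorts and matched
negative-binomial count matrices with full ground truth (pixel masks,
condition effects, planted informative transcripts and link coefficients),
so every stage is testable end to end without any external data.

## Worked example

Simulate a 10 + 10 cell cohort (40×40 px maps, 0.2 µm pixels, peak SNR ≈ 10
at 786 cm⁻¹, the D4 state scaling the 786 cm⁻¹ nucleic-acid peak by 0.8),
segment it, classify it, and link it to a matched synthetic transcriptome:

```r
library(ramanxome)

lib <- make_component_library()                       # Gaussian-peak spectra
geo <- cell_geometry(40, 40, 0.2, cell_radius = 2.8, nucleus_radius = 1.8)
sim <- simulate_cohort(10, 10, lib, geo, noise_sd = 1, seed = 7)

seg <- segment_cohort(sim$maps, k = 10, seed = 7, n_init = 10,
                      subsample = 8000)
table(seg$assignment$mapping)
#> background  cytoplasm    nucleus
#>          4          3          3
segmentation_accuracy(seg$model, seg$assignment, sim$truth)
#> [1] 1

cm    <- compartment_matrix(seg, "nucleus")
ratio <- peak_ratio_test(cm$spectra, cm$labels, cm$axis)
#> 752/786 ratio: D0 0.811 vs D4 1.023 (Welch p = 2.75e-21)
pcm <- fit_pca(cm$spectra, n_keep = 9, axis = cm$axis)
ld  <- fit_lda(pcm, cm$labels)
loo_classify(cm$spectra, cm$labels, n_keep = 9)
#> <loocv_result> sensitivity 100.0%, specificity 100.0% (TP 10 FP 0 TN 10 FN 0)

ps  <- make_pseudoreplicates(pcm$scores, cm$labels, 3, seed = 7)
tx  <- simulate_transcriptome(2000, 30, ps$targets, dispersion = 0.1, seed = 7)
res <- crossmodal_analysis(tx$counts, pcm, cm$labels, ld, seed = 7)
res$loo$predictions[, c("sample", "condition", "ld_score", "call")]
#>      sample condition  ld_score call
#> D0-1   D0-1        D0 -12.43532   D0
#> D0-2   D0-2        D0 -11.27291   D0
#> D0-3   D0-3        D0 -14.89527   D0
#> D4-1   D4-1        D4  11.09687   D4
#> D4-2   D4-2        D4   7.22492   D4
#> D4-3   D4-3        D4  15.11942   D4
vip_recovery(res$vip, tx$truth, 20)
#> [1] 1
```

The `table` shows how the 10 shared clusters were assigned to compartments;
`segmentation_accuracy` compares the per-pixel assignment with the
generator's masks. The ratio test shows the activated cells' raised
752/786 ratio (the 786 cm⁻¹ band weakens on activation). The six
leave-one-out PLS predictions land on the correct side of the LD threshold
(negative = D0, positive = D4), and the top-20 VIP transcripts recover the
planted informative set completely in this run.

The same flow is scriptable: `run_pipeline(config, seed, out_dir)` writes
TSV/JSON artifacts per stage plus a YAML run manifest, `build_report()`
assembles them into a static HTML report, and a thin CLI wraps both
(`inst/scripts/ramanxome simulate|segment|classify|crossmodal|all|report
--config cfg.yaml --seed N --out DIR`).

## File formats

* **Hypermap container** (one file per map, versioned): a 7-line commented
  header (`# hypermap v1`, id, condition, height, width, pixel size,
  channels), one tab-separated wavenumber-axis line, then one pixel
  spectrum per line in row-major order. Doubles are written with `%.17g`,
  so write∘read is the identity.
* **Cohort directory**: `manifest.yaml` plus one map container (and
  optionally one integer mask grid: 0 background, 1 cytoplasm, 2 nucleus)
  per map.
* **Counts**: TSV, first column transcript ids, one column per sample;
  condition labels from the sample-id prefix (`D0-1`, …) or supplied
  explicitly.

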