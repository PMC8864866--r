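# aplsmear

Screening digitized bone marrow smears (BMS) for **acute promyelocytic
leukemia (APL)** with a multi-stage image-analysis pipeline, plus a seeded
synthetic smear generator so the whole pipeline can be trained, tested and
benchmarked without any patient data.

APL is the AML subtype driven by t(15;17)/PML-RARα. Morphologically it is
marked by an excess of abnormal, heavily granulated promyelocytes, some
bearing needle-shaped Auer rods; prompt recognition matters because early
mortality is high and effective therapy (ATRA/ATO) exists. The package
follows the hierarchical design used for this problem in practice, rather
than attempting end-to-end whole-image classification:

1. **Detection** — a two-stage cell detector (background-model proposals +
   a learned region scorer) finds nucleated cells and emits elliptical
   regions with confidences; an intensity-based refinement polishes each
   ellipse. Supports iterative human-in-the-loop correction rounds.
2. **Per-cell classification** — each fixed-size cell crop is scored by
   three independent binary classifiers (myeloblast, promyelocyte, Auer
   rod) over a fixed convolutional/statistical feature extraction with a
   trainable fully connected head (1–3 layers, dropout). Cells keep a
   multi-label encoding: a promyelocyte with one Auer rod is
   `(myeloblast 0, promyelocyte 1, Auer rod 1)`. Classical morphometrics
   (size, sphere-equivalent volume proxy, RMS contrast) are attached.
3. **Smear classification** — per-cell calls are pooled into per-smear
   ratios `r_X = #(p_X ≥ τ) / n_cells` for X ∈ {myeloblast, promyelocyte,
   Auer rod}, and a single fully connected layer without dropout (an
   affine map + sigmoid, the "ensemble net", ENN) maps the ratio vector to
   `P(APL)` for one of two binary tasks: APL vs healthy donor, or APL vs
   non-APL AML.
4. **Evaluation** — COCO-style detection metrics (greedy confidence-ordered
   matching; mAP/mAR at IoU 0.5 and averaged over 0.50:0.95), ROC and
   precision-recall AUC, and **patient-level threefold cross-validation**
   with a 2:1 train:test split so no patient ever crosses between training
   and test. Fold metrics are macro-averaged.
5. **Explainability** — occlusion sensitivity maps: patches are masked one
   grid cell at a time and the drop in the image-level score is recorded
   and rendered as a viridis overlay.

The synthetic generator renders elliptical cells with type-specific
texture (granulation, eccentric nuclei, Auer-rod line primitives), smudge
artifacts and optional cell overlap, with exact elliptical ground truth.
Cohort compositions mimic the three clinical groups (healthy marrow ≈ no
blasts; non-APL AML ≈ myeloblast excess centred at 63.5%; APL ≈
promyelocyte-family excess centred at 63%, partly Auer-rod-bearing), with
per-patient composition drawn once and shared across that patient's
images.

## Worked example

```r
library(aplsmear)

# one synthetic APL smear with ground truth
spec <- cohort_spec("APL", n_patients = 1, cells_per_image_range = c(25L, 25L))
sm <- generate_smear(spec, patient_id = "APL_p01", seed = 42)
dim(sm$image)
#> [1] 384 512   3
dplyr::count(sm$annotations, cell_type, has_auer_rod)
#> # A tibble: 3 × 3
#>   cell_type    has_auer_rod     n
#>   <chr>        <lgl>        <int>
#> 1 myeloblast   FALSE            5
#> 2 other        FALSE           10
#> 3 promyelocyte FALSE           10
plot_smear(sm$image, sm$annotations)   # raster with yellow ellipse overlays

# a small end-to-end cross-validated run (≈1 min on one CPU)
cfg <- pipeline_config(task = "APL_vs_HEALTHY", seed = 7, n_patients = 6,
                       images_per_patient = 1,
                       enn = list(epochs = 300, lr = 0.2, hpo_trials = 0),
                       cohort_args = list(image_size = c(256L, 192L),
                                          cells_per_image_range = c(12L, 16L)))
res <- run_pipeline(cfg)
res$report
#> <eval_report: APL_vs_HEALTHY>
#>   macro ROC AUC 0.9583 (sd 0.0722), macro PR AUC 0.9444 (sd 0.0962)
#> # A tibble: 3 × 6
#>    fold roc_auc pr_auc precision recall    f1
#>   <int>   <dbl>  <dbl>     <dbl>  <dbl> <dbl>
#> 1     1   0.875  0.833     0          0   0
#> 2     2   1      1         1          1   1
#> 3     3   1      1         0.667      1   0.8
tidy(res$models$enn)
#> # A tibble: 4 × 2
#>   term               estimate
#>   <chr>                 <dbl>
#> 1 (Intercept)          -0.692
#> 2 ratio_myeloblast   -109.
#> 3 ratio_promyelocyte   10.3
#> 4 ratio_auer_rod       58.8
```

The fold table reads as usual: each fold's test patients are scored end to
end (detect → crop → per-cell classify → ratios → ENN) and ROC/PR AUCs are
computed on the image-level `p_apl`; the header line is the macro average
with the dispersion of the fold values. The tidied ENN shows the expected
biology: a high promyelocyte or Auer-rod ratio pushes towards APL, a high
myeloblast ratio away from it (towards "not APL" in this healthy-donor
task the myeloblast ratio separates nothing, so its weight is free to be
large and negative on the near-zero ratios).

At full desk scale (17 patients per arm, the default), the same pipeline
reaches macro ROC/PR AUC ≈ 1.0 on both binary tasks, and the detector
reaches mAP/mAR ≈ 0.99 at IoU 0.5 on held-out clean smears — clean
synthetic smears are intentionally an easier problem than stained marrow.

A thin CLI over the same functions lives in `inst/cli/aplsmear.R`
(`synth`, `pipeline`, `occlude` subcommands).

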