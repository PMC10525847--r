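# fundusroi

Multi-label ocular disease classification for ultra-widefield fundus
images, built around disease-specific regions of interest.

Ultra-widefield fundus photography captures most of the retina in a
single image, but each of the common ocular diseases manifests in a
characteristic part of it: diabetic retinopathy (DR), retinal break
(RB) and retinal vein occlusion (RVO) scatter lesions across the whole
retina; epiretinal membrane (ERM) and age-related macular degeneration
(AMD) concentrate around the macula; glaucoma-suspect (GS) findings sit
on and around the optic disc. `fundusroi` implements a pipeline that
exploits this:

1. **Landmarks** — locate the optic disc and macula (detector
   interface + ground-truth oracle; proposal filtering with boundary
   removal and IoU > 0.7 non-maximum suppression; top-1-per-class
   selection).
2. **ROIs** — extract two square crops anchored to the optic-disc box
   diagonal `d`: edge `αd` at the disc center `O` (default `α = 3`) and
   `βd` at the macula center `M` (default `β = 6`), padded at borders
   so the shape is always `round(k·d)²`.
3. **Branches** — three label-routed classifiers (disc → GS, two-class
   softmax cross-entropy; macula → ERM+AMD and whole image → DR+RB+RVO,
   element-wise sigmoid BCE), trained with Adam, batch size 8, learning
   rate 1e-3 (ROI branches) / 1e-4 (whole image) halved every 10
   epochs, online flip/rotation augmentation, checkpoint restored from
   the epoch of highest mean validation AUC.
4. **Evaluation** — per-disease cut-offs tuned to maximize
   `sensitivity × specificity`; one-vs-rest AUC/accuracy/sensitivity/
   specificity, micro-averages from pooled confusion counts, a derived
   Normal class (all labels zero / no probability above threshold),
   repeated-run Student-t 95 % confidence intervals, Welch significance
   tests, ROC export and a single-label misclassification matrix.
5. **Synthetic data** — a seeded generator of fundus-like scenes
   (circular field, bright disc with cup, darker macula, per-disease
   lesion placement regimes) so the whole pipeline is testable without
   clinical data. A whole-image six-label baseline and ablation
   harnesses (ROI-size sweep with an "entire image" row; backbone
   comparison) reproduce the method's comparisons qualitatively.

Everything is plain R (no deep-learning framework is required): the
registered backbones are small seeded MLPs behind a registry, and
images are 8-bit grayscale PNGs handled by a built-in codec.

## Worked example

```r
library(fundusroi)

cfg <- pipeline_config(synth = synthetic_config(seed = 1), n_images = 200,
                       epochs = 5, n_runs = 2, seeds = 1:2)
res <- run_end_to_end(cfg)
subset(res$summary, metric == "auc")
#>    class metric  mean half_width
#> 1     dr    auc 0.530       2.80
#> 5     rb    auc 0.708       1.13
#> 9    rvo    auc 0.560       0.00
#> 13   erm    auc 0.815       2.34
#> 17   amd    auc 0.833       2.12
#> 21    gs    auc 1.000       0.00

round(res$runs[[1]]$thresholds, 3)
#>    dr    rb   rvo   erm   amd    gs
#> 0.343 0.291 0.369 0.224 0.252 0.449
```

Reading the output: each row is a one-vs-rest validation AUC averaged
over the two runs, with a Student-t 95 % half-width (wide here because
`n_runs = 2`; the half-width uses `t(0.975, 1) ≈ 12.7`). The ROI-routed
diseases (ERM, AMD at the macula; GS at the disc) are learned well even
in this 5-epoch smoke profile, while the whole-image branch at its
faithful 1e-4 learning rate has barely started on DR/RVO — exactly the
region-vs-whole-image gap the method is built on. The thresholds are
the tuned per-disease cut-offs from the first run. Determinism: calling
`run_end_to_end(cfg)` again reproduces every number (and every report
file byte) exactly.

Lower-level pieces are exported individually:

```r
scene <- generate_scenes(synthetic_config(seed = 7), 1)[[1]]
lm    <- select_landmarks(oracle_detect(scene))
rois  <- make_rois(scene$image, lm, roi_config(alpha = 3, beta = 6))
dim(rois$od_roi)   # round(3 d) x round(3 d)
```

A command-line wrapper with `generate`, `extract-rois`, `run-all` and
`ablate-roi` subcommands is installed under `inst/cli/fundusroi` (see
`?cli_main`).

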