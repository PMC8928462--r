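# pcrCAD

Computer-aided diagnosis (CAD) pipeline for calling **pathological complete
response (pCR)** after neoadjuvant chemotherapy from 2D breast MR lesion
images, plus the reader-study statistics used to evaluate such systems.
The package is aimed at methodologists who want a fully testable, seedable
implementation of the classic radiomics CAD recipe:

1. **Segmentation** — a small trainable U-Net-style encoder-decoder
   (residual conv blocks, max-pool encoder, skip-connected upsampling
   decoder; Adam + pixel-wise cross-entropy) producing a binary tumor mask.
2. **Shape** — the 13 normalized-radial-length (NRL) descriptors of the
   mask: roundness 4πA/P², bounding-box and inertia aspect ratios, NRL
   mean/SD/entropy, area ratio, leaflet count, spiculation,
   boundary roughness, direction angle, and two normalized-ellipse
   measures.
3. **Texture** — the 48 gray-level co-occurrence matrix (GLCM) features:
   energy Σp², correlation Σ(i−μx)(j−μy)p/σxσy, contrast Σ(i−j)²p and
   entropy −Σp log₂p at 3 offset distances × 4 directions, computed
   strictly inside the mask on a 32-level quantization.
4. **Classification** — a maximum-margin SVM (linear by default) on the
   61-feature vector under a stratified **5-part split rotation**: each
   rotation trains on 3 parts, selects hyperparameters and the Youden
   operating threshold on 1 validation part, and scores 1 test part, so
   every case is tested exactly once and test metrics pool cleanly.
5. **Evaluation** — sensitivity/specificity/accuracy, Mann–Whitney AUC
   with DeLong 95% CI, the single-operating-point AUC (Se+Sp)/2 for
   call-only readers, chi-square/McNemar method comparisons, reader⊕CAD
   OR-fusion, molecular-subtype subgrouping, and rate→count
   reconstruction that makes printed diagnostic tables internally
   checkable.

A seeded **lesion phantom generator** (radial-harmonic contours, optional
spicules, homogeneous or necrosis-like heterogeneous texture) emulates a
cohort with configurable class and subtype margins, so the entire pipeline
runs and is tested without any clinical data.

## Worked example

```r
library(pcrCAD)

# a 60-case synthetic cohort with well-separated classes
co <- makeCohort(16, 44,
                 c(LuminalA = 15, LuminalB = 15, `HER2+` = 15, TN = 15),
                 classEffect = 1, seed = 1L, imageSize = 64L)
co
#> LesionCohort with 60 cases (non-pCR: 44, pCR: 16)
#>   subtypes: HER2+ 15, LuminalA 15, LuminalB 15, TN 15

feats <- extractFeatures(co)              # 13 shape + 48 texture columns
res   <- runRotations(feats, makeSplits(co, seed = 1L))
cad   <- decisionSet(res$call, res$label, score = res$score,
                     subtype = res$subtype, caseId = res$case_id)
confusionMetrics(cad)
#> DiagnosticSummary (n=60: 16 pos / 44 neg)
#>   TP 16  FP 0  TN 44  FN 0
#>   Se 100.00%  Sp 100.00%  Acc 100.00%  AUC 1.000 (95% CI 1.000-1.000)
```

At `classEffect = 1` the phantom classes barely overlap, so the pooled
5-rotation test AUC is essentially 1 — a mechanical validation; at
`classEffect = 0` the same pipeline hovers at AUC ≈ 0.5. Shape features
recover the generating geometry: a 4-lobe phantom
(`lobulationOrder = 4, lobulationAmp = 0.3`) yields

```r
ph <- makePhantom(phantomSpec(imageSize = 96L, baseRadius = 20,
                              lobulationOrder = 4L, lobulationAmp = 0.3,
                              seed = 2L))
round(shapeFeatures(lesionMask(ph))[c("roundness", "leaflet_count",
                                      "spiculation", "elongation")], 3)
#>     roundness leaflet_count   spiculation    elongation
#>         0.629         4.000         0.108         1.000
```

Published diagnostic tables can be checked without the images behind
them. From a reader's printed sensitivity/specificity (82.93 / 84.15)
and class sizes 123/347:

```r
r <- reconstructCounts(82.93, 84.15, 123, 347)
c(tp = r$tp, tn = r$tn,
  accuracy = roundHalfUp(r$accuracy, 2), auc = roundHalfUp(r$auc, 3))
#>       tp       tn accuracy      auc
#>   102.000  292.000   83.830    0.835
```

i.e. the printed accuracy (83.83) and AUC (0.835) follow exactly from the
printed rates and class sizes.

## Command line

A thin CLI over the same functions ships in `inst/cli/pcr-cadkit.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pcr-cadkit.R", package = "pcrCAD"))')
Rscript $CLI run-all --config my.yaml --seed 4 --outdir run1
```

Subcommands: `generate`, `train-seg`, `segment`, `extract-features`,
`train-clf`, `predict`, `evaluate`, `report`, `run-all`. Every run writes
its resolved YAML config, a log with seed/config hash/stage timings, and
CSV outputs that are byte-identical on rerun with the same config.

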