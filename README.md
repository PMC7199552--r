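# tumorpatch

Automated detection and localization of multiple brain tumors — including
very small, early-stage ones — in single 2-D grayscale MRI slices.

Bright tumors a few pixels across are invisible to detectors tuned to the
native image resolution: any cleanup strong enough to remove noise also
removes noise-sized objects. `tumorpatch` implements a deterministic,
classical pipeline built around patch magnification:

1. **k-means intensity clustering** (k = 3) splits the slice into dark,
   medium (cerebrum) and bright (skull, possible tumors) regions;
   clustering quality is exposed as the within/between sums of squares
   SSW = Σᵢ (xᵢ − c₍ₖ₎)² and SSB = Σⱼ nⱼ (cⱼ − x̄)².
2. The **largest surrounding edge** (the skull outline) is extracted from
   the bright∪medium clusters, filled to measure the brain area *A*, and
   *A* is mapped to a Euclidean distance threshold through the reference
   anchors (5000 px → 5 px, 8000 px → 6 px, 100000 px → 25 px, linear in
   between).
3. A **modified image** — cerebral mask × (box-mean filtered slice ×
   49.99–50.01 % intensity window, re-stretched to 10–90 %) — concentrates
   the signal on bright tissue inside the cerebrum.
4. **Patch-based detection:** 200×200 patches upscaled 3×, binarized at
   thresholds {0.1, 0.3, 0.5, 0.7, 0.9, Otsu}, small objects removed,
   holes filled, binary images accumulated; candidates are extracted by
   object counting with incremental-disk erosion and seeded region
   growing, eliminating each detected object before re-counting.
5. **Shift voting:** the scan repeats at grid offsets of 0/50/100/150 px;
   pixels detected in ≥ 2 passes survive.
6. **False-tumor rejection:** candidates whose minimum Euclidean distance
   to the skull edge falls below the brain-size threshold are flagged as
   false tumors; everything is reported with centroid, bounding box, area,
   distance and accept/reject flag.

Pixel-level evaluation (precision, recall, specificity, Dice, accuracy)
and a seeded synthetic phantom generator with ground truth are included,
so the whole pipeline is testable without clinical data.

## Worked example

```r
library(tumorpatch)

ph <- default_suite(seed = 1)$mixed8          # phantom with 8 tumors
report <- detect_tumors(ph$image, pipeline_config(), keep_masks = TRUE)
report
#> Detection report: 8 candidate region(s), 8 accepted
#> Image shape: 512 x 512
#>   #1 centroid=(255.0, 149.0) area=421 dist_to_skull=42.00 ACCEPTED
#>   #2 centroid=(329.0, 189.0) area=764 dist_to_skull=57.45 ACCEPTED
#>   #3 centroid=(199.0, 189.0) area=137 dist_to_skull=75.13 ACCEPTED
#>   #4 centroid=(255.0, 255.0) area=1226 dist_to_skull=139.92 ACCEPTED
#>   #5 centroid=(158.9, 254.9) area=43 dist_to_skull=90.00 ACCEPTED
#>   #6 centroid=(339.0, 309.0) area=69 dist_to_skull=72.62 ACCEPTED
#>   #7 centroid=(199.0, 319.0) area=21 dist_to_skull=80.96 ACCEPTED
#>   #8 centroid=(255.0, 359.0) area=230 dist_to_skull=47.00 ACCEPTED

pred <- attr(report, "intermediates")$accepted_mask
compute_metrics(confusion(pred, ph$truth))
#> precision    1.0000
#> recall       0.9526
#> specificity  1.0000
#> dice         0.9757
#> accuracy     0.9994
```

All eight planted tumors (radii 3–20 px) are found and localized;
centroids and bounding boxes are 0-based (row, col). The `dist_to_skull`
column shows why each region survived the false-tumor rule: this brain
measures ~95 500 px, giving a 24.07-px rejection threshold, and every
accepted region clears it. On the decoys-only phantom (bright blobs
hugging the skull) the same configuration reports the candidates but
accepts none of them.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/tumorpatch.R phantom --seed 1 --suite-index 3 \
    --out slice.png --truth truth.png
Rscript inst/cli/tumorpatch.R detect slice.png --report report.json \
    --mask detected.png
Rscript inst/cli/tumorpatch.R eval --pred detected.png --truth truth.png
Rscript inst/cli/tumorpatch.R config --dump pipeline.yaml
```

Exit codes: 0 success, 2 no brain found, 3 I/O error, 4 config error.

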