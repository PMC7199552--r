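---
title: "Patch-based detection of multiple brain tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based detection of multiple brain tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorpatch)
```

## The problem

Bright, well-circumscribed tumors in a single 2-D brain MRI slice range
from large masses down to early-stage lesions a few pixels across. A
detector tuned to the native image resolution misses the small ones: any
cleaning step aggressive enough to remove noise also removes objects of
noise-like size. `tumorpatch` implements a classical, fully deterministic
pipeline that addresses this with patch-based magnification: the slice is
cut into 200×200 patches, each patch is upscaled three-fold, detection runs
at the working scale, and results are mapped back and combined across
shifted patch grids by per-pixel voting.

## Pipeline

Given a min–max normalized slice (all intensities in [0, 1]):

1. **Intensity clustering.** One-dimensional k-means with k = 3 splits the
   pixels into dark (background), medium (cerebrum) and bright (skull,
   possible tumors) clusters. Lloyd iteration is seeded deterministically
   at the (2j−1)/2k intensity quantiles, so no RNG is involved; an empty
   cluster is re-seeded at the pixel farthest from its current centroid,
   drawing only from clusters that keep at least one member (the naive
   farthest-pixel rule cycles forever on constant images). Clustering
   quality is exposed through the within- and between-cluster sums of
   squares (`ssw()`, `ssb()`); their sum equals the total sum of squares,
   which the tests verify to 1e−9, and the SSW trace is non-increasing
   across iterations.
2. **Skull edge.** The union of the bright and medium clusters is reduced
   to an outline by removing interior pixels (all four axial neighbors
   set); the largest 8-connected outline component is the *largest
   surrounding edge* — the skull. Unlike skull stripping, the edge is kept:
   filling its holes measures the brain area, and that area sets the
   Euclidean distance threshold used later to reject skull-adjacent "false
   tumors". The size→threshold curve is a piecewise-linear interpolation
   through its three reference anchor points (5 000 px → 5 px, 8 000 px →
   6 px, 100 000 px → 25 px), extrapolated linearly outside and floored at
   3 px. Only the anchors are citable; the curve between them is a
   declared modeling choice, not data.
3. **Cerebral mask and modified image.** The filled skull is eroded
   inward with the 3×3 cross kernel (10 iterations by default, about a
   10-px band) and that band is removed from the medium cluster; the
   largest remaining component, holes filled, is the cerebral mask. In
   parallel, the slice is box-mean filtered (3×3, reflected borders) and
   multiplied by a near-binarization of the *unfiltered* slice through the
   49.99–50.01 % intensity window — keeping only supra-mid-intensity
   pixels, i.e. candidate abnormal tissue — and re-stretched through the
   10–90 % window. The product of the cerebral mask with this focused
   image is the detection input: bright structures outside the cerebrum
   are zeroed, interior tumors survive.
4. **Per-patch detection.** Each patch (upscaled 3×, bilinear) is
   processed twice: raw, and contrast-boosted through the 30–70 % window.
   A pass zeroes intensities below 0.05, smooths with the 3×3 mean,
   binarizes at thresholds {0.1, 0.3, 0.5, 0.7, 0.9} plus the per-patch
   Otsu cut, removes objects below the minimum area, fills holes, and sums
   the binary images into an accumulation image. Candidates are then
   extracted iteratively: the component carrying the maximum accumulated
   vote (ties broken by area, then topmost-leftmost centroid) is eroded
   with growing Euclidean disks until a single object survives, a region
   is grown from that object's center (8-connected flood admitting pixels
   within 0.2 of the seed intensity), the region joins the candidate mask,
   and the detected object — the grown region together with its
   accumulation component — is eliminated before re-counting, up to 20
   candidates per pass.
5. **Shift voting.** The whole scan is repeated with the patch grid
   shifted by 0, 50, 100 and 150 columns; each shift contributes one vote
   per detected pixel, and pixels with at least 2 votes survive. This
   suppresses patch-boundary artifacts: an object cut by one grid is
   interior to another.
6. **False-tumor rejection.** Each surviving 8-connected region is scored
   by the minimum Euclidean distance from its pixels to the skull edge
   (exact distance transform); regions closer than the brain-size
   threshold are flagged as rejected, the rest accepted. Nothing is
   deleted — the report lists every candidate with its geometry, distance
   and flag, and carries the applied threshold so acceptance can be
   re-audited from the report alone.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 3 | clusters | dark / medium / bright partition |
| `kmeans_tol` | 1e−4 | intensity | centroid-shift stop rule |
| `edge_expand_iterations` | 10 | px | width of the inward skull band |
| `patch_size` | 200 | px | patch side at native scale |
| `scale` | 3 | × | patch magnification before detection |
| `shifts` | 0/50/100/150 | px | horizontal grid offsets |
| `min_votes` | 2 | votes | shifts that must agree |
| `thresholds` | 0.1–0.9 + Otsu | intensity | binarization ladder |
| `min_object_area` | 100 | working px | small-object cutoff |
| `grow_delta` | 0.2 | intensity | region-growing tolerance |
| `low_intensity_cutoff` | 0.05 | intensity | background elimination |

Two defaults deserve their rationale spelled out.

**`min_object_area = 100` (working-scale pixels).** The cutoff must
separate two populations at the working scale: blobs spawned by a single
supra-window noise pixel (about 30–50 px after 3× upscaling and
smoothing) and the smallest tumors the method targets (radius ≥ 2 px
native, ≥ ~117 px at 3×). Any value between those bands works; 100 sits
just under the smallest-tumor band. The same cutoff applied at native
scale (`scale = 1`) swallows tumors below roughly 6 px radius — which is
precisely the phenomenon that motivates upscaling patches in the first
place, and the test suite demonstrates it: the r = 3 phantom tumor is
found at 3× and lost at 1×.

**`original_image_pass = FALSE`.** The pipeline can additionally run the
scanning passes on the raw normalized slice and pool those votes. Enabled,
this degenerates on every test phantom: a region grown from a
medium-intensity seed floods the entire cerebrum, the cerebrum-wide
candidate 8-connects with every true detection, and the merged region is
rejected wholesale by the distance rule — zero accepted tumors. The
pooled vote range would also be 0–8, whereas the reference behavior of
the voting image is a 0–4 range, consistent with four passes over a
single image. The extra passes therefore stay available but off.

## Numerical and convention choices

- **Connectivity.** Foreground components are 8-connected; hole filling
  uses the dual 4-connected background reachable from the image border.
  The labeller is implemented in C++ (stack-based flood fill); the
  general-purpose morphological primitives (erosion, distance transform,
  Otsu, bilinear resize) come from EBImage. Erosion is wrapped to treat
  out-of-image pixels as background (EBImage's own convention is the
  opposite), so border-touching objects erode correctly.
- **Coordinates.** In R, matrices are indexed 1-based as usual; serialized
  reports use 0-based (row, col) with half-open bounding boxes, declared
  once in `detection_report()`.
- **Region-growing floor.** The flood's acceptance level is
  `seed − delta`, floored at the low-intensity cutoff. Without the floor a
  dim seed (level ≤ 0) floods the whole patch; with it, growth can never
  enter background.
- **Ties.** Maximum-vote component selection breaks ties by area, then by
  topmost-then-leftmost centroid; the k-means quantile initialization and
  the column-major labeller make every remaining choice deterministic, so
  `detect_tumors()` is bit-reproducible (asserted in the tests).
- **Degenerate inputs.** Constant images normalize to all zeros; a
  constant patch skips its Otsu threshold; an all-dark slice returns an
  empty report flagged `no_brain_found`/`no_cerebral_tissue` rather than
  an error; an open (leaking) skull edge fills to itself.
- **Mean filter.** 3×3 box mean with edge-reflected padding; the output
  is clipped back into the input range to absorb FFT round-off from the
  underlying convolution.

## The phantom generator

Clinical MRI slices with ground truth are not distributable with the
package, so every end-to-end test runs on seeded synthetic phantoms
(`phantom_spec()`, `make_phantom()`, `default_suite()`): a dark background
(0.02), a bright elliptical skull annulus (0.9, 8 px thick), a cerebral
interior at 0.40 with Gaussian noise (σ = 0.03, seeded Mersenne–Twister,
bit-reproducible), anti-aliased tumor disks (1-px coverage blending,
truth = ≥ 50 % coverage) and optional skull-adjacent decoys excluded from
the truth. The eight-phantom battery covers: a large tumor, a tiny (r = 3)
tumor, eight mixed sizes and intensities, tumors just beyond the distance
threshold, decoys only, an empty brain, low-contrast tumors (0.55), and a
tumor straddling a patch boundary.

What the phantoms do *not* emulate: Rician noise statistics, bias fields,
partial-volume texture, anatomical heterogeneity of real cerebral tissue,
or irregular tumor shapes. Passing the suite therefore shows the pipeline
implements its specification and behaves correctly on geometrically
faithful inputs; it does not certify clinical performance. One consequence
worth knowing: low-contrast tumors (0.55 on a 0.40 cerebrum) cluster with
the *medium* k-means class, not the bright one — they are recovered by
the 50 % narrow window, not by clustering, and the tests pin down both
facts.

## Problem sizes in the tests

Unit tests run on 10–120 px toy arrays with independent oracles
(breadth-first-search component counting, brute-force pairwise distances,
exhaustive 1-D two-means partitions, an exhaustive 256-bin Otsu scan).
End-to-end tests use the 512×512 phantom battery with the default
configuration, and a 256×256 phantom with 100-px patches at 2× for the
fast pipeline checks.

## Known limitations

- Single 2-D slices only; no volumetric context, no DICOM ingestion, no
  bias-field correction.
- The method presumes tumors are bright relative to cerebrum; hypointense
  lesions are out of scope.
- The size→threshold mapping between the reference anchors is linear by
  declaration; other monotone curves through the same anchors are equally
  compatible with the available evidence.
- Brain coverage is approximated by the filled skull outline; an open
  skull contour (e.g. a cropped slice) degrades both the brain-size
  estimate and the rejection threshold.

## Worked example

```{r example, eval = FALSE}
library(tumorpatch)

ph <- default_suite(seed = 1)$mixed8       # 8 tumors, known truth
report <- detect_tumors(ph$image, pipeline_config(), keep_masks = TRUE)
report

pred <- attr(report, "intermediates")$accepted_mask
compute_metrics(confusion(pred, ph$truth))
```
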