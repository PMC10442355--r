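---
title: "Screening histology for perineural invasion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening histology for perineural invasion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pniscreen)
```

## The problem and the screening strategy

Perineural invasion (PNI) — tumor cells around or within a nerve — is a
prognostic factor in pancreatic ductal adenocarcinoma that is laborious to
assess: a single small invaded nerve among dozens of slides flips the
patient's PNI status, so every slide must be combed. The screening strategy
implemented here mimics how a pathologist actually works. Rather than
training a detector on scarce examples of the composite event "PNI", the two
constituent entities — **nerve** and **tumor** — are detected independently,
and suspicion is then *reasoned about spatially*: wherever detected nerve and
detected tumor come close, a candidate field is cut out and shown to a
pathologist, who makes the diagnostic call. The pipeline never diagnoses; it
ranks and presents. That division of labor is what lets a small training
cohort suffice.

The chain is:

1. **Segment** each slide into per-class confidence maps for tumor and nerve
   (channels are independent detectors, not a softmax partition, because the
   two classes are thresholded and evaluated separately downstream).
2. **Post-process** each class at a confidence threshold (operating default
   0.5; a pixel scores 1 at or above the threshold, 0 below), label connected
   components, and discard foci smaller than 10,000 pixels — small spurious
   foci dominate false alarms, and structures of diagnostic interest at this
   resolution are much larger.
3. **Rank** all (nerve component, tumor component) pairs of a case by exact
   minimum pixel distance; crop a presentation field around each closest
   pair, suppress near-duplicate windows, and present the top 40 fields (20
   for cases where only tumor-bearing slides were scanned).
4. **Review**: the pathologist confirms or rejects each field; any confirmed
   field makes the case PNI-positive. In this package the reviewer is
   simulated against ground truth (below).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold` | 0.5 | confidence | pixel score cutoff per class |
| `min_area` | 10,000 | pixels | small-focus filter, applied per class to predictions |
| `connectivity` | 8 | — | component adjacency |
| `max_distance` | 100 | pixels | pairs farther apart are never candidates |
| `k` / `k_tumor_only` | 40 / 20 | fields | presentation budget per case |
| `field_size` | 512 | pixels | presentation window side |
| `overlap_iou` | 0.5 | IoU | near-duplicate window suppression |
| `contact_distance` | 2 | pixels | rasterized abutment (adjacent pixel centers are 1 or √2 apart) |
| `encirclement_min` | 0.33 | fraction | invasion criterion for intratumoral nerves |
| `encirclement_epsilon` | 3 | pixels | boundary-to-tumor distance counting as abutted |

The size filter is applied to **both** classes by default. The textual
motivation for the filter concerns spurious tumor foci, but the figure-level
description applies it to all labels and the nerve false-alarm rate drops
sharply under it; both per-class cutoffs are therefore independently
configurable. `max_distance = 100` px operationalizes "close proximity",
which is never quantified in the clinical workflow; it only bounds which
pairs can be presented, not how they are ordered, so its exact value mostly
affects compute. Distances are between pixel centers (contact or overlap is
distance 0/1), since nothing finer than "smallest distances" is specified
anywhere.

Ranking ties (equal distance) are broken by descending combined component
area, then by slide and window position. The tie rule is an invention of this
package, chosen so that ranking is a deterministic function of the candidate
*set* — any input permutation yields the same presentation order.

## Evaluation metrics

Three curves are computed per class against the confidence threshold:
intersection-over-union, detection rate, and false-alarm rate. The
figure-caption phrases these derive from ("percentage of overlap", "percentage
detected", "percentage falsely identified") do not pin down whether the
quantities are pixel-level or object-level, nor the normalizer of the
false-alarm rate. Both readings are therefore always computed and reported
side by side, with `mode` recorded in every output row:

* **pixel**: IOU = |P∩G|/|P∪G|; detection = |P∩G|/|G| (recall); false alarm
  = |P\\G|/|P| (false-discovery fraction).
* **object**: detection = fraction of reference components with ≥ 50% of
  their pixels covered; false alarm = fraction of predicted components with
  < 50% of their pixels inside the reference; IOU = Jaccard of matched
  components.

Aggregation pools raw counts (or component verdicts) across the image set
before taking any ratio, so empty images contribute nothing rather than
undefined ratios. Empty-denominator conventions: IOU(∅,∅) = 1, detection with
empty reference = 1, false alarm with empty prediction = 0.

## The simulated reviewer

The reviewer consults ground truth, standing in for the pathologist's
knowledge of the tissue. A candidate is confirmed when

1. its predicted nerve and tumor components each overlap a *true* component
   of their class (a benign gland misread as tumor therefore never confirms a
   candidate — benign glands do not sit hard against nerves, which is exactly
   why their misclassification is tolerable in this design); and
2. the true spatial relationship satisfies the accepted diagnostic
   convention: tumor abutting the nerve *outside the main tumor body* is PNI,
   while a nerve *inside* the tumor body must be encircled over at least a
   third of its circumference to count as invasion rather than focal
   abutment.

"Inside the main tumor body" has no operational definition in the clinical
literature the rule comes from. This package calls a nerve intratumoral when
**at least half of its pixels lie inside the filled convex hull of the tumor
component**. An earlier centroid-in-hull variant was rejected during
development: the centroid of a long wavy nerve frequently falls inside the
hull of a tumor cluster that merely abuts it tangentially, which misroutes
genuine contact events into the encirclement criterion (end-to-end zero-noise
sensitivity was 0.8 with the centroid rule and is 1.0 with the majority
rule). Encirclement itself is the fraction of the nerve component's boundary
pixels within `encirclement_epsilon` (3 px) of tumor; boundary pixels are
component pixels 8-adjacent to non-component pixels or the raster edge.

## Clinical comparison statistics

Study-level positivity under the original pathology report versus under the
algorithm-assisted read is compared with a **pooled two-proportion z-test
without continuity correction** (two-sided normal p; z² equals the Pearson
chi-square of the 2×2 table). This test was chosen because it reproduces the
published comparison p-value exactly from the published case counts, which a
McNemar-style paired test does not; the package documents it as its
comparison statistic without claiming the original analysis specified one.
Reading-time and image-number comparisons are served by a Mann–Whitney
rank-sum test (exact enumeration for n₁+n₂ ≤ 12 without ties, tie-corrected
normal approximation otherwise), provided as this package's comparison tool.

## The synthetic-data generator

No imaging data from the motivating study is deposited, so validation runs on
seeded synthetic tiles that emulate the *structural* features the pipeline
depends on, not histological appearance:

* eosin-pink background with multi-octave noise;
* nerves as smoothed random-walk ribbons (thickness 22–34 px by default) with
  internal fiber striping, or as round bundles when an encirclement event is
  planted (a nerve cut transversely);
* malignant glands as one irregular connected cluster of overlapping
  nucleus-dense disks;
* benign glands as regular rings kept ≥ 50 px from any nerve — the
  characteristic confounder that looks like tumor to a segmenter but never
  forms proximity candidates;
* planted PNI events with controlled nerve–tumor distance (±2 px verified at
  generation) and encirclement fraction (±0.1 verified), realized by placing
  the tumor cluster against the nerve (contact events) or by carving a
  partially-gapped tumor collar around an intratumoral nerve bundle
  (encirclement events).

Default tiles are 512×512 px with no magnification semantics; all areas are
raw pixel counts. Nerve and tumor-cluster sizes default to ≥ 10,500 px so
that true structures survive the operational 10,000-px filter — the
generator models the regime the filter was designed for (large true
structures, small spurious foci). On small demonstration tiles
`min_component_area` must be lowered accordingly. Cases draw their slide
counts from rounded normals truncated at 1 — mean 27, sd 9.4 for fully
scanned cases and mean 6.1, sd 1.8 for tumor-only cases — and a study of
`n` cases at prevalence `p` contains `round(n·p)` positive cases, each with
its planted events on uniformly chosen slides. Every generator is a pure
function of its seed; one top-level seed fans out to named substreams per
case and slide.

What the synthetic tiles deliberately do **not** model: stain variability,
texture that would challenge a real segmenter, tissue deformation, scanner
artifacts, or whole-slide pyramids ("slides" are single-resolution tiles).
Passing end-to-end tests therefore demonstrates correctness of the
*screening logic* — post-processing, exact distance geometry, ranking,
review rules, statistics — not clinical segmentation performance.

The **oracle-noise segmenter** is the bridge between the two: it corrupts
ground truth with exactly the error modes observed operationally — whole
components missed at a set rate, spurious small foci at a Poisson rate per
tile per class, boundary jitter, graded confidences — so pipeline behavior
under controlled degradation can be measured without any trained model in
the loop.

### A sensitivity ceiling worth knowing about

With per-component miss probability *m*, a planted contact event survives
segmentation only if both its nerve and its tumor component are kept, so
case-level sensitivity for single-event cases is bounded in expectation by
*(1−m)²* — at *m* = 0.1 that is **0.81**, not 0.9. Multi-slide, multi-event
cases are progressively immune to this (any surviving event rescues the
case), which matches the clinical observation that PNI-rich cases are easy
and sparse-PNI cases are the hard ones. The end-to-end tests assert perfect
recovery at zero noise and report measured sensitivity/specificity under
noise.

## The trainable segmenter

The trainable route is a compact pixel-level classifier: two independent
binomial logistic regressions (tumor-vs-rest, nerve-vs-rest) on local colour
and texture features — raw RGB, box means at radii 2 and 6 px, and a local
luminance standard deviation at radius 4 px — fitted on a stratified pixel
sample per tile, with benign glands trained as background (unmarked tissue is
negative for both classes). On the synthetic tiles, whose classes are
colour/texture separable by construction, it exceeds held-out pixel IOU 0.5
per class from 32 training tiles within seconds on one CPU. It exists to
exercise the train/predict surface and the augmentation contract
(flips, right-angle rotations, brightness/hue jitter, geometric transforms
applied identically to tile and mask); by design the *oracle-noise*
segmenter, not the trained one, feeds every acceptance-path computation, so
no test outcome depends on a model fit.

## Numerical and degenerate-input choices

* Thresholding uses ≥, so `binarize(map, class, 0)` selects every pixel and a
  pixel at exactly the operating threshold is positive.
* Connected components are labeled in row-major raster order of their first
  pixel — labelings are reproducible across runs and platforms.
* Component distances use a per-component exact Euclidean distance transform
  (integer-squared arithmetic, lower-envelope algorithm) sampled at the other
  class's pixels; results are bit-identical to brute-force pairwise minima,
  which the test suite asserts on hundreds of random rasters.
* Empty masks, empty candidate sets, empty studies and all-tied rank-sum
  samples all return defined values (see module documentation) rather than
  erroring.
* Problem sizes in the shipped tests and acceptance script — 128–512 px
  tiles, 30-case studies, 200-raster oracle sweeps — were chosen as the
  smallest sizes at which every contract under test is exercised at the
  operational parameter values (notably the 10,000-px filter, which needs
  full-size tiles).

## Known limitations

* The synthetic appearance model is structural, not photorealistic; no claim
  transfers to real H&E segmentation accuracy.
* The simulated reviewer is noiseless and fully informed; inter-observer
  variability is out of scope.
* Published analytical-performance curve values are not reproducible without
  the original slides and trained weights; the evaluation module reproduces
  the *metrics*, verified against brute-force oracles, not the numbers.
* Intraneural (endoneural) invasion subtyping and vascular invasion are not
  modeled.
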