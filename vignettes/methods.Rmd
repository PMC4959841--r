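---
title: "Methods: unsupervised tracing of peroxidase-labeled processes in serial-section EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised tracing of peroxidase-labeled processes in serial-section EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Genetically encoded peroxidases (APEX2, APX, ER-targeted HRP) catalyse a
DAB polymer that binds osmium, so labeled neurons appear strongly
electron-dense — dark — against textured neuropil in scanning EM of serial
sections. `emtracer` exploits this single, strong photometric cue. It makes
three assumptions about its input:

1. **Polarity.** Labeled structures are low-intensity. Every foreground
   criterion in the package is a *closed lower set* `{v ≤ τ′}`.
2. **Bimodality per section.** Each section's intensity histogram carries
   enough dark labeled mass to separate from the background by a two-class
   variance criterion. This is the regime the method is designed for;
   unlabeled or near-empty sections fall back gracefully (see "Degenerate
   inputs").
3. **Geometric continuity.** A labeled process changes position and size
   slowly from section to section, so cross-sections on neighbouring
   sections are mutually nearest neighbours in the image plane, and an
   abrupt, very large object interrupting an otherwise smooth progression
   is an imaging artifact.

No membrane model, no training data and no supervision are involved; the
only tunable quantities are the thresholds and bounds listed below.

## Pipeline stages

**Thresholding.** `cluster_threshold()` maximizes the between-class
variance over 256 candidate bin edges on [0, 1] (Otsu's criterion),
breaking ties toward the lowest candidate — the conservative choice, since
a lower threshold means a smaller dark foreground. The threshold is then
*modulated* toward the marker's known contrast-enhanced range
(`modulate_threshold()`): `τ′ = 0.82 τ` when `τ < 0.6` (strict), else
`τ′ = 0.86 τ`. Both factors are ≤ 1, so modulation only tightens the
foreground criterion. The boundary `τ = 0.6` takes the high factor because
the printed comparison is strict. `equalize_histogram()` (cumulative-
histogram mapping, monotone, idempotent up to one bin width) is available
for acquisitions whose brightness drifts across sections; the pipeline
applies it only when `threshold.equalize` is set, because equalization
rank-uniformizes any continuous histogram — on sections whose labeled
fraction is small, the two-class optimum of a uniformized histogram sits
mid-background rather than in the label/background valley, which floods the
mask. Sections generated or already normalized on a common intensity scale
(the phantom, a calibrated acquisition) should not be equalized.

**2D segmentation.** Connected components of the binary mask use
8-connectivity, so thin diagonal neurites do not fragment. Geometry follows
the moment conventions stated on each function: 0-based pixel-center
coordinates, half-open bounding boxes, and a major axis of
`4·sqrt(λ_max)` of the raw pixel-coordinate covariance (normalized by n, no
+1/12 discrete-pixel correction) — the convention under which the 900 px
bound is applied. A 5×5 filled square therefore has major axis
`4√2 ≈ 5.657`.

**Filtering and pruning.** `filter_segments()` applies the strict bounds
`3 px < area < 130000 px` and `major axis < 900 px`: area 3 and area
130000 are both removed. `prune_artifacts()` concretizes "irregularly
large artifacts between adjacent segments" as an area-progression test: a
segment is flagged when it has candidate neighbours (within the linking
radius) on adjacent sections both above and below *and* its area exceeds
`prune_area_ratio` (default 10) times the median neighbour area. Segments
with neighbours on only one side are never flagged — their progression
cannot be assessed. Flagged segments are retained with a reason code, never
deleted, so pruning is auditable.

**Linking.** Candidate pairs live within `radius_nm` (default 2000 nm,
several dendrite diameters — fine SAC dendrites are under 100 nm across) at
z-offsets 1…`max_gap_sections` (default 3). Distances are *in-plane
physical* distances (pixel pitch × pixel offset): with 30–270 nm section
spacing, a z term would swamp in-plane proximity, and the z-offset is
constrained separately. Each segment links to its `k = 2` nearest
candidates *pooled across all allowed z-offsets*: a continuing process
fills its own two slots with its next cross-sections before a neighbouring
process can compete, while a true bifurcation can claim both slots on one
section. Ties break toward the smaller label for determinism. The search
runs upward only; edges are undirected. `bridge_gaps()` re-runs the same
rule and adds only z-gap ≥ 2 edges — a separately testable pass that
reconnects processes across dropped or subsampled sections.

**Merging.** 3D components are connected components of the link graph
(union-find). A final consistency pass merges two components that own
same-section segments whose *bounding boxes* overlap by at least 50% of
the smaller box — duplicate detections of one structure. Bounding boxes are
the overlap currency because the durable segment store keeps geometric
summaries, not pixel masks (segments from a single labeling pass are
pixel-disjoint by construction, so pixel overlap would be identically
zero). Component numbering is deterministic: descending total area, ties by
smallest member label.

## The phantom: what it emulates, and what it does not

`phantom_spec()` defaults define the study conditions used by the test
suite and the acceptance script: 100 sections of 512×512 px at 20 nm/px
with 30 nm spacing (the overview-imaging regime), 10 labeled tubes of
radius 8 ± 1 px, stained intensity 0.15 ± 0.03 against background
0.65 ± 0.02 with texture correlation length 32 px, per-pixel noise sd
0.025, per-section alignment jitter ±2 px, and 5 giant dark distractor
blobs (radius clamped to 205–250 px) emulating erythrocytes and staining
artifacts.

Two defaults are *designed*, not arbitrary:

* **Separability.** A two-class variance criterion prefers the
  label/background valley over a mid-background split when the dark pixel
  mass satisfies `f·Δμ² > 0.64·σ_bg²` (the right side is the between-class
  variance of splitting a Gaussian background at its mean, where
  `E|X−μ| = σ√(2/π)` gives half-means `∓σ√(2/π)` and hence
  `0.25·(2·1.6σ/2)²·4 ≈ 0.64σ²`). The defaults give
  `f ≈ 0.0077`, `Δμ = 0.5`, so `f·Δμ² ≈ 1.9×10⁻³` against
  `0.64σ_bg² ≈ 0.8×10⁻³` with `σ_bg ≈ 0.032` — a ~2.4× margin. Phantoms
  with much sparser or much noisier content leave the regime the method
  assumes, and segmentation degrades exactly as it would on weakly labeled
  tissue.
* **Mutual separation.** Tube centerlines are correlated random walks
  (per-step heading perturbation capped at π/3, step 0.5 px — a tube cannot
  double back within one section) confined to a ±12 px corridor around
  grid-seeded start points ≥ 150 px apart. Inter-tube distance therefore
  always exceeds the 2000 nm default link radius, emulating a sparsely
  labeled, well-separated plexus — the regime in which unambiguous
  automatic linking is possible at overview resolution. Densely fasciculating
  dendrites (which do occur in real SAC plexus data) are *not* emulated,
  and passing phantom tests says nothing about resolving such contacts.

Distractors are drawn darker than the processes and larger than the
130 000 px area bound, so filter efficacy is exercised: the blob (merged
with any tube it covers) is discarded, the affected tube loses one 2D
cross-section, and gap bridging restores 3D continuity. These blobs are the
dominant cause of the few percent of missed 2D truth segments at the
default conditions. Note that distractor pixels count as *background* in
`phantom_cnr()`, which is why the pooled phantom CNR (~4.4) sits below the
value the class means alone would suggest.

Further non-goals: no membranes, organelles or synapses are rendered; noise
is Gaussian and stationary (no charging, no focus drift); jitter is a rigid
integer translation, standing in for residual alignment error. Section
dropout removes images but keeps z-indexing — a gap, not a renumbering —
mirroring every-10th-section overview subsampling.

## Parameters

| group | parameter | default | unit | meaning |
|---|---|---|---|---|
| threshold | `cutoff` | 0.6 | intensity | modulation branch point (strict `<`) |
| threshold | `factor_low` / `factor_high` | 0.82 / 0.86 | — | modulation factors below / at-or-above cutoff |
| threshold | `n_bins` | 256 | — | histogram resolution for equalization and Otsu search |
| filter | `min_area_px` / `max_area_px` | 3 / 130000 | px | exclusive area bounds |
| filter | `max_major_axis_px` | 900 | px | exclusive moment-ellipse bound |
| filter | `prune_area_ratio` | 10 | — | artifact pruning area multiple |
| link | `k` | 2 | — | nearest candidates per segment (supports branching) |
| link | `radius_nm` | 2000 | nm | in-plane candidate radius |
| link | `max_gap_sections` | 3 | sections | maximum link z-offset |
| eval | `min_overlap` | 0.5 | fraction | single-segment coverage of a truth segment's area (closed bound) |

The evaluation is recall-oriented, as befits a screening stage whose
purpose is not to miss labeled material; precision is reported for
diagnostics but carries no acceptance weight. Missed-segment size is
summarised as mean bounding-box height × width.

## Numerical choices and degenerate inputs

* Otsu ties break to the lowest threshold; a consequence worth knowing is
  that on *noise-free* synthetic images the histogram gap between label and
  background is empty, every gap threshold ties, and the chosen τ hugs the
  label's upper edge — downward modulation can then exclude the label
  entirely. Any realistic noise level removes the ties. Geometric
  properties on noise-free phantoms are therefore tested by binarizing at a
  stated mid-gap threshold.
* A constant section raises a "degenerate histogram" error from
  `cluster_threshold()`; the pipeline catches it and applies the fixed
  fallback `τ′ = cutoff · factor_low`.
* A pixel exactly at τ′ is foreground; a truth segment covered exactly at
  `min_overlap` is matched; a segment with area exactly 3 or 130000 px is
  removed. All boundary conventions are fixed, documented on the function,
  and tested.
* Zero-spread CNR: equal means give 0, unequal means give signed infinity.
* Labels are consecutive positive integers in (z-index, discovery-order),
  with discovery order the column-major scan order of the component's
  first pixel; all orderings that feed numbering are total, so every
  output is a pure function of (input, parameters, seed).

## Problem sizes

The test suite and acceptance script run the full pipeline on the default
100-section 512×512 phantom (about 1000 truth segments) for seeds 1–5 plus
an every-10th-section-removed variant — roughly two minutes per suite on a
single CPU. Unit tests use an 8-section 160×160 phantom. Sizes are chosen
so each property is exercised at the default study conditions while the
whole suite stays fast enough to run habitually.

## Known limitations

* Touching or fasciculating labeled processes merge: there is no
  boundary-evidence splitting, by design (the method's contrast assumption
  replaces membrane classification).
* The consistency merge measures bounding-box, not pixel, overlap; highly
  concave duplicate detections could in principle evade or overshoot it.
* The pruning rule is a concrete area-ratio test standing in for the
  broader idea of "expected morphological progression"; processes whose
  true cross-section area legitimately varies tenfold between adjacent
  sections would be falsely flagged (they remain in the store, flagged,
  and can be restored by raising `prune_area_ratio`).
* Thresholding is global per section; slow intensity gradients *within* a
  section are not modeled. For such data an adaptive scheme would be
  needed, which is out of scope here.
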