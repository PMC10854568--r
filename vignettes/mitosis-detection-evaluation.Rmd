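---
title: "Evaluating mitosis detection: agreement, patches, thresholds, and review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating mitosis detection: agreement, patches, thresholds, and review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoseval)
```

## The problem

Mitotic count over a standard area (ten high-powered fields, ~2 mm²) is a
grading criterion for canine Soft Tissue Sarcoma, and in particular for the
Perivascular Wall Tumour subtype this package targets. Counting is
laborious and shows substantial inter-observer variability, which motivates
automated detection — but an automated detector is only as good as the
evaluation pipeline around it: how ground truth is built from imperfect
expert annotations, how slides become patches, how scored boxes are matched
to ground truth, and how an operating point is chosen. `mitoseval`
implements that evaluation pipeline end to end, with a synthetic-data
generator standing in for the scanner, the pathologists and the trained
detector.

## Ground truth from dual annotation

Each pathologist marks a suspected mitosis with a single centroid — a weak
annotation with no delineated boundary. A mitosis enters the ground truth
only when both annotators agree.

Two choices here were genuinely open, because point "overlay" is not a
quantitative criterion:

* **Agreement radius.** Two centroids agree when their Euclidean distance
  is at most `radius_px`, default 25 px at level 0 (≈ 5.75 µm at
  0.23 µm/px) — roughly half a mitotic-figure diameter, so two marks on the
  same figure agree while marks on adjacent figures do not. It is a
  configurable parameter of `match_annotator_centroids()`.
* **Pairing rule.** Pairs are committed greedily in ascending distance
  order (ties: lower index in the first list, then the second), giving a
  deterministic one-to-one pairing. On instances where at most two
  candidates compete per point the greedy pairing is maximum-cardinality;
  the test suite checks this against an exhaustive matcher on small random
  instances. A Hungarian-style optimal assignment would differ only on
  contrived geometries and would be harder to reason about.
* **Consensus position.** The agreed mitosis is placed at the midpoint of
  the paired centroids, the symmetric choice.

Per-slide agreement percentages are `100 · n_agreed / n_anno_i`, rounded
half **up** to two decimals (base R's banker's rounding would disagree with
conventionally formatted tables), and the per-annotator averages are
unweighted means over slides. Slides where an annotator marked nothing have
an undefined percentage; it is reported as `NA` and excluded from the
average rather than treated as zero.

Agreed centroids become square ground-truth boxes (default 32 px at level 1,
the one box size the source material fixes) centred on the level-rescaled
centroid and clipped to the slide.

## Patches and the hold-out geometry

Tissue masks are built at a factor-32 downsample. How the original masks
were produced is unstated, so the package uses the standard recipe: Otsu
threshold on inverted luminance (tissue is darker than glass), a 3×3
morphological closing, and removal of connected components under 10 mask
pixels (EBImage provides all three primitives). A constant thumbnail admits
no Otsu split and is classified wholesale by a mid-gray cutoff, with a
warning.

Patch extraction tiles the slide with non-overlapping 512×512 patches
anchored at (0,0); partial edge tiles are dropped. A patch is kept iff its
tissue fraction is **at least** 0.75 — the dismissal rule is "less than
75%", so exactly 75% stays. The fraction is computed over the factor-32
mask cells covering the patch footprint (whether the original computation
used mask or full resolution is unstated; the mask is the cheaper and, at
factor 32 under a 512 patch, near-identical choice). Training/validation
keep only patches containing at least one ground-truth mitosis; testing
evaluates every patch.

The test set is one 4096 × 2560 region at 20× per slide — ten contiguous
HPFs — which tiles row-major into exactly 40 patches; 11 slides would give
440. Ground-truth boxes attach to the unique patch containing their centre
(half-open tiles, so a centre exactly on a shared edge goes to the
higher-index tile); a box straddling a boundary is clipped to its owning
patch.

## Matching, metrics, and the threshold sweep

Detections are first reduced by greedy NMS: keep the highest-scoring
remaining box, discard remaining boxes with IoU strictly above 0.1 against
it, repeat. Then score-ordered greedy matching: each detection (descending
score, ties by input order) takes the unmatched ground-truth box of highest
IoU provided IoU ≥ 0.5; otherwise it is a false positive, and leftover
ground truth is false negatives. Counts are summed over all patches of a
split *before* computing sensitivity, precision and F1 (a global
micro-average; per-patch F1 values are never averaged). Ratios with zero
denominators are defined as 0 so degenerate splits stay well-defined.

The operating point is chosen on the validation split by sweeping
t = 0.01 … 1.00 in steps of 0.01 (the step is our choice; the reported
thresholds all lie on this grid), keeping detections with score ≥ t
(boundary our choice), rematching from scratch at each t, and taking
`T = argmax F1(t)`. Ties go to the **largest** maximizing t: the point of
thresholding is false-positive reduction, so among equal optima we keep the
fewest detections. Rematching per threshold rather than filtering a fixed
match set is equivalent for greedy matching when scores are distinct; a
test asserts that sweeping only the exact score values reproduces the
100-point grid's optimum. The pipeline order is NMS → threshold → match;
the relative order of NMS and thresholding is not fixed by the source
description, and this order means the review stage (which needs
unthresholded matches) and the thresholded evaluation share one NMS pass.

Report tables round metrics half-up to 3 decimals (full precision is kept
internally), and mean rows average the *rounded* per-fold values — the
convention under which the published summary means reproduce exactly.

## The review cycle

Every false positive from the unthresholded evaluation — deliberately
including arbitrarily low-scoring ones — is exported for expert review,
deduplicated across folds by same-slide IoU > 0.5 identity. Decisions are
consensus-only: conflicting reviewer verdicts raise an error listing the
candidates, mirroring the two-annotator agreement ethos of the initial
annotation (majority voting would silently manufacture ground truth).
Accepted candidates are appended verbatim as ground-truth boxes — they are
not re-centred, since no re-annotation step is described. The updated
dataset version records provenance and is idempotent under re-application;
`dataset_diff()` reports additions per slide and warns on removals, which
the workflow should never produce.

## What the generator emulates — and what it does not

`simulate_slide()` renders, directly at the factor-32 scale, one or more
elliptical tissue regions with low-order harmonic boundary noise, tissue
darker than glass with mild Gaussian texture, and true mitosis centroids
placed uniformly over tissue. No full-resolution WSI is ever synthesized:
nothing downstream needs one. `simulate_annotators()` marks each true
mitosis with per-annotator probability, applies isotropic Gaussian jitter,
and adds Poisson-distributed false marks uniformly in tissue.
`simulate_detections()` turns ground truth into jittered true-positive
boxes with probability `sensitivity` and adds Poisson false positives per
patch, placed at least one box-diagonal from any true centroid so that
every simulated false positive really is false under IoU-0.5 matching —
which makes the simulation's confusion counts exact and the refinement
tests sharp.

Score distributions default to Beta(8, 2) for true positives (mean 0.8) and
Beta(2, 8) for false positives (mean 0.2), with detector sensitivity 0.9
and 3 false positives per patch. No distributional description of the real
detector's scores exists, so these are a stand-in, chosen once and exposed
as configuration. `expected_f1_threshold_oracle()` computes the operating
point implied by those distributions in closed form (Beta survival
functions on the same grid, same tie-break), and the test suite requires
the empirical pipeline to recover it within ±0.05 in at least 9 of 10
seeds at 600 ground-truth boxes and 600 expected false positives.

The generator does **not** emulate: H&E texture or mitotic-figure
morphology (masking is exercised on intensity contrast only), non-mitotic
nuclei or other hard-negative structure (so simulated score distributions
are cleaner than a real detector's), scanner artefacts, or spatial
clustering of mitoses (placement is uniform). Passing tests therefore
demonstrate that the *evaluation machinery* is correct and self-consistent,
not that any particular detector performs well on real cPWT tissue.

## Problem sizes and determinism

The analysis cohort is six training/validation slides (three validation
folds, assigned round-robin at the slide level) and three hold-out test
slides, each 55,000 × 36,000 px at level 0 with 45–400 true mitoses —
about a quarter of the linear extent of a typical scanned specimen, chosen
so the full workflow runs in about a minute on one CPU while keeping
hundreds of ground-truth objects per fold. Every simulation entry point
takes an explicit seed and uses a single RNG stream internally (saving and
restoring the caller's RNG state), so identical configurations are
byte-identical: the pipeline's metric reports reproduce exactly under a
fixed seed.

## Known limitations

* Greedy (not optimal) matching everywhere; differences from optimal
  assignment arise only when detections contend for crowded ground truth.
* Two annotators exactly; the agreement machinery does not generalise to
  panels.
* The threshold grid is fixed at step 0.01; finer operating points are not
  searched (and could not be validated against the published thresholds).
* Tissue masking is intensity-based; heavily stained artefacts on glass
  would be masked as tissue.
* The review simulation adjudicates candidates against the generator's
  truth, a best-case reviewer; real expert review brings its own
  variability, which is out of scope here.
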