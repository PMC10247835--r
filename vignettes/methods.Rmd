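---
title: "Predicting rotational atherectomy debulking from pre-procedural imaging: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting rotational atherectomy debulking from pre-procedural imaging: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotadebulk)
```

## The problem

Rotational atherectomy (RA) debulks severely calcified coronary plaque with a
diamond-coated burr advanced over a dedicated guidewire. Because the burr
follows the wire, an intravascular imaging pullback acquired before the run
should, in principle, predict where and how much tissue will be removed: draw
a circle of the burr's diameter on each pre-RA cross-section and intersect it
with the vessel wall. Two candidate centers for that circle exist on the
image — the imaging catheter and the guidewire — and they disagree exactly
when the catheter and wire are not in contact.

`rotadebulk` implements this prediction geometry and its evaluation as a
reusable pipeline:

* **Per frame** (one cross-section, 1 mm spacing): the predicted ablation
  area *P* (burr-sized circle at the catheter or wire center, clipped to the
  wall), the actual ablation area *A* (post-RA lumen minus the registered
  pre-RA lumen), their overlap *O*, the angular extents of all three about
  the pre-RA lumen centroid, and the scores
  %Correct = 100·O/P and %Error = 100·(A−O)/A for both areas and angles.
* **Per lesion**: P-, A-, O-volumes by summing areas over the 1-mm frame
  stack, with volume-level %Correct/%Error.
* **Per cohort**: a median split of the analyzable frames into four
  prediction-quality groups (good / over / insufficient / irrelevant),
  cross-tabulation of post-RA findings (deep vessel injury, intimal flap)
  against the groups, a univariable p < 0.15 screen feeding a multivariable
  logistic regression with odds ratios per 0.1 mm of device clearance, an
  ROC cutoff of the catheter–wire clearance for irrelevant ablation, and
  contact-stratified Mann–Whitney comparisons of the catheter-based versus
  wire-based prediction mode.

The clinical images such methods are developed on are not publicly
shareable, so the package ships a seeded synthetic cross-section generator
with exact ground truth; every claim the package makes about itself is
validated on that generator against independent oracles.

## Geometry

Frames live in mm, Cartesian, y-up coordinates; polar angles are degrees
counter-clockwise from +x. Contours are simple polygons (counter-clockwise,
implicit closure); regions produced by clipping may have several components
and holes. Boolean operations use the Clipper engine (the `polyclip`
package); areas are signed-shoelace sums over the result rings.

Choices that were genuinely open:

* **Circle polygonization.** Device circles become inscribed regular
  n-gons, n = 360 by default, understating the disc area by
  `1 - (n/2π)·sin(2π/n)` < 0.02%. n is configurable everywhere.
* **Angle center.** The angular extents of *P*, *A* and *O* are all
  measured about the **pre**-RA lumen centroid. The source method says
  "lumen center" without fixing pre or post; using the pre centroid keeps
  the predicted angle computable before the run and puts all three angles
  in one frame of reference.
* **Angular extent of a region.** For a region not containing the center,
  the subtended angle set equals the union over boundary edges of the short
  arcs between the edge endpoint angles; the package computes that union
  exactly (wrap-around at 0/360 merged). Disconnected components therefore
  contribute the union of their intervals, not their spanning arc — the
  conservative reading of "angle of the area". Asking for the extent of a
  region that contains the center is an error, not 360°.
* **Actual ablation.** *A* is post-lumen minus pre-lumen. Any pre-lumen
  area outside the post lumen (apparent lumen loss, e.g. prolapse or
  registration imperfection) is excluded from *A* and surfaced per frame as
  `lumen_loss_area`, because "ablated" means removed tissue.
* **Clearances.** Device clearances are edge-to-edge: discs are solid
  (overlapping devices have clearance 0), the lumen contour is a boundary
  curve (a device inside the lumen has a positive gap to the intima).
  Clearances at or below `contact_threshold` (default 1 nm) are reported
  as exact 0, and contact is defined as zero catheter–wire clearance,
  matching the "> 0.0 mm" cutoff convention.
* **Lumen diameters.** Chords through the lumen centroid at 1° steps over
  0–179°; a re-entrant chord (non-convex contour) contributes its total
  in-lumen length and is counted in `n_reentrant`.
* **Sliver filtering.** Clipping shapes that share boundary stretches
  (post = pre ∪ notch is the canonical case) can emit hairline rings of
  area below 1e-8 mm² but wide angular footprint; these are dropped from
  region results.

## Per-frame scoring and exclusions

%Correct area = 100·O/P, %Error area = 100·(A−O)/A, with angle analogues.
Frames whose P-area or A-area falls below `epsilon_area` (default
0.001 mm²) are flagged `excluded` with a reason, and their percentage
fields are `NA` — they are reported, never silently dropped, and an
exclusion caused by A ≈ 0 is by construction mode-independent. Calcification
is typed nodular (annotation takes precedence), circumferential (union arc
coverage ≥ 270°), or eccentric; the boundary case of exactly 270° counts as
circumferential. The burr/lumen ratio divides the burr diameter by the
frame's mean lumen diameter.

Lesion volumes are area sums times the frame spacing over included frames
(the 1-mm analogue of a rectangle rule). Note that %Correct volume is
P-area-weighted — it is not the mean of the per-frame %Correct values, and
the two coincide only when P is constant across frames.

In the median split, "high" means at or above the cohort median
(deterministic half-open rule); an all-identical metric classes every frame
high, with a warning. Finding cross-tabulations use a chi-square test,
switching to Fisher's exact test when any expected cell is below 5; a
finding that never occurs yields a degenerate result reported as no
association rather than an error.

## Statistics

* **Screen and fit.** One-predictor logistic regressions select candidates
  at Wald p < 0.15 for the joint fit; odds ratios carry Wald 95% CIs.
  Distance covariates are rescaled to per-0.1-mm units for reporting.
  Complete separation flags the candidate and removes it from selection.
  Frames are treated as independent observations, as in the source
  analysis; a per-lesion cluster-robust (CR0 sandwich) variance is
  available via the `cluster` argument of `multivariable_logistic()` but is
  off by default. This shared limitation — frames within a lesion are
  correlated — should be kept in mind when reading the p-values.
* **ROC.** The "optimal" cutoff criterion was not specified at the source;
  the package maximizes the Youden index (ties broken toward the smaller
  cutoff, classification rule "positive when score > cutoff"). The AUC is
  the Mann–Whitney statistic (equivalent to trapezoidal integration with
  tie handling) and its p-value against AUC = 0.5 uses the tie-corrected
  normal approximation.
* **Mode comparison.** Catheter-based and wire-based %Correct/%Error areas
  and angles are compared per contact stratum with two-sided unpaired
  Mann–Whitney tests, reporting per-mode medians — the same convention as
  the source analysis, even though the frames are paired across modes.

## The synthetic generator

`generator_config()` fixes the study conditions; the defaults are the
published cohort's where stated, and a single realistic choice where not:

| parameter | default | basis |
|---|---|---|
| lesions × frames | 55 × (5 + Pois(3.6)) ≈ 474 frames | published cohort size |
| lumen area | lognormal, median 2.91 mm², sdlog 0.55 | published median and IQR |
| burr sizes | 1.50/1.75/2.00/2.15/2.25 mm, weights 19/26/8/1/1 | published burr usage |
| catheter | 0.9 mm, on the wall with p = 0.65, else exp(0.12 mm) gap | published median clearance 0.00 (IQR 0.00–0.09) |
| wire | 0.229 mm; touches catheter with p = 0.753 | published contact fraction 75.3% |
| non-contact clearance | grid 0.05–0.60 mm, weights ∝ exp(−d/0.15) | gridded for cutoff-recovery tests; median clearance 0.00 |
| wire–intima gap target | lognormal median 0.21 mm | published median |
| ablation center | catheter if contact, else wire; N(0, 0.23 mm) jitter, capped at 0.5 | mechanism + calibration (below) |
| ablation depth | burr × lognormal(median 0.90, sdlog 0.15) | calibration (below) |
| findings | injury 0.005→0.075, flap 0.02→0.20, interpolated by realized misablation | published prevalences 3.8% / 10.5% |

Lumen contours are Fourier-perturbed ellipses (harmonics 3–5, relative
amplitude sd 0.02, shape floor 0.3) rescaled to the exact target area;
they are star-shaped about the origin by construction. The catheter's
radial position is solved by bisection against the measured boundary
distance so its realized surface clearance equals the drawn one. The post
lumen is the union of the pre lumen and the ablation disc, so pre ⊆ post
holds exactly and the true ablated area is the lumen area gain — the
conservation law the validation suite leans on. Depth noise is applied to
the disc, not the contour, precisely to preserve that containment.
Infeasible draws (burr or catheter too large for the lumen) are retried up
to `max_retries` times per frame.

The jitter and depth parameters (0.23 mm, 0.90, 0.15) are the one
calibrated choice: they were tuned once, on a small pilot sweep, so that
the emergent cross-section medians (P-, A-, O-areas and the four
percentage scores) track the published ones, and were not revisited.
`scripts/acceptance.R` recomputes the emergent medians for any seed, so
the achieved agreement is inspectable rather than asserted here.

One global seed drives everything; per-lesion substreams are derived as
`(100003·seed + 7919·lesion_id) mod (2^31 − 1)`, so any lesion regenerates
identically in isolation.

`simulate_risk_table()` is the generator's tabular shortcut for
calibration and power studies of the regression/ROC layer: it draws
catheter–wire clearances from the same placement model (75.3% point mass
at zero plus the positive grid) and a binary outcome whose log-odds rise
linearly with clearance, skipping the geometry entirely.

### What the generator does and does not emulate

It reproduces the cohort's marginal geometry (lumen areas, clearances,
burr ratios, calcium arcs), the contact mechanism, and the association
structure between clearances and prediction quality. It does **not**
emulate: multiple burr passes or burr upsizing within a lesion; serial
correlation of contact status along a pullback (contact is i.i.d. per
frame); wire position drift during the run beyond isotropic jitter;
pre-lumen loss (prolapse), so `lumen_loss_area` is identically zero here;
or any pixel-level imaging physics. Because the non-contact mechanism is
sharp (the ablation recenters entirely on the wire), the contrast between
the two prediction modes in the non-contact stratum is stronger in
synthetic cohorts than in the published one; passing tests demonstrate
correct computation and direction, not clinical effect sizes. Likewise, at
the published deep-injury prevalence (~4%, a dozen events per cohort) the
4×2 association test is underpowered in a single synthetic cohort, and its
p-value is reported as computed.

## Numerical conventions

* Areas in mm², volumes in mm³, angles in degrees, clearances in mm.
* Polygon simplicity is enforced at construction and file load (O(n²)
  segment test); generator contours are simple by construction and skip
  it.
* Clipper vertex snapping perturbs coordinates at the 1e-9 level; tests
  that compare clipped against constructed geometry allow for that, and
  the angle analogues of constructed identities carry a sub-degree
  tolerance.
* Validation problem sizes: the Monte-Carlo area oracle uses 10^6
  stratified jittered samples per frame over 200 generated frames
  (agreement within max(1%, 0.005 mm²)); the ray oracle samples at 0.1°
  (agreement within 0.5°); logistic recovery uses 100 replicate cohorts of
  500 frames; the screen calibration 500 replicates.

## Known limitations

* Frames are analyzed as independent; the cluster-robust option exists but
  defaults off to mirror the source analysis.
* The wire-placement direction search optimizes a sampled target gap over
  72 candidate directions, so the wire–intima distribution is matched in
  location, not in shape.
* `read_lesion()` validates geometry and schema but does not check that
  devices avoid each other (a wire overlapping the catheter loads fine;
  its clearance is simply 0).
* The four-group labels depend on cohort medians and are therefore
  relative: subsetting a frame table and re-splitting changes labels.
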