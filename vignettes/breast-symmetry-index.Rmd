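---
title: "The Breast Symmetry Index: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Breast Symmetry Index: model, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastsym)
```

## The measurement model

Cosmetic outcome after breast conserving therapy is classically rated by eye
on the four-level Harris scale (excellent / good / fair / poor), which is
cheap but poorly reproducible between observers. The Breast Symmetry Index
(BSI) replaces the judgement with geometry: an annotator marks, on one frontal
photograph, the jugulum, the two nipple centres and the two breast borders as
closed polygons, and every aesthetic judgement the score makes is reduced to a
comparison of a left-side measurement with its right-side counterpart.

The elementary comparison is the ratio factor
$f = \min(a, b)/\max(a, b) \in [0, 1]$: symmetric in its arguments,
scale-free, and equal to 1 exactly when the two sides agree. Six components
are compared this way: the direct jugulum–nipple distance, its horizontal and
vertical projections, the 24-cut radial profile of the nipple within its
border, the border area, and the border perimeter. Component asymmetries
$d_k = 1 - f_k$ are combined linearly,

$$\mathrm{BSI} = 15\sum_k w_k\, d_k, \qquad \sum_k w_k = 1,\ w_k \ge 0,$$

split for reporting into a mammilla sub-score (direct, horizontal, vertical,
radial) and an area sub-score (area, circumference) whose sum is the total.
The linear transform $d = 1 - f$ is the minimal reading of "deviation of the
factor from 1 encodes asymmetry"; together with normalised weights it
guarantees the endpoint semantics of the scale: all factors 1 gives exactly 0,
all factors 0 gives exactly 15.

### Weights

The published description states that nipple position is weighted more
heavily than area and circumference, but not the numeric weights. The
package therefore derives defaults from the published importance
questionnaire (10 experts, 8 non-experts, items scored 1 = very important to
4 = not important): panel means are pooled by panel size, each BSI-relevant
item receives the inverted raw weight $5 - m$, and the three item weights are
normalised. Scars are rated in the questionnaire but never enter the score,
so they are excluded before normalising. The questionnaire offers no
within-item breakdown for nipple position, so its group weight is split
equally over the four mammilla components. With the published panel values
this yields group weights of about 0.390 (mammilla), 0.311 (area) and 0.299
(circumference) — reproducing the intended ordering from the questionnaire's
own numbers. Users can override any of this with `bsi_weights()` or a
`key: value` weights file (`read_weights()`); weights must be non-negative
and sum to one.

A note on the published pooled means: recomputing the overall column from the
printed group means reproduces 1.41 (mamilla position) and 2.24
(circumference) exactly, while the area item computes to 2.13 against a
printed 2.12 — a rounding quirk in the source table. The package uses the
recomputed value.

### The radial profile

The radial factor compares, cut by cut, the distance from the nipple to the
border in 24 directions. Three conventions are not fixed by the published
description and are resolved here as package decisions:

* **Anchor and direction.** Cut 1 starts at 12 o'clock (straight up on the
  displayed image) on both sides; the left breast is swept clockwise and the
  right counter-clockwise, both as seen on screen. Because the two sweeps are
  mirror images, cut $i$ on one side faces cut $i$ anatomically on the other,
  and any fixed anchor would serve equally; 12 o'clock is chosen for
  legibility. A left–right flip of the scene with the orientation flag
  reversed reproduces a profile exactly, which the test suite asserts
  bit-for-bit.
* **Nearest crossing.** For a non-convex border a ray may cross the boundary
  more than once; the distance taken is to the nearest crossing. Traced
  breast borders are near-star-shaped around the nipple, so this rule is
  robust to annotation wiggles where a farthest-crossing rule would jump.
* **Cut count as a parameter.** 24 is the default of `radial_profile()` and
  `compute_factors()`, not a constant, so the suite can test the general
  mechanism; all shipped behaviour uses 24.

Coordinates throughout are image pixels, x rightward and y downward, and
"left"/"right" are viewer-relative — matching what the annotator sees.
"Clockwise" is likewise defined on the displayed image.

### Harris banding

The published BSI-to-Harris correspondence enumerates half-unit score values
(group 1: 1–2.5, group 2: 3–6.5, group 3: 7–10, group 4: 10.5–15), leaving
gaps such as 2.6–2.9 undefined. `harris_band()` therefore rounds to the
nearest 0.5 first (ties away from zero) and then looks the rounded value up;
rounded values below 1 are group 1, since 0 is the best attainable symmetry.

### Degenerate measurements

A bilateral pair that is zero on both sides (e.g. both nipples exactly on the
jugulum's vertical) is perfectly symmetric, so its factor is defined as 1; a
pair that is zero on exactly one side is maximally asymmetric, factor 0.
A nipple lying exactly on its border is rejected at validation time rather
than producing a zero radial distance. Polygons are validated on
construction: at least three vertices, no repeated consecutive vertices, no
self-intersection (an $O(n^2)$ vectorised segment test, ample for traced
borders of a few hundred vertices), and strictly positive area.

## Agreement statistics

Inter-rater reliability uses the intraclass correlation for the two-way model
with absolute agreement, computed from the two-way ANOVA mean squares
(subjects MSR, raters MSC, error MSE):

$$\mathrm{ICC}(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE)},
\qquad
\mathrm{ICC}(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}.$$

The published evaluation reports "average ICC", read here as the
average-measures form ICC(A,k), which is the default; the single-measures
form is exposed alongside since the variant is never printed. Confidence
bounds use the F-distribution method for ICC(A,1), stepped up to average
measures via Spearman–Brown; the level defaults to 95% and is configurable.
Only complete subject × rater grids are accepted — the evaluated panels were
complete, and missing-data ICC estimation is out of scope. A grid with zero
between-subject variance has no defined ICC and is reported as `NA` with an
explanatory note rather than silently as 0. Pearson correlation (with the
t-based p-value and $r^2$) is a thin wrapper over `stats::cor.test()` that
refuses constant input explicitly.

In the test suite the implementation's mean-squares arithmetic is checked to
1e-9 against values frozen from an independent `stats::aov` computation on a
6 × 4 fixture, and the same `aov` route is recomputed in the test as a second
opinion.

## The synthetic annotation generator

No photographs ship with the package; `make_symmetric_pair()` generates the
study material instead. One breast contour is a star-shaped radial function
about its centre — an ellipse $r(\theta) = ab/\sqrt{(b u_x)^2 + (a u_y)^2}$
with an optional inferior elongation $(1 + \mathrm{droop} \cdot \max(0, u_y))$
and, optionally, smooth low-order sinusoidal irregularity — discretised into
`n_vertices` points and mirrored exactly about the torso midline. Defaults
(semi-axes 120 × 100 px, droop 0.15, 96 vertices, a ~1000 px wide virtual
image) are chosen once as a realistic frontal-photograph scale. Star-shape
guarantees the radial profile is well defined for any interior nipple.
`apply_asymmetry()` then grafts controlled defects onto one side: a nipple
displacement, an isotropic border rescaling about the nipple (area scales
with the square of the factor), and a vertical shift of the whole side.

`simulate_rater_panel()` emulates k investigators annotating the same image:
every landmark and border vertex is displaced by isotropic Gaussian error
with marginal standard deviation `jitter_sd`. Displacements along a border
are spatially smooth (a low-order Fourier field over the vertex index, scaled
so the per-vertex marginal is exactly `jitter_sd`): a human mis-traces whole
stretches of a border coherently, whereas independent per-vertex noise of
realistic magnitude would turn a polygon whose vertices sit a few pixels
apart into a self-intersecting scribble. Landmark points are jittered
independently. Draws violating the annotation invariants are resampled a
bounded number of times. A single explicit seed threads all randomness; a
fixed seed reproduces a panel bit-for-bit.

What passing tests on this material shows — and what it does not: the
generator exercises the full scoring pipeline (mirror-zero exactness,
similarity invariance, dose-response monotonicity, reliability under noise)
on idealised smooth contours with a single-knob error model. It does not
emulate photograph segmentation ambiguity, perspective, patient posture or
illumination, so test results quantify the correctness of the computation,
not the photographic performance of the method.

## Numerical choices and problem sizes

* Mirror-symmetry and swap-invariance assertions use a 1e-9 tolerance on the
  score; reflected coordinates agree to machine precision and the tolerance
  absorbs the few ULPs lost in mirroring arithmetic.
* Ray–edge intersection solves each 2 × 2 system directly; the edge parameter
  interval carries a 1e-9 slack so a ray passing exactly through a vertex
  (shared by two edges) cannot slip between both half-open intervals.
* Annotation JSON is written at 17 significant digits, so a write/read round
  trip reproduces coordinates exactly.
* Property suites run at sizes chosen to probe the geometry thoroughly while
  keeping the default check fast: 200 random symmetric annotations for the
  mirror-zero property, 500 factor/weight fuzz draws, a 10^6-sample
  Monte-Carlo area oracle, and reliability curves over 20 seeds at four
  jitter levels with 6–10 subjects of 60 vertices each.

## Known limitations

* The original software's exact component weights are unpublished; the
  questionnaire-derived defaults reproduce the stated ordering but cannot be
  calibrated against the original tool's outputs (no landmark data
  accompanies its screenshots), so absolute scores from other
  implementations may differ while orderings agree.
* Whether the original averaged the 24 per-cut ratios (as implemented) or
  took one ratio of averaged lengths is not fully explicit in the published
  text; the per-cut reading follows its description of comparing
  corresponding lengths and combining them by arithmetic mean.
* Headline clinical numbers (Pearson r against subjective panels on real
  patients, ICC near 0.99 across trained raters) require the original
  photographs and are not reproducible here; the package instead verifies
  the reproducible arithmetic and the properties above.
* Scar visibility, 3-D shape and texture are outside the score by design.
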