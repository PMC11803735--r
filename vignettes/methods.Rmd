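---
title: "Behavioral strobe-response screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral strobe-response screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strobescreen)
```

# The screening problem

Insecticides acting as GABA-gated chloride-channel antagonists (the
endosulfan/fipronil pharmacology) produce a distinctive behavioral signature
in larval zebrafish: generally elevated motor activity and, most
discriminating, *paradoxical movement under strobing light* — untreated
larvae freeze almost completely when a blue or green light strobes at 4 Hz,
while antagonist-treated larvae keep moving or move more. `strobescreen`
implements the full analysis chain that turns multiwell-plate video of such
a screen into ranked chemistry: motion-index quantification, strobe-response
scoring and hit calling, behavioral-profile classification and embedding,
chemotype clustering of hits, and the downstream pharmacology (oocyte
percent-block, insect diet-assay LC50).

No public recording of the original campaign exists, so the package ships a
first-class synthetic-data generator that reproduces the *structure* of the
experiment — plate layouts, battery timing, phenotype classes, oocyte
epochs, diet-assay designs — and every stage is tested against it.

# Motion index

For consecutive video frames the motion index of a well is

$$MI_t = \sum_{(i,j) \in ROI} | \,f_{t+1}(i,j) - f_t(i,j)\,
|,$$

the sum of absolute pixel-intensity differences inside the well's ROI.
`compute_mi()` evaluates this in double precision (exact for integer
intensities), yielding `N - 1` samples for `N` frames; sample `t` is
timestamped at the later frame. MI is kept in raw arbitrary units with no
per-well area normalization: wells on a plate share one ROI grid of equal
rectangles, so areas cancel in every comparison the pipeline makes.

Two conventions worth stating:

* a single-frame stack returns an empty trace rather than an error;
* schedules and scoring windows are half-open intervals `[start, end)` in
  seconds, and trace sample `t` (1-based) carries timestamp `t / f` at frame
  rate `f`, so a window `[a, b)` selects samples
  `floor(a f) < t <= floor(b f)`.

The battery-average MI (`battery_average_mi()`) reduces a well to one
number; an average below 1 is called lethal (`lethality_flag()`, strict
inequality — an average of exactly 1 is not lethal). Dose-response curves
summarize battery averages per concentration with Student-t 95% confidence
intervals, appropriate at the 12-wells-per-condition design size.

# The behavioral battery and the strobe score

The default battery (`gen_battery_schedule()`) lasts 1200 s at 25 Hz: rest
blocks, two acoustic and two tap startle assays, a steady purple-light
assay, and the two diagnostic strobe assays — blue then green, each 120 s
strobing at 4 Hz (30000 MI samples per well in total). Segment metadata
records the nominal wavelength and irradiance. All segments are
configurable; `assays = character(0)` leaves the minimal strobes-plus-rest
battery used widely in the tests.

The strobe score of a well for one channel is

$$s = \frac{1}{6}\sum_{w=1}^{6} \max_{t \in W_w} MI_t \;-\;
\overline{MI}_{\text{baseline}},$$

the mean over six 5-s windows of the within-window MI maximum, minus the
mean MI over a baseline interval. The six windows are spread evenly across
the 120 s segment with maximal spread (starts at `i (D - 5)/5` seconds into
a segment of duration `D`; for `D = 120`: 0, 23, 46, 69, 92, 115 s).

The baseline term deserves comment. A raw average of window maxima is
nonnegative, yet solvent-treated wells are reported with *negative* mean
strobe scores — only possible if pre-stimulus activity is subtracted.
`strobe_score()` therefore subtracts the mean MI over the 30 s immediately
preceding the strobe segment (configurable via `baseline_interval_for()`).
Freezing larvae then score negative (window maxima near zero, active
baseline), hyperactive larvae strongly positive, which reproduces the
published sign structure of solvent vs endosulfan-like scores.

Scores are additionally min-max normalized to [0, 1] per screening batch
and channel (`normalize_scores()`; order-preserving, idempotent). The
normalization is for cross-batch display; *hit calling always operates on
raw scores*, because the screening threshold is defined in score units.

# Hit calling

`call_hits()` declares a test well a primary hit when its raw blue strobe
score satisfies

$$s \ge \max(\text{solvent}) + 2\,\widehat{\sigma}_{\text{solvent}},$$

the sample SD of the batch's solvent wells added twice to the *highest*
solvent score. Ties at the threshold count as hits ("at least 2 SD"). The
empirical solvent maximum is the screen's false-positive control; no
multiple-testing correction is applied, matching screening practice for
this rule. The green channel is computed and reported for the score
scatter but not thresholded. Under a simulated null the rule is very
conservative (empirical hit rate well below 1% with 58 solvent wells), and
a shift at the endosulfan-scale separation (~7 solvent SDs) is detected in
more than 95% of wells — both properties are exercised in the test suite
and the acceptance script.

# Profile classification and embedding

`build_profile_matrix()` stacks per-well MI vectors (optionally
block-averaged; factor 25 gives per-second bins) into a wells-by-time
matrix. `classify_profiles()` fits a 500-tree random forest under
stratified 5-fold cross-validation and reports the out-of-sample confusion
matrix with per-class recall. Cross-validation is used because a confusion
matrix on training predictions would say nothing about whether phenotypes
are "distinct and predictable"; 5 folds is the smallest standard choice
that leaves 12+ training wells per class at the 12-24 wells/class design.
Parallelism is treated purely as a performance knob — results depend only
on the seed.

`embed_2d()` is an exact O(n²) t-SNE written for this package (per-point
Gaussian bandwidths calibrated to a target perplexity by binary search,
Student-t output kernel, momentum gradient descent with early
exaggeration, PCA initialization). At screen sizes — tens to a few hundred
wells — exact t-SNE is the standard tool; no approximate-neighbor machinery
is warranted. Duplicate profile rows describe the same point in behavior
space, so unique rows are embedded and duplicates share their first
occurrence's coordinates exactly. Defaults: perplexity 30 (reduced
automatically when `3·perplexity > n - 1`), 500 iterations, seed-fixed.
Embeddings are compared across runs only at the level of class separation
(silhouette), never coordinates.

# Chemotype clustering

`make_fingerprint()` computes hashed topological linear-path fingerprints
(OpenBabel FP2: paths up to 7 bonds hashed into 1024 bits) from SMILES;
the fingerprint is invariant to SMILES canonicalization, and single-atom
molecules — which have no bond paths — get the empty fingerprint.
Similarity is Tanimoto, `|a∧b| / |a∨b|`, defined as 1 when both vectors
are empty. `cluster_compounds()` runs average-linkage hierarchical
clustering on `1 - Tanimoto` and cuts the tree at distance `1 - 0.45`:
compounds sharing a cluster are those merged at similarity ≥ 0.45, the
only reading that makes a similarity threshold operational on a
dendrogram. Average linkage is the default (single and complete are
available) for robustness to within-chemotype noise. Labels are
canonicalized by each cluster's smallest member id, making the assignment
invariant to input order. `pick_representatives()` selects each cluster's
medoid (maximal mean intra-cluster similarity, lexicographic tie-break) —
an explicit replacement for the expert judgment used in the original
triage.

The synthetic fingerprint generator plants chemotypes by sampling a
prototype of bit density 0.08 per cluster and letting members keep each
prototype bit with probability `2s/(1+s)`, which gives expected
within-cluster Tanimoto `s`; between-cluster similarity concentrates near
`0.08/1.92 ≈ 0.04`, far below the 0.45 threshold. The canonical fixture —
35 compounds in 11 chemotypes — is recovered exactly at 0.45.

# Oocyte percent block

Recordings are annotated with baseline, GABA-only, co-application and
washout epochs at a −60 mV clamp. Conventions:

* `leak_qc()`: oocytes with mean baseline current more negative than
  −1000 nA are excluded; exactly −1000 nA passes (only *excessive* leak
  fails).
* `epoch_amplitude()`: baseline-subtracted mean current over the final 1 s
  of an epoch (a steady-state convention; the measurement window is a
  package choice), reported as the magnitude of the inward current.
* `rundown_fraction()`: GABA responses desensitize, so untreated control
  oocytes estimate the loss — the mean of `1 - late/early` amplitude
  ratios, floored at 0. The control's late epoch sits at the same temporal
  position as a treated oocyte's co-application epoch, so the fraction
  measures exactly the loss that block quantification must discount.
* `percent_block()`: remaining current `co/pre` is divided by
  `(1 - rundown)` — rundown is a multiplicative amplitude loss, so the
  correction is a division, not a subtraction of percentage points (a
  subtractive mode exists for sensitivity analysis) — and
  `block = 100(1 - adjusted)`, clipped to [0, 100]. An inactive compound
  scores 0%, a full channel block 100%, and crediting more loss to rundown
  *lowers* the block attributed to the compound (100×(1−0.4/0.9) ≈ 55.6%
  for pre 100 nA, co 40 nA, rundown 0.10, versus 60% uncorrected).

The published description of which amplitude is the numerator is
internally ambiguous; the convention above is the only one that yields 0%
for inactive compounds and 100% for full block, and it is asserted against
planted block/rundown grids (recovery within two propagated noise SDs in
every cell).

# Insect LC50

The diet assay scores a well dead only when its *least-affected* larva is
dead. `fit_lc50()` fits a 2-parameter log-logistic dose-mortality model
(asymptotes fixed at 0 and 1) by maximum likelihood to well-level binary
outcomes. By default the likelihood respects the scoring rule:

$$P(\text{well dead} \mid d) = F(d;\, \lambda, \beta)^{\,n},$$

with `F` the per-larva log-logistic CDF and `n` the well's larvae count, so
the reported LC50 is the per-larva median lethal dose. This is the reading
under which a planted per-larva LC50 is a recoverable estimand: a plain
well-level logistic (`least_affected = FALSE`, also provided) estimates the
dose at 50% *well* mortality, which for 3-5 larvae/well sits some 40-60%
above the per-larva value by construction. Under the reference design — 7
doses spanning 2-16 µg/well geometrically, 12 replicate wells, 3-5
larvae/well — the median relative error of the default estimator over 200
simulations is below 10%.

Numerical choices: slope bounded in [0.05, 50]; complete separation (no
dose level with mixed well outcomes) and zero mortality variation are
flagged as non-convergence with no estimate fabricated; confidence
intervals are profile-likelihood on log(LC50); the estimator is exactly
scale-equivariant in dose units. Abbott background-mortality correction is
available but off by default (the reference assay observed none).

# The synthetic-data generator

The generator is the package's stand-in for the unavailable campaign data
and defines the study conditions used by every test:

* **Plates**: 96 wells, 8 larvae/well (bookkeeping — the well is the
  analysis unit), 25 Hz. Default map: 8 vehicle wells, 2 lethal controls,
  2 hyperactive positive controls, 84 test compounds at a single screening
  concentration (0.39 µM, inside the sub-micromolar hyperactive window).
* **Phenotypes** (`stock_phenotypes()`): vehicle — baseline 30 MI units,
  startle gain 2, strobe gain 0.05 (freezing); lethal control — flat trace
  with battery average well below 1; hyperactive (endosulfan-like) —
  baseline 150, strobe gain 2.8, Hill midpoint 0.3 µM with slope 3, lethal
  above 1.5 µM. These scales reproduce the published sign and rough
  magnitude of solvent (negative, tens of units) and hyperactive
  (positive, hundreds of units) strobe scores and the
  rise-then-collapse dose curve.
* **Dose interpolation**: every parameter is interpolated between the
  vehicle anchor and the full phenotype with a Hill fraction
  `c^h/(c^h + ec^h)`; at or above the toxicity cutoff the lethal profile
  replaces the phenotype.
* **Noise**: truncated Gaussian on MI (clipped at 0), because MI is a
  nonnegative sum of absolute differences; plus a mean-one lognormal
  per-well baseline multiplier (CV 10%) emulating larva-batch variability —
  without it a 30000-sample battery average would have no between-well
  spread at all. The distributional form is a stated assumption, not an
  empirical claim.
* **Determinism**: one global seed; each well draws from a stream seeded by
  a stable polynomial hash of (seed, plate, well), so generation order
  never changes results, and the full pipeline is byte-reproducible.
* **Frame stacks** are generated only as oracle fixtures for the MI
  formula: `gen_frames()` constructs integer frames whose per-step absolute
  pixel differences equal an arbitrary integer target trace exactly, giving
  an exact round-trip test of `compute_mi()`. No video-scale simulation is
  attempted — it would add camera modeling, not science.

What passing tests on this generator do **not** show: robustness to
tracking artifacts, illumination drift, edge-well effects, non-Gaussian
burst noise, or real larval behavioral idiosyncrasies (habituation,
circadian drift). The generator emulates the experiment's design and the
analysis's assumptions, not larval biomechanics.

# Problem sizes

The shipped analyses and tests run at deliberately modest sizes chosen to
exercise every design feature: 4 plates (384 wells) for the screening
demonstration, 16 wells/class for classification (within the 12-24 design
band), 35 compounds / 11 chemotypes for triage, 4 oocytes per compound, and
200 simulations for LC50 recovery. The generator accepts the full campaign
scale (9512 test + 2336 vehicle wells) — streaming plate by plate keeps
memory flat — but the statistical properties under test do not change with
scale.

# Known limitations

* The strobe-score baseline interval (30 s pre-segment) reconciles the
  scoring formula with negative solvent scores but is an assumption; it is
  configurable and all raw ingredients are reported.
* Whether the primary screen scored single wells or replicate means per
  compound is not recorded; the pipeline scores single wells.
* The batch normalization maps to [0, 1] per channel; a unit-norm scaler
  cannot do that, so the stated 0-1 intent wins and normalized scores are
  display-only.
* `embed_2d` is exact t-SNE: quadratic memory in wells. Beyond a few
  thousand wells an approximate implementation would be needed.
* The LC50 model fixes asymptotes at 0 and 1 (logistic on log dose); a
  probit link is a one-line change but is not exposed because the
  reference assay gives no basis to prefer it.
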