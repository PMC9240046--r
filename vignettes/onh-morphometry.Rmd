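---
title: "ONH rim and lamina morphometry: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ONH rim and lamina morphometry: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhmorph)
```

## The measurement model

All indices live in a per-section 2D frame: `x` lateral (µm), `z` axial (µm,
posterior-positive). Inputs are already-segmented boundary polylines — ILM,
Bruch's membrane with its two opening (BMO) termination points, and the
anterior lamina cribrosa surface (ALCS) — with strictly increasing `x` and
linear interpolation between vertices. Device calibration to µm is assumed
done upstream; segmentation and image processing are out of scope.

The **BMO reference line** joins the temporal and nasal termination points;
its length is the opening width *W*. We treat it strictly per section: the
construction is drawn independently on every B-scan rather than from a 3D
plane fitted across sections, because the inputs are independent 2D curves
and every downstream index is defined within a single scan.

* **HRW** is measured along the reference line from a BMO point to the
  nearest ILM–line crossing on the rim side of that point (temporal side:
  crossings temporal of the temporal BMO point, and symmetrically nasally).
  A side whose ILM never crosses the line is flagged unmeasurable and
  excluded from aggregation rather than imputed.
* **MRW** is the exact minimum Euclidean distance from the BMO point to the
  ILM polyline, via closed-form projection onto every segment (vertex-only
  minima understate the distance between samples). It is a
  per-horizontal-section minimum: radial-scan BMO-MRW is a different
  protocol and deliberately not implemented.
* **LCCI**: perpendiculars from both BMO points (posteriorly, normal to the
  reference line) meet the ALCS at two feet; LCCD is the maximum
  perpendicular depth of the ALCS below the foot-point line, restricted to
  the span between the feet because the lamina is rarely segmentable beyond
  the opening; LCCI = 100·LCCD/*W*. Dividing by *W* makes the index
  scale-invariant, which the tests assert numerically for scale factors
  0.5, 2 and 10. A perpendicular that misses the ALCS flags the section and
  excludes it from the LCCI aggregate.

**Aggregation** follows the three-location/three-scan protocol: scans at
offsets −2/0/+2 around each of three locations placed at fractions 0.25,
0.5, 0.75 of the vertical disc diameter ("equidistant" placement is
otherwise unspecified, so we chose the symmetric quartile positions).
Location value = mean of usable scans; eye value = mean of the three
locations. HRW and MRW average the temporal and nasal sides with equal
per-section weight; **HMR is computed per section as HRW/MRW and then
averaged** like any other index — consistent with its per-measurement
definition, and the only reading under which a group's mean HMR can differ
from the ratio of its mean HRW to mean MRW, as reported study tables do.
Scans flagged for vessel shadow are replaced by the adjacent scan line when
one exists, else dropped; a location left with no usable scan flags the eye
incomplete.

## What the synthetic generator emulates

The generator exists so that every downstream stage — measurement,
screening, matching, statistics — can be exercised end to end without any
real data. Per eye it draws latent indices (HRW*, MRW*, LCCI*) and clinical
covariates from independent truncated normal distributions whose moments
are shipped in `inst/extdata/group_params.csv` (three groups: NTG, CRAO,
healthy fellow eyes of the CRAO subjects; 31 eyes per group by default;
fellow eyes share subject-level age and sex with their CRAO partner). It
then *renders* geometry that measures back to those latents:

* BMO width per scan is the horizontal chord of the disc ellipse (axes from
  disc area and ovality) at the scan height, scan lines 32 µm apart.
* The ALCS is a parabola through the two perpendicular feet (250 µm below
  the BMO line — a typical anterior lamina depth) with apex depth
  LCCI*·W/100, so the measured LCCI is the prescribed one by construction.
* The ILM is a piecewise profile built in line coordinates: a descending
  far tail crossing the reference line at exactly the prescribed HRW on
  each side, a flat rim run at exactly the prescribed MRW above each BMO
  point (every other ILM piece is kept provably farther away), and a smooth
  cup between the rims. Construct-then-measure residuals are below 1 µm
  before jitter; the tests assert this.
* Per-scan multiplicative jitter (default SD 2% of the value) models
  within-eye scan-to-scan variability; a small per-eye tilt (SD 2°, capped
  at ±5°) rotates the frame so nothing depends on axis alignment. The
  temporal/nasal split uses the group-specific temporal-to-overall
  fractions from the parameter table, so temporal-only aggregates are
  slightly smaller than overall ones, as in real rims.

Randomness: one root seed; per-eye child seeds derived by a fixed integer
splitting rule (`(seed mod 1000003)·2017 + key·7919 mod 2147483629 + 1`,
exact in double arithmetic), so cohorts are reproducible byte-for-byte and
independent of generation order.

**Joint distribution choice.** Only marginal means and SDs are specified
per group; the within-group joint distribution of (HRW, MRW, LCCI) is
unreported in the source material, so the generator draws them
independently apart from the geometric constraint MRW* ≤ 0.98·HRW*. The
constraint is enforced by drawing HRW* first and then MRW* from its exact
conditional (upper-truncated) distribution — equivalent to resampling the
marginal until the constraint holds. Drawing the *pair* conditionally
instead would inflate NTG HRW by roughly 30 µm (the constraint binds for
~30% of NTG draws), distorting the quantity the generator most needs to
preserve; conditioning only MRW leaves HRW and LCCI exactly at their
configured marginals at the cost of a downward NTG MRW bias of ~15 µm where
the constraint binds. HMR is never sampled — it emerges as a ratio. No
within-group HRW–LCCI correlation is imposed; the pooled negative
association across disease groups emerges from between-group mean
differences.

**What passing tests do not show.** The generator produces smooth,
noise-free polylines with exactly one rim crossing per side, a strictly
parabolic lamina and no vessel artefacts, segmentation errors or
magnification error. Recovery of configured group means therefore validates
the pipeline's internal consistency, not its robustness to real
segmentation noise.

## Screening and matching

Exclusions are deterministic rules with strict thresholds (ovality > 1.3,
torsion > 15°, spherical equivalent outside [−8, +3] D, more than five
quality-failed sections, maximum IOP > 21 mmHg, incomplete-type CRAO,
neovascular glaucoma, prior surgery, retinal/neurological disease, branch
occlusion, glaucoma history), reported in a fixed taxonomy order and
independent of row order. The pre-screening pool fixture assigns exclusion
attributes to the first *k* rows per reason so the screening counts are
exact, not expected values. Matching is greedy nearest-neighbour on the
Euclidean distance of z-standardised age, IOP at OCT, disc area and global
RNFL thickness, accepting the globally smallest admissible distance first;
pairs must fall within per-variable calipers (defaults 5 y, 3 mmHg,
0.3 mm², 10 µm — chosen as clinically conventional tolerances; the source
protocol does not state an algorithm or tolerances). Ties break toward
smaller eye id, making the result deterministic. Optimal (Hungarian) or
propensity-score matching would be a reasonable extension; greedy matching
was chosen for determinism and transparency.

## Statistics

Per variable, each group is tested with Shapiro–Wilk at α = 0.05; if all
three pass, one-way ANOVA with Tukey HSD, otherwise Kruskal–Wallis with
Dunn's rank test (tie-corrected, Bonferroni over the three pairs). Dunn
after Kruskal–Wallis is a choice — the analysis plan we mirror prints
pairwise P values without naming the nonparametric post-hoc — and is
configurable. Groups too small for Shapiro–Wilk (n < 3) or with zero
variance fall to the nonparametric branch, since normality cannot be
supported. Pairwise results are summarised as an ordering pattern
("A < B = C"): groups sorted by mean, "<" only where the pairwise P is
below α. No multiplicity correction is applied across variables, mirroring
the study-style analysis. Two-group comparisons are gated the same way onto
t / Mann–Whitney / paired-t / Wilcoxon tests; all-zero paired differences
return P = 1 by convention (the signed-rank zero rule leaves no ranks).

Interobserver agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single measures — computed from the two-way mean squares with
McGraw–Wong F-based 95% bounds. The ICC model is a choice (the convention
for continuous interobserver measurements); the two-way mean-squares
identity is cross-checked against base R's `aov()` in the tests.

## Numerical choices and edge cases

* Segment–line intersection, point-to-segment projection and
  perpendicular-ray intersection are exact closed forms; dense-sampling
  brute-force oracles in the test suite bound any discrepancy at 0.5 µm.
* An exactly collinear curve/line overlap raises a classed error
  (`onh_collinear_error`) rather than returning an arbitrary point set.
* Ties in the minimum-distance foot resolve toward smaller x.
* Curves must have strictly increasing x; the ILM construction bounds its
  steep rim segments so this holds for tilts up to ±5°.
* Default curve sampling pitch is 10 µm, matching the lateral resolution
  scale of ONH B-scans; the parabola apex and both feet are placed as exact
  vertices so LCCD is sampled without discretisation loss.
* Section JSON is written with 2-decimal µm precision; round-trips are
  byte-identical after one write–read–write cycle.

## Problem sizes

The recovery and significance simulations use 200 replicate cohorts of
31 eyes per group (the study's group size), nine scans per eye; the type-I
calibration uses 1000 null replicates; the geometric property sweep uses
10,000 random sections. These sizes put Monte-Carlo error comfortably below
the decision thresholds they feed (a rate estimated from 200 replicates has
binomial SE ≤ 3.5 percentage points).

## Known limitations

* The generator's independence assumptions (within-group indices,
  covariates) are conventions, not estimates of the real joint structure.
* MRW here is the within-horizontal-section minimum; values are not
  comparable to radial-scan BMO-MRW devices.
* The measured NTG group mean MRW sits ~15 µm below its configured marginal
  as the documented price of the rim-consistency constraint; comparisons
  *between* groups are unaffected in direction.
* Matching quality depends on the candidate pools; the greedy algorithm
  does not guarantee the maximum number of within-caliper pairs.
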