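---
title: "Quantifying quadruped gait: kinematics, interlimb phase, and footfall indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying quadruped gait: kinematics, interlimb phase, and footfall indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgait)
```

## The measurement problem

Rodent locomotor studies — in particular studies of recovery after thoracic
spinal cord injury (SCI) and of targeted manipulation of spinal interneuron
populations such as long ascending propriospinal neurons — quantify stepping
from two kinds of digitized video data:

* **sagittal marker trajectories** of one hindlimb (iliac crest, hip, ankle,
  toe; the knee is deliberately not marked because skin slippage over that
  joint makes its localization unreliable), from which joint angles and
  intralimb coordination are computed; and
* **footfall event tables** from a ventral camera: per-limb initial-contact
  and lift-off times, toe positions, and a plantar/dorsal label for each
  hindlimb step (weight borne on the dorsum of the paw is a hallmark SCI
  deficit).

`quadgait` turns these inputs into the standard derived measures: joint-angle
excursions and proximal–distal lag, step-cycle spatiotemporal measures,
interlimb circular phase with an irregularity classification, the
footfall-pattern indices RI/CPI/PSI/DSI, and the statistics used to compare
conditions (two-proportion z, Watson two-sample U², circular descriptives,
speed-curve regressions, paired t). A fully seeded synthetic generator
produces data with the statistical structure these analyses assume, under
four behavioral conditions (uninjured/SCI × control/silenced).

## Kinematics

The **proximal angle** is the interior angle at the hip between the segments
hip→crest and hip→ankle; the **distal angle** is the interior angle at the
ankle between ankle→hip and ankle→toe. Both are reported in degrees on
(0, 180] and are invariant to rigid motion and uniform scaling of the marker
set — the package's tests verify this invariance to 1e-9 degrees. Frames
with coincident adjacent markers (a zero-length segment) are excluded with a
warning rather than propagating NaNs.

**Excursion** is max − min of an angle over a window. **Intralimb lag** is
the delay of the distal peak behind the proximal peak within one step cycle,
as a fraction of the lead angle's peak-to-peak period. Peak detection uses a
5-frame centred moving average and a minimum prominence of 5°; both are
configurable, and the defaults were chosen for 100–150 frames/s video of
rat-scale excursions (25–95°), where they reject digitization ripple without
displacing sinusoid-scale peaks by more than one frame. When the two first
peaks tie exactly the proximal angle is taken as lead (a deterministic
tie-break); cycles in which either angle has no identifiable peak return
`NA` and are excluded from aggregates.

## Step cycles and footfall sequences

A step cycle runs from initial contact to the next initial contact of the
same limb (stride time); stance is contact→lift-off, swing the remainder,
and instantaneous speed is the limb's own toe displacement over its stride
time (pass speed is stride-derived throughout; no independent body-marker
speed is computed). Per-frame contact traces are debounced — contact-state
runs shorter than 3 frames merge into the surrounding state — before
segmentation, because single-frame dropouts are digitization noise, not
steps. Dorsal/plantar labels are treated as input data and pass through
segmentation and merging untouched; nothing in the package attempts to
infer them from images.

Four-limb footfall sequences merge the contact onsets of all limbs in time
order; simultaneous placements take the fixed tie order LH < RH < LF < RF so
that downstream pattern matching is deterministic.

## Interlimb phase and the irregularity classification

The phase of a test limb in a reference limb's stride is the test limb's
initial contact time measured from the reference contact, divided by the
reference stride time: 0 (≡ 1) is synchrony, 0.5 strict alternation.
Reference limbs are fixed: left hindlimb for the hindlimb pair, left
forelimb for the forelimb pair, and the hindlimb for both hindlimb–forelimb
pairs. Cycles containing two test contacts ("double steps") contribute one
observation each, flagged, rather than being dropped — they are real
post-injury events that CPI is designed to detect.

To remove lead-limb preference the circular value is folded to a linear
scale: `[0.5, 1]` for the nominally alternating pairs (hindlimb, forelimb,
homolateral, swim), `[0, 0.5]` for the nominally synchronous heterolateral
pair. The transform is idempotent and symmetric under `raw → 1 − raw`.

Irregularity thresholds are the mean ± 2 sample SD of the **uninjured
control** distribution on the linear scale, pooled across animals (a
per-animal option exists but pooling is the default, since the published
threshold boxes are single group-level bounds). A step is irregular only if
strictly beyond the bounds — a boundary value is regular, matching a
"> 2 SD" rule. Mean and SD are deliberately computed linearly, not
circularly: the folded scale is a bounded interval and the 2-SD boxes are
drawn on it.

## Footfall-pattern indices

The six **normal step sequence patterns** are the canonical cruciate,
alternate and rotary orders (`normal_step_patterns()`), written with their
two lead-limb variants:

| class | a | b |
|---|---|---|
| cruciate | RF→LF→RH→LH | LF→RF→LH→RH |
| alternate | RF→LH→LF→RH | LF→RH→RF→LH |
| rotary | RF→LF→LH→RH | LF→RF→RH→LH |

**RI** (regularity index) removes dorsal placements, scans the remaining
placement string left-to-right greedily and non-overlappingly for the six
patterns, and reports `100·(matches×4)/placements`, the denominator counting
post-exclusion placements (consistent with RI excluding dorsal steps
altogether; counting pre-exclusion placements would conflate the two
deficits RI and DSI separate). **CPI** (central pattern index) rolls a
four-placement window one placement at a time and scores each window. A
design point worth stating explicitly: the six patterns as linear strings
are lead-limb representatives of the normal *cyclic* orders. A rolling
window that advances one placement at a time lands on arbitrary rotations
of the underlying cycle, so CPI compares windows cyclically — a window is
correct when it contains each limb exactly once and its cyclic order is one
of the six patterns'. Literal string matching would cap CPI at 50% on a
perfectly patterned pass, which contradicts what the index is defined to
measure. RI is unaffected (its greedy scan simply slides to a
forelimb-initiated window) and keeps literal matching, so its greedy
contract remains simple and oracle-testable. Both indices are verified
against independent brute-force oracles on every footfall string of length
≤ 8.

**PSI** is `100·hindlimb plantar steps / forelimb plantar steps` (capped at
100 by default; configurable off). **DSI** is `100·dorsal hindlimb steps /
total hindlimb steps`, with sidedness as the right/left split of the dorsal
steps. Indices are computed per pass, averaged per animal, and only then
averaged per group, so animals with many passes do not dominate group means.

## Statistics

* **Two-proportion z**: both pooled and unpooled variance conventions are
  implemented and the variant is recorded in every result. Both are needed
  because published z statistics for irregular-step counts are internally
  consistent only under a per-analysis convention; the package default is
  unpooled. Under a true null at n = 160 per group the unpooled test's
  type-I error is within 0.05 ± 0.01 (verified by simulation in the test
  suite).
* **Watson two-sample U²** compares two circular samples' empirical
  distribution functions around the circle and is invariant to a common
  rotation. The p-value defaults to seeded label permutation (9,999
  permutations); an asymptotic series is provided for larger samples. Ties
  are processed in blocks so the statistic is deterministic under any input
  order.
* **Circular descriptives**: vector-sum mean direction, resultant length R,
  and circular SD `sqrt(−2 ln R)`; R = 0 returns an undefined-mean sentinel.
* **Speed curves**: stance and stride times follow exponential decay
  `y = y0 + a·e^(−b·x)` against speed; stride distance is linear. The
  exponential is fit by Levenberg–Marquardt least squares started from a
  conditional-linear grid search on the rate, so convergence does not depend
  on hand-supplied starting values. The 95% prediction interval is built
  from the residual variance with a t quantile at n − p degrees of freedom;
  parameter uncertainty is deliberately excluded (the interval describes new
  single observations, and at the n used here — hundreds of steps — the
  approximation costs well under a percentage point of coverage, verified
  by simulation).
* **Paired t** on differences, with an explicit error on zero-variance
  differences.

No multiple-testing correction is applied by default; comparisons are
reported per test with their variance convention, seed and permutation
count. Mixed-model and repeated-measures ANOVA are routine external tools
and are out of scope here.

## The synthetic generator

The generator exists so every pipeline stage can be validated against known
ground truth, and its defaults encode the structure of the four behavioral
conditions:

* **Phase**: left-right hindlimb phase is a two-component wrapped-normal
  mixture — an alternation component at 0.5 and a synchrony component at 0.
  Wrapped-normal (rather than von Mises) noise is used so the linear-scale
  2-SD thresholds downstream have an exact generative counterpart.
  Uninjured controls: SD 0.03 cycle, no synchrony component. Silencing in
  the uninjured animal: SD 0.06 with a 0.35 synchrony weight (producing
  ~45–55% of steps beyond the control box, the magnitude seen with
  conditional silencing). SCI control: SD 0.10, weight 0.15, post-injury
  silencing: SD 0.05, weight 0.05.
* **Dorsal steps**: per-step Bernoulli with probability 0.25 (SCI control)
  vs 0.12 (SCI silenced), split ~60/40 right/left, matching the reported
  DSI contrast (≈24% vs ≈12%) and sidedness. Dorsal steps modify only the
  label, never timing.
* **Timing**: stance time follows `y0 + a·e^(−b·speed)` plus Gaussian noise
  (0.008 s); swing is Gaussian and speed-independent; coefficients were set
  so that SCI-control passes at ≈55 cm/s give stance ≈0.196 s, swing
  ≈0.087 s and duty cycle ≈0.68–0.70, the published post-injury operating
  point, with silencing lengthening swing to ≈0.106 s.
* **Footfall order**: each forelimb leads its diagonal hindlimb by a
  consistent 0.1 cycle (the diagonal-couplet lead of a walking gait). This
  is what makes the zero-noise pass exactly the alternate pattern and the
  heterolateral pair synchronous; a symmetric jitter around exact synchrony
  would instead randomize the within-couplet order and destroy the pattern
  indices even for "perfect" gait. The forelimb pair's internal phase is an
  independent draw from the same mixture model, so the two girdles share
  stride timing but not phase noise.
* **Kinematics**: joint angles are sinusoid templates with configured
  excursions (proximal 47–52°, distal 75–93° across conditions) and an
  intralimb lag (0.08 cycle uninjured, 0.15 SCI control, 0.10 silenced),
  converted to marker coordinates with fixed segment lengths (crest–hip
  2.5 cm, hip–ankle 4 cm, ankle–toe 2 cm — arbitrary but recorded in the
  manifest and exactly invertible by `compute_joint_angles()`).
* **Cohort structure**: per-animal parameters are jittered (±10% dispersion
  and dorsal probability, ±5% excursions and swing) from one seeded stream;
  the manifest records every realized value. Identical configurations give
  bit-identical output. Camera frame rate (120 fps) and strides per pass
  (3–9) are configurable defaults, not claims about any particular study.

What the generator does **not** emulate: musculoskeletal or
central-pattern-generator dynamics, video digitization itself, skin-marker
slippage, 3D camera geometry (coordinates are planar sagittal), fatigue or
within-pass drift, and any correlation between phase irregularity and
stance-time noise. Passing tests therefore show that the *analysis* is
correct and well calibrated on data with the assumed statistical structure
— not that real video pipelines are free of their own artifacts.

## Numerical choices and degenerate inputs

Problem sizes in the test suite were chosen to estimate each quantity
stably: cohorts of 4–6 animals × 6–8 passes × 5–10 strides give 300–700
hindlimb steps per condition, enough for circular means to ±0.01, binomial
checks of the dorsal probability, and <10% relative error on the stance
curve; calibration checks use 20,000 null simulations (type-I error) and
3,000 fresh observations (prediction-interval coverage). Other choices:

* exactly collinear markers give interior angles of exactly 180°; the acos
  argument is clamped to [−1, 1] to avoid NaN from rounding;
* zero-length reference strides are an error, never silently skipped;
* an all-identical pair of circular samples returns U² = 0, p = 1;
* empty passes are skipped with a warning by the pipeline; empty cycle lists
  are errors in summaries (a mean over nothing is a bug upstream);
* percentages printed by the classifier are rounded to two decimals, which
  is the precision at which published counts are cross-checked.

## Known limitations

* Coordinates are planar sagittal; no two-camera 3D reconstruction.
* Dorsal-step identification is consumed as an input label; the package has
  no access to video.
* The swim module analyzes peak-extension events; it does not model stroke
  kinematics.
* BBB scores are observer ratings and are out of computational scope; only
  generic downstream count/proportion handling applies to them.
* Group means of indices from any particular published cohort are not
  reproducible without that cohort's raw per-animal data; the package's
  end-to-end validation therefore rests on synthetic cohorts with known
  ground truth and on the published count-level statistics, which are
  reproduced exactly.
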