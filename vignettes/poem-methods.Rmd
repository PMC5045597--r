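---
title: "POEM scoring: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{POEM scoring: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poem)
```

## The grading model

POEM grades sublingual microcirculatory function on a 5-point ordinal
scale from four video clips taken at one patient/time point. The model's
unit of observation is the *vessel segment*: an individually
distinguishable stretch of microvessel annotated with one of four ordinal
flow categories (`absent` < `intermittent` < `sluggish` < `continuous`).
Two assumptions underlie the design: that flow and its spatial
heterogeneity — not vessel density — carry the clinically discriminating
information, and that adjacent-category confusion is the dominant error a
human grader makes.

Per clip, the fraction *f* of sluggish/stopped segments sets the flow
grade (normal *f* < 0.25; impaired 0.25 ≤ *f* ≤ 0.50; critically impaired
*f* > 0.50), and heterogeneity is present when strictly more than 5
segments flow differently from the remainder. Four clip grades aggregate
by counting rules into the overall score (see `?computePoem`).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `normalUpper` | 0.25 | fraction | published normal/impaired boundary |
| `criticalLower` | 0.50 | fraction | published impaired/critical boundary |
| `hetDeviantThreshold` | 5 | segments | published "> 5 segments" rule |
| `stoppedCategories` | absent, intermittent, sluggish | — | see below |
| `smallVesselMaxDiameter` | 20 | µm | conventional small-vessel cutoff |
| `perfusedCategories` | sluggish, continuous | — | usual consensus reading |

Band boundaries are closed on the impaired side: exactly 25 % and exactly
50 % are impaired, matching the printed band wording ("less than 25 %",
"25–50 %", "more than 50 %"). The boundary behaviour is exact at the
machine-representable neighbours of 0.25 and 0.50, and fractions arrive as
exact ratios of small integers, so no tolerance is applied.

**"Stopped" semantics.** The grade definitions say "sluggish/stopped"
without pinning "stopped" to the four-category vocabulary. The default
counts `absent`, `intermittent` and `sluggish` as stopped — an
intermittently flowing segment is stopped part of the time — and the set
is configurable because the alternative reading (excluding `intermittent`)
is defensible.

**Heterogeneity reference.** "Different flow to the remainder" is
operationalized against the modal flow category. The deviant count
`n − max(category counts)` is unchanged by how a plurality tie would be
broken, so no tie rule is needed. Impaired and critically impaired clips
are heterogeneous by construction (heterogeneity was universal in such
clips during the score's development), which also fixes how non-normal
clips enter the heterogeneity tally H when sequences mix grades.

**The uncovered combination.** Exactly one critically impaired plus
exactly one impaired clip triggers neither "two or more critical" nor
(read literally) "two or more impaired". This package counts a critically
impaired clip toward the impaired tally (rule C + I ≥ 2 → score 2): flow
in such a clip is, a fortiori, at least impaired, and this is the most
conservative reading consistent with the algorithm's severity ordering.
It is a documented choice, not a rule printed in the grade table.

**Arity.** Exactly four clips are required; three- or five-clip sequences
are rejected rather than rescaled, because the counting rules (e.g. "two
or more", "all four") are defined on four clips.

**Per-segment weighting.** Fractions weight each segment equally rather
than by centerline length — the grading counts "vessel segments in view".

## Consensus parameters

TVD and PVD use the length-density convention: summed centerline length of
small vessels (diameter ≤ 20 µm) divided by field area, in mm/mm². The
grid-crossing (De Backer) variant is deliberately out of scope. PPV is the
perfused share of small-vessel segment counts. The quadrant MFI assigns
each segment to the quadrant containing its arc-length midpoint, scores
each non-empty quadrant by its predominant category (ties toward the lower
flow score — conservative and deterministic), and averages over non-empty
quadrants; empty quadrants are excluded rather than scored 0 so sparse
fields are not penalized. MHI is computed across the four clip-level MFIs
of a sequence — the "per time point" unit — as (max − min)/mean, so it is
zero exactly when the four MFIs are equal and invariant to positive
rescaling.

## Agreement statistics

The ICC uses the two-way random-effects model (items and raters both
random). Whether the original analysis used single- or average-measure
coefficients is not recoverable from its description, so both are exposed
and `single` is the default: the reliability of one rater's score is what
matters at the bedside. Consistency excludes rater variance from the
denominator; agreement includes it. Confidence intervals are the standard
F-based interval (consistency) and the Satterthwaite-approximation
interval (agreement), at 95 %. The implementation computes mean squares
directly from sums of squares; the test suite checks both flavors and both
measures against an independent `aov()`-based oracle to 1e-10 on random
matrices, and against `pingouin.intraclass_corr` conventions during
development.

Error-score regression subtracts the expert score from each observed score
and fits `error ~ item + rater` with marginal F tests per predictor; an
all-zero error matrix is reported as degenerate rather than raised, since
it is the expected outcome of a perfect panel. Dunn's pairwise z statistics
use pooled mid-ranks with the tie correction; the omnibus H comes from
`stats::kruskal.test`. The multiplicity adjustment is selectable and
defaults to Bonferroni, the conservative choice, because the original
analysis names the test but not a correction. Rating matrices must be
complete; the intended design is every rater scoring every item, and
imputation is out of scope.

## The synthetic-data generator

No microcirculation videos or rater sheets are publicly deposited, so all
testing runs on synthetic annotations. The generator emulates three layers:

1. **Vessel fields**: 10–40 segments per clip (three-point polylines with
   random position, orientation, arc length 60–350 µm, folded inside a
   1000 × 750 µm field), lognormal diameters around 9 µm so most segments
   fall under the 20 µm small-vessel cutoff.
2. **Severity**: a single tilt parameter *s* ∈ [0, 1] maps the 0–3 flow
   score to a Binomial(3, 1 − *s*) distribution — all-continuous at
   *s* = 0, all-absent at *s* = 1, mixed compositions in between. A
   fraction `heterogeneityLevel` of segments is drawn from a regime one
   severity band (1/3 of the scale, one category step in expectation)
   away, toward worse flow unless the base regime is already in the worst
   third. Mixing weights are kept below 0.5 where the sweep design chooses
   them: the deviant regime is by definition a minority of the field.
3. **Raters**: each simulated rater misclassifies each clip's state one
   ordinal step (on critical < impaired < normal-with-heterogeneity <
   normal-without) with probability `raterNoise`, then aggregates —
   matching the adjacent-grade confusion seen in human raters. Noise acts
   at the clip-grade level, not the segment level; segment-level noise is
   a documented alternative left unimplemented.

The default study panel (five design points from healthy-homogeneous to
critically impaired) emulates a validation set chosen to span the score
range, as such panels are in practice. Ground-truth scores near band
boundaries still vary with the seed — faithfully to real borderline clips.

The severity/heterogeneity sweep (`poemParameterSweep`) stratifies the
*expected realized* stopped fraction evenly over [0, 1], solving the
severity that hits each target given the heterogeneity mixing, so all
three flow bands are evenly covered when POEM is compared with MFI and
MHI.

What the generator does **not** emulate: pixel-level appearance, velocity
estimation, vessel-detection errors, pressure artifacts or video-quality
variation, and any coupling between vessel density and severity. Passing
tests therefore demonstrate correctness of the scoring arithmetic and the
statistical machinery, and directional consistency between POEM and the
consensus parameters — not clinical performance on real video, and not the
original study's printed ICC or R² values, which depend on its
non-public clips and raters.

## Numerical choices

* ICC residual sums of squares are accumulated from the two-way residuals
  (not by subtracting SS terms), so a noiseless integer rating matrix
  yields an exactly zero residual and ICC exactly 1.
* When the residual mean square is zero the confidence interval collapses
  to the point estimate instead of propagating an infinite F.
* A constant response in `linearR2` returns R² = 0 and p = 1 directly; a
  constant predictor is an error (slope undefined).
* Empty clips, empty rating cells, single groups and zero-mean MFI vectors
  raise informative errors naming the offending object.

## Problem sizes

The test suite and acceptance checks use: exhaustive enumeration of all
256 four-clip state combinations (and all 1024 single-clip degradations);
50 random matrices for the ICC oracle; 200 replicates per rater-noise
level (0, 0.1, 0.2, 0.3) of a 5-sequence × 32-rater study for the
noise-monotonicity check; and a 200-sequence sweep for the POEM–MFI/MHI
correspondence. These sizes give stable Monte Carlo means for the
monotonicity and correlation checks while keeping the full suite
comfortably fast on a single CPU.

## Known limitations

* The scoring of the one-critical/one-impaired/two-normal combination is a
  documented convention (score 2), not a published rule.
* Whether raters in the original study counted `intermittent` as stopped
  is unknown; the default here is a choice.
* TVD/PVD follow the stated length-density convention, not the internals
  of any proprietary analysis package.
* MHI is undefined when all four clip MFIs are zero; such sequences are
  excluded from correspondence analyses.
* Synthetic severity compositions are conventions, not estimates of any
  study's case mix.
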