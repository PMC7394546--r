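---
title: "Directional analysis of EB1 comet tracks in neuronal somas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional analysis of EB1 comet tracks in neuronal somas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eb1comet)
```

## The scientific problem

Neurons maintain sharply different microtubule polarity in their two
compartment types: axons are plus-end-out, while mature proximal dendrites
of *Drosophila* dendritic arborisation (da) neurons are predominantly
minus-end-out. EB1-GFP marks growing microtubule plus ends as moving
"comets", so comet trajectories recorded in the soma report where
microtubules are born and where their plus ends go. Two quantitative
questions drive this package:

1. **Directional bias at birth.** Do comets nucleated at somatic Golgi
   stacks grow preferentially towards the axon entry site, and do comets
   from the same stack share a direction?
2. **Fate at neurite mouths.** Of the comets born in the soma, what
   fraction approaches the axon versus a dendrite, what fraction of
   approachers actually enters, how often do growing plus ends turn inside
   the soma, and what polarity do comets display in the proximal dendrite?

`eb1comet` implements the full measurement chain from raw track tables to
these statistics, plus a synthetic track generator so the chain can be
validated end to end without microscopy data.

## The measurement model

### Initial growth angle

For each comet the initial growth angle is measured at the comet origin
between (a) the ray from the origin to the axon entry point and (b) the
comet's initial direction of growth. The initial direction is the
total-least-squares line through the first `n_direction_points` positions
(default 3, i.e. the origin plus the next two frames, about 10 s of growth
at the 5 s frame interval), oriented by the net displacement. Three points
is the minimum that smooths single-frame localisation jitter; the window is
a parameter because the appropriate horizon depends on frame rate and
noise. Angles are signed, positive counterclockwise in math-convention
coordinates, in (-180, 180]; for frequency distributions they are folded to
[0, 180] by taking the absolute value, since growth to the left or right of
the axon is not distinguished.

Input files may use the image convention (origin top-left, y increasing
downward, as ImageJ exports do). Geometry files must declare their
convention (`y_axis: image` or `math`) and `as_math_convention()` performs
one explicit flip; all internal arithmetic is math-convention. Making the
flip explicit prevents silent sign errors in the angle handedness.

### Per-stack resultant vectors

Each comet angle becomes a unit vector with Y = cos(angle) (the
toward-axon axis) and X = sin(angle), so a comet growing straight at the
axon entry maps to (0, 1). For every Golgi stack that produced at least two
comets, the vectors are averaged; the resultant length

d = ||mean unit vector|| in [0, 1]

is 1 when all comet angles from the stack coincide and 0 when they cancel,
the standard mean-resultant-length measure of circular concentration. A
resultant with positive Y points on average towards the axon ("upper
quadrants" of the resultant scatter); the skew between upper and lower
quadrants is tested with an exact binomial tail at p0 = 0.5.

### The Monte-Carlo uniform-angle null

To ask whether observed resultant lengths are larger than chance, the
analysis rebuilds the null the original measurement design implies: each
comet angle is replaced by an independent draw from the continuous uniform
distribution on (-180, 180), keeping the per-stack comet counts fixed, and
the resultant lengths are recomputed. The continuous uniform is the
measure-theoretically natural reading of "a random angle"; integer-degree
draws differ negligibly. Observed and null lengths are binned on [0, 1]
(default 10 equal bins) and compared with a one-way chi-squared
goodness-of-fit test against the pooled-null bin proportions; bins with
zero null mass are merged into their lower neighbour so all expected
counts are positive. The default of 3 null replicate sets mirrors a
plotting convention; moment checks in the test suite use 10^4 to 10^5
stacks for stability. Useful analytic anchors: for two-comet stacks the
expected null length is 2/pi (about 0.637), and for large n it approaches
the Rayleigh limit (sqrt(pi)/2)/sqrt(n).

The seed handling derives one RNG substream per replicate from a single
top-level seed, so every null is bit-reproducible.

### Entry zones, approach and entry

A band of width 0.5 um (the published operational definition) is laid
across each neurite mouth, bounded by an inner gate on the soma side and an
outer gate on the neurite side, both perpendicular to the outward soma
boundary normal at the entry point. A comet **approaches** a neurite when
its path first touches the band, and **enters** when the path subsequently
crosses the outer gate leaving the soma. A comet may approach without
entering; once entered, later positions are outside the soma
classification domain. Approach denominators are per neurite, matching the
"entered as a proportion of those that approached" reading; a comet that
touches one zone, retreats and enters another counts as approaching both
but entering one. Comets whose origin already lies inside a band are
excluded from approach/entry denominators (an ambiguity a large soma never
presents, but a simulation can).

The gate length (the neurite mouth caliber) is not derivable from the
geometry file, which stores entry points rather than neurite silhouettes;
it is an explicit `caliber` argument, default 2 um, clamped to [1, 5] um —
wide enough to cover a proximal neurite mouth, narrow enough not to
capture soma-interior passes.

### Turning

Turning was originally scored by eye; reproducibility requires a stated
rule, so the classifier uses an explicit operational definition with all
parameters in `turning_params()` and reported in the run manifest:

* **Qualification.** The within-soma path (truncated at the first
  entry-zone contact) must be longer than 2 um, and the comet must not be a
  cortex traveller (at least half its within-soma points within 1 um of
  the soma outline). Both thresholds restate the published qualification;
  the one-half rule operationalises "travelled along the cortex".
* **Detection.** Directions are smoothed over a 3-frame window; a turn is
  an angular change of at least 45 degrees between consecutive
  non-overlapping windows. The direction-change vertex is localised at the
  maximal pointwise bend inside the window span and must lie farther than
  1 um from both the soma outline and the nucleus: direction changes at
  boundaries are collisions (reflections off the cortex or nuclear
  envelope), not guided turns. Localising the vertex at the maximal bend,
  rather than at the window midpoint, is what excludes boundary
  collisions exactly even when a smoothing window partially overlaps one.

45 degrees separates guided redirection from tracking jitter (localisation
noise of 0.05 um over 0.5 um steps produces apparent bends well below it);
the 3-frame window matches the angle-measurement horizon.

### Dendrite polarity

Within the proximal segment of a dendrite — the corridor from the entry
zone's outer gate to the dendrite's branchpoint marker, which is a
geometry-file field and never inferred — a comet's polarity is the sign of
its net displacement projected on the dendrite axis: anterograde (away
from the soma, plus-end-out) or retrograde (towards, minus-end-out). Net
displacements under 0.2 um are below localisation noise and are excluded
as indeterminate.

### Inference

Every reported fraction is a `proportion()` with a Wilson score 95%
interval. The Wilson interval is used because the event proportions of
interest sit at extremes (2% dendrite entries, 89% retrograde comets)
where the Wald interval misbehaves; the interval method is recorded in
output metadata. Distribution comparisons use the one-way chi-squared
goodness-of-fit test; two-condition comparisons use the 2x2 Pearson
chi-squared **without** continuity correction. The uncorrected variant is a
deliberate, documented choice: it is the test whose p-values match the
published two-condition comparisons (e.g. p = 0.0098 for 114/1058 vs
47/666), whereas the Yates-corrected variant does not. Binomial tails are
exact term-by-term sums. No multiple-testing correction is applied,
matching the original analysis.

## The synthetic data generator

`simulate_neuron()` emulates the statistical structure the analysis
assumes, not the physics of microtubule growth:

* an elliptical soma (default semi-axes 6 x 5 um, a class I da-neuron-like
  soma) with a concentric nucleus (default 0.5 of the soma), the axon
  leaving at the top, two dendrites at the bottom, and Golgi stacks on the
  mid-cytoplasmic annulus;
* comets originate at a Golgi stack with probability `frac_golgi_origin`
  (default 0.6) with an initial angle von Mises-distributed about the
  origin-to-axon direction (`kappa_nucleation`, default 3), else uniformly
  in the cytoplasm with a uniform angle. The von Mises family is the
  canonical unimodal circular distribution and nests the uniform null at
  kappa = 0, so bias is a single tunable dial;
* growth is a straight-segment walk at 0.1 um/s sampled every 5 s with a
  0.005/s catastrophe hazard — stand-in kinetics chosen so tracks span a
  few micrometres over tens of frames, as in the source movies; none of
  these values is asserted as a measured truth;
* per frame, a guided turn fires with probability `p_turn_per_frame`
  (default 0.04) and redirects growth towards the axon entry with von
  Mises jitter, a phenomenological stand-in for guidance along a polarised
  microtubule network (explicit rail microtubules and stalling forces are
  out of scope). Turns are suppressed for the first two frames, so the
  nucleation angle stays measurable, and for six frames after any
  direction change, since guidance events are not instantaneous
  re-engagements;
* cortex and nuclear-envelope contacts reflect the direction (collisions,
  not turns); on first entry-zone contact a single Bernoulli draw decides
  entry (defaults 0.54 for the axon and 0.28 for dendrites, the control
  entry proportions), after which an entering comet runs 1 um past the
  outer gate and terminates while a rejected comet terminates inside the
  band;
* Gaussian localisation noise (default 0.05 um) is added to emitted
  coordinates only, never to the internal dynamics.

Each comet carries a ground-truth record: origin stack, true nucleation
angle, gate contacted and its Bernoulli outcome, termination cause, and
turning labels. The `turned` label applies the angular turn-signature
definition above to the noise-free internal path, so with zero noise the
classifier must recover it exactly; `clean_turn_event` is an event-log
fact (a guided turn of at least 45 degrees away from boundaries with
three undisturbed frames on either side) that is sufficient for a
detectable signature and is checked independently of the signature code
path.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: detection and linking failures of real
tracking, z-drift and focal-plane loss, comets growing into the soma from
dendrites, heterogeneous per-neuron geometry, non-straight growth between
frames, and any mechanistic coupling between turning and entry (in the
generator they are independent processes). Agreement on synthetic data
validates the measurement chain, not the biology.

`fixture_counts()` and `fixture_turning()` construct deterministic
piecewise-linear tracks whose classified counts equal a requested table
exactly (no sampling), which is how the package reconstructs published
percentages from their underlying counts.

## Numerical and design choices

* Polygons are ordered vertex lists; point-in-polygon is an even-odd
  crossing test with a 1e-9 boundary tolerance, hand-vectorised because it
  sits in the simulator's per-frame loop and cross-checked against
  `pracma::inpolygon` in the test suite.
* The boundary normal at an entry point is the normal of the nearest
  polygon edge; on a 64-gon circle this deviates from the analytic normal
  by at most half the edge angle (about 2.8 degrees), which is far below
  the angular effects under study.
* Ties when assigning an origin to equidistant Golgi stacks break to the
  lexicographically first stack name, with a message (association radius
  default 1 um, about a Golgi ministack footprint).
* Resultants with Y exactly 0 count as neither upper nor lower quadrant
  and shrink that denominator, with a message.
* Simulated comets appear at frame 1: frame 0 is reserved for the
  first-frame exclusion rule (comets already present at a movie's first
  frame may be pre-existing microtubules and are excluded by
  `filter_first_frame()`).
* Degenerate inputs are legal where the science allows: a geometry with
  zero Golgi stacks simply yields empty resultant analyses; an empty event
  table yields zero denominators flagged as `NA` rather than errors.
* p-values are stored at full precision; "p < 0.001"-style thresholds are
  display-only.

## Problem sizes used in validation

The test suite validates the null moments at 10^4 to 10^5 stacks, Wilson
coverage at 10^4 binomial draws, parameter recovery over 100 simulation
replicates of 150 comets (entry probabilities 0.54/0.28, kappa = 3), test
size at kappa = 0 over 200 replicates of about 150 measurable Golgi-origin
angles, and ground-truth agreement on 500 noise-free simulated comets.
These sizes give stable Monte-Carlo estimates (binomial standard errors of
a few percent on coverage and rejection rates) for a test suite that runs
in minutes.

## Known limitations

* The turning rule is an operational definition of behaviour the original
  scoring judged by eye; its parameters are reported with every run but
  other reasonable definitions exist.
* Approach/entry classification assumes non-overlapping entry zones and
  rejects geometries that violate this.
* All analysis is 2-D single-plane; comets leaving the focal plane appear
  as terminations.
* The simulator's kinetic constants are placeholders for testing the
  measurement chain, not estimates of microtubule dynamics; quantities
  that depend on them (track lengths, event rates per minute) should
  never be read as predictions.
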