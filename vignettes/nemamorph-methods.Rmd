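---
title: "Quantitative muscle, locomotion and synaptic phenotyping: methods and design"
author: "nemamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative muscle, locomotion and synaptic phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nemamorph` turns a set of manual and semi-interactive phenotyping protocols
for *Caenorhabditis elegans* neuromuscular disease models into a tested,
deterministic pipeline. It covers four read-out families:

1. **Muscle morphometry** from GFP::MYO-3 fluorescence images of body-wall
   muscle: a binary myosin-fibre mask, a single-cell region of interest, a
   one-pixel skeleton whose branch lengths approximate individual filament
   lengths, and the gap-to-total-cell-area ratio that summarizes fibre loss.
2. **Locomotion metrics** from posture and centroid time series: swimming
   thrash rate, crawling body-bend rate, path and net speed, population
   activity counts from an infrared beam grid, and the levamisole read-outs
   (relative body-length change, time to paralysis).
3. **Spontaneous postsynaptic current (PSC) analysis** from voltage-clamp
   traces recorded at a holding potential of -60 mV: event detection,
   frequency and mean amplitude.
4. **The statistical battery** used to compare genotypes: one-way ANOVA with
   Dunnett's many-to-one post hoc test, the two-sided F test of variances,
   per-group 2x2 Pearson chi-square tests under Benjamini-Hochberg FDR
   control, and Gaussian kernel density summaries.

Because the original measurements were made on live animals, none of the
published group values can be recomputed from data we possess. The package
therefore ships a first-class synthetic-data module (`generateMuscleImage`,
`generatePostureSeries`, `generateActivityWells`, `generatePscTrace`,
`generateGroupDataset`) that produces every input type with known ground
truth, and every pipeline stage is validated by parameter recovery against
that truth.

# Muscle morphometry

## Segmentation

The interactive pixel-classifier training step of the manual workflow is replaced
by a deterministic chain: Gaussian smoothing (`smoothSigma`, default 0.5 um,
about a quarter of a fibre width), the iterative-intermeans (isodata)
automatic threshold, and removal of foreground components smaller than
`minObjectArea` (default 1 um^2). On high-contrast GFP-labelled fibres the
intensity histogram is strongly bimodal, which is the regime where
intermeans thresholding is reliable; the threshold is the fixed point of
`t = (mean below t + mean at/above t) / 2` iterated from the midrange, and
pixels at or above `t` are foreground. A constant image has no threshold and
raises an error rather than guessing.

The single-cell region is obtained by morphological closing of the fibre
mask with a disc (`closingRadius`, default 4 um), hole filling, and keeping
the largest connected component. The closing radius must exceed half the
widest gap it has to bridge; 4 um handles the multi-micrometre lesions seen
in degenerated muscle while not merging neighbouring structures. A
user-supplied polygon ROI (CSV of 0-based x,y pixel vertices) overrides the
automatic region, mirroring the manual polygon workflow.

## Skeletonization

`skeletonize` is a topology-preserving thinning built around the classical
two-sub-iteration (Zhang-Suen) parallel scheme, with three amendments that
we found necessary to guarantee the package's stated invariants (no 2x2
all-foreground block; the number of 8-connected components exactly equals
that of the input mask):

* each parallel sweep is accepted only if it leaves the 8-connected
  component count unchanged; otherwise that sweep is re-run as sequential
  single-pixel deletion with a proper simple-point test. A bare parallel
  sweep deletes an isolated 2x2 block outright, which silently removes a
  component.
* a final *minimalization* pass deletes every non-endpoint pixel whose
  foreground neighbours remain 8-connected without it and which has a
  background 4-neighbour. This removes the redundant staircase corner
  pixels that the parallel scheme is known to leave along diagonals (their
  Rutovitz crossing number is 2, so the classical conditions never select
  them); without this pass a diagonal fibre acquires hundreds of spurious
  3-neighbour pixels and the branch decomposition becomes meaningless.
* rare 2x2 blocks at dense crossings whose four pixels all anchor distinct
  arms cannot be resolved by deletion alone; a last-resort pass deletes one
  corner and re-routes its orphaned arm through an adjacent background
  pixel, verified against the global component count. This sacrifices strict
  mask-subset membership for one pixel in pathological inputs, in exchange
  for an unconditional one-pixel-width guarantee.

Connectivity is 8-connected for foreground everywhere; note that
`EBImage::bwlabel` is 4-connected, so the package carries its own
8-connected labelling.

## Branch semantics and filtering

`buildSkeletonGraph` classifies skeleton pixels by 8-neighbour count
(endpoint = 1, junction >= 3, isolated = 0) and traces branches between
node pixels; a closed loop with no node gets one designated node and a
single cycle branch. Branch length sums `pixelSize` per orthogonal step and
`pixelSize * sqrt(2)` per diagonal step. A "fibre" is a skeleton branch
between nodes — the branch semantics of the standard skeleton-analysis
plugin — rather than the longest path per component. Whether the original
length cap was applied per branch or per component is not decidable from
the protocol description; branch semantics is our choice and is applied
uniformly.

`filterFibreLengths` keeps lengths in (0, 250] um: zero-length records are
excluded as non-physiological, records *longer than* 250 um are excluded as
exceeding the maximum reasonable filament length, and exactly 250 um is
kept (the exclusion rule is strictly "more than").

`gapAreaRatio` defines gap pixels as cell-region pixels not covered by the
fibre mask, retained as 8-connected components of at least `minGapArea`
(default 5 um^2); the ratio divides by the cell-region pixel count. The
component floor suppresses sub-resolution inter-striation slivers that a
manually traced gap polygon would never include. The automated gap
definition as a whole is our construction: the original workflow delimited
gaps by eye.

# Synthetic muscle images

`generateMuscleImage` draws parallel fibre stripes at a configurable angle
inside a spindle-shaped cell whose chord tapers quadratically toward the
flanks; per-fibre lengths are jittered around the taper profile. With the
default `fibreWidth == fibreSpacing` the stripes tile the cell contiguously
and striation appears as a cosine intensity modulation, so the only
fibre-free area inside the cell is what the generator erased — making the
gap-to-area ratio a clean recovery target. Setting `fibreWidth <
fibreSpacing` produces separated fibres for per-fibre length recovery.

Gap lesions are rectangles spanning one to a few adjacent fibres (1.5-4 um
half-length, 1.5-3 um half-width), erased at random interior positions
until the realized fraction is within 0.01 of the request, never
overshooting by more than that. Two aspects deserve emphasis:

* lesions are **interior** to the cell. The imaging protocol this emulates
  only admits cells with a complete, traceable outline, and a closing-based
  automatic ROI cannot re-enclose a lesion that breaches the cell boundary.
* lesions are **multi-fibre patches**, matching the appearance of
  degenerated muscle, not sub-fibre notches; notches smaller than the
  pipeline's own 5 um^2 gap floor would be invisible by design.

Clump artefacts (bright Gaussian blobs at 3-5x fibre intensity) emulate
GFP aggregation and are available to stress segmentation. Blur defaults to
a 0.2 um point-spread sigma and additive Gaussian noise to 0.02 of the unit
fibre intensity. The pixel size defaults to 0.25 um/pixel, a plausible
value for a 400x magnification setup; the true calibration of the original
images is unpublished, and the default is configurable everywhere.

What the generator does *not* emulate: uneven illumination, out-of-focus
sections, sarcomere substructure, neighbouring cells touching the target
cell, and 3-D effects. Passing recovery tests therefore demonstrates that
the pipeline measures what the generator encodes, on images of realistic
geometry and contrast — not that it is robust to every artefact of real
micrographs.

# Locomotion

Both counters run the signed bend angle through a hysteresis state machine
with thresholds at +/- `hysteresisDeg`: the state becomes +1 above the
upper threshold, -1 below the lower, and is otherwise unchanged. A
**thrash** is one completed two-alternation cycle (maximum bend to one
side and back); the count is `floor(alternations / 2 + 0.5)`, which makes
the count invariant (to within one) under dorsoventral relabelling of the
angle sign. A **body bend** is one entry into a new state — two per full
sinusoidal cycle — and a repeated excursion to the same side cannot
re-enter the state, which implements the rule that a reverse bend in the
same direction is not counted again. Omega bends are counted as ordinary
alternations; there is no separate omega detector.

The default hysteresis is `max(10 deg, 0.3 x the 90th percentile of
|angle|)`. The manual counters' implicit noise threshold is unknowable, so
this fixed-plus-adaptive default is a free parameter, chosen to reject
angle noise an order of magnitude below typical bend amplitudes without
per-video tuning. Series must be uniformly sampled (frame interval constant
within 1%) and cover at least 10 s.

Speed is path speed (mean per-frame displacement over frame interval), with
net displacement over duration reported as a secondary quantity. Activity
counts sum beam-state toggles over beams per time bin, the arbitrary-unit
read-out of a beam-grid motility reader. `relativeLengthChange` is
`100 * (after - before) / before`. `timeToParalysis` returns the start of
the first window in which speed stays below `epsUmS` (default 5 um/s) and
the absolute angle rate below `epsDegS` (default 2 deg/s) continuously for
`sustainS` (default 10 s), or `NA` if none exists; no published values exist for
these thresholds, so they are exposed as configuration.

# PSC detection

The baseline is a running median (`windowMs`, default 200 ms), robust to
sparse millisecond-scale events while tracking drift. The noise scale is
`1.4826 x MAD` of the baseline-subtracted trace. Samples below
`-kMad x sigma` (default `kMad = 4`) mark event regions, subject to two
guards that determinism makes cheap to audit:

* regions narrower than `minWidthMs` (default 1 ms) are discarded — noise
  excursions beyond 4 sigma last one or two samples at 10 kHz, while a
  genuine event with ~1 ms rise and ~6 ms decay stays below threshold for
  several milliseconds;
* two regions merge unless the trace recovers above half the detection
  threshold between them (re-arm hysteresis), so a noise blip on an
  event's decay does not split it.

Each region contributes its deepest point as one event; events closer than
`minSepMs` (default 5 ms) merge into the deeper one. The amplitude is the
mean of the baseline-subtracted trace over +/-0.3 ms around the peak: the
raw minimum rides the noise trough and overstates amplitudes by roughly one
noise SD. Only inward (negative) deflections are considered, per the -60 mV
holding convention. The detection settings of the commercial software used
originally are unreported; these defaults are declared parameters of this
implementation, not a reproduction claim. No template matching or
deconvolution is attempted.

The trace generator places events at Poisson times, each adding a negative
biexponential `exp(-t/decayTau) - exp(-t/riseTau)` normalized to peak
`-amplitude` (defaults: rise 0.8 ms, decay 6 ms, 25 +/- 5 pA, 2 Hz,
noise 2 pA at 10 kHz). Truth times are kernel peak times, matching the
detector's event-time semantics.

# Statistical battery

* `oneWayAnova`: classical fixed-effects F on (k-1, N-k) degrees of
  freedom, delegated to `stats::oneway.test(var.equal = TRUE)`.
* `dunnettTest`: per-group t statistics against the control with pooled
  within-group variance; the family-wise adjusted p is
  `P(max_j |T_j| >= |t_j|)` under the equicorrelated multivariate-t null,
  evaluated by seeded Monte Carlo (default 200,000 draws; standard error of
  an adjusted p about 0.001). Monte Carlo was chosen over quadrature for
  simplicity and testability — the unit tests cross-check it against an
  independent multivariate-t implementation and against the t-test in the
  single-comparison case. Adjusted p-values are clamped to be at least the
  raw p, removing sub-millesimal Monte Carlo inversions.
* `varianceFTest`: `F = s_a^2 / s_b^2`, two-sided p as twice the smaller
  tail, via `stats::var.test`.
* `chiSquarePosthocFdr`: each non-control group versus the control as a
  2x2 Pearson chi-square without continuity correction (the default of the
  standard chi-square post hoc R tooling), Benjamini-Hochberg
  adjusted across the comparison family. Whether the original analysis
  compared all pairs or only mutant-versus-control is not stated; the
  many-to-one family matches the wording "compared between wild-type and
  mutant animals" and is the implemented choice. Expected counts of zero
  raise a degenerate-table error.
* `kdeDensity`: Gaussian kernel on a stated grid, Silverman's
  rule-of-thumb bandwidth (`stats::bw.nrd0`) unless given, with the sample
  variance returned for pairing with the F test. A zero-variance sample
  yields a flagged point-mass result with a warning.

# Pipeline, configuration and determinism

`runPipeline` executes synth (or file input) -> morphometry -> locomotion
-> PSC -> statistics, writing per-animal CSVs (`morphometry.csv`,
`fibre_lengths.csv`, `locomotion.csv`, `psc.csv`), a `stats.csv`, a
`summary.json` and a `manifest.json` carrying the config snapshot, package
version, per-stage wall times and MD5 checksums of every output. Every
output row carries its source identifier. Configuration is a YAML file or
list validated by `validateConfig`, which fills defaults and reports every
unknown key by name. A stage failure names the stage and removes partial
outputs.

All generators are pure functions of their arguments and a seed (the
caller's RNG state is saved and restored), so identical config and seed
reproduce byte-identical CSVs; the demo (`runDemo`) builds a two-genotype
study — a wild-type-like group (gap fraction 0.02, 40 um fibres, 1 Hz
thrashing, 2 Hz PSC rate) against a degenerated mutant-like group (gap
fraction 0.21, 18 um fibres, 0.4 Hz thrashing, 0.6 Hz PSC rate) — and runs
everything in well under a minute. Within a synthetic group, animals and
cells span +/-15% of the group means deterministically, providing the
within-group variance the statistical battery needs.

# Problem sizes in the test suite

The shipped tests were sized to exercise every claim at meaningful
precision while staying quick to run end to end: gap recovery uses a
3-fraction x 5-seed grid of 256 x 256 px images; fibre-length recovery
three sparse 288 x 288 px images; skeleton invariants 100 random 64 x 64
masks; counter checks 20 noisy 60 s series; PSC recovery 20 seeds of 60 s
at 10 kHz; ANOVA and F-test calibration 5,000 null replicates and Dunnett
family-wise error 2,000 replicates at 2,000 Monte Carlo draws each. The
same computations, re-run from scratch, form `scripts/acceptance.R`.

# Known limitations

* Branch-versus-component fibre semantics changes the length distribution
  on highly branched skeletons; dense (contiguous-stripe) cells yield
  branch lengths of the skeleton web, not of individual fibres — per-fibre
  length recovery is only meaningful on separated fibres.
* The automatic cell ROI under-reaches when fibre loss breaches the cell
  boundary; the manual-polygon override exists for exactly that case.
* The PSC detector resolves overlapping events only down to the re-arm
  criterion; at rates far above the defaults' regime (several tens of Hz)
  merging biases frequency low.
* The thinning's re-routing last resort can place single skeleton pixels
  outside the input mask on adversarial inputs (dense random noise); on
  fibre-like masks it never triggers.
* Type-I calibration was verified for the normal null; the battery makes
  the usual normality and homoscedasticity assumptions of its classical
  members.
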