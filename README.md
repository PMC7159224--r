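# nemamorph

Quantitative phenotyping of *Caenorhabditis elegans* neuromuscular disease
models, as an R package. Studies of muscle-degeneration mutants (for
example CMT2-gene loss-of-function strains) typically score muscle defects
by eye and count locomotor behaviour by hand; `nemamorph` re-implements
that whole read-out battery as deterministic, tested code, for researchers
who image GFP::MYO-3-labelled body-wall muscle, track worm posture and
centroids, record neuromuscular-junction currents, and then need
defensible statistics comparing mutant strains with wild type.

## What it computes

**Muscle morphometry.** From a calibrated fluorescence image: an
iterative-intermeans (isodata) threshold segments the myosin fibres; a
morphological closing estimates the single muscle-cell region (or a manual
polygon ROI overrides it); topology-preserving thinning produces a
one-pixel skeleton whose branches are measured in micrometres (orthogonal
steps at the pixel pitch, diagonal at √2 times it); branch lengths ℓ are
filtered to 0 < ℓ ≤ 250 µm; and the gap-to-total-cell-area ratio

&nbsp;&nbsp;&nbsp;&nbsp;*R* = (gap pixels within the cell, in components ≥ 5 µm²) / (cell pixels)

summarizes fibre loss — ≈ 0.02 in healthy muscle, ≈ 0.21 in strongly
degenerated muscle.

**Locomotion.** A hysteresis state machine over the signed bend angle
counts swimming thrashes (one per complete bend cycle) and crawling body
bends (one per side-to-side alternation, same-side repeats counted once);
centroid tracks yield path and net speed; beam-grid state series yield
population activity counts; body-length pairs and quiescence detection
yield the levamisole contraction and time-to-paralysis read-outs.

**Synaptic events.** Spontaneous postsynaptic currents in a −60 mV
voltage-clamp trace are detected as inward deflections beyond 4 robust
noise SDs below a running-median baseline (with minimum-width and re-arm
guards), giving event frequency (Hz) and mean amplitude (pA).

**Statistics.** One-way ANOVA with Dunnett's many-to-one post hoc test
(adjusted p by seeded Monte Carlo of the max-|T| multivariate-t null),
two-sided F tests of variances, per-group 2×2 Pearson chi-square tests
under Benjamini–Hochberg FDR control, and Gaussian kernel densities.

**Synthetic data with ground truth.** Seeded generators produce every
input type — striated muscle-cell images with controllable gap fraction,
sinusoidal posture/centroid series, beam-grid activity wells, Poisson PSC
traces, grouped normal samples — so each stage has a parameter-recovery
test surface. Published group values come from live animals and cannot be
recomputed; the generators encode those regimes (e.g. gap fractions 0.02
vs 0.21) as ground truth instead.

## Worked example

```r
library(nemamorph)

# a degenerated-muscle image with known truth, and its recovery
sim   <- generateMuscleImage(gapFraction = 0.21, seed = 42)
morph <- summarizeMorphometry(sim$image)
morph
#> MuscleMorphometry: 20 fibres kept (mean 9.0 um), gap ratio 0.211, excluded 0 low / 0 high
sim$truth$trueGapFraction
#> [1] 0.218

# a swimming worm at 1.8 Hz with angle noise: thrashes per minute
sw <- generatePostureSeries(duration = 60, bendFrequency = 1.8,
                            noiseSdAngle = 4, seed = 42)
countThrashes(sw$posture)$perMin
#> [1] 108

# spontaneous PSCs at 2 Hz, 25 pA, detected blind
psc <- generatePscTrace(eventRate = 2, seed = 42)
detectPscEvents(psc$trace)
#> PscEventSet: 131 events in 60.0 s (2.18 Hz), mean amplitude 24.5 pA
```

The gap ratio 0.211 recovers the generated truth 0.218 within the
pipeline's ±0.03 recovery band; 108 thrashes/min matches the programmed
1.8 Hz bend frequency; the detector reports 2.18 Hz against a realized
Poisson truth near 2 Hz and a mean amplitude of 24.5 pA against the
programmed 25 pA.

A full two-genotype study (wild-type-like vs degenerated), including all
output tables and the statistical battery, runs with:

```r
runDemo("demo-out", seed = 1)   # deterministic: rerunning reproduces
                                # byte-identical CSVs
```

or from a shell: `Rscript inst/scripts/nemamorph.R demo --out demo-out --seed 1`.

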