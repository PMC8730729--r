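---
title: "Models and methods behind cargoQuant"
author: "cargoQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cargoQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargoQuant)
```

cargoQuant implements the three quantitative assays used to characterize
how motor cargo-adaptor complexes (the FTS--Hook--FHIP family and
similar systems) connect cytoplasmic dynein to its cargos: label-free
scoring of proximity-labeling (BioID) interactomes from spectral counts,
classification and rate statistics for single-molecule motility traces,
and ROI-based organelle-accumulation and motile-tubule summaries from
live-cell imaging. Each stage ships with a seeded generator that
produces synthetic inputs with known ground truth, so the whole chain is
testable on any machine without external data. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot establish about real experiments.

## BioID interactome scoring

### From peptide counts to dNSAF

The raw quantity in spectral counting is the number of MS/MS spectra
assigned to each peptide in each replicate run. Peptides shared between
proteins must not be counted twice, so shared counts are *distributed*:
a peptide mapped to proteins $j \in S$ contributes to protein $k$ in a
replicate in proportion to $k$'s unique spectral count in that
replicate,

$$\mathrm{dSpC}_k \;=\; \mathrm{uSpC}_k \;+\;
  \sum_{\text{shared peptides}} \mathrm{sSpC}\,
  \frac{\mathrm{uSpC}_k}{\sum_{j \in S}\mathrm{uSpC}_j}.$$

When none of the sharing proteins has unique evidence in a replicate
the proportional weight is 0/0; the count is then split equally, the
only symmetric rule that still conserves totals. Distribution conserves
the per-replicate total count exactly (to floating tolerance), a
property the test suite asserts against a brute-force peptide-by-peptide
splitter on randomized instances.

Longer proteins produce more peptides at equal molar abundance, so the
distributed count is length-normalized and rescaled to a per-run
composition, the distributed normalized spectral abundance factor

$$\mathrm{dNSAF}_k = \frac{\mathrm{dSpC}_k / L_k}
  {\sum_j \mathrm{dSpC}_j / L_j},$$

with $L_k$ the protein length in amino acids. Each replicate column of
a `DnsafExperiment` therefore sums to 1 (or to 0 for an empty run), and
the value is invariant to rescaling all counts in one run -- the
normalization that makes runs comparable.

### Enrichment against the cytoplasmic control

For each protein the bait and control conditions are summarized by the
mean dNSAF over the replicates in which the protein was observed
(nonzero dNSAF); their ratio is the fold enrichment. A protein absent
from every control replicate but present in the bait has infinite fold,
which is preserved as `Inf` in the results (and in exported tables via a
documented sentinel) and capped only in the display column
`log2_fold` (default cap 10).

Significance comes from a two-tailed two-sample Student's t-test
(equal-variance; Welch available via `welch = TRUE`). By default the
vectors entering the test follow the same nonzero-replicates convention
as the averages, falling back to the full vector when a condition has
fewer than two nonzero replicates so the test is always defined. The
rationale: in spectral counting a zero usually means the protein was not
*identified* in that run, not that its abundance was measured as zero.
Treating those zeros as measurements inflates the within-group variance
so strongly that a single missing replicate makes an arbitrarily large
enrichment non-significant at $n = 4$ (the t statistic converges to
about 2.1 regardless of effect size). Both behaviours are exposed via
the `zeros` argument; the degenerate zero-variance limits are defined
explicitly (equal means give $p = 1$, different means $p = 0$, flagged
in the `degenerate` column). A Benjamini--Hochberg adjusted column is
emitted for information, but the hit verdict deliberately uses the raw
p value, matching standard practice for this assay.

### The three-part hit filter and intersections

`callHits()` declares a protein a hit when all of the following hold:

1. fold enrichment $\ge$ 3, or complete absence from the control;
2. $p < 0.05$;
3. nonzero dNSAF in at least 3 of 4 bait replicates.

All three thresholds are parameters. `intersectHits()` assigns each
protein in the union of several baits' hit lists to the exact subset of
baits that called it, producing the counts used in interaction diagrams;
the subsets partition the union, which the tests assert. Node and edge
tables for graph viewers round-trip losslessly through
`exportInteractionTables()` / `readInteractionNodes()`.

### The proteomics generator

`simulateSpectralCounts()` draws peptide counts as Poisson with a
protein-level rate proportional to abundance times length (about one
peptide per 60 residues, at least two per protein). This is the simplest
model reproducing the mean--variance behaviour spectral counting
assumes; real data are often overdispersed, so passing recovery tests
here demonstrates correctness of the pipeline, not performance on any
particular instrument. Defaults emulate the study design the pipeline
targets: 4 bait + 4 control technical replicates, 500 background
proteins, 20 planted interactors at 5-fold enrichment over a baseline of
10 expected counts, 10% shared peptides, and 10% per-replicate dropout
of interactors. Under these conditions the filter recovers planted
interactors with mean sensitivity above 0.9 at essentially zero
background false positives, and a null generator (enrichment factor 1)
keeps the background hit rate far below the nominal 5% -- the fold and
presence clauses only ever remove hits.

## Single-molecule motility

### Event taxonomy

A trace is the position of one particle along a microtubule sampled at
a fixed frame interval (default 0.4 s over 3 min movies). The
classification uses one length scale, 0.6 µm:

* **diffusive** -- the positions rise more than 0.6 µm above their
  running minimum *and* fall more than 0.6 µm below their running
  maximum (an excursion in each direction, anywhere in the trace);
* **processive** -- not diffusive, total displacement at least 0.6 µm
  (all opposing excursions are then necessarily at most 0.6 µm);
* **static** -- total displacement below 0.6 µm.

The running-extremum formulation is equivalent to enumerating all
ordered position pairs, which is exactly what the brute-force oracle in
the test suite does. Positions are used raw by default; an optional
odd-width running-mean smoothing window (`smoothWindow`) is available
but off, because smoothing interacts with the excursion threshold in
ways that should be the analyst's explicit choice.

### Segmentation, pauses, velocities

Manual kymograph annotation splits multivelocity events by eye; the
package replaces this with deterministic bottom-up change-point
merging: per-frame displacements start as single-interval segments,
adjacent segments whose mean velocities differ by less than
`velMergeThreshold` (0.2 µm/s) merge repeatedly, and segments shorter
than `minSegmentFrames` (3) are absorbed into the closer-velocity
neighbour. Absorption can make two halves of one pause adjacent again,
so the two passes alternate until stable. Segments tile the event span
exactly.

A segment is a **pause** when it spans at least `pauseMinFrames` (3)
intervals, its *median* per-frame step stays below `pauseDisplacement`
(0.1 µm, several times the localization error and well below a moving
particle's per-frame advance), and its overall speed is below
`pauseMaxVelocity` (0.15 µm/s). The median-step criterion is the robust
version of "the particle does not move": at frame resolution the
interval straddling a pause boundary mixes movement into the segment,
so a net-displacement criterion misses a substantial fraction of real
pauses, while the median ignores up to half contaminated intervals.
The velocity ceiling prevents steady slow movement from being mistaken
for a pause.

Segment velocities are slopes over the segment span, computed after
trimming one interval from each end of segments with at least five
intervals -- the trimmed intervals are the ones that can straddle a
change point. Velocity statistics include the absolute velocities of
non-pause segments from processive events, with the ">5 frames"
qualification applied both to the event span and to each segment,
since each segment of a multivelocity event is counted as its own
event and a slope over fewer frames is dominated by localization error.

Summary statistics follow the field's definitions: the **landing rate**
counts processive events that start after the first and end before the
last movie frame, divided by microtubule length times movie time;
**run length** is the summed magnitude of segment displacements of a
processive event; **pausing frequency** is total pauses in
multivelocity events divided by total run length; an event is
**colocalized** when the second channel is present on at least one of
its samples. Two-condition comparisons use Welch's t-test or the
Mann--Whitney test (normal approximation with tie and continuity
corrections), both checked against independently coded references.

### The trace generator

`simulateTraces()` lands events along each filament as a Poisson
process (`landing_rate_true`, default 0.003 events µm⁻¹ s⁻¹ on 12 µm
microtubules over 50 movies, giving roughly 300 events). Processive
events draw a velocity from a normal distribution (0.8 ± 0.08 µm/s), a
run length of at least 1 µm (exponential beyond the minimum, mean
4 µm, truncated at the filament end; the landing position is drawn so
the run fits on the filament), and pause sites along the run from a
stationary hard-core renewal process at exactly `pause_rate_true` per
µm (default 0.2) with 1 µm minimum spacing -- two stops closer than the
frame-resolvable movement scale are a single pause to any analyzer, so
unspaced sites would make the nominal rate unrecoverable by
construction. Pause durations are Gamma distributed (shape 6, mean
4 s), which keeps essentially all pauses resolvable at the 0.4 s frame
interval. Localization noise (0.02 µm) is added per frame. Diffusive
and static landings can be enabled through the class fractions; they
default to 0 because the assay regime the defaults describe --
activated motor complexes in vitro -- produces almost exclusively
processive landings, and because the landing-rate recovery property
compares the analyzer's processive count to the total landing rate.

Under the default conditions the analyzer recovers the median velocity
within a few percent, the landing rate within two Poisson standard
errors (the residual deficit comes from events still running at the
movie's end, which the estimator by definition excludes), and the
pausing frequency within 15%. The generator's ground-truth log records
every emitted event, and events visible for fewer than two frames are
dropped from both the log and the trace table, keeping the two in
exact correspondence.

What the generator does not emulate: photobleaching, stage drift
(excluded movies in real analyses), intensity-dependent localization
error, motor back-stepping, or crowding on the filament. Recovery under
the generator therefore validates the estimators' logic, not their
robustness to every optical artefact.

## Imaging quantification

### Centrosome accumulation

For each cell the accumulation statistic is the fraction of total
fluorescence inside the centrosome ROI divided by the fraction of the
cell's area that the ROI occupies:

$$R \;=\; \frac{I_c / I_w}{A_c / A_w}.$$

$R = 1$ means uniform fluorescence; the statistic is invariant to
global intensity rescaling and to the area unit. ROI geometry (the
circle around the brightest centrosomal punctum, the whole-cell
membrane mask) is upstream image analysis; this module starts from the
measured sums, which is where the arithmetic begins. No background
subtraction is applied by default, matching the assay's convention; a
constant per-area offset is available as a parameter. The generator
plants a known ratio with mean-one lognormal noise and clips to the
whole-cell total, so noiseless fixtures recover the planted value
exactly and noisy ones recover it within sampling error.

### Motile tubules

A tracked tubule counts as motile when it moved from its initial
location *and* exceeded 1 µm length at some point; per-cell counts feed
the percentage of cells with more than five motile tubules (strict
inequality), with optional per-replicate percentages for mean ± SEM
reporting. Track linking across frames is assumed done upstream.

### Multi-group statistics

Group comparisons of accumulation ratios and tubule counts use the
Kruskal--Wallis omnibus test followed by Dunn's pairwise z tests on the
pooled ranks with the tie-corrected variance; the assay this package
models names Dunn's test without naming the multiplicity correction, so
a Bonferroni-style adjustment over the tested pairs is the default and
the adjustment method is a parameter. No installed package provides
Dunn's test, so the z statistics are computed directly from their
closed form and verified against an independently written reference in
the tests.

## Numerical and design choices, in brief

* Frames are 0-based integer indices; segment spans are half-open.
* Conservation and normalization invariants are asserted at 1e-9;
  agreement with reference statistics at 1e-6 relative.
* Ties in the proportional count split (no unique evidence) are split
  equally; ties in segment absorption go to the closer-velocity
  neighbour, the left one first.
* Reported velocities are magnitudes; the position axis increases
  toward the microtubule minus end so dynein-direction velocities are
  positive.
* The t-test's zero-variance limits are defined rather than erroring,
  because control proteins absent everywhere are routine.
* All generators take an explicit integer seed and are byte-identical
  under the same configuration and seed; they restore the caller's RNG
  state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the study-scale defaults:
20 generator seeds for the interactome recovery and null calibration
(520 proteins, 4+4 replicates each), one 50-movie motility simulation
(~300 events), randomized property checks (100 instances for count
distribution, 500 traces against the classification oracle, 1,000
filter rows, 100 datasets per statistical test), and 55--240 cells for
the imaging summaries. These sizes keep the whole suite under a few
minutes on one CPU while leaving the recovery tolerances meaningful.

## Known limitations

* The Poisson count model understates real MS run-to-run variability;
  sensitivity figures from the generator are upper bounds.
* The enrichment t-test on 4+4 replicates has limited power for weakly
  enriched proteins regardless of implementation.
* Change-point segmentation with a single velocity-difference threshold
  cannot separate velocities closer than that threshold, and pause
  detection below three frames is impossible by definition.
* The excursion taxonomy interprets ">0.6 µm in each direction"
  anywhere in the trace; a stricter single-excursion-pair reading would
  classify some borderline traces processive instead of diffusive.
* The ROI statistic assumes the centrosome ROI is fully contained in
  the whole-cell ROI and inherits any upstream segmentation errors.
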