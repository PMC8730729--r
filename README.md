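# cargoQuant

Quantification toolkit for motor cargo-adaptor studies: the three
analysis chains used to characterize how adaptor complexes (such as the
FTS–Hook–FHIP family) link cytoplasmic dynein to its cargos.

1. **BioID interactome scoring** — from peptide-level spectral counts to
   distributed normalized spectral abundance factors (dNSAF), fold
   enrichment against a cytoplasmic control, a three-part hit filter,
   and multi-bait hit intersections.
2. **Single-molecule motility** — classification of kymograph traces
   into processive / diffusive / static events by the 600-nm excursion
   rule, change-point segmentation of multivelocity runs, and velocity,
   run-length, landing-rate, pausing-frequency, and colocalization
   statistics with Welch / Mann–Whitney comparisons.
3. **Imaging quantification** — area-normalized centrosome-accumulation
   ratios, motile-tubule counting, and Kruskal–Wallis/Dunn multi-group
   statistics.

Every stage has a seeded synthetic-data generator with known ground
truth, so the full pipeline is testable end to end with no external
data.

## The statistics at the core

Counts of peptides shared between proteins are distributed in
proportion to each protein's unique evidence, then length-normalized
into a per-run composition:

```
dSpC_k  = uSpC_k + Σ_shared sSpC · uSpC_k / Σ_j uSpC_j
dNSAF_k = (dSpC_k / L_k) / Σ_j (dSpC_j / L_j)
```

A protein is an interactome hit when its bait/control ratio of average
dNSAF (averaged over nonzero replicates) is ≥ 3 — or the protein is
absent from the control — **and** the two-tailed Student's t-test gives
p < 0.05 **and** the protein appears in ≥ 3 of 4 bait replicates.

Motility events are diffusive if the trace makes a >0.6 µm excursion in
each direction, processive if net movement reaches 0.6 µm with no
larger opposing excursion, static otherwise. Landing rate counts
complete interior processive events per µm of microtubule per second;
pausing frequency is pauses per µm of run length.

The centrosome accumulation ratio is
`(I_centrosome / I_cell) / (A_centrosome / A_cell)`, exactly 1 for
uniform fluorescence.

## Worked example

```r
library(cargoQuant)

## simulate a 4+4-replicate BioID design with 8 planted interactors
sim <- simulateSpectralCounts(proteomeSimConfig(
  n_background_proteins = 120, n_true_interactors = 8, seed = 42))
se  <- dnsafExperiment(sim$peptides, sim$proteins)
res <- callHits(enrichmentTest(se, "bait", "control"), verbose = TRUE)
#> 128 proteins: 8 pass fold/absence, 28 pass p < 0.05,
#> 128 pass presence >= 3; 8 hits

head(as.data.frame(res[res$is_hit, c("protein_id", "fold_enrichment",
                                     "p_value", "n_present_bait")]), 4)
#>   protein_id fold_enrichment  p_value n_present_bait
#> 1     INT001            3.58 4.48e-05              4
#> 2     INT002            3.64 1.21e-05              4
#> 3     INT003            3.67 1.18e-05              4
#> 4     INT004            3.29 5.13e-05              4

sum(sim$truth %in% res$protein_id[res$is_hit])   # 8 of 8 recovered
```

The hit table reads as in any label-free interactome study: `INT001`
is 3.6-fold enriched over the cytoplasmic control at p = 4e-05 and was
identified in all four bait replicates, so it passes all three filter
clauses.

```r
## single-molecule motility on simulated 3-minute movies
tr <- simulateTraces(motilitySimConfig(n_movies = 10, seed = 42))
ev <- classifyEvents(tr$traces, frameInterval = 0.4,
                     nFrames = tr$movies$n_frames[1])
su <- motilitySummary(ev, mtLength = 12 * 10, movieDuration = 180)
#> n processive 59 | median velocity 0.81 um/s |
#> landing rate 2.69e-03 /um/s | pausing 0.19 /um | coloc 0.49
```

The generator planted 0.8 µm/s runs landing at 0.003 events µm⁻¹ s⁻¹
with 0.2 pauses/µm and 50% two-color colocalization; the summary
recovers each of them.

## Documentation

`vignettes/cargoQuant-methods.Rmd` documents the models, parameter
defaults and their rationale, the numerical choices (tie rules,
degenerate cases, tolerances), what the synthetic generators do and do
not emulate, and known limitations.
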