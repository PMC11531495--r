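# punctapulse

Quantitative analysis of oncogenic protein condensates and their
signaling consequences in live-cell fluorescence microscopy.

Fusion kinases such as EML4-ALK form cytoplasmic condensates (bright
puncta over diffuse background) that sequester shared RTK adapter
proteins like GRB2 and SOS1. Sequestration blunts signaling from
transmembrane receptors; inhibiting the fusion kinase releases the
adapters — they dissociate from the condensates with an exponential
half-life and translocate to the membrane again on growth-factor
stimulation — and resensitizes cells to paracrine ligands, visible as
transient ERK pulses in kinase-translocation-reporter (KTR) imaging,
concentrated around dying neighbor cells.

`punctapulse` is an R package for the analyses this biology requires,
for imaging labs and computational biologists working from per-cell
label masks and tracked single-cell traces:

- **Puncta detection**, per cell: intensities normalized to the cell
  median, enhanced by Gaussian → white top-hat → negated
  Laplacian-of-Gaussian, seeded at thresholded local maxima, and grown
  iteratively at a threshold of `growth_scale × local background`
  (background recomputed as puncta are claimed). Two-channel
  **colocalization** as the per-cell fraction of channel-A puncta whose
  pixels overlap a channel-B punctum.
- **Membrane translocation**: membrane localization
  `ML = mean(edge) / mean(core)` with the edge a fixed-width ring
  (default 10 px) inside the cell boundary; translocation
  `ΔML = ML(post) − ML(pre)` at a fixed post-stimulus time (default
  1.5 min); suppression `1 − median(oncogene)/median(wt)` with
  quartiles from 1000 seeded bootstrap resamples.
- **ERK pulse calling** from cytoplasmic/nuclear KTR ratio traces:
  expression QC, topographic-prominence peak detection, exclusion of
  division-proximal artifact pulses (10 frames = 50 min before
  division), truncation at death, and lineage deduplication so a
  parent's pulses are counted once even though divided cells carry
  copied history.
- **Death-neighborhood enrichment**: neighbors are cells within 100 px
  of a dying cell during the 10 pre-death frames; each event gets a
  count-matched random control group drawn from cells that neighbor no
  death over the same span; groups are compared with a one-sided
  bootstrap median test.
- **Statistics & kinetics**: bootstrap difference-of-medians test
  (`p = (1 + #[stat* ≤ 0]) / (n_boot + 1)`), Wilson proportion
  intervals, and dissociation half-life fits
  `I(t) = offset + amplitude · 2^(−t/t½)` with bootstrap SE.
- A **synthetic-data module** that generates puncta scenes,
  pre/post-stimulation image pairs, 22-h KTR datasets (5-min frames,
  10–20 min pulses, divisions, deaths, spatially elevated pulse rates
  near deaths) and decay traces — all with ground truth and
  byte-reproducible under a single seed — so every stage is testable
  without any external data.

## Worked example

```r
library(punctapulse)

## condensates and colocalization on a synthetic two-channel scene
scene    <- simulate_puncta_scene(puncta_scene_config(seed = 7))
puncta_a <- detect_puncta(scene$channel_a)
puncta_b <- detect_puncta(scene$channel_b)
puncta_a
#> <puncta_set> 45 puncta in 9 cells
head(coloc_fraction(puncta_a, puncta_b), 3)
#>   cell_id n_puncta_a n_overlapping coloc_fraction
#> 1       1          5             4            0.8
#> 2       2          5             4            0.8
#> 3       3          5             4            0.8

## ERK pulses in a 22-h KTR dataset (250 founder cells, 5-min frames)
sim <- simulate_ktr_dataset(ktr_sim_config(seed = 11))
pulses_per_cell(sim$traces, pulse_params(), lineage = sim$truth$lineage)
#> <pulse_summary> 688 pulses in 282 of 317 QC-passing cells (89.0% pulsing)

## are pulses enriched near dying cells?
traces_qc <- qc_filter(sim$traces, 100)$traces
pulses    <- detect_pulses_all(traces_qc, pulse_params())
asg       <- sample_controls(find_neighbors_all(traces_qc), traces_qc,
                             seed = 1)
pulse_enrichment(asg, pulses, seed = 1)
#> <neighbor_summary> 95 events
#>   median pulses/cell: neighbors 0.364, random 0.000
#>   fraction pulsing: neighbors 0.340, random 0.077
#>   one-sided bootstrap p (neighbor > random): 0.0010

## adapter dissociation kinetics after kinase inhibition
decay <- simulate_decay_traces(decay_sim_config(seed = 3))
fit_dissociation(decay, seed = 1)
#> <half_life_fit> t1/2 = 16.82 +/- 0.47 min (k = 0.0412 /min,
#>   offset = 0.206, amplitude = 0.997, rmse = 0.013, n = 20 traces)
```

The detector recovers all 45 planted puncta; the per-cell
colocalization matches the scene's configured 0.8; the enrichment
summary shows the spatial signal the generator planted (neighbors of
dying cells pulse, random controls mostly do not); and the half-life
fit recovers the generating 17-min half-life within its bootstrap SE.

## Package layout

- `R/synthetic.R` — generators with ground truth
- `R/puncta.R`, `R/labeled_image.R` — condensate detection and the
  image container
- `R/translocation.R` — ring partition, membrane localization,
  suppression
- `R/ktr_pulses.R` — QC, prominence peaks, exclusion, deduplication
- `R/neighbors.R` — death events, neighbor sets, controls, enrichment
- `R/stats_kinetics.R` — bootstrap test, Wilson CI, half-life fit
- `vignettes/punctapulse-methods.Rmd` — full methods description,
  parameter rationale, and limitations
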