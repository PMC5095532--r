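# macactivate

Computational pipelines for discovering and characterizing candidate
regulators of macrophage activation, built around four analyses:

1. **TMT time-course proteomics screen** — macrophages stimulated with
   IFNγ (pro-inflammatory, `M(IFNg)`) or IL-4 (anti-inflammatory,
   `M(IL-4)`) are profiled by 6-plex tandem-mass-tag proteomics over
   0–72 h alongside an unstimulated control `M(-)`. The screen looks for
   proteins that rise early and stay up under IFNγ while falling under
   IL-4, beyond the envelope of control drift.
2. **Network proximity** — a two-gene seed module (the expressed first
   neighbours of a gene pair such as PARP9–PARP14 in a functional
   interaction network) is tested for shortest-path proximity to disease
   modules built by random walk with restart, against size-matched random
   gene sets with Benjamini–Hochberg correction.
3. **Single-cell qPCR pipeline** — 96.96 dynamic-array Ct matrices are
   cleaned (per-gene missing-value rules, limit-of-detection transform,
   housekeeping QC, Winsorization), z-scored, and clustered (Manhattan
   distances, minimum spanning tree, Ward linkage) to resolve cell
   subpopulations.
4. **ADP-ribosylation occupancy** — MS/MS spectra are screened for the
   ADP-ribose marker ion (m/z 348.1), unmodified precursor targets are
   computed by subtracting the ADP-ribose mass (541.06 Da) on the neutral
   scale, and site occupancy is quantified from extracted-ion-chromatogram
   areas.

Every stage has a matching synthetic-data generator with known ground
truth, so the whole package is testable end to end without any external
downloads.

## Core quantities

* PSM reference normalization and rollup: for reporter intensities
  `x_1 ... x_6` (time zero first), the protein's abundance at time *i* is
  `log10(median_PSMs(x_i / x_1))`, so the time-zero column is identically 0.
* Baseline band: `upper = max` (and `lower = min`) of control log10
  abundance at the 8 h anchor; a maximum control fold change of 1.35 gives
  the `+0.13` log10 screening threshold.
* Random walk with restart: `p ← (1 − r) W p + r p0` with `W` the
  column-normalized adjacency matrix, restart probability `r = 0.5`.
* Proximity: per seed-module gene `g`, `d(g) = min` shortest-path distance
  to the disease module; significance is the one-sided rank-sum statistic
  of the observed distances referred to `n_random` size-matched random
  draws.
* Limit-of-detection transform: `log2exp = max(0, LOD − Ct)` with
  `LOD = 24`; undetected reads (sentinel 999) map to 0.
* Site occupancy: `AUC_mod / (AUC_mod + AUC_unmod)`.

## Worked example

```r
library(macactivate)

cfg <- tmt_sim_config(n_candidate_proteins = 5, n_background_proteins = 50,
                      rng_seed = 42)
sim  <- simulate_tmt_experiment(cfg)
roll <- lapply(sim$psms, rollup_proteins)
band <- derive_baseline_band(roll[["M(-)"]])
#> baseline band: [-0.081, 0.103] log10
filter_candidates(roll[["M(IFNg)"]], roll[["M(IL-4)"]], band)
#>   protein method species
#> 1 CAND001  filter    <NA>
#> ...
#> 5 CAND005  filter    <NA>
round(roll[["M(IFNg)"]]$log10_abundance["CAND001", ], 3)
#>     0     8    12    24    48    72
#> 0.000 0.178 0.170 0.265 0.291 0.297
```

All five planted regulators (and no background protein) pass the filter:
their IFNγ profiles exceed the control envelope (+0.103 here) by 24 h and
stay above it, while their IL-4 profiles drop below the lower edge.

```r
net <- simulate_interactome(net_sim_config(rng_seed = 42))
mod <- build_seed_module(net$network, net$seeds, net$expressed)
#> seed module: 36 expressed first neighbours (15 + 30)
res <- adjust_pvalues(lapply(net$disease_modules, function(d)
  proximity_test(net$network, mod, d, n_random = 1000, rng_seed = 1)))
#> proximal: mean d = 1.33, adj p = 0.0080
#> distal:   mean d = 4.6-4.9, adj p = 1.0000
occupancy(3.2e6, 1.1e6)
#>   auc_mod auc_unmod occupancy
#> 1 3200000   1100000  0.744186
```

The planted proximal disease module is called significantly close to the
seed module while the three distal modules are not.

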