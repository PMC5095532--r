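---
title: "Methods: macrophage-activation screening pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macrophage-activation screening pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macactivate)
```

# Setting

Macrophages polarize along a spectrum between pro-inflammatory
(IFNγ-driven, `M(IFNg)`) and anti-inflammatory (IL-4-driven, `M(IL-4)`)
activation states; molecules that rise during IFNγ activation and fall
during IL-4 activation are candidate regulators of that balance (the
PARP9–PARP14 pair being the motivating example). `macactivate` implements
the four computational analyses used to find and characterize such
regulators, plus synthetic-data generators with ground truth so each stage
can be validated end to end. This vignette records the models, the
parameters that matter, and the design decisions taken where the
underlying procedures left genuine freedom.

# TMT time-course screen

## Normalization and rollup

Each peptide-spectrum match (PSM) carries six reporter intensities, one
per time point (0, 8, 12, 24, 48, 72 h). Intensities are normalized to
the time-zero channel (`x_i / x_1`), a protein's abundance per time point
is the median of its PSM ratios, and results are stored as log10 ratios,
making the time-zero column identically zero. Only proteins supported by
at least two distinct unique-to-group peptides are quantified
(`min_unique_peptides = 2`). PSMs with a non-positive reference intensity
cannot be normalized and are dropped with a warning. The rollup is
scale-invariant: multiplying all channels of a PSM by a positive constant
leaves its ratios unchanged.

## Baseline band and Method 1 filter

The unstimulated control defines a drift envelope: the band's upper edge
is the maximum control log10 abundance at the 8 h anchor (a maximum
control fold change of 1.35 reproduces the familiar +0.13 threshold), and
can be overridden with a fixed value. Only the upper edge has a canonical
published value; for the lower edge we default to the minimum control
abundance at the anchor time, with a symmetric `-upper` option
(`lower = "symmetric"`), since screening IL-4 profiles requires a lower
bound and neither choice is canonical.

A candidate must (1) exceed the upper edge at some time point within the
early window (default 24 h), (2) remain above it at *every* sampled time
from `sustain_from` (default 24 h) through 72 h — our operationalization
of "an early increase followed by sustained levels" — and (3) fall below
the lower edge at some time point in `M(IL-4)`. A per-protein control
containment check (the protein's own control profile inside the band at
all times) is available via the `control` argument but off by default:
the band itself already summarizes the control data set, and the explicit
per-protein check mostly removes true candidates whose control profiles
drift transiently. Thresholds are applied per time point, not to profile
maxima.

## Method 2: model-based clustering

Profiles are converted back to the linear ratio scale and sum-normalized
(each profile scaled to unit mass across time points) so that the shape,
not the overall abundance, drives the fit; this also removes the
degenerate constant time-zero column. Gaussian mixtures are fitted by EM
for each candidate cluster count (default `K_range = 1:9`) and the count
is chosen by BIC, via `mclust`. We default to the diagonal covariance
family (`EII`, `VII`, `EEI`, `VEI`, `EVI`, `VVI`): with six-dimensional
profiles and modest protein counts, full covariances are poorly
conditioned; they can be requested through `model_names`. Identical
profiles (no structure at all) short-circuit to a single cluster, since
EM cannot fit zero-variance components.

Cluster trend labels operationalize visual inspection: a cluster
"increases" if its mean log10 profile exceeds `tol` at any time point,
"decreases" if it goes below `-tol`, and is "within band" if the mean
stays inside the baseline band. `tol = 0` by default (any excursion
counts, which the zero-noise calibration requires); with noisy data a
small dead zone such as `tol = 0.02` avoids labelling near-flat clusters
as trending. A protein is selected when its `M(IFNg)` cluster increases,
its `M(IL-4)` cluster decreases, and its `M(-)` cluster stays within the
band.

## Cross-species intersection and heat maps

Candidates found in both a mouse and a human screen are prioritized.
Accession-level identity cannot hold across species, so matching is by
uppercased gene symbol by default, with an explicit two-column orthology
map supported. Heat-map matrices are row z-scores
(`z = (x - mean) / sd`), with rows ordered by the leaf order of an
average-linkage tree on Euclidean distances; constant rows get z-scores
of zero with a warning.

# Network proximity

## Random walk with restart and modules

Disease modules are built from gene–disease association seeds by random
walk with restart on the functional network:
`p ← (1 − r) W p + r p0`, with `W` the column-normalized adjacency matrix
and `p0` uniform over the seeds. Defaults `restart_prob = 0.5` and
`tol = 1e-10` (L1) are conventional for gene prioritization; the walk is
unweighted by default with a `weighted` option. A module of size `s`
takes the association genes first (ranked by walk score) and then the
top-ranked novel genes, which makes modules nested across sizes. The seed
module is the union of the first neighbours of the two seed genes,
restricted to the macrophage-expressed gene list.

## Distances and the null

Proximity uses unweighted shortest paths (the reported distances are
small integers, and functional-association weights have no metric
interpretation): for each seed-module gene, its distance is the minimum
over disease-module genes, and the observed statistic summarizes that
per-gene distance vector. Unreachable genes are excluded from the mean
and reported as a count, since a single infinite distance would otherwise
dominate.

The null redraws `n_random` (default 1000) gene sets of the disease
module's size. Two samplers are provided: `"uniform"` node sets (default)
and `"connected"` random subgraphs grown by frontier sampling, for the
view that disease modules form connected components. The uniform sampler
is the default because it is the exchangeable counterpart of how
unrelated (distal) gene sets arise, and its calibration can be verified
directly.

## Significance: why the empirical rank-sum

The per-gene distances of a single draw are strongly positively
correlated — if a random gene set lands near a hub, *all* seed-module
genes get smaller distances at once. A plain rank-sum test of the
observed distances against the pooled null distances treats those values
as independent and is therefore anticonservative; in our calibration
experiments it rejected at roughly 3–4 times the nominal rate. The
default (`p_method = "empirical"`) therefore computes the Wilcoxon
rank-sum statistic of every draw (observed and null) against the pooled
distances and reports the empirical rank of the observed statistic among
the null statistics, `p = (1 + #{U_b <= U_obs}) / (1 + n_random)`. This
is exactly calibrated under exchangeability — the package's tests verify
that null p-values are approximately uniform — and its resolution is
`1 / (n_random + 1)`. The pooled asymptotic p-value remains available as
`p_method = "asymptotic"` for comparison. Benjamini–Hochberg correction
is applied across all disease modules tested in one batch.

# Single-cell qPCR pipeline

## Missing values and the LOD transform

Raw 96.96 arrays are cells × genes Ct matrices with 999 marking
undetected reads. Per gene column: if fewer than 10% of reads are
positive (Ct < 25), the whole gene is undetectable for that array and set
to 999; otherwise 999 entries are imputed with the mean of the positive
reads. The rule is idempotent. Expression is
`log2exp = max(0, LOD − Ct)` with `LOD = 24`, the platform's recommended
default — one cycle below the limit of detection equals one doubling.
Note the deliberate composition of the two rules: reads with
24 ≤ Ct < 25 count as "positive" for detectability yet transform to zero
expression. We preserve this exactly rather than harmonizing the two
cutoffs, because the two rules serve different purposes (detectability vs
quantification).

## QC, Winsorization, z-scores

Cells without housekeeping (GAPDH) expression are removed; then cells
whose GAPDH log2exp deviates from the retained-cell mean by more than 3
s.d. The s.d. rule is literal — a cell that merely looks extreme but sits
within 3 s.d. is kept. Transcriptional-burst extremes are contained by
per-gene Winsorization at the 5th/95th percentiles (linear interpolation
between order statistics, `type = 7`; the convention is configurable
because software disagrees and none was canonical). Genes are z-scored
with the sample s.d. (n − 1) over the combined matrix of the arrays under
comparison; per-array standardization is possible by calling the pipeline
per array.

## Geometry: Manhattan map, Euclidean Ward

Cell similarity maps use Manhattan distances and their minimum spanning
tree (Prim's algorithm on the dense matrix, ties broken by smallest index
pair for determinism). Cluster assignments use Ward's minimum-variance
criterion, which presumes Euclidean geometry, so `ward_cluster` operates
on Euclidean distances of the z-score matrix (`ward.D2`) by default while
accepting a precomputed distance object for the Manhattan variant. This
dual use — Manhattan for the visual map, Ward/Euclidean for the cut — is
intentional. A chosen cluster can be recursively subdivided
(`subdivide_cluster`), mirroring the two-stage discovery of subgroups
within the stimulated-cell cluster. Group comparisons use a two-sample
t-test per gene, with an F test deciding between the pooled and Welch
forms; gene–gene association is Pearson correlation by default (Spearman
optional), with zero-variance genes flagged and set to 0.

# ADP-ribosylation occupancy

Candidate ribosylated spectra are flagged by the m/z 348.1 marker ion.
Matching uses a ppm tolerance (default 20 ppm) rather than a fixed Da
window because the relevant instruments are high-resolution; the
tolerance is a parameter. The unmodified counterpart of a modified
precursor subtracts the ADP-ribose mass (541.06 Da) on the *neutral*
scale, converted by charge (`mz − 541.06 / z`), which avoids the common
off-by-proton error. Inclusion lists carry both forms with their
retention-time windows, merged on duplicates and sorted. Occupancy is
`AUC_mod / (AUC_mod + AUC_unmod)`; chromatographic peak integration
itself is out of scope — areas are consumed as inputs.

# Synthetic data: what it emulates, and what it does not

All generators take one integer seed, route their randomness through a
seed-preserving wrapper, and are byte-reproducible.

* **TMT** (`tmt_sim_config`): planted candidates rise linearly to the
  full effect at 24 h and stay there (mirror-image fall under IL-4);
  every protein drifts with per-time Gaussian noise on the log10 scale,
  and PSMs add independent reporter noise. Defaults — effect 0.3, drift
  s.d. 0.03, PSM noise s.d. 0.05, 3 PSMs/protein, 10 candidates over 100
  background — are the screen's working regime: an effect roughly 3×
  the band width, realistic for a strongly induced protein. Not
  emulated: isotope-impurity crosstalk between reporter channels,
  missing channels, fraction effects, or shared peptides.
* **Interactome** (`net_sim_config`): a preferential-attachment graph
  (n = 3000, one edge per new node) gives the heavy-tailed degree
  structure of functional networks while keeping shortest-path distances
  spread enough to be informative at this order; two seed genes have
  their degrees topped up to 15 and 30 neighbours. The proximal disease
  module is sampled within `proximal_radius` (default 1) of the seed
  neighbour set — i.e. inside its 2-neighbourhood — and distal modules
  uniformly from nodes farther than distance 2 from every neighbour;
  80% of genes are marked expressed. Not emulated: edge weights,
  confidence tiers, or modular community structure.
* **Ct arrays** (`ct_sim_config`): three donors × 96 cells × 96 genes;
  two planted subpopulations separated by 4 log2exp on a 20-gene block
  (Ct noise s.d. 0.5); per-entry missing-completely-at-random dropout at
  rate 0.2 (per-gene rates accepted, so both branches of the
  missing-value rule can be exercised); GAPDH at 12 log2exp with a small
  number of outlier cells shifted +8 Ct. Not emulated: dropout that
  depends on expression level, amplification failure patterns, or
  donor batch effects.
* **Occupancy pairs**: neutral masses 800–2500 Da, charges 2–3, AUC
  totals split exactly by the planted occupancy, with optional
  multiplicative noise.

Because the generators are idealized in these ways, passing recovery
tests demonstrates that the pipeline logic is correct and calibrated
under its stated assumptions — not that real arrays or spectra meet those
assumptions.

# Numerical choices and degenerate inputs

* EM: `mclust` defaults (model-based hierarchical initialization,
  log-likelihood tolerance `1e-5`); non-converging cluster counts are
  skipped with a warning, and an all-identical profile matrix returns
  K = 1 directly.
* Random walk: L1 tolerance `1e-10`, iteration cap 10,000; isolated
  nodes get a self-normalizing column so the operator stays stochastic.
* MST and hierarchical merges break ties deterministically (smallest
  index pair / `hclust` conventions).
* Degenerate proximity nulls (all distances identical) return p = 1 with
  a warning; both-zero AUC pairs return `NA` occupancy with a warning;
  constant genes/rows z-score to 0 with a flag.

# Problem sizes

The validation suite and the acceptance script use 20 simulation
replicates per recovery statement, 200 null draws per calibration
p-value (1000 for the power runs), 110-protein TMT experiments, a
3000-gene interactome, and 3 × 96 × 96 Ct arrays. These sizes give
stable recovery statistics (binomial s.e. below 2 percentage points on
calibration fractions) while keeping a full run in the order of a minute.

# Known limitations

* The mixture-model path labels whole clusters, so its candidate set is
  deliberately a superset of the planted truth when clusters are coarse;
  specificity comes from the intersection with the filter path and the
  cross-species step.
* The empirical proximity p-value cannot go below `1 / (n_random + 1)`;
  very small p-values require more draws.
* Symbol-level orthology ignores paralog splits and many-to-many
  mappings; supply an explicit map where that matters.
* The single-cell pipeline assumes one housekeeping gene; multi-gene QC
  panels would need a straightforward extension.
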