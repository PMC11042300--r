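---
title: "Measuring meiotic DSB end resection: models and methods in resectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic DSB end resection: models and methods in resectr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectr)
```

## The biological problem

Meiotic recombination in budding yeast begins with programmed DNA
double-strand breaks (DSBs) made by Spo11 at hotspots — short intervals,
mostly promoter nucleosome-depleted regions (NDRs), flanked by positioned
nucleosome arrays. Each DSB end is resected 5'→3' in two steps: the
Mre11–Rad50–Xrs2 complex with Sae2 (MRX/Sae2) nicks near the break, then the
processive exonuclease Exo1 extends digestion away from it, producing the 3'
single-stranded tails that drive homology search. Because Exo1 is strongly
blocked by nucleosomes in vitro, chromatin remodeling is thought to clear its
path; the SWI/SNF-family ATPase Fun30 plays this role in meiosis.

resectr implements the computational side of this analysis: strand-specific
endpoint maps (S1-seq), hotspot-anchored resection tract-length estimation,
nucleosome-anchored metaprofiles and clustering of resection patterns against
MNase-seq chromatin structure, spike-in calibrated ChIP-seq comparisons, and
a mixture model of tetrad spore viability. A seeded synthetic-data generator
provides ground-truthed inputs for every stage.

## Signal tracks and coordinates

All genomic signal lives in a `strand_track`: per-chromosome numeric vectors
at 1-bp resolution, either a top/bottom strand pair or a single unstranded
vector. Every coordinate in the package — internal, bedGraph, BED, hotspot
TSV — is 0-based and half-open, the bedGraph convention. Top-strand signal at
a hotspot represents rightward-moving resection endpoints, bottom-strand
signal leftward ones; "co-orienting" means reading the right flank off the
top strand and the reversed left flank off the bottom strand, so that index
*d* always means "*d* bp from the hotspot midpoint, moving away from the
DSB".

Track curation mirrors the standard pipeline: masking (chromosome ends,
DSB-independent signal) with `apply_mask()`, then `normalize_rpm()` to reads
per million *remaining* reads. Masked positions are zeroed before the
denominator is computed, so they are excluded from the RPM total; the
package enforces the mask-then-normalize order and normalization is
idempotent. Replicates are averaged position-wise after normalization.

## Tract lengths and censored medians

Resection tract lengths are measured at "loner" hotspots — by default
narrower than 400 bp with no other hotspot within 3 kb — so that signal at a
given distance can be attributed to the anchoring hotspot. Separation is
measured edge-to-edge between hotspot intervals (the conservative choice
against signal bleed-in; midpoint-to-midpoint is available via `by =
"midpoint"`). The two oriented flanks of each loner are pooled into a
weighted distance distribution (`tract_length_distribution()`, default flank
3 kb, matching the isolation radius), distances taken from the hotspot
midpoint because the per-molecule DSB position is unobservable.

Medians are *lower weighted medians*: the smallest distance at which
cumulative weight reaches half the total. No interpolation is attempted —
with tens of thousands of 1-bp-resolution endpoints the difference is
sub-nucleotide, and the lower-median convention makes results exactly
reproducible. `pooled_median()` sums distributions position-wise before
taking the median (a pooled median, not a median of medians), and conserves
total weight.

Censoring bounds default to `[40, 2000]` nt. The lower bound excludes
endpoints inside the hotspot NDR itself, which are dominated by unresected
or aberrant species rather than genuine tracts; the upper bound caps the far
tail at 2 kb, beyond the longest biologically plausible tracts
(~700–1200 nt). Censoring over bounds that cover the whole support
reproduces the uncensored median exactly, and in practice censoring moves
pooled medians by well under 1%.

Hotspot sides are weighted equally in genome averages and pooled
distributions, not by hotspot heat: heat weighting would let a handful of
very hot hotspots dominate the landscape. `weight_by_heat = TRUE` is
available in `coorient_average()` for sensitivity checks.

## Smoothing kernels

Genome-average profiles are smoothed with a Hann (raised-cosine) window —
100 bp for co-oriented landscapes, 41 bp for nucleosome-anchored
metaprofiles — and calibrated ChIP maps with a 1-kb Parzen (triangular)
window. Kernels are symmetric and unit-sum; the effective kernel length is
`window + 1` points when `window` is even (a "100-bp window" is the usual
odd 101-point kernel) and `window` when odd (a 41-bp window has 41 points),
so kernels are always odd and centered. At vector edges, and next to missing
positions, the truncated kernel is renormalized over the available support;
consequently interior-supported signal is conserved to numerical precision
and missing positions neither vanish nor leak. Convolution is computed by
FFT, which agrees with direct convolution to better than 1e-9.

## Nucleosome-anchored analysis and clustering

`anchored_average()` averages oriented windows around arbitrary anchors
(nucleosome midpoints, hotspot midpoints, axis-factor peaks, random
controls). `region_percentages()` quantifies an anchored profile over a
contiguous region scheme — for example an NDR at offsets −219..−74 and a +1
nucleosome at −73..+73 relative to the +1 midpoint — expressing each region
as a percentage of a chosen reference total.

For clustering, each sufficiently isolated hotspot (no neighbor within 1 kb;
no width filter) contributes two rows: the raw 1-kb, 1-bp-resolution signal
right of the midpoint (top strand) and left of it (bottom strand, reversed).
Each row has its minimum subtracted — the lowest signal in the profile,
taken as that profile's background — and is divided by its total, so
clustering sees spatial shape, not DSB frequency. Flat rows (zero after
subtraction) are dropped and recorded. No dimensionality reduction is
applied; rows enter k-means as 1000-dimensional vectors.

`kmeanspp_cluster()` is Euclidean k-means with k-means++ seeding, best of
`n_init = 10` seeded restarts by total within-cluster sum of squares, and a
fixed iteration cap (300). The published analysis used a library k-means++
call without stating restarts; restarting makes the partition insensitive to
the seeding draw at negligible cost. Clusters are relabeled by increasing
signal-weighted mean distance of their centroid, so cluster 1 is always the
shortest-resection group regardless of row order or seed — this canonical
relabeling is what makes the row-order invariance testable. Degenerate
inputs (fewer distinct profiles than k) are clustered at the reduced k and
flagged. `cluster_summaries()` then averages *raw* signal (and MNase
occupancy, read in the same orientation) within clusters and computes each
cluster's pooled median resection length; on occupancy-gated synthetic data
the cluster medians anti-correlate with cluster mean occupancy, the
literally testable form of the chromatin–resection correlation.

## Spike-in calibrated ChIP-seq

Coverage from the test species is divided by the number of reads uniquely
mapped to the spike-in species (`spike_normalize()`); since IP and input
from one culture share the spike-in proportion, calibrated signals are
comparable across samples and depths — scaling raw coverage and its spike
count together changes nothing, to 1e-12. `calibrated_ratio()` divides
normalized IP by normalized input, marking positions missing where raw input
coverage is below `input_floor` (default 1 read — a ratio over less than one
input read is noise, and the choice is configurable because the original
handling of zero-input positions is unstated). Missing positions are
excluded, not zeroed, in all downstream smoothing, averaging, binning and
correlation. `difference_map()` subtracts two same-stage maps (e.g.
DSB-competent minus DSB-dead) to isolate the DSB-dependent component;
smoothing is applied after ratio/difference computation (display-level
smoothing; the order is configurable by smoothing inputs instead).
`binned_correlation()` sums both maps in 1-kb windows and reports Pearson's
r over bins defined in both, on untransformed sums (no log transform is
applied, none being stated in the source analysis).

## The tetrad viability mixture

A tetrad's four spores die by two routes: random spore death (RSD), each
spore independently with probability *r*; and meiosis-I nondisjunction
(MI-NDJ), per chromosome with probability *d*. With `P = 1 − (1−d)^C` the
probability that at least one of the C = 16 chromosomes missegregates, an
NDJ tetrad has exactly two dead nullisomic spores (the two disomes are
viable — standard yeast genetics, and multiple NDJ events in one tetrad are
not additive in deaths), and its two survivors remain subject to RSD — which
is what makes viability classes 1 and 0 reachable from NDJ tetrads. Class
probabilities are therefore a mixture of Binomial(4, 1−r) and a shifted
Binomial(2, 1−r), summing to one identically.

`tetfit()` fits (r, d) by exhaustive grid search. The default objective is
the sum of squared differences between expected and observed class
*frequencies* — distribution matching — with a multinomial log-likelihood
option; ties break toward smaller d, then smaller r. Death shares per spore
are closed forms: `ndj_death_share = P/2`, `rsd_death_share = r (1 − P/2)`,
and `per_chromosome_rate_from_share()` inverts the former for d. The default
configuration keeps the published defaults (500-point grids, RSD bounds
0–0.8, NDJ bounds 0–0.017, `anid = 0.035`, `ndm = 10`); `anid` and `ndm`
are accepted and recorded but unused, since their semantics are not defined
by the model implemented here, and the default `maxnd = 0.017` must be
raised by the user for strongly NDJ-elevated strains — the bounds must cover
the truth for the fit to find it. When choosing grid resolutions for
recovery experiments, note that the statistical precision of the estimates
at 1e5 tetrads is roughly 0.0015 in r and 0.0002 in d; grids finer than that
cannot be expected to pin the truth to one step.

Genetic distances from fluorescent-marker tetrads use the Perkins formula
`cM = 100 (TT/2 + 3 NPD) / (PD + NPD + TT)` with a delta-method standard
error on the multinomial class frequencies. Tetrads are classified from the
joint two-marker pattern; the MI-NDJ signature is exactly two spores
carrying the centromere-linked marker with both marker-less spores dead.
Tetrads with dead spores that do not match the NDJ signature are unscorable
rather than guessed.

## What the synthetic data emulates — and what it does not

The generator produces, with full ground truth and bit-reproducible seeding:

* genomes of equal-length chromosomes with narrow hotspots (NDR widths
  120–300 bp, long-tailed log-normal heats normalized to 1, edge-to-edge
  separation enforced at 3 kb by default);
* phased nucleosome arrays flanking each NDR (repeat length 165 bp = 147 bp
  core + 18 bp linker, Gaussian positional jitter, Bernoulli per-nucleosome
  presence) and the corresponding MNase-like occupancy track;
* S1-seq endpoint tracks from two generators. The *mechanistic* generator
  draws a DSB uniformly within the NDR (no finer intra-hotspot model being
  justified), resects the two sides independently, places the MRX/Sae2 nick
  uniformly at 20–160 bp from the DSB (20–90 bp in remodeler-null presets,
  motivated by endpoints straddling the NDR edge and the +1 nucleosome when
  both the remodeler and Exo1 nuclease are absent), and extends through the
  present-nucleosome array with a per-nucleosome traversal probability,
  stopping in the proximal linker — so mean extension beyond the first
  nucleosome follows the geometric law `spacing · q/(1−q)`. The
  *distribution-level* generator (`simulate_s1seq_direct()`) draws tract
  lengths log-normal with a requested median (log-sd 0.4), which is the
  design used for median-recovery experiments because the generative median
  is then known exactly. Endpoint counts are multinomial at fixed total
  depth, the simplest model consistent with count data;
* two-condition ChIP coverage (Poisson counts over basal + Gaussian peaks at
  hotspots and axis sites, amplitudes optionally coupled to hotspot heat)
  with verbatim spike-in read counts;
* tetrad viability tallies and two-marker fluorescence patterns. Marker
  class frequencies come from a no-chromatid-interference (Poisson-exchange)
  model whose Perkins estimate is numerically inverted to equal the
  requested distance, so round trips recover the distance in expectation;
  distances beyond the ~83.3 cM ceiling of that model are a parameter error.

The generator deliberately omits read-level artifacts (no sequences, no
FASTQ, no mappability structure), transcription and replication effects on
chromatin, per-chromosome NDJ differences, MII nondisjunction, crossover
interference, and the real genome. Passing tests therefore demonstrate that
the *estimators* are correct and well-calibrated under a faithful generative
model of the assays — not that any particular biological conclusion holds in
real data. The exact resection rate model of the real enzymes is likewise
not restated here; the mechanistic generator is a deliberately simple
stand-in whose qualitative structure (NDR origin, nucleosome gating, linker
stops) matches the assay's logic.

## Problem sizes and numerical choices at a glance

Median-recovery experiments use 200 loner hotspots with 50 endpoints per
side (20,000 endpoints), which estimates a pooled median to ~1% — a
comfortable margin inside the ±5% acceptance band while keeping a full run
under a minute. Tetrad recovery uses 1e5 tetrads on a 161 × 81 grid over
r ∈ [0, 0.8], d ∈ [0, 0.08]. Clustering recovery plants three archetypes in
300 profile sides with noise at 10% of peak signal. Kernel and median
implementations are verified against direct-convolution and cumulative-sum
oracles at 1e-9 and exact equality respectively; spike-in depth invariance
at 1e-12; class-probability normalization at 1e-12 over a 100 × 100
parameter sweep.

## Known limitations

* Masks are user-supplied; the package does not ship the curated mask
  coordinates of any particular genome build, and no background
  (DSB-null control) subtraction is performed.
* Tracks are dense doubles; genomes far beyond yeast scale would want an
  Rle-backed store.
* The Perkins inversion assumes no crossover interference, which real yeast
  intervals violate mildly; for simulation round trips this is immaterial,
  but measured distances from real tetrad data carry the usual caveats.
* `tetfit()` assumes exactly the two death routes of the mixture; strains
  with, e.g., germination defects that kill spore pairs will bias d upward.
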