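---
title: "Morphology-corrected gene positioning analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-corrected gene positioning analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpos)
```

## The problem

Whether a gene's activity depends on its proximity to heterochromatin is an
old and contested question. Two heterochromatin compartments matter in mouse
nuclei: the periphery (facultative heterochromatin lining the lamina) and
chromocenters (clusters of pericentric constitutive heterochromatin, visible
as DAPI-dense bodies). Measuring locus-to-compartment distances across cell
states is confounded by morphology: nuclei flatten, grow, and fuse their
chromocenters during myogenic differentiation, so a raw micrometre distance
is not comparable between a myoblast and a myotube. `nucpos` implements a
single-cell Monte Carlo normalization that removes this confound, plus the
downstream statistics that relate positioning to expression changes and to
the genomic neighborhood (RIDGE/anti-RIDGE features).

## Distance measurement

Nuclei are represented as voxel masks on the anisotropic confocal grid
(default voxel $0.08 \times 0.08 \times 0.2\ \mu m$). The nuclear mask is
the thresholded (pooled-histogram Otsu) smoothed DAPI signal; chromocenters
are voxels brighter than $\mathrm{mean} + k \cdot \mathrm{SD}$ within the
nucleus. No quantitative threshold for "high-intensity DAPI" exists in the
underlying protocol, so $k$ is an explicit, logged parameter (default 2).
In MeCP2-transfection experiments the chromocenter channel can be replaced
by the anti-MeCP2 immunofluorescence channel.

For a locus at continuous position $p$ the package reports the shortest 3D
distance to (1) the nearest out-of-mask voxel (the periphery, "edge of the
DAPI signal") and (2) the nearest chromocenter voxel surface, zero if the
locus lies inside one (distances are unsigned; the compartment surface is
the reference). Internally a separable anisotropic Euclidean feature
transform (exact, in physical units) stores for every voxel its nearest
target voxel; the reported value is the distance from $p$ to that voxel's
axis-aligned box. Using the box rather than the voxel centre removes most
of the half-voxel outward bias at compartment surfaces. Sub-voxel precision
is bounded by half a voxel diagonal ($\approx 0.11\ \mu m$ at the default
grid); tests assert exact (< $10^{-6}\ \mu m$) agreement with a brute-force
scan at voxel centres, and analytic sphere expectations within
$3\,\mathrm{SE}$ plus this discretisation bound.

## Monte Carlo normalization

For each nucleus, 10,000 points are simulated uniformly over the in-mask
physical volume (uniform voxel choice plus uniform in-voxel jitter, which
avoids lattice artifacts) and measured exactly like loci. A locus distance
$d$ is then re-expressed against its own nucleus's background sample
$b_1, \ldots, b_n$ by the mid-rank empirical CDF

$$ \tilde d = \frac{\#\{b_i < d\} + \tfrac12 \#\{b_i = d\}}{n} \in [0, 1]. $$

Two properties make this percentile form the right choice (rather than,
say, dividing by the mean background distance):

* **Exact null.** If loci are positioned uniformly at random, $\tilde d$ is
  uniform on $[0,1]$ by the probability integral transform, so each
  0.25-wide bin holds exactly 25% in expectation — which is precisely the
  null hypothesis of the downstream chi-square test. No other normalization
  makes "25% per bin" exact.
* **Invariance.** $\tilde d$ is invariant under any monotone rescaling of
  raw distances, hence insensitive to units and to nucleus size per se.

Mid-rank tie handling avoids saturation bias at 0/1 and guarantees that the
background's own points average exactly 0.5. Nuclei without chromocenters
contribute periphery values only; their chromocenter distance is reported
missing, never zero. One background serves all loci of its nucleus and is
cached with its seed in the run manifest.

## Randomness test and correlations

Normalized distances are binned in 0.25 steps (right-closed last bin) and
compared with the uniform expectation $E_i = n/4$ by
$\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ on 3 degrees of freedom. The verdict
threshold is $\alpha = 0.05$; no $\alpha$ is stated for this test in the
source protocol, so the level used for correlation significance was adopted
by analogy (and is a parameter). Below 8 loci the expected counts are too
small for the asymptotic distribution and a warning is logged.

Repositioning is summarized per gene as $\Delta D$, the mean normalized
distance in condition B minus condition A (per-nucleus means first).
Positive $\Delta D$ means the locus moved away from the compartment.
Expression changes enter as signed log2 fold changes, so a positive Pearson
correlation means up-regulated genes move away from the compartment — the
"heterochromatin as silencing compartment" direction; a negative
correlation contradicts it. Correlations are computed at four aggregation
scales: the gene itself, the ~180-kbp BAC probe containing it
(overlap-weighted), and 2-/5-Mbp windows centred on the gene (1 and 2.5 Mbp
up- and downstream of the gene midpoint).

`pearson_ci()` wraps the product-moment coefficient with a t-based p-value
($n-2$ df) and a Fisher z confidence interval at the 0.95 level. Published
interval tables in this field often show one bound pinned at $\pm 1$,
which corresponds to a one-sided interval in the direction of the observed
coefficient; `one_sided = TRUE` reproduces that convention, the default is
two-sided. No multiple-testing correction is applied to the per-cell
reports; a Benjamini–Hochberg column is emitted alongside, clearly labelled
as supplementary.

## Expression profiling

The input is an RMA-style log2 probe-by-sample matrix (computing RMA from
raw arrays is out of scope). Per probe and condition, replicates pass
through a single-pass Nalimov outlier test at $p = 0.001$:
$q = |x^* - \bar x| / s \cdot \sqrt{n/(n-1)}$ for the most extreme
replicate, removal if $q$ exceeds the tabulated critical value. Critical
values for $n = 3..10$ come from the classic published table (Kaiser &
Gottschalk, as widely reprinted); beyond $n = 10$ an extreme-studentized-
deviate bound via the t distribution is used. Two numerical facts shaped
the design here:

* $q$ is bounded by $\sqrt{n-1}$ (= 2.0 at five replicates) while the
  $p = 0.001$ critical value is 1.982, so only gross aberrations are
  detectable at typical replicate counts — a 5-noise-SD Gaussian shift is
  flagged only ~6% of the time. The synthetic generator therefore plants
  40-noise-SD aberrations (emulating scanner/hybridization artifacts),
  which the stage flags essentially always.
* Removal is single-pass: iterating risks emptying five-replicate groups.

Fold changes are ratios of antilog means ($\mathrm{mean}(2^{x_B}) /
\mathrm{mean}(2^{x_A})$ on kept replicates), while the unpaired two-sided
Student's t test (and the one-way ANOVA across all conditions) runs on the
log scale, where variance is stabilized. This asymmetry is deliberate and
documented; whether the original tests ran on log or antilog values is not
recorded, and the log scale is the statistically defensible choice. Genes
are selected at $p \le 4 \times 10^{-6}$. When several probe sets map to
one gene, the maximally regulated probe (largest $|\log_2 FC|$) is kept,
ties broken by smaller p, then lexicographic probe id. BAC-level expression
is the mean over overlapping genes of overlap-fraction-weighted values;
neighborhood expression is the plain mean over entries overlapping the
half-open window.

## Genomic context (RIDGE features)

Five features are computed per gene-centred window: gene count (≥ 1 bp
overlap, half-open coordinates), CpG-island count, GC fraction (N excluded
from the denominator), and SINE/LINE merged-union coverage fractions. CpG
islands follow the classic three-threshold definition — length ≥ 500 bp,
GC ≥ 50%, observed/expected CpG ≥ 0.60 with the Gardiner-Garden & Frommer
ratio $N_{CpG} \cdot L / (N_C \cdot N_G)$ — implemented as a 1-bp-step
sliding 500-bp window scan; qualifying windows are merged, and each merged
region is re-tested and symmetrically trimmed until it qualifies or drops
below 500 bp. Windows containing N never qualify. The original workflow
took islands from a genome-browser track, so a BED-input mode is provided
alongside the sequence-based caller; the caller itself is validated against
an exhaustive, naively-recomputed oracle. High-level coordinates in plain
tables are 0-based half-open; conversion to 1-based closed happens only
inside `GRanges` and at BED/GFF boundaries.

## The synthetic data generator

The generator exists so that every stage is testable end to end without any
external data, and its defaults are the study conditions the analysis
assumes:

* **Nuclei**: flat ellipsoids (semi-axes $5 \times 5 \times 2.5\ \mu m$,
  ±10% per-nucleus jitter emulating cell-to-cell variability) on the
  0.08/0.08/0.2 µm grid, 50 per condition (the study benchmark is at least
  47, enforced as a logged warning). Chromocenter presets mirror the two
  cell states — myoblast-like: 10–15 spheres of 0.4–0.6 µm radius;
  myotube-like (or high ectopic MeCP2): 4–8 spheres of 0.65–0.95 µm —
  placed fully inside the nucleus, pairwise disjoint with a voxel-scale
  gap so segmentation can separate them.
* **Loci**: uniform placement reuses the background-sampling machinery, so
  the probability integral transform holds exactly. Biased placement maps
  Beta- or explicitly-targeted quantiles through the inverse ECDF of the
  nucleus's own background, guaranteeing self-consistency with the
  normalization stage.
* **Expression**: four conditions (MB, MT, low/high MeCP2) with five
  replicates each, log2 noise SD 0.1, planted log2 fold changes per pair
  (an 11-fold plant mirrors the largest effect in the motivating system),
  and optional gross aberrant replicates as described above.
* **Coupling**: `planted_rho` draws per-gene latent effects so that planted
  expression changes and planted position changes correlate at the
  requested $\rho$; position changes are planted as background-quantile
  shifts (scale 0.3, per-locus jitter 0.05), so the full pipeline is a
  parameter-recovery experiment.
* **Genome**: one chromosome of alternating 2-Mbp RIDGE-like blocks
  (GC 0.55, 8 planted CpG islands/Mbp, gene-dense, 25% SINE, 5% LINE) and
  anti-RIDGE blocks (GC 0.42, island-free, gene-poor, 5% SINE, 25% LINE).
  Background sequence is CpG-suppressed (observed/expected ≈ 0.2, as in
  real vertebrate genomes) — without suppression, any GC ≥ 50% iid
  sequence would qualify as one giant CpG island. BAC-like probes of
  150–250 kbp are centred on genes. The alphabet is A/C/G/T only; the
  callers nevertheless tolerate N.

What the generator does **not** emulate: chromatin texture, optical PSF
and depth-dependent aberrations, chromosome territories, segmentation
errors on real images, probe cross-hybridization, and correlated
inter-gene expression structure. Passing tests therefore demonstrate the
statistical machinery and its null behaviour, not robustness to real
microscopy artifacts.

## Problem sizes and numerical choices

Test and verification runs use 50 nuclei with 10,000-point backgrounds and
4,000 uniformly placed loci for null checks (bin frequencies within ±2
percentage points, ≥ 90% "random" verdicts over 100 re-placements), and
200 genes over 2 × 50 nuclei for recovery of a planted $\rho = 0.8$
(accepted when the estimate falls in the 95% Fisher interval around 0.8).
Unit tests run on coarser grids (0.12–0.3 µm voxels, 2–3 µm semi-axes) to
stay fast; the oracle comparisons (distance transform, CpG caller,
Pearson) use exact tolerances ($10^{-6}\ \mu m$, exact intervals,
$10^{-12}$). Degenerate inputs are contracts, not accidents: empty
chromocenter sets yield missing distances, constant replicate sets skip
the outlier test with a log entry, zero-variance correlations raise an
error rather than reporting $R = 0$, and zero p-values are clamped to the
smallest positive double before $-\log_{10}$.

## Limitations

Percentile normalization discards absolute distance information: a
normalized 0.9 in a large and a small nucleus are equivalent by design.
The chi-square verdict tests marginal uniformity only, not spatial
clustering. The one-background-per-nucleus scheme couples all loci of a
nucleus through shared reference noise; with 10,000 background points and
tens of loci per nucleus this inflation is negligible, but it is visible
when thousands of loci share one background (the package's own uniformity
tests use a larger reference sample in that regime). Finally, the Nalimov
stage's bounded statistic means small-sample outlier screening is
intrinsically weak at $p = 0.001$; this is a property of the published
test, not of the implementation.
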