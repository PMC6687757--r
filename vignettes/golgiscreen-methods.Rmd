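---
title: "Methods: simulating and scoring an epistatic Golgi-fragmentation screen"
author: "golgiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring an epistatic Golgi-fragmentation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiscreen)
```

## The assay this package models

In mammalian cells the Golgi apparatus forms a compact juxtanuclear
ribbon. Depleting a subunit of either of two CATCHR-family retrograde
tethering complexes — COG (intra-Golgi tethering, via COG3) or NRZ
(Golgi-to-ER tethering, via ZW10) — disperses the ribbon into
clustered punctate elements, raising the number of detectable
fluorescent Golgi fragments per cell roughly five-fold over the
control baseline of about 4.5. If co-depleting a second protein (a
Rab GTPase or a kinesin-family motor, Kif) *suppresses* that
fragmentation, the second protein is inferred to act upstream of, or
alongside, tether-dependent vesicle traffic: the suppression is an
epistatic readout.

`golgiscreen` re-implements this screen end to end as testable code:

1. **synthetic data** — fluorescence fields with per-cell ground
   truth, full screen measurement tables with planted suppressors,
   messy interaction tables, and per-stack EM morphometry tables;
2. **image quantification** — Richardson–Lucy deconvolution,
   maximum-intensity projection, robust intensity segmentation, and
   per-cell fragment/area measurement;
3. **hit calling** — per-siRNA fractional suppression, a
   majority-based per-target rule, strict replication, and the
   four-way category partition;
4. **interaction networks** — parsing, high-confidence filtering,
   graph cleaning, neighbourhood extraction with localization
   filters, betweenness centrality, seed-to-tether distances;
5. **EM morphometry** — condition summaries and fold/percent-change
   comparisons.

Everything stochastic is a pure function of its arguments and an
integer seed.

## The synthetic fluorescence field

A field (`generate_field()`) renders each cell as a dim nucleus disk,
a diffuse cytoplasmic halo, and a set of bright Golgi fragments:
Gaussian-profile blobs with a hard support radius, scattered
isotropically around a juxtanuclear anchor offset from the nucleus.
Each fragment occupies one z-plane of the stack. The expected image
is blurred with a Gaussian PSF and then passed through a standard
camera model — Poisson shot noise followed by additive Gaussian read
noise. No noise model is prescribed by the assay itself; this is the
conventional photon + readout decomposition, with all parameters in
`field_spec()`.

Key generative choices:

* **Fragment counts.** Per-cell counts are drawn as
  `1 + NegBin(mu = fragments_mean - 1, size = fragments_dispersion)`:
  every cell has at least one fragment, the mean is exactly
  `fragments_mean`, and the expected count is monotone in the
  parameter. Cell-to-cell variability of fragment counts is not
  published for this assay, so the dispersion is a free calibration;
  the default `size = 20` gives variance about twice the mean at
  fragmented levels, a moderate overdispersion typical of per-cell
  phenotypes.
* **Presets.** `phenotype_presets()` pins `control` at 4.5 fragments
  (tight scatter, 6 px) and `tether_kd` at 22.5 (five-fold, wide
  scatter, 30 px) — the two anchors of the assay; an intermediate
  `basal_fragmenting` preset (18, four-fold) models targets that
  fragment the Golgi on their own. These are calibrations of the
  observable, not mechanistic claims.
* **Detectable fragments.** The published baseline counts
  *detectable* fragments, so the renderer enforces a ≥3 px gap
  between a cell's fragments (rejection placement, 40 tries). Without
  it, blob overlap in compact cells silently merges planted
  fragments and the rendered control baseline drifts well below its
  nominal mean.
* **Ground truth.** Truth is defined on the pre-PSF, pre-noise
  Golgi-only render: its connected components are the true fragments,
  each assigned to the nearest nucleus — the same rule the quantifier
  uses. Truth and measurement therefore share one observable
  definition, making exact-recovery tests well-posed even if a blob
  drifts toward a neighbouring cell.

What the generator deliberately does **not** model: 3D
optical-section physics, spectral crosstalk, cell movement or
division, cell-shape heterogeneity, uneven illumination, and
autofluorescence. Passing recovery tests on these fields therefore
demonstrates the *pipeline's* correctness under its own generative
assumptions, not segmentation performance on real micrographs.

## Image quantification

`quantify_field()` chains four steps.

**Deconvolution.** The reference assay sharpened confocal stacks with
commercial deconvolution before projection; here `deconvolve()` is
Richardson–Lucy with a Gaussian PSF (default 20 iterations, in
config). The multiplicative update preserves non-negativity, and a
zero-width PSF or zero iterations are exact no-ops.

**Projection.** `max_project()` is the pixelwise maximum over
z-planes.

**Segmentation.** `segment_golgi()` thresholds at
`median + k * MAD` (default `k = 6`). The median+MAD rule suits this
signal because Golgi pixels are a sparse bright minority over a
dominant background, which Otsu's bimodal assumption does not
guarantee; Otsu remains available as an option. On noiseless images
the MAD collapses to zero, so it is floored at a small fraction
(default 1%) of the image's dynamic range above the median —
otherwise the threshold degenerates to the median and the cytoplasmic
halo floods the mask. Components are labeled under 8-connectivity
(4 available) and components below 4 px are discarded as shot-noise
specks; both knobs sit in `seg_params()`. Labels are numbered in
raster order, so labeling is deterministic.

**Per-cell assignment.** Each fragment goes to the nucleus seed
nearest its centroid; ties break to the lowest cell id. Cells whose
nucleus disk touches the image border are dropped, and fragments
nearest a dropped cell leave with it rather than inflating a
neighbour. Coordinates are 1-based (row, col), origin top-left;
areas are reported in px and, given a pixel size, µm².

`summarize_condition()` reports mean ± SEM (sample SD, n−1, over
√n) of fragments and area, normalized to a control condition;
conditions under 30 cells — the assay's minimum for a screen-grade
data point — are flagged rather than rejected.

## Scoring the epistatic screen

For a tether background with control-normalized fragment counts
`F_control < F_KD` and a double-knockdown value `F_double`, the
fractional suppression is

$$S = \frac{F_{KD} - F_{double}}{F_{KD} - F_{control}},$$

0 at no rescue and 1 at complete rescue. Strengths: `strong` at
`S ≥ 0.7`, `weak` at `0.3 ≤ S < 0.7`. The published screen never
quantified "strong"/"weak"; these cutpoints are configuration, and
all recovery claims in this package are validated against planted
synthetic truth, not against the original raw data. Conditions where
the tether knockdown failed to fragment (`F_KD ≤ F_control`) are
unscorable and are reported as such, never silently dropped.

A target is a **suppressor** in a background when strong calls reach
half its siRNAs, or weak-or-better calls reach three quarters
(both rounded up) — at four siRNAs this is exactly the published
"strong with 50% of siRNAs, or weak with three of four" rule, and the
ceiling-based form generalizes it to other panel sizes, including
pooled siRNAs (n = 1, where weak-or-better passes). Replication is a
strict AND across the two screen replicates, matching the exclusion
of a motor that suppressed in only one replicate; a majority rule is
available. We read "50% of siRNAs" as counting strong calls only —
the weaker reading (weak-or-better) is subsumed by the second clause
at n = 4 anyway.

Basal (no-tether) phenotypes are classified from the normalized
single-knockdown value: two-fold or more is `fragments_alone`;
toxicity and the cytokinesis-failure "stretched strands" phenotype
are not readable from fragment counts and enter as explicit flags.
`partition_targets()` then emits the four-way category partition
(both / ZW10-only / COG3-only / non-suppressive) per target class.
Area is reported throughout but never gates a call — fragment counts
decide, and no hypothesis testing is attached because the original
scoring used none.

The synthetic screen (`generate_screen()`) draws ≥30 per-cell counts
for every (target, siRNA, background, replicate) cell of the design,
interpolating the double-knockdown mean linearly from the tether-KD
level toward control in proportion to siRNA efficacy:
`mu = mu_KD - e * s * (mu_KD - mu_control)`, with `s = 1` exactly when
the planted suppression class covers the background. Efficacies
default to two effective (0.8–0.95) and two poor (0.05–0.4) siRNAs
per multi-siRNA target, emulating the real screens' heterogeneity in
knockdown efficiency. Linearity is a testability choice: it makes the
expected `S` of a planted suppressor equal its efficacy, so
closed-form expectations exist for every condition.

## Interaction networks

Interaction tables arrive either as a PSI-MITAB 2.5-style file or as
a simplified 5-column TSV. Filtering keeps records whose detection
method and interaction type are whitelisted (biochemical and
cell-biology assays; physical, never genetic interactions) and whose
confidence reaches a minimum (default 0.5). The whitelists are
editable configuration: the underlying principle — physical
interactions from high-confidence assays — is fixed, but no canonical
term list is, and no live database is ever queried; reproducibility
from files is preferred over fidelity to a moving snapshot, which is
also why the original network's node/edge census is not a
reproduction target.

Cleaning removes self-loops, collapses A–B/B–A duplicates into one
undirected edge (merging provenance), and leaves no orphaned nodes;
it is idempotent. Neighbourhoods: first-degree is the induced
subgraph on seeds plus direct partners; second-degree adds
neighbours-of-neighbours whose annotated localization intersects
{Golgi, vesicle} — the compartments relevant to Golgi-derived vesicle
traffic — with first-degree nodes exempt and unannotated second-ring
nodes excluded. Betweenness is unnormalized, undirected and
unweighted, each unordered pair counted once, with lexicographic tie
order; the implementation is validated in the test suite against an
independent exhaustive shortest-path enumeration on dozens of random
graphs. `seed_to_tether_distance()` reports, per tether complex, the
minimum edge count from a seed to any subunit — the "how many edges
to the tether" comparison — with unreachable complexes flagged as
infinite.

## EM morphometry

EM enters as per-stack records (condition, maximum cisterna length,
cisternae count, vesicles within 1 µm) because the analysis needs a
raw measurement unit even though published tables print only
aggregates; the synthetic generator supplies such records from
zero-truncated normal draws (lengths and counts cannot be negative;
SD 0 reproduces means exactly). "Within 1 µm" is a recorded field,
not recomputed — EM image analysis is out of scope. Summaries are
mean ± SEM per condition; `compare_conditions()` reports
`fold = mean_b / mean_a` and a percent change anchored explicitly on
the reference condition, avoiding the "30% of what" ambiguity. On the
bundled reference table this arithmetic gives a 29.3% vesicle
decrease for the ZW10+Rab33B double knockdown relative to Rab33B
alone, and a 2.82-fold vesicle increase for ZW10 over control — the
prose accompanying the original table rounds the latter to "~2-fold";
we compute from the printed means and note the discrepancy rather
than reconcile it.

## Orchestration, determinism, problem sizes

`run_pipeline()` runs simulate → quantify → score → network → em from
one configuration (R list or YAML), validates the configuration
before any stage runs, rejects unknown keys, derives one sub-seed per
stage from the master seed, and writes a manifest with an MD5 hash of
every output. Identical configurations give byte-identical tables.

Default problem sizes were chosen so a full simulation + analysis
cycle stays interactive on a single core: fields of 256×256×3 with 6
cells, screens of ~20 targets × 4 siRNAs × 2 backgrounds × 2
replicates × 30 cells, networks of tens of nodes, and EM tables at
the reference table's stack counts. All scale up through
configuration.

## Known limitations

* Segmentation is projection-based 2D counting (as in the source
  assay); true 3D object counting is out of scope, and fragments
  overlapping in projection merge.
* The nearest-nucleus assignment needs seeds; there is no
  marker-free cell segmentation.
* The efficacy→phenotype map is linear by design; saturating or
  cooperative rescue would need a different map (one configuration
  point, `rescue` interpolation, isolates it).
* Betweenness is unweighted; confidence-weighted centralities are
  deliberately not provided.
* The EM generator draws metrics independently per stack; real
  cisternal metrics are correlated.
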