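---
title: "Multi-modal small-world graph analysis of simultaneous EEG-fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal small-world graph analysis of simultaneous EEG-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmgraph)
```

## The analysis problem

A single session of 1 Hz rTMS over premotor cortex produces short-lived,
widespread connectivity changes. To characterize their topology, recordings
taken simultaneously in two modalities — 31-channel EEG and resting-state
fMRI parcellated into 160 spherical ROIs — are analyzed with the same graph
pipeline: node-by-node Pearson correlation, density-matched binarization,
and null-normalized small-world metrics, compared across healthy controls
(HC) and patient sessions before (R1) and immediately after (R2)
stimulation. The hypothesis structure is ordinal: disease lowers clustering
and small-worldness relative to controls, stimulation restores (and may
overshoot) them.

`mmgraph` implements that pipeline as composable functions plus an
orchestrator (`run_study()`), and — since the patient recordings are not
distributable — a synthetic-cohort generator that plants a known effect of
the same shape, so every inferential claim the package makes can be
exercised against ground truth.

## Pipeline and model

**Preprocessing.** EEG is band-passed 0.5–45 Hz with a 4th-order zero-phase
(forward–backward) Butterworth filter, cut into 3-s epochs, and epochs whose
peak-to-peak amplitude exceeds 150 µV on any channel are removed before
concatenation; the band of interest (default beta2, 20–30 Hz; theta, alpha
and beta1 are also computed for the band summary) is extracted the same way.
fMRI ROI series are residualized on an intercept plus nuisance regressors
(white matter / CSF means, when supplied) and band-passed 0.01–0.09 Hz.
Zero phase matters because EEG epochs are aligned to fMRI dynamics;
a causal filter would shift one modality against the other.

**Connectivity and binarization.** Pearson correlation across all retained
samples gives a symmetric matrix with zero diagonal (Fisher z is available
for export; it is monotone, so binarization is unaffected). At sparsity S
the `round(S * N(N-1)/2)` strongest edges are kept. Edge strength defaults
to |r|: the source analyses do not state how negative correlations were
treated, and magnitude ranking is the common toolbox convention; a
`strength = "positive"` switch is provided. Exact ties are broken
lexicographically by (min node, max node) index so that every run, on every
platform, selects identical edge sets; this also makes the realized edge
count exact whenever enough distinct strengths exist. Thresholding over the
grid S = 0.11…0.45 (step 0.01) shares one edge ranking, so edge sets are
nested across levels.

**Small-world metrics.** Clustering uses the binary per-node definition
(`2·t(i)/(k(i)(k(i)-1))`, zero for degree < 2); the graph value is the
unweighted node mean. Path length is the mean BFS distance over reachable
ordered pairs; unreachable pairs are excluded and flagged rather than made
infinite, which keeps sparse thresholds estimable while surfacing
fragmentation (a harmonic-mean efficiency variant was considered and left
out of the defaults). Null normalization divides by the means of an
ensemble of Maslov–Sneppen degree-preserving rewirings (double-edge swaps;
swap attempts that would create loops or multi-edges are skipped and
counted). One shared ensemble serves both C and L. Defaults are 100
references and 10 swap attempts per edge; ensemble standard deviations are
stored for diagnostics. All ensemble members are seeded as `seed + index`,
so results are reproducible and node-permutation invariant up to ensemble
sampling noise.

**Group statistics.** Per sparsity level: pooled-variance two-sample t for
HC contrasts (the groups are unpaired, n = 20 vs 14), paired t for R1 vs R2
(pairing from the manifest). Benjamini–Hochberg FDR is applied per contrast
x metric across the 35 levels, and per contrast across nodes for regional
tables; the largest rejected p is reported as the data-dependent threshold,
which is how thresholds like "p < 0.0062" arise descriptively in published
tables — the pipeline treats them as outputs, not inputs. Significant levels
are formatted as contiguous percent ranges ("11%–17%, 20%–24%"). Tests are
two-sided throughout.

**Effect sizes.** Cohen's d uses the equal-n pooled form
`(m2 - m1)/sqrt((s1^2 + s2^2)/2)` even for the paired contrast: recomputing
a published regional table from its printed means and SDs with this formula
reproduces the printed d (0.91, 1.22, 0.93, 0.94, 0.95 on the five rows
checked exactly), whereas the paired-SD form is not recoverable from printed
summaries; two further rows differ by exactly 0.01, consistent with rounding
of the printed summaries. Effect-size r is `d/sqrt(d^2 + 4)`. The bundled
`reference_region_table()` carries those published summaries as a fixture
for desk checks and as an export template.

**Regional (node-level) γ.** Published regional tables report a single γ per
region without naming a sparsity level. The package summarizes a recording's
node i as the grid mean of `node_C(i) / node_C_rand(i)` — the per-node
analogue of γ averaged over the sparsity range. Levels where a node's null
clustering is zero are excluded for that node; nodes undefined everywhere
are flagged rather than imputed. This aggregation is an interpretation and
is stated as such.

**Cross-modal correlation.** For each (electrode, ROI) pair restricted to
the nodes with FDR-significant R1→R2 changes, the per-subject change scores
(R2 − R1 node γ; a switch allows raw R2 values) are correlated across
subjects. A pair is reported when |r| > 0.4 and the two-sided p from the t
transform (df = n − 2, pairwise-complete n) is ≤ 0.05. Published p-values
of this form do not always match the standard t transform at the stated n;
the pipeline reports its own exact p rather than attempting to match.

## The synthetic cohort: what it emulates and what it does not

Each subject gets a Watts–Strogatz base graph per modality (defaults: 31
nodes / k = 6 and 160 nodes / k = 16, rewiring p = 0.1) — the canonical
small-world generator, chosen because the ring lattice has closed-form
clustering `3(k-2)/(4(k-1))` that anchors the tests. Covariance is
`I + c·A` (c = 0.12, validated positive definite by eigendecomposition;
`c < 1/lambda_max(A)` is always safe), plus observation noise
(`noise_sd = 0.5` on unit-variance channels). Time series are i.i.d.
multivariate Gaussian draws (an optional AR(1) factor with
variance-preserving innovations exists for filter testing); Pearson
correlation, the only quantity the pipeline consumes, is exercised exactly.

The planted treatment effect adds `delta` to the covariance of
within-cluster pairs — disjoint contiguous blocks of 8 nodes. A disjoint
clique mask has smallest eigenvalue −1, so a boost below the base
covariance's positive-definiteness margin is safe by construction at both
node counts. Because the boost exceeds the edge coupling, density-matched
thresholding tilts the retained edge set toward triangle-closing local
pairs, raising binarized clustering and σ at matched density — the same
observable the real effect produces. HC covariances receive half the boost,
planting the ordinal pattern R1 < HC < R2; the per-subject boost is
jittered (uniform ±25%) and shared across modalities so that cross-modal
change-score correlations exist to find. The published effect is reported
only as significance and effect sizes, never on the connectivity scale, so
`delta = 0.2` is calibrated to make power simulations meaningful (strong,
comfortably detectable at n = 14) rather than to match the patients; with
`delta = 0` the generator provides exact null cohorts for type-I checks.

Not emulated: EEG artifacts (gradient, ballistocardiogram, ocular — their
removal is out of scope of this pipeline), volumetric hemodynamics, head
motion, and volume conduction. Passing tests therefore demonstrate that the
pipeline recovers graph-level effects from correlation-faithful signals;
they say nothing about robustness to artifacts the generator does not
produce.

## Numerical and design choices

- **Degenerate nulls**: if an ensemble's mean clustering is zero, γ is
  undefined and the call fails loudly rather than returning Inf. This can
  occur for very small, very sparse graphs; at the study's node counts it
  does not arise on the grid.
- **Fisher clipping**: |r| ≥ 1 off-diagonal entries (duplicate channels)
  are clipped to 1 − 1e−7 with a warning before arctanh.
- **Constant channels** fail `correlation_matrix()` by name; `validate_inputs()`
  reports them cohort-wide without failing.
- **Rejection statistic**: "channel variation" is read as peak-to-peak range
  per epoch (the common amplitude-rejection convention); an absolute-value
  criterion is available. Visual inspection and ICA denoising from the
  original workflow are deliberately replaced by this deterministic rule.
- **Initial dynamics**: the first five dynamics (15 s at TR = 3 s) are
  dropped from on-disk recordings in both modalities; synthetic cohorts are
  generated post-drop.
- **250 Hz EEG** is an input expectation (the original data were
  downsampled from 5 kHz during artifact correction, which is out of scope);
  the generator emits 250 Hz directly.
- **Band policy**: all four bands feed the band summary; inferential outputs
  default to beta2, mirroring the restriction used to limit comparisons.
- **Seeds**: one master seed per run; sub-seeds are derived deterministically
  per recording and per ensemble member, all kept below 2^31.
- **Provenance**: every output directory carries a MANIFEST.json with the
  config hash (MD5 of the serialized configuration), seed, per-stage counts
  (epochs kept, edges per level, ensemble sizes) and file checksums; two
  runs with equal hashes are byte-identical.

## Problem sizes used by the test suite

The suite validates kernels against exhaustive brute force (500 random
graphs of ≤ 8 nodes; Floyd–Warshall and triangle counting), and runs the
cohort-level claims at reduced cost chosen to keep the planted effect's
detectability realistic: 14 paired + 20 control subjects, 31 EEG channels,
4000 samples per recording (the full design is 135 000), null ensembles of
5 per graph, 50 replicates for power and 60 for the null family-wise rate.
At these sizes the planted pattern — HC above R1 and R2 above R1 in γ and σ
over a contiguous mid-sparsity range surviving FDR — is recovered in ≈100%
of replicates, and null cohorts reject at the nominal rate. The same
computations, from scratch, are what `scripts/acceptance.R` reports.

## Limitations

- Connectivity is plain correlation of band-passed signals; coherence or
  phase-based EEG coupling, partial correlation and dynamic connectivity are
  out of scope.
- Graphs are binary and undirected; weighted metrics, modularity, rich-club
  and lattice-referenced small-worldness variants are not computed.
- The regional γ aggregation over the sparsity grid is one defensible
  reading of a convention the source analyses leave unstated.
- The multiple-testing family behind published descriptive thresholds is
  not recoverable; this package fixes its families explicitly (per contrast
  x metric across levels; per contrast across nodes) and logs them.
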