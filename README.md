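# mmgraph

Multi-modal small-world graph analysis of simultaneous EEG–fMRI.

Low-frequency repetitive transcranial magnetic stimulation (rTMS) is used
therapeutically in focal dystonias such as writer's cramp, but what a single
session does to whole-brain network topology is hard to see with motor
physiology alone. `mmgraph` implements the full analysis chain used to ask
that question with simultaneous EEG–fMRI: band-limited EEG and ROI-level
fMRI time series are turned into Pearson connectivity matrices, binarized
over a fixed sparsity grid so every subject's graph has the same number of
edges, and summarized by null-normalized small-world metrics that are then
compared across healthy controls (HC), pre-rTMS (R1) and post-rTMS (R2)
sessions, per sparsity level and per node, with a final across-subject
correlation of EEG-electrode and fMRI-ROI clustering changes.

For a binary graph with mean clustering coefficient *C* and characteristic
path length *L*, and an ensemble of degree-matched Maslov–Sneppen random
references with means *C_rand* and *L_rand*:

- normalized clustering **γ = C / C_rand**
- normalized path length **λ = L / L_rand**
- small-worldness **σ = γ / λ** (σ > 1: lattice-like clustering with
  random-like path lengths)

Graphs are binarized at sparsity S ∈ {0.11, 0.12, …, 0.45} (fraction of
possible edges retained), group contrasts use pooled two-sample t-tests
(HC vs R1, HC vs R2) and paired t-tests (R1 vs R2) with Benjamini–Hochberg
FDR across the 35 levels, regional tables report Cohen's
d = (m₂ − m₁)/√((s₁² + s₂²)/2) and effect size r = d/√(d² + 4), and
cross-modal pairs are significant when |r| > 0.4 and p ≤ 0.05 across
subjects.

Because no patient recordings are distributed, the package ships a seeded
synthetic-cohort generator (`generate_cohort()`) that emulates the study
design — 14 paired R1/R2 patients plus 20 controls, 31 EEG channels at
250 Hz, 160 fMRI ROIs at TR = 3 s — with a plantable clustering boost in R2,
so the whole pipeline is testable end to end.

## Worked example

```r
library(mmgraph)

## Small-world metrics of a single graph
g <- generate_small_world_graph(n_nodes = 100, k = 6, p_rewire = 0.05, seed = 1)
m <- normalized_metrics(g, n_null = 50, seed = 2)
sprintf("C=%.3f L=%.3f gamma=%.2f lambda=%.2f sigma=%.2f",
        m$C, m$L, m$gamma, m$lambda, m$sigma)
#> "C=0.567 L=5.171 gamma=12.53 lambda=1.88 sigma=6.66"
```

The graph keeps the ring lattice's clustering (γ ≫ 1) at only modestly
inflated path length (λ = 1.88), hence strongly small-world (σ = 6.66).

```r
## A synthetic cohort through the group pipeline (beta2 band, 20-30 Hz)
spec <- synthetic_cohort_spec(n_paired_subjects = 14, n_hc_subjects = 20,
                              n_eeg_channels = 31, n_fmri_rois = 16,
                              eeg_samples = 4000, fmri_volumes = 40,
                              ws_k_fmri = 4, seed = 42)
coh <- generate_cohort(spec)
eeg <- coh$manifest[coh$manifest$modality == "eeg", ]
curves <- lapply(seq_len(nrow(eeg)), function(i) {
  ts <- bandpass_filter(coh$recordings[[eeg$recording_id[i]]], 20, 30)
  curve_long(metrics_over_sparsity(correlation_matrix(ts), n_null = 5,
                                   seed = 1000 + i * 200))
})
compare_metric_curves(do.call(rbind, curves), "gamma", "R1_vs_R2")
#> <mm_group_comparison> R1_vs_R2 (paired), 35 units, 35 FDR-significant [11%-45%]
```

The planted post-stimulation clustering boost is recovered at every level of
the sparsity grid: at S = 0.20 the paired contrast gives R1 γ = 1.22 ± 0.16
vs R2 γ = 4.18 ± 0.75 (t = −15.0, Cohen's d = 5.44), and the significant
range is reported in the conventional percent notation (`11%-45%`).

`run_study(study_config(...))` executes the same chain for both modalities of
a cohort (in memory, on disk via `write_cohort()`/`read_cohort()`, or
generated from a spec) and writes curves, per-sparsity comparison tables,
regional effect-size tables, the cross-modal pair table, BrainNet Viewer
`.node` files and a `MANIFEST.json` carrying the config hash and seed;
reruns with the same seed are byte-identical.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/mmgraph-run.R --config study.json --seed 42 --out results/
```

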