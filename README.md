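# wmcoupling

Structure–function coupling of white-matter connectivity: quantify how
white-matter **BOLD functional connectivity** (FC) relates to band-limited
intracranial **SEEG FC**, and how both are constrained by streamline-count
**structural connectivity** (SC), on networks whose nodes are depth-electrode
contacts in white matter.

The package is written for researchers working with simultaneous-implant
cohorts (SEEG + preoperative fMRI + diffusion tractography) and for
methodologists who want a fully synthetic, ground-truth-controlled testbed of
the analysis chain.

## The statistics at the core

For each participant and each SEEG band
(1–4, 4–8, 8–13, 13–30, 30–40, 40–70, 70–170 Hz):

1. Half-vectorize the two connectivity matrices into edge vectors over
   unordered contact pairs.
2. Regress the pairwise Euclidean distance `d_ij` out of each edge vector by
   OLS (`y ~ 1 + d`), since proximity inflates connectivity in every
   modality.
3. Spearman rank correlation `r` between the residual vectors (mid-ranks for
   ties; two-sided p from the t approximation with `n_edges − 2` df).
   For SC comparisons, only pairs with `SC > 0` enter.
4. Benjamini–Hochberg FDR across **all participants × all bands** within each
   comparison family (`bold_vs_seeg`, `sc_vs_seeg`, `sc_vs_bold`);
   per-band medians of `r` across participants summarize the study.

Upstream of the statistics: SEEG conditioning (third-order Butterworth
0.5–300 Hz bandpass, power-line band-stops at 49–61 … 299–300 Hz, all
zero-phase; flat/noisy channel exclusion; white-matter common average
reference; ten 6 s segments averaged into one trace), per-band Pearson FC
(or Welch coherence), sphere-ROI BOLD extraction (19 voxels ≈ 3 mm radius at
2 mm; 7 and 27 variants), BOLD temporal preprocessing (drop 5 volumes,
detrend, optional 24-parameter confound regression, 0.01–0.2 Hz bandpass),
and streamline counting between 2 mm contact spheres.

Because patient recordings cannot be redistributed, the package ships a
synthetic study generator (`synth_config()`, `synth_participant()`) whose
participants have *known* coupling: a sparse distance-dependent structural
network, a two-timescale neural model (fast coupled autoregressive network
plus network-mixed infra-slow excitability fields), and BOLD as an
HRF-convolved noisy envelope rendered into 4D volumes. `coupling_strength`
dials the ground truth; `0` is an exact null.

## Worked example

```r
library(wmcoupling)

study <- study_config(
  participants   = 2,                                  # synthetic
  synth_template = synth_config(coupling_strength = 0.5),
  seed           = 7)
res <- run_study(study)
res$band_summary
```

```
     comparison   band median_r n_participants n_significant
1  bold_vs_seeg    1-4   0.1668              2             2
2    sc_vs_seeg    1-4   0.2788              2             1
3  bold_vs_seeg  13-30   0.2351              2             2
4    sc_vs_seeg  13-30   0.7460              2             2
5  bold_vs_seeg  30-40   0.1420              2             2
6    sc_vs_seeg  30-40   0.4688              2             2
7  bold_vs_seeg    4-8   0.1458              2             2
8    sc_vs_seeg    4-8   0.4852              2             2
9  bold_vs_seeg  40-70   0.1553              2             2
10   sc_vs_seeg  40-70   0.4602              2             2
11 bold_vs_seeg 70-170   0.0908              2             1
12   sc_vs_seeg 70-170   0.1962              2             0
13 bold_vs_seeg   8-13   0.2370              2             2
14   sc_vs_seeg   8-13   0.3370              2             2
15   sc_vs_bold   bold   0.8030              2             2
```

Each row is a (comparison, band) cell: `median_r` is the median
distance-residualized Spearman correlation across participants — e.g. BOLD FC
and 13–30 Hz SEEG FC share rank structure at `r ≈ 0.24` — and
`n_significant` counts participants whose FDR-adjusted p is below 0.05. The
full per-participant table is in `res$table` (columns `participant`, `band`,
`comparison`, `r`, `p`, `n_edges`, `p_fdr`, `significant`).

The per-stage operations are exported individually
(`broadband_filter()`, `powerline_notch()`, `common_average_reference()`,
`segment_and_average()`, `band_filter()`, `pearson_fc()`, `coherence_fc()`,
`extract_roi_timeseries()`, `bandpass_bold()`,
`count_streamline_connections()`, `couple_fc_fc()`, `couple_sc_fc()`,
`fdr_correct()`, `summarize_bands()`), so real data can be driven through
any subset of the chain; `run_study()` also accepts per-participant file
paths (contacts TSV, panel TSV, NIfTI volume, streamline text).

See `vignettes/wmcoupling-methods.Rmd` for the model, parameter rationale,
and what the synthetic tests do and do not demonstrate.

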