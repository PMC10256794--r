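---
title: "Methods: structure-function coupling of white-matter connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-function coupling of white-matter connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Depth (SEEG) electrodes implanted for epilepsy surgery leave many contacts in
white matter. White-matter BOLD signals were long treated as nuisance, yet
they carry a correlation structure. This package implements the analysis
chain for asking, on networks whose nodes are white-matter contacts:

1. Does white-matter BOLD functional connectivity (FC) agree with intracranial
   SEEG FC, band by band (1-4, 4-8, 8-13, 13-30, 30-40, 40-70, 70-170 Hz)?
2. Are both constrained by streamline-count structural connectivity (SC)?

Every comparison is a Spearman rank correlation between half-vectorized
connectivity matrices after ordinary-least-squares removal of the Euclidean
distance between contact pairs, because proximity inflates connectivity in
every modality. SC comparisons are restricted to pairs with nonzero
streamline counts. P values are Benjamini-Hochberg corrected jointly across
all participants and all bands within each comparison family, and per-band
medians across participants summarize the study.

Patient recordings cannot ship with a package, so a synthetic study
generator with known ground-truth coupling stands in for them: every stage
of the pipeline is exercised, and its statistical behavior (null
calibration, recovery) is verified against that ground truth.

## Pipeline stages and their parameters

**SEEG conditioning.** Raw panels (channels x samples at 2000 Hz; 2048 Hz
recordings are polyphase-resampled) pass through a third-order Butterworth
0.5-300 Hz bandpass and cascaded third-order band-stops at 49-61, 99-101,
149-151, 199-201, 249-251 and 299-300 Hz. All filters are applied zero-phase
(forward-backward). The filters' one-pass order is 3; zero-phase application
squares the magnitude response. Zero-phase was chosen because a one-pass
IIR filter delays each channel identically only in the passband; any
channel-specific transient would bias correlation FC. Channels are excluded
when flat (variance below `flat_tol`, default 1e-10) or when the robust z
score of their log variance exceeds `noise_z` (default 5) — a programmatic
stand-in for exclusion by visual inspection. Remaining channels are
re-referenced to the common average of all white-matter channels. A 60 s
excerpt is split into ten 6 s segments whose pointwise average is the
analysis trace (4 s and 8 s variants supported); averaging raises SNR at the
cost of treating the segments as repeated observations of a common pattern.
Note that at the band edge, the 49-61 Hz stop delivers about 13 dB at
exactly 50 Hz (deepest attenuation is mid-band); this follows from the
third-order design itself.

**Band FC.** Each band is a zero-phase third-order Butterworth bandpass of
the averaged trace; FC is the Pearson correlation across the full trace.
A coherence alternative (Welch: 1 s Hann windows, 50% overlap,
magnitude-squared coherence averaged over in-band frequency bins) is
provided for sensitivity analysis. The segment-averaging step is implemented
literally as time-domain averaging; per-segment FC averaging is a plausible
alternative we deliberately did not make the default.

**BOLD.** ROI time series are sphere means around each contact on the 2 mm
grid: 19 voxels (3 mm radius) by default, 7 or 27 as variants. The temporal
chain is: drop the first five volumes, demean/detrend, optionally regress a
confound table (e.g. 24 motion regressors), zero-phase Butterworth bandpass
0.01-0.2 Hz (0.01-0.08 Hz variant), Pearson FC. Extraction happens before
nuisance regression; the alternative order is not implemented. Full
anatomical preprocessing (registration, distortion correction,
normalization) is out of scope: the package consumes voxel grids already in
a common frame with a diagonal affine.

**SC.** Edges count streamlines connecting two contact spheres (radius one
voxel = 2 mm by default, separate from the 3 mm BOLD sphere). A streamline
connects a pair if any of its points lies in both spheres' radius
(pass-through convention, since tracking software conventions differ);
polylines are densified at 0.5 mm — the tracking step length — so a segment
crossing a sphere between stored vertices still counts. Voxel assignment
rounds half away from zero on each axis; the convention is asserted in
tests because no standard fixes it.

**Coupling statistics.** Half-vectorization uses lexicographic (i, j) order,
i < j. Distance is residualized by OLS with an intercept on raw (not
rank-transformed) distances, before ranking; the Spearman statistic is the
Pearson correlation of mid-ranks, with a two-sided p from the t
approximation on n - 2 degrees of freedom (an exact permutation p is
available for n <= 8). Edges with undefined FC (a zero-variance channel) are
dropped pairwise with a message. For SC comparisons the mask (SC > 0) is
applied first and distance is residualized within the masked set; the
alternative (residualize, then mask) answers a subtly different question and
is not the default. BH-FDR is applied within each comparison family across
all participants x bands jointly; families are not pooled.

## The synthetic study generator

The generator emulates, per participant:

- **Geometry** — `n_contacts` (default 30, matching the per-participant
  white-matter contact counts of implanted cohorts) scattered uniformly in
  an 80 mm box with a minimum separation of 8 mm. Eight millimetres (4
  voxels) provably prevents two 19-voxel sphere neighborhoods from sharing
  a voxel; the naive bound of twice the voxel size does not.
- **Structural network** — edge probability
  `min(1, sc_density * exp(-distance_decay * d))` (defaults 0.8 and
  0.04/mm), weights `1 + Poisson(3)`. The result is sparse with many zero
  connections, as real streamline matrices are. For every counted
  streamline a polyline is emitted whose endpoints lie inside the two
  contact spheres and which is re-routed (jittered midpoint) until it
  clears every other contact's counting sphere, so streamline counting
  recovers the weights exactly — a round-trip the tests assert.
- **Neural dynamics** — a two-timescale model.
  The fast component is a stable linear stochastic network at 2000 Hz,
  `z_t = (a I + K) z_{t-1} + e_t` with self-coupling `a = 0.85` and
  `K = coupling_strength * 0.14 * W / rho(W)`. The one-sample coupling lag
  makes the cross-spectrum's real part change sign where `cos(2 pi f / fs)
  < a`; at `a = 0.85` that is 176 Hz, just above the top analysis band, so
  band-limited correlations stay positive in all seven bands. The drive has
  a 1/f-like low-frequency boost (each node's white input mixed with its
  one-pole-filtered copy, pole 0.98). Spectral-radius normalization keeps
  the system stable for `coupling_strength <= 1`; larger values are
  rejected. A 10 s burn-in is discarded. On top, each node is multiplied by
  an infra-slow excitability field `exp(0.5 * s_i)`: unit-variance slow
  processes (autocorrelation time 3 s, simulated at 2 Hz — slow enough to
  survive HRF smoothing, fast enough to supply many independent
  fluctuations per scan) mixed across the
  network as `I + 3 * coupling_strength * W / rho(W)`. A purely linear fast
  model transmits only about the square of the fast correlation into
  amplitude envelopes — far too weak a cross-modal channel; slow
  co-modulation of excitability is the physiologically motivated route by
  which coupling reaches the hemodynamic signal. With
  `coupling_strength = 0` both channels vanish and nodes are exactly
  independent, which is what makes the null calibration clean.
- **BOLD** — per node, the 1 s moving-RMS envelope of the neural signal is
  mapped onto the scan timeline, convolved with a canonical double-gamma
  HRF (peak ~5 s, undershoot ~15 s) on a 0.5 s grid, sampled at TR = 2 s,
  standardized, and given white noise of SD 0.2 (roughly the thermal noise
  of a standardized gray/white-matter voxel average). The neural process
  spans the whole 480 s acquisition by default; the SEEG stage analyses its
  first 60 s, the way one selects an excerpt from a chronic recording while
  the scanner sees the full session.
- **Volumes** — each contact's BOLD series is painted into its 19-voxel
  neighborhood on the 2 mm grid; everywhere else is independent noise.
  Rendering refuses overlapping neighborhoods rather than blending them.

What the generator does **not** emulate: epileptiform transients, scanner
artifacts and motion, spatial autocorrelation of the BOLD background,
gray-matter signal leakage, non-stationarities, and any realistic vascular
geometry. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under a faithful-but-idealized forward model,
not that the scientific conclusions transfer to any particular patient
cohort.

### Calibration of the generator defaults

The defaults are fixed study conditions, chosen once: 2000 Hz LFP, TR 2 s,
240 volumes, 2 mm voxels and the 60 s / ten 6 s segment scheme are the
acquisition values; 30 contacts per participant matches implanted cohorts;
`ar_self`, `coupling_gain` and the modulator parameters were set by design
calculation (stationary covariance of the two-node system; sign analysis of
the cross-spectrum) so that `coupling_strength = 0.5` yields connected-pair
broadband correlations near 0.4 and reliably detectable coupling at
realistic edge counts, while `coupling_strength = 0` is an exact null.

```{r}
library(wmcoupling)
study <- study_config(participants = 2,
                      synth_template = synth_config(coupling_strength = 0.5),
                      seed = 1)
res <- run_study(study)
res$band_summary
```

## Numerical choices and degenerate inputs

- All floating text output is written at 12 significant digits so
  write/read round-trips are testable (1e-9).
- Voxel rounding: half away from zero, per axis.
- Filters: `signal::butter` designs; zero-phase application is a C++ kernel
  that reproduces `signal::filtfilt`'s zero-padded forward-backward
  convention across all channels at once.
- Spearman ties: mid-ranks everywhere. Constant vectors are an explicit
  error, not a silent `NA`.
- A constant distance vector (degenerate geometry) is an explicit error.
- Rank-deficient confound designs drop dependent columns with a warning.
- Zero-variance channels propagate as named warnings and pairwise edge
  drops, never silent `NaN`s.
- RNG: one study-level seed; every stage derives an independent substream
  via a small string hash, so artifacts are pure functions of
  (config, seed) and participant order cannot leak randomness across
  stages.

## Problem sizes used in validation

The packaged experiments run at desk scale, chosen as the smallest sizes at
which the questions are still meaningfully posed: null calibration uses 100
participants with 20 contacts, 15 s of LFP and 120 volumes; recovery uses
20 participants at the full default conditions (30 contacts, 480 s LFP,
240 volumes). The per-band medians those runs print (roughly 0.1-0.25 for
BOLD vs SEEG and 0.25-0.6 for SC vs FC at `coupling_strength = 0.5`) are in
the range reported for real cohorts, which is a sanity check on realism,
not a fit.

## Known limitations

- The envelope-plus-HRF forward model is a stand-in, not a mechanistic
  claim; the real LFP-to-white-matter-BOLD transform is unknown.
- Coherence FC is Welch-windowed at 1 s; very narrow bands (width below
  1 Hz) would have too few bins.
- The streamline counter counts each streamline once per connected pair; if
  a tracking tool counts per crossing, absolute weights differ (rank
  statistics are largely insensitive).
- No spatial-autocorrelation-preserving nulls (spin tests) and no
  group-level mixed models; inference is per participant with joint FDR.
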