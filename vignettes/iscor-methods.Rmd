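---
title: "Methods: intersubject correlation, mediation, temporal windows and coherence in iscor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intersubject correlation, mediation, temporal windows and coherence in iscor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`iscor` implements an analysis stack for multi-subject naturalistic-stimulus
BOLD recordings: intersubject correlation (ISC) within and across stimulus
conditions, chunk-shuffling permutation inference with generalized-Pareto
(GPD) tail p-values and max-statistic familywise-error (FWE) control,
model-mediated ISC, temporal-receptive-window (TRW) mapping, and wavelet
coherence of stimulus descriptor streams. This vignette records the models,
the tunable parameters, and the design decisions — in particular the choices
made where the underlying methodology leaves details open.

## 1. The ISC model and its statistic

A `bold_group` holds one condition's subjects as voxel × timepoint matrices
at a fixed TR, concatenated across runs. Correlations are computed on
run-concatenated series **after per-run mean removal**: runs are normalized
per run during standard preprocessing, so run means carry no stimulus
information, and removing them prevents slow inter-run offsets from
masquerading as synchronization. (Whether the mean is removed before or
after concatenation is immaterial for the within-run signal; we remove it
per run, before any smoothing.)

`isc_within` averages Pearson r over all N(N−1)/2 unordered pairs;
`isc_across` over all N~A~ × N~B~ cross pairs only, so that every pair
spans the two conditions (10 × 10 → 100 pairs; 9 × 9 → 81). Plain r values
are averaged, **not** Fisher-z transformed: the map reports the mean pair
correlation itself. The per-voxel statistic is

t = r̄ / (sd(pair r) / √n_pairs),

which treats pair correlations as independent observations. They are not —
pairs share subjects — but the statistic is only ever referred to its own
permutation distribution, which reproduces the same dependence, so
calibration is inherited from the null, not from a t reference
distribution. Voxels with an undefined pair correlation (zero variance)
are marked invalid (`NA`) and excluded.

## 2. Surrogate-based inference

The null model is absence of stimulus-locked shared signal. Surrogate
series (`surrogate_series`) splice each run into `chunks_per_run = 3`
contiguous chunks (remainder timepoints to the run's last chunk), pool the
chunks of **all** runs (18 for a 6-run scan), permute them globally, and
time-reverse each chunk independently with probability 1/2. Pooling across
runs (rather than within) treats the chunk set as one pool; per-chunk
reversal maximizes surrogate entropy while preserving each series' value
multiset — hence mean and variance — exactly, and local autocorrelation
approximately. In each permutation **every subject's every voxel** is
surrogated independently (both members of every pair; one-sided surrogacy
is not used because the null hypothesis concerns all subjects).

Empirical p-values use the (1 + k)/(n + 1) estimator, never zero. When the
empirical p falls below 0.10, the upper tail is modelled by a GPD fitted by
maximum likelihood to the exceedances over the 90th percentile; the fit is
checked with an Anderson–Darling test at the 5% level against the
Choulakian–Stephens asymptotic critical values (interpolated over the
shape), and on rejection the threshold is raised by dropping the 10
smallest exceedances and refitting; with fewer than 30 exceedances left
the empirical estimate is returned. The tail p is floored at machine
precision. These constants (90th percentile start, batches of 10, floor of
30) follow common tail-approximation practice; they are our choice.

FWE control thresholds the observed map at the empirical 95th percentile
(linear interpolation) of the per-permutation maximum statistic.
Significance masks are then cluster-extent filtered: supra-threshold
voxels are grouped by 18-connectivity (face + edge; 6 and 26 available)
and components below 20 voxels removed. The defaults (18, 20) reflect
common volumetric practice.

One caveat worth stating: because each voxel is referred to its **own**
permutation distribution, p-values are not globally monotone in the
observed t across voxels; a pooled null would restore monotonicity but is
not what the procedure specifies.

## 3. Model-mediated ISC

Feature models (`feature_model`) are time × feature matrices at their
native rate, tagged `low_auditory`, `low_visual`, `high_semantic`, or
`editing`. Before use, every model is orthogonalized against the editing
descriptors (`orthogonalize`): each column is replaced by the residual of
its regression on an intercept plus all editing columns, since cuts, scene
transitions and dialogue structure inject variance into both low- and
high-level descriptors.

`build_design` aligns a model to BOLD space: columns are convolved with a
canonical double-gamma haemodynamic response (gamma shapes 6 and 16 at
rate 1 — response peak 5 s, undershoot 15 s, peak:undershoot 6:1), averaged
within TR bins, z-scored per run, and per-run intercept columns are
appended. HRF convolution is **our addition** — the feature-to-BOLD
alignment is otherwise unspecified — and can be disabled (`hrf = FALSE`)
for lag-zero regression. `residualize_bold` replaces every series by its
least-squares residual against the design (adding an intercept unless the
design already carries run intercepts); the regression runs on
run-concatenated data with per-run intercepts, mirroring run-wise
normalization.

`mediated_isc` computes ISC before and after residualization; the per-voxel
**drop** (original − mediated) measures how much synchronization the model
carries. Its significance (`drop_significance`) uses the same surrogate
machinery, one-tailed on the drop, with max-drop FWE and cluster
filtering. For contrasting two models, the drop is decomposed per subject
pair (r_pair(raw) − r_pair(residualized), `pairwise_drops`) and a
two-sided Wilcoxon signed-rank statistic (W = sum of ranks of positive
differences, midranks, zeros dropped; voxels with fewer than 5 non-zero
differences are untestable) is referred to a sign-flip null: each pair's
difference is flipped with probability 1/2, with the flip pattern shared
across voxels so the spatial maximum is meaningful. FWE thresholds are the
95th percentile of max-W and 5th of min-W; with 2^n_pairs ≤ n_permutations
the flip null is enumerated exhaustively. Note that removing a model that
carries a fraction f of the shared **variance** reduces the correlation by
a factor ≈ f only in the weak-correlation regime (shared variance ≪ noise
variance); at high ISC the relation is nonlinear.

## 4. Temporal receptive windows

`trw_profile` smooths every (per-run-demeaned) series with rectangular
sliding windows — default widths 2 to 240 s in 2 s increments, stride one
timepoint, **full windows only** (no padding: padded edges would bias
long-window correlations) — recomputes ISC at every width, and takes per
voxel the width of maximal mean r (`trw_peak`). Mean r, not t, is
maximized. Ties break toward the **smallest** width, the most conservative
temporal-integration claim. The row at width = 1 TR is exactly the
classical ISC map (the same correlation engine runs on unsmoothed data).

Significance (`trw_significance`) is voxel-tuned: each permutation
surrogates all subjects and evaluates ISC **at that voxel's observed peak
width** (re-maximizing over widths per permutation would be stricter and
is not the default). Map similarity between chronotopic maps
(`map_similarity`) is Spearman's ρ over a voxel mask, referred two-sided
to peak maps recomputed from surrogate data (`trw_null_maps`; 200 by
default), which preserve the maps' spatial smoothness.

## 5. The synthetic-data generator

`generate_bold_groups` emulates the statistical structure of a study in
which distinct groups receive corresponding stimulation: per shared voxel
one latent series embedded in **every subject of both groups** with weight
`shared_amplitude`; optional stimulus-driven components `model_amplitude ·
(design × weights)` with per-voxel random weights; independent AR(1) noise
per subject (unit innovation variance, coefficient 0.3 — a typical BOLD
lag-one autocorrelation, configurable; the noise spectrum of real
preprocessed data is not characterized here, so AR(1) is a stand-in);
noise re-initialized at run boundaries, one continuous latent across runs;
everything emitted per-run demeaned ("preprocessed"). Defaults mirror the
study scale: 10 subjects per group, 1,614 timepoints at TR = 2 s in 6 runs.

**The latent is band-limited, not lowpass.** A moving-average (lowpass)
latent cannot serve TRW recovery: with a lowpass signal plus noise,
smoothing always improves the signal-to-noise ratio, the expected
ISC-versus-width profile is monotone increasing, and the peak sits at the
largest window regardless of the planted timescale. The latent is
therefore a random-phase sinusoid, and its period is **calibrated by
numerically inverting the expected profile**: for a candidate period the
generator computes the expected sample variance of the smoothed latent
(per phase, per-run demeaned, the same moving-average code the analysis
uses) and of the smoothed run-demeaned AR(1) noise (a small fixed-seed
internal Monte-Carlo), forms their ratio across widths, and bisects for
the period whose profile peaks at the declared timescale. The calibration
target is the median over phases of the per-phase argmax, since each
realized voxel has a single phase. Run demeaning matters here: it
suppresses smoothed-noise variance as the window approaches the run
length, and ignoring it biases recovered peaks upward by several width
steps at long timescales.

`generate_feature_models` builds editing columns as independent boxcar
trains (events of 4–20 s, ~30 s mean spacing) and model columns as
`c · (standardized editing blend) + √(1−c²) · unique smooth component`, so
a column's squared multiple correlation on the editing set is c² in
expectation. `generate_stimulus_streams` returns two independent noise
streams sharing, inside each declared event, a common sinusoid at the
event period (amplitude 1 by default: within a wavelet band this is far
above the in-band noise floor, giving high in-event coherence while
limiting the temporal bleed of the detected event).

What the generator does **not** emulate: haemodynamic forward dynamics,
spatial correlation between voxels, head motion, scanner drift, or
realistic 1/f noise spectra. Passing recovery tests therefore demonstrates
the correctness and calibration of the analysis machinery under the
generative assumptions — not robustness to every artefact of real data.

## 6. Wavelet coherence

`cwt_morlet` is an analytic Morlet transform (centre frequency ω₀ = 6,
Fourier-domain implementation, zero padding to a power of two). Coherence
follows standard cross-wavelet practice: cross- and auto-spectra scaled by
1/scale, smoothed in time by a Gaussian of width equal to the scale and
across scales by a 0.6-octave boxcar; the default period grid is
log-spaced at 12 voices per octave from 4/fs to a quarter of the stream
duration. The cone of influence marks cells within the e-folding distance
√2·scale of an edge. Self-coherence is identically 1 outside the cone;
coherence is clamped to [0, 1].

`coherent_events` thresholds the plane outside the cone and groups cells
by 8-connectivity. Two rules suppress noise blobs whose footprint is just
the smoothing kernel: components smaller than 5 cells are dropped, and a
component must span at least `min_cycles = 3` of its own (coherence-
weighted mean) period — the combined wavelet-and-smoothing kernel has an
e-folding footprint of about 2.7 periods, so anything shorter is
indistinguishable from the kernel's own spread. The threshold is either fixed (0.9) or calibrated
on surrogate pairs (`coherence_null_threshold`: phase-randomized copies of
both streams) — both are offered because no canonical criterion for
"highly coherent" exists. The calibrated default is a **pointwise**
cluster-forming quantile (1 − α of all null cells outside the cone, α =
0.001), combined with the extent rules above — the direct analogue of
cluster-forming plus cluster-extent thresholding of statistical maps. A
familywise variant (`type = "max"`: quantile of the per-surrogate maximum)
is available but deliberately not the default: the max of the null plane
sits near the upper envelope of noise coherence and can exceed the plateau
of genuine moderate-amplitude events. Event onset/duration
accuracy is limited by the combined wavelet-envelope and smoothing spread,
roughly the kernel's e-folding diameter 2√2·scale (≈ 22 s at period 8 s).

## 7. Numerical and interface choices

- Voxel ordering: in-mask voxels are flattened in ascending linear index
  of the mask grid; the inverse mapping is kept in the group geometry, so
  emitted maps re-read exactly.
- All statistical volumes are written unthresholded with companion p and
  mask volumes, so thresholds can be revised without recomputation.
- `run_pipeline` orchestrates the three-experiment logic (within-condition
  ISC → across-condition ISC → conjunction → second-population ISC on the
  conjunction voxels → mediation with cross-modal low-level and shared
  high-level assignment → model contrast → TRW maps and similarities),
  writes a JSON manifest with versions, seed and parameters, and skips —
  with an explicit log line — stages whose inputs are missing. The
  package's functions and this driver are the interface; there is no
  separate shell executable.
- Degenerate inputs fail loudly and specifically: zero-variance series name
  the offending series; mismatched grids name the offending file;
  rank-deficient designs are rejected (rank-deficient *editing* matrices
  are pruned with a warning, since dropping redundant nuisance columns is
  safe).
- Reproducibility: every stochastic routine takes a seed
  (`surrogate_spec$seed`, `sim_spec$seed`, function arguments) and restores
  the caller's RNG state afterwards; identical inputs give bit-identical
  outputs.

## 8. Problem sizes in the test suite

The suite exercises the stack at sizes chosen to make Monte-Carlo checks
sharp while keeping a full run in minutes: oracle-equivalence instances of
up to 5 subjects × 10 voxels × 50 timepoints (checked to 1e−12 against
double-loop references); calibration runs of 5 + 5 subjects × 200 voxels ×
300 timepoints with 500 permutations (the type-I rate is pooled over three
such datasets, since a single 200-voxel dataset estimates a 5% rate with
sd ≈ 0.015); FWE calibration over 100 null datasets of 4 + 4 subjects ×
40 voxels with 200 permutations each; TRW recovery at the full study scale
(10 + 10 subjects, 1,614 timepoints, 6 runs) with 50 replicates per
planted timescale, scored on the across-condition profile; and
coherent-event recovery on 150 s streams at 25 Hz.

## 9. Known limitations

- The pair t-statistic's independence assumption is absorbed by the
  permutation null but makes the *nominal* t scale uninterpretable on its
  own.
- GPD tail p-values below ~1/n_permutations are extrapolations; their
  accuracy degrades for very heavy observed exceedance tails.
- TRW peak extraction by argmax is noisy for profiles that are flat near
  their maximum (long timescales); recovered peaks carry an upward scatter
  of roughly one width step under the default conditions.
- The cluster-extent filter assumes the mask grid is meaningful
  volumetrically; groups without geometry fall back to unclustered
  thresholding.
- `resample_model` uses linear interpolation; strongly non-smooth
  descriptors sampled near their Nyquist rate should be binned upstream
  instead.
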