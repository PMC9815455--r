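---
title: "Removing ocular artifacts from continuous-reading MEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing ocular artifacts from continuous-reading MEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MEG recorded while a subject reads pages of continuous text is dominated,
on anterior sensors, by two ocular artifact families. The corneo-retinal
dipole of each eye — positive pole at the cornea, aligned with the gaze
axis — rotates with every saccade, producing step-like offset changes whose
size grows roughly linearly with saccade amplitude. During reading these
steps occur several times per second, march rightward along each text
line, and reset with a long return sweep at every line end, so the
continuous artifact is a semiperiodic ramp. A minority of saccades
(10–15% in skilled readers) are regressions and move backward. Blinks
short-circuit the ocular dipole as the eyelid slides over the eyeball,
producing solitary frontal, bilateral spikes lasting a few hundred
milliseconds. Both artifact families overlap the cortical signal in time
and frequency, so they must be separated out, not filtered or excised.

This package implements and compares two blind-source-separation routes:

1. **Two-stage (SOBI → FastICA).** Saccades are extracted first by
   second-order blind identification — joint approximate diagonalization
   of lagged covariance matrices, with the lag set enriched by every lag
   at which the subject's horizontal EOG autocorrelation reaches 0.3 —
   and removed; a negentropy-based fixed-point ICA then extracts blinks
   from the saccade-cleaned data. The order matters: removing blinks
   first disrupts the temporal structure SOBI needs for saccades.
2. **One-stage (AMICA-lite).** A simplified adaptive-mixture ICA models
   every source density as a mixture of three generalized Gaussians
   (`exp(-|(x-mu)/beta|^rho)` components, shape clamped to `[1, 4]`),
   optionally fitting several concurrent models with per-sample
   responsibilities; both artifact types are removed at once, using
   cross-model removal when the best saccade and blink components live in
   different models.

Both routes operate on the model `x(t) = A s(t) + n(t)` and remove
artifacts by `x_clean = x - A[, ind] W[ind, ] x`, computed at the
method's estimation scale (1e10 for FastICA, 1e8 for AMICA, 1 for SOBI)
and rescaled exactly.

## The synthetic world

The subject data behind the original comparison are not public, so the
package carries a first-class generator
(`sim_config()` / `simulate_reading_dataset()`) whose defaults state a
fixed world:

* 102 sensor sites on a mirror-symmetric spherical cap, two orthogonal
  planar gradiometers per site (baseline 16.8 mm), 600 Hz sampling;
* pages of 8 lines spanning 15.4° × 7.7° of visual angle; lognormal
  fixation durations (mean 220 ms, sd 60 ms); forward saccades of mean
  2°, regressions with probability 0.125, a return sweep at every line
  end (so each page contains exactly `lines_per_page` sweeps);
* Poisson blinks at 0.2/s lasting 300 ms, flagged as undefined gaze;
* ocular sources follow gaze position (baseline-offset model); the blink
  source is a squared half-sine pulse of amplitude 25 gaze-degree
  equivalents — blinks are the largest single frontal deflections, about
  three times a full-line ramp;
* mixing columns come from corneo-retinal dipoles at two fixed eye
  positions (±31, 82, −20 mm, mirrored, just inside the conducting
  sphere) through the closed-form dipole-in-a-sphere forward model;
  horizontal gaze tilts the dipole sideways, vertical gaze and blinks
  tilt it up/anterior;
* ten brain sources (amplitude-modulated oscillations plus 1/f
  background) at random intracranial locations with tangential
  orientations; the first is always an occipital 10 Hz oscillator so
  posterior-power retention is testable; brain projections are scaled to
  a median channel RMS of 1e-11 T/m (~100 fT/cm);
* artifact gain calibrated so frontal-sensor artifact RMS matches
  `snr_artifact` (default 0 dB) relative to frontal brain RMS; white
  sensor noise at 5% of the combined signal RMS.

A single integer seed drives all draws in a documented order (gaze
events, blinks, brain sources, noise), so identical configurations are
byte-identical. The construction identity
`data = A_art s_art + A_brain s_brain + n` holds exactly and the full
ground truth is retained for parameter-recovery tests.

**What the generator does not emulate** — and hence what a green test
does not establish: cortical geometry and individual anatomy;
spatially correlated (environmental) noise and its suppression;
microsaccades, tremor, drift and saccadic spike fields (argued to be
negligible for continuous data); head movement; EEG. Real recordings also
reach the decompositions rank-reduced by external-interference
suppression, which the world mimics only through the PCA reduction
applied before FastICA.

### Choices made where the papers were silent

* **Noise floor (5%).** With 30% white noise the blink source — active
  ~5% of the time — is only ~44% linearly recoverable from the sensors,
  so *no* unmixing can exceed |corr| ≈ 0.66 with the truth; that
  contradicts the near-0.99 cross-method blink correlations observed on
  real data. 5% reflects the effective floor of bandpassed,
  interference-suppressed gradiometer data and keeps the blink ~96%
  recoverable. This was fixed before the acceptance suite was frozen.
* **Saccade spectrum.** The baseline-offset model necessarily puts the
  position-signal's power at the ~0.5 Hz line-sweep fundamental; the
  4–20 Hz band reported for saccades describes the movement dynamics.
  The spectral check therefore asserts ≥60% of the *first difference's*
  power in 4–20 Hz (blink: ≥60% below 5 Hz on the source itself).
* **Artifact-to-brain ratio (0 dB at frontal sensors)** follows the
  build specification's stated default; real reading data are likely
  more artifact-dominated, which would only make extraction easier.

## Numerical and algorithmic choices

* **Joint diagonalizer.** Givens-rotation sweeps with the closed-form
  angle (the classic Jacobi-like scheme). The spec-level default angle
  tolerance (1e-9) is unreachable on noisy lagged covariances: rotations
  among noise-flat directions neither reduce the off-diagonal loss nor
  shrink below such a threshold, so `sobi_decompose()` uses the
  canonical sample-size-driven threshold `1/(100 sqrt(T))` and treats
  the sweep cap (100) as a warning-carrying stop, not a failure.
* **FastICA.** log-cosh contrast, symmetric decorrelation, tolerance
  1e-4 (the canonical epsilon of the original implementation), up to 5
  seeded restarts. Components report a negentropy proxy; when all
  proxies sit at the Gaussian baseline the rotation is unidentifiable
  and the result is flagged low-confidence. Non-convergence returns the
  final estimate with a warning by default (`on_fail = "error"`
  restores strict behaviour): on data with an iid-noise subspace the
  iteration keeps cycling in directions that carry no structure long
  after the artifact components have stabilized. For the same reason the
  pipeline reduces to 30 principal components before the fixed-point
  iteration.
* **AMICA-lite.** Natural-gradient updates preconditioned by the
  pairwise-Hessian (relative Newton) solve
  `[eta_i m_j, 1; 1, eta_j m_i] b = g` per component pair — without it
  the plain natural gradient needs thousands of iterations at ≥40
  channels and cannot meet the 200-iteration CI budget; this matches the
  reference lineage, which is Newton-accelerated. The learning rate
  anneals ×0.5 on any likelihood decrease (with the step reverted, so
  the recorded trace is non-decreasing) and recovers ×1.05, stopping at
  `max_iter` or when the rate falls below 1e-8. Fits are computed on at
  most 30 000 evenly strided samples (density estimates converge far
  below that; the reference binary also processes blocks); the demixing
  applies to the full recording. Shapes are clamped to `[1, 4]`,
  initialized at 1.5, locations at source quantiles, and the demixing at
  the whitening matrix plus a small seeded perturbation per model.
  Intentional simplifications versus the reference: no component sharing
  across models and no data-rejection heuristics.
* **Identification** is an automated surrogate for the original expert
  visual selection. A component is a *blink* when its spike count
  matches the tracked blink markers, |r| against the vertical EOG and
  its kurtosis pass, and its localization is ocular; it is a *saccade*
  when it is not blink-like, is ocular, and shows gaze-locked structure
  — a passing sawtooth template correlation *or* a passing EOG
  correlation. The disjunction matters: reading gaze has both a
  horizontal ramp component (strong horizontal-EOG correlation) and a
  vertical page-staircase component whose EOG correlations are diluted
  by blink deflections; the staircase is caught by its page-period
  sawtooth plus eye localization. The sawtooth detector looks for
  full-range jumps within a ~60 ms window (a line sweep traverses most
  of the component's range; single forward saccades move only a
  fraction of it) and correlates the component with the ramp template
  those resets imply. Thresholds (|EOG r| ≥ 0.6, eye fraction ≥ 0.5 of
  the top-500 leadfield-correlation points, kurtosis ≥ 5, sawtooth
  ≥ 0.6) are exposed in `identify_thresholds()`. The localization
  maximizes the Pearson correlation over tangential orientations in
  closed form, making the topography sign irrelevant; the grid embeds
  denser point clusters around the eyes so ocular sources are
  localizable at all.
* **Degenerate inputs.** Radial dipoles and sphere-centre dipoles return
  zero leadfields (documented physics, not errors); zero-variance
  topographies/EOG raise errors; beamformer divisions are guarded at
  `1e-12 × median` and flagged; rank truncation for the common DICS
  filter uses the smaller cleaned-condition rank.
* **Pipeline behaviour without artifacts.** `run_pipeline()` warns and
  returns the (demeaned) input when no component passes identification
  even after escalating to three AMICA models; `strict = TRUE` turns
  that into an error.

## Evaluation (DICS)

Band cross-spectral densities (Welch, 1 s Hann segments, 50% overlap —
the estimator is unstated in the source; this is the field default) are
computed for the uncleaned and both cleaned recordings in six bands
(1–4, 5–8, 8–13, 15–25, 31–47, 60–90 Hz). One common filter per band is
built from the averaged CSD with a pseudoinverse truncated to the
smaller cleaned rank, and applied to each condition's full-rank CSD.
Reduction maps are normalized by uncleaned power, pipeline differences by
the power the second pipeline removed; negative reductions (erroneously
estimated increases) are preserved. Grid points are aggregated into a
deterministic geometric parcellation (hemisphere × anterior/central/
posterior × superior/inferior + eye region) standing in for an
anatomical atlas, and group differences use two-sided uncorrected
t-tests at p < 0.005 with a 0.05 group-mean selection threshold —
deliberately uncorrected, since the aim is consistent large differences.

## Known limitations

* AMICA-lite's separation of the *saccade* source degrades when the
  ocular mixing columns excite only a handful of channels (few sensor
  sites) — second-order structure (SOBI) is the more reliable saccade
  route, which is exactly the two-stage pipeline's rationale.
* The spherical-cap geometry approximates, but is not, a commercial
  helmet; leadfield magnitudes are comparable only in order.
* The geometric parcellation supports group statistics on the shared
  synthetic grid; it does not map onto anatomical atlas labels.
* Serialization uses RDS rather than a hierarchical binary container,
  and FIF import is not provided (no reader available in the supported
  dependency set).

Every empirical number quoted above (recoverability fractions, band
fractions) is recomputed by the test suite; the vignette states no result
the tests do not check.
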