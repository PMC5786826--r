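---
title: "Correlated components and intersubject correlation of EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated components and intersubject correlation of EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isceeg)
```

## The model

When several subjects experience the same time-locked stimulus, part of
each subject's EEG is stimulus-driven and therefore correlated across
subjects, while the rest (background rhythms, artifacts, noise) is
subject-specific. Intersubject correlation (ISC) quantifies the shared
part without choosing electrodes or event markers in advance.

Writing `x_k(t)` for subject *k*'s `D`-channel voltage vector, the
un-normalized pairwise cross-covariances
`R_kl = Σ_t (x_k(t) − x̄_k)(x_l(t) − x̄_l)ᵀ` are pooled into the average
within-subject covariance `R_W = (1/N) Σ_k R_kk` and the average
between-subject cross-covariance
`R_B = (1/(N(N−1))) Σ_{k≠l} R_kl`. Correlated component analysis
(CorrCA) maximizes the between/within correlation ratio
`vᵀR_B v / vᵀR_W v`; the maximizers are the eigenvectors of
`R_W⁻¹R_B`. Each subject is then scored against the rest of the group,
per component, by `C_ik = v_iᵀR_b,k v_i / v_iᵀR_w,k v_i` with

* `R_b,k = (1/(N−1)) Σ_{l≠k} (R_kl + R_lk)` and
* `R_w,k = (1/(N−1)) Σ_{l≠k} (R_kk + R_ll)`,

and the subject's ISC is the sum of `C_ik` over the first `K = 3`
components. We implement `R_w,k` literally as the symmetrized average of
the subject's own and the peers' within-covariances, even though other
per-subject normalizations appear in the literature; by Cauchy–Schwarz
each `C_ik` then lies in `[−1, 1]`, which the code asserts on every run.
Because every ratio is scale-invariant, the covariance sums are left
un-normalized over time; a test verifies that rescaling them by
`1/(T−1)` changes no `C_ik`.

Component count `K = 3` is the conventional choice for this statistic
(the correlation mass beyond the third component is typically
negligible) and is configurable in `fit_corrca()`.

### Numerical treatment of the eigenproblem

`R_W` can be rank deficient: channels marked bad are zeroed so that they
contribute nothing to any covariance. Rather than pseudo-inverting the
full matrix, `fit_corrca()` whitens within the principal subspace of
`R_W` whose eigenvalues exceed `rank_tol` (default `1e-9`, relative to
the largest), solves the now-symmetric eigenproblem there, and maps the
eigenvectors back. Zeroed channels therefore receive exactly zero weight
in every projection. Eigenvalues are sorted descending with ties broken
by first occurrence; each projection is normalized to unit length with
its largest-magnitude entry made positive (eigenvector signs being
arbitrary). Forward models `a_i = R_W v_i / (v_iᵀR_W v_i)` map each
component back to expected channel voltages, and
`topography_similarity()` compares models by the absolute cosine of
index-matched forward vectors — matching by eigenvalue rank is a
deliberate choice, since no canonical cross-group component
correspondence exists.

One practical consequence of subspace whitening is that the
transformation-invariance of ISC (a common invertible spatial transform
applied to all subjects leaves every `C_ik` unchanged) holds numerically
to about `machine-eps × cond(R_W)`; the invariance test therefore uses a
cohort whose spatial noise correlation keeps `R_W` well conditioned.

## Preprocessing

The conditioning chain runs, in order: resample to 125 Hz, high-pass at
1 Hz, band-stop 59–61 Hz, EOG regression, robust PCA. Parameters sit in
`preprocess_recording()` with defaults `fs_target = 125`, `hp_hz = 1`,
`notch = c(59, 61)`, `order = 4`.

* **Resampling** is polyphase: zero-stuff by the numerator of the
  reduced rate ratio, zero-phase FIR low-pass at 0.9 of the target
  Nyquist, decimate by the denominator. The FIR is applied
  forward–backward so resampled samples stay aligned in time.
* **Filtering** uses Butterworth prototypes of order 4 applied
  forward–backward (`signal::filtfilt`), so the effective magnitude
  response is that of order 8 and the phase response is zero. Zero-phase
  filtering is essential here: ISC compares sub-second temporal structure
  across subjects, and causal group delay would deflate correlations.
  Forward–backward IIR filtering has edge transients whose time scale is
  set by the high-pass corner (~1 s at 1 Hz, decaying roughly a decade
  per second); the data are extended by odd reflection over six
  high-pass time constants before filtering and cropped after, keeping
  the transient below `1e-6` of the signal amplitude away from the outer
  second.
* **EOG regression** removes ocular artifacts by jointly regressing all
  scalp channels on the EOG channels (ordinary least squares on demeaned
  signals, solved by QR). Residuals are zero-mean and exactly orthogonal
  in time to every EOG channel, and total variance never increases.
* **Unequal record lengths** across subjects are resolved by truncating
  to the shortest; truncation avoids imputation and the cohort assembly
  refuses to reorder channels silently — mismatched channel names are an
  error, because silent misalignment would corrupt every covariance.

## Robust PCA

Gross sparse artifacts (electrode pops, movement spikes) are removed by
decomposing each recording `M` (channels × samples) into low-rank plus
sparse parts, `min ‖A‖_* + λ‖E‖₁ s.t. A + E = M`, via the inexact
augmented Lagrange multipliers (IALM) iteration: soft-threshold `E`,
singular-value-threshold `A`, update the multiplier, grow `μ`
geometrically. Defaults are the standard ones: `λ = 1/√max(m, n)`,
`μ₀ = 1.25/‖M‖₂`, growth 1.5, tolerance `‖M−A−E‖_F/‖M‖_F ≤ 1e-7`,
at most 500 iterations. The recording is replaced by `A`.

Two properties deserve honesty:

* The primal objective is **not** monotone iteration by iteration —
  IALM enforces the constraint only asymptotically, so early iterates
  can raise `‖A‖_* + λ‖E‖₁` while feasibility improves. What the tests
  assert instead is the true contract: feasibility at convergence, and
  an objective that lands at the value of the planted optimal
  decomposition on recovery-regime fixtures.
* Exact recovery of a planted low-rank matrix under sparse corruption
  holds in the standard regime where the matrix is not too wide relative
  to its rank (incoherence): with `λ = 1/√max(m, n)`, a rank-2
  `100 × 200` matrix with 5 % corrupted entries is recovered to below
  `1e-3` relative error, while very wide, very low-`D` matrices
  (e.g. `20 × 200`) sit outside the guarantee and recover only
  approximately. On EEG-shaped data (channels ≪ samples) the
  decomposition is used as an artifact suppressor, not an exact
  recovery, and the spike-removal test quantifies exactly that: planted
  20-RMS spikes attenuated by more than 80 % while spike-free samples
  move by less than 10 % RMS.

## SSVEP band power

Flicker trials (2.4 s, 25 Hz drive) are handled by three operations.
`reject_trials()` drops a trial when, for any electrode, its power
(mean squared amplitude) or its peak absolute value exceeds the mean
across trials by more than `z = 3` standard deviations; an electrode
with zero spread never triggers (its threshold is infinite).
`trim_onset()` removes the first 200 ms so the onset evoked response
does not contaminate the steady state. `band_power()` Fourier-transforms
each remaining trial (rectangular window, no padding) and sums power
over the bins whose centers fall within 0.25 Hz of 25 Hz — with 2.2 s
usable trials at 125 Hz the bin spacing is 125/275 ≈ 0.4545 Hz and
exactly one bin sits at 25.0 Hz. Bin power uses the single-sided
amplitude normalization `2|X_j|²/T²`, so a pure sinusoid of amplitude
`a` on a bin center contributes exactly `a²/2`. Trials are averaged
regardless of condition label, then the named (occipital) electrodes are
averaged; the electrode list is a configuration item because montages
differ.

## Eigenvalue spectra

`eigenspectrum()` decomposes each subject's channel covariance — here
normalized by `T − 1`, unlike the raw sums in the ISC stage, so the
eigenvalue sum is the per-sample total variance ("overall power").
`fit_loglog_slope()` regresses `log10 λ_i` on `log10 i`; a shallower
slope means appreciable power across more dimensions, i.e. higher
effective dimensionality. Eigenvalues below `1e-9` of the largest are
excluded from the fit (zeroed channels produce exact zeros whose log is
undefined), and fewer than three usable eigenvalues is an error rather
than a two-point fit.

## Group statistics

All inferential steps delegate to the standard R machinery behind the
module's interface: Pearson correlations (`stats::cor.test`),
Benjamini–Hochberg FDR across the per-stimulus test family
(`stats::p.adjust`), two-way main-effect ANOVAs on the additive model
with **Type II** sums of squares (`car::Anova`) because the age and sex
groups are unbalanced, Tukey–Kramer studentized-range post hocs
(`stats::TukeyHSD`, valid for unequal group sizes), and OLS
residualization of ISC on SSVEP amplitude. The median split assigns
subjects at or below the cohort median age to "young"; a fixed boundary
(e.g. 14 years) is available so a split chosen in one cohort can be
reapplied verbatim to another. Tests verify each of these against
hand-computed oracles (brute-force BH definition, `t² = F`, balanced
2×2 sums of squares, the `k = 2` Tukey reduction, OLS orthogonality) and
calibrate type-I error on 200 seeded null replicates.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis
assumes, so every stage is testable without recordings:

* a small number (default 3) of shared band-limited (0.5–15 Hz)
  source time courses — filtered noise, not periodic, because
  naturalistic stimuli drive aperiodic, stimulus-locked activity;
* a ground-truth mixing matrix to scalp channels, spatially smooth
  across the channel index;
* a per-subject gain
  `max(0, baseline + slope·(age − 6) + offset·male)`, defaults
  `baseline = 1` (signal-to-noise ≈ 1 at the youngest age),
  `slope = −0.02`/yr, `male offset = +0.2` — planting the negative
  age–ISC relation and the male ISC elevation the statistics stage must
  detect;
* spatially correlated `1/f` background noise (spectral shaping plus
  smoothing mixing of independent channels);
* EOG-like channels (drift plus saccade-like steps) leaking into the
  scalp; sparse gross spikes at 20× channel RMS, four per minute;
* a `Rest` condition that forces the shared gain to zero, and a `Flash`
  condition adding a 25 Hz drive on occipital channels gated in
  2.4 s-on / 1 s-off trials. `simulate_flicker_trials()` produces the
  trialized counterpart with per-subject amplitudes from the same gain
  model.

Ages are drawn uniformly over 6–44 years; sexes are balanced and
alternate along the age order so that every cell of an age-by-sex median
split is populated. Everything is reproducible from a single seed, and
the ground truth (mixing, gains, spike positions) is returned for tests.

Deliberate omissions: no biophysical head model (mixing is abstract), no
non-stationarity, no alpha-band structure or physiological rhythms, no
realistic artifact morphology beyond single-sample spikes, and channel
counts far below a dense montage. Passing tests on this generator
demonstrate that the estimators recover the structure they are defined
on — planted components, gains, spectra — not that any particular
empirical effect exists in real recordings.

### Problem sizes

The default generator scale (12 subjects, 16 + 2 channels, 40–60 s at
125 Hz) and the replicate counts in the tests (20 cohorts for null
bands and planted-effect detection, 200 replicates for type-I
calibration) were chosen as the smallest sizes at which the planted
effects are detected with high probability, keeping the whole suite in
the tens of seconds on one CPU.

## Known limitations

* The per-subject score uses components fitted on data that include the
  subject; on short recordings this overfits slightly, so null-cohort
  mean ISC carries a small positive bias that shrinks with `T`. Null
  behavior is therefore assessed against a Monte-Carlo null band of
  shared-signal-free cohorts rather than against literal zero.
* With SSVEP amplitude and shared-signal gain driven by the same
  generator parameter, regressing SSVEP out of ISC removes essentially
  the whole age effect in simulation — the generator cannot distinguish
  "evoked-response magnitude" from "response similarity" the way real
  data can.
* EDF support covers the common 16-bit EDF/EDF+ continuous layout with a
  single sampling rate; annotation channels are ignored.
* `two_way_anova()` fits main effects only (additive model); interaction
  terms are out of scope, as the group comparisons it serves report main
  effects.
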