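---
title: "Estimating attractor dynamics around event-related EEG potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating attractor dynamics around event-related EEG potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Trial-averaged, event-locked EEG (the ERP) describes the mean trajectory of
task-evoked cortical activity. This package characterizes something
different: how quickly single-trial *fluctuations around* that mean decay
back to it. If the underlying circuit implements an attractor, fluctuations
relax toward the mean trajectory, and the relaxation rate indexes the
steepness of the attractor basin.

The observation model, per trial $i$ and condition $j$:

1. Single-trial sensor activity is projected onto two spatial components
   and z-scored within subject, giving latent series $s_{i,j}(t)$.
2. The residual is $x_{i,j}(t) = s_{i,j}(t) - \bar{s}_j(t)$, where
   $\bar{s}_j(t)$ is the same-condition trial mean.
3. In a 100 ms moving window, residuals follow a first-order linear
   dynamical system
   $$x(t+1) = A\,x(t) + \varepsilon(t),$$
   with $A$ a real $2\times 2$ matrix and $\varepsilon(t)$ i.i.d.
   Gaussian. At the 30 Hz analysis rate a window holds three samples per
   trial, i.e. two transition pairs; pairs are pooled over all trials and
   all four task conditions and $A$ is estimated by ordinary least squares
   through the $2\times2$ normal equations, with no intercept (residuals
   are mean-zero by construction).

The eigenvalues of $\hat A$ are the per-step decay factors of the two
dynamic modes: a value near 0 means fluctuations vanish within one 33 ms
step (a steep basin); a value near 1 means the system integrates
fluctuations rather than correcting them. We report the eigenvalue
*modulus*. A real $2\times 2$ matrix can have a complex-conjugate pair
(a spiral relaxation); the modulus is still the decay rate of the mode and
reduces to the eigenvalue itself in the real non-negative case, so it is
the scalar that remains interpretable in both regimes. Windows with a
complex pair are flagged (`complex`) rather than silently averaged away.
Eigenpairs are labeled by component association — the eigenvector with the
larger absolute loading on component $k$ occupies slot $k$, ties resolved
by loading magnitude — so `eig1`/`eig2` track the same mode across
adjacent windows without a heuristic memory of previous windows.

## Stages and their parameters

**Lowpass and resampling.** The ERP spectrum is dominated by frequencies
below 10 Hz, so the data are lowpassed at 15 Hz and analysed at 30 Hz. The
filter family is not dictated by the analysis, only the cutoff; we use a
4th-order Butterworth applied forward and backward (zero phase), because
phase distortion would leak into the lag-1 statistics that the AR fit
measures. Edges are reflect-padded and the series demeaned before
filtering so startup transients act on a zero-mean signal. After
filtering, samples are linearly interpolated onto the 30 Hz grid aligned
so that $t = 0$ is a sample; all remaining energy is far below the new
Nyquist, so interpolation there is accurate.

**Segmentation.** Trials are cut around three event locks: fixation cue
($-600$ to $500$ ms), flanker stimulus ($-400$ to $600$ ms) and button
response ($-500$ to $500$ ms), inclusive of both endpoints (at 30 Hz:
34, 31 and 31 samples). Only trials with a button response are kept —
correct and commission-error trials in both congruency conditions;
omissions are dropped. A recording enters a lock's analysis only with at
least 50 clean trials for that lock; the rule is applied per lock, so a
recording can be excluded from one lock and retained in another.

**Spatial reduction.** The two spatial components are the top
eigenvectors of the sensors-by-sensors covariance of the time-concatenated
grand-average condition ERPs, fit once on the stimulus- and
response-locked conditions pooled over all recordings and reused unchanged
for every subject and age (no per-age refit — a refit would confound
spatial and dynamic age differences). The concatenated means are centered
over the concatenated time axis before the covariance is formed (standard
PCA centering; fitting on raw cross-products would mix the grand mean into
the first component). The four conditions enter with equal weight.
Eigenvector sign is fixed by making the largest-|loading| sensor positive,
which keeps the downstream component-association labeling deterministic.
Cue-locked data are projected with this space but excluded from its fit.

**Within-subject standardization.** Each component is z-scored with a
single mean and SD per subject, pooled over *all* trials and time points
of the session across every lock analysed. This matters: a per-timepoint
standardization would whiten exactly the temporal structure the dynamics
model estimates, so the package does not offer one.

**Window sweep.** Windows are 100 ms wide, labeled by their centre, and
stepped one sample (~33 ms) — the finest grid the data support. A window
needs at least 4 pooled pairs (the parameter count of $A$); windows below
that report missing values rather than zeros. Pairs must have both
endpoints inside the window. Conditions represented by a single trial have
identically zero residuals and are excluded from fitting.

## Inference

Age, sex and behavior effects on the eigenvalue time courses are tested
window-wise with random-intercept linear mixed models
(`eigenvalue ~ age + (1 | participant)` and analogues), which absorb the
longitudinal dependence of repeated recordings from the same child. The
per-window fixed-effect $t$ statistics are enhanced with one-dimensional
threshold-free cluster enhancement,
$$\mathrm{TFCE}(p) = \sum_{h = dh,\,2dh,\ldots}^{s(p)} e(h,p)^{E}\, h^{H}\, dh,$$
with the standard $E = 0.5$, $H = 2$ and $dh = \max |t| / 100$. All tests
are one-tailed in the hypothesized direction (eigenvalues decrease with
age; RT and RT variability increase, and accuracy decreases, with the
eigenvalue); the $t$ series is negated for negative tails so enhancement
always runs on the hypothesized sign.

Family-wise calibration resamples the fixed-effect predictor with
replacement across recordings — each recording keeps its outcome time
course and covariates, but receives another recording's predictor (for
eigenvalue predictors, the whole predictor time course moves as a unit).
This breaks the predictor–outcome linkage while preserving outcome
autocorrelation. Every replicate refits the mixed model in all windows
(variance components are not recycled from the observed fit; recycling
them would understate null variability), enhances the tail-oriented
series, and records the extreme score; 10,000 replicates by default.
P-values use the add-one convention $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + \text{reps})$, so no p-value is exactly zero. Because
the resampling wording admits a permutation reading, a permutation variant
(resampling without replacement) is available via `method =
"permutation"`; the resampling unit is the recording session, with the
participant-level alternative left to the caller via aggregation. The
Bonferroni family is $\alpha/6$ for the age tests (2 eigenvalues × 3
locks) and $\alpha/18$ for behavior (3 measures × 3 locks × 2
eigenvalues), one-tailed. Windows whose mixed model fails (too few
observations, constant predictor) are recorded as missing and enter the
enhancement as zeros, breaking cluster extent rather than fabricating
evidence.

Two REML engines are provided. `lme4::lmer` is the reference.
A compiled solver specialized to the single-random-intercept structure
(profiled 1-D REML in the variance ratio, golden-section on its log) makes
the $6 \times 10{,}000 \times \sim\!30$-window refit loop tractable; the
test suite requires its $t$ statistics to agree with `lmer` to $10^{-4}$,
and the bootstrap uses it for both the observed and the resampled fits so
the comparison is internally consistent.

## The synthetic cohort

`simulate_cohort()` inverts the analysis model: per trial a latent 2-D
residual evolves under a ground-truth, possibly age- and epoch-dependent
$A$, is added to per-condition ERP templates, mixed through a rank-2
sensor topography, and wrapped in white sensor noise with full trial and
recording metadata. Defaults emulate the target study design: 104 sensors,
384 trials per session in four flanker conditions (congruent/incongruent ×
correct/commission error, with accuracies near 0.97 and 0.77), three
longitudinal waves at target ages 12/15/18 (true age jittered, SD 0.5
years), and independent per-wave missingness of 0.24 (so ~2.3 recordings
per subject, matching a cohort where not every child is seen at every
age). The ground-truth eigenvalues default to (0.55, 0.35) at age 15 with
a slope of $-0.025$/year applied in the stimulus- and response-locked
epochs only and a flat cue epoch, i.e. a drop of 0.15 across ages 12–18;
per-subject offsets (SD 0.03) create the between-subject variance the
random intercept absorbs. Session behavior is coupled to the session's
ground-truth second eigenvalue: standardized mean RT moves 0.233 SD per SD
of eigenvalue, accuracy decreases and is clipped to $[0,1]$.

Choices the analysis cannot pin down and that are therefore configuration,
not inference: ERP template morphology (2–3 Gaussian deflections per
condition and component, early negative stimulus deflection on component
1, an error-sensitive post-response deflection on component 2); the
evoked-to-residual amplitude ratio (`erp_scale = 0.4` — in single-trial
EEG the evoked response is substantially smaller than the trial-to-trial
fluctuation, and 0.3–0.5 is the realistic range); and the sensor noise SD
(0.2, small relative to the mixed latent signal, as the spatial reduction
in real pipelines leaves component-space noise well below the residual
fluctuation). The latent process is generated directly on the 30 Hz
analysis grid where the ground truth is defined; with `fs_raw = 250` the
band-limited signal is interpolated onto the acquisition grid so the
filtering stage can be exercised, and the 15 Hz filter is then transparent
to it by construction. The generator's single seed fans out into
per-subject substreams, so subsetting a cohort never changes the data of
the subjects kept.

What the generator deliberately does **not** emulate: ongoing band-limited
oscillations (alpha/gamma), eye or muscle artifacts, volume-conduction
head models, non-Gaussian innovations, and drifting electrode impedance.
Passing tests therefore certify the estimator and inference chain under
the stated model, not robustness to every physiological nuisance in real
recordings.

The latency-jitter control (`make_jittered_dataset()`,
`run_jitter_control()`) builds the complementary null: every trial is the
condition-mean ERP shifted by a per-trial offset $\tau \sim N(0,
\sigma_{\text{age}})$ — $\sigma$ defaulting to the age groups' RT SDs of
97/76/72 ms — plus white noise matched to the typical residual SD
(`eps_sd = 1` in z-units). There is no true dynamics gradient; any
apparent eigenvalue structure comes from timing variability alone. The
shift is implemented by linear interpolation with nearest-value edge
padding (the treatment of samples shifted past the epoch edge has to be
fixed somehow; nearest-value padding adds no spurious energy). Pushing
these cohorts through the identical pipeline shows whether an observed age
effect could be explained by faster, less variable response timing in
older participants rather than by relaxation dynamics.

## Numerical and degenerate-case decisions

- **Window sums** use cumulative cross-products, so the sweep is exact and
  $O(T)$; the single-window closed form is kept as the tested reference.
- **Singular pooled second-moment matrices** (e.g. all-zero residuals from
  a zero-jitter, zero-noise control) raise an error rather than returning
  a value; skipped windows (too few pairs) are missing, never zero.
- **Golden-section REML** runs on $\log\gamma \in [-18, 12]$
  ($\gamma = \tau^2/\sigma^2$) and compares the interior optimum against
  the $\gamma = 0$ boundary, where the model collapses to OLS — the
  one-recording-per-participant case lands there and reproduces `lm()`
  $t$ statistics to $10^{-6}$.
- **Degenerate bootstrap draws** (a resampled predictor with zero
  variance) are redrawn and counted, never fit.
- **Bonferroni levels** are kept at full precision internally
  ($0.05/6 = 0.008\overline{3}$, $0.05/18 = 0.002\overline{7}$).
- **Deterministic orientation**: PCA signs, eigenvector signs and the
  component-association rule are all tie-broken explicitly so identical
  inputs give identical outputs on any platform.

## Desk-scale validation design

The statistical guarantees are checked end to end on reduced cohorts
(the full design would add nothing but runtime to these checks):
40 subjects, 48 trials per session, 8 sensors, generated at the analysis
rate. Type-I calibration uses 200 independent null pipelines (no age
gradient) at 500 bootstrap replicates and requires the family-wise
rejection rate of the 6-test age family to sit inside the binomial 95%
band around 0.05. Power/specificity uses 50 pipelines with the $-0.025$/yr
gradient and requires significant stimulus- and response-locked clusters
with a null cue epoch in at least 90% of runs. The jitter control uses 50
cohorts and requires no significant age clusters in at least 90%. Estimator
accuracy is checked separately: eigenvalue recovery within $\pm 0.05$ from
5,000 pooled pairs, closed-form/brute-force agreement to $10^{-8}$, TFCE
against an explicit threshold-loop oracle to $10^{-6}$ and the
isolated-peak closed form $h^3/3$.

## Known limitations

- The AR(1) window fit estimates linear relaxation; genuinely nonlinear or
  higher-order dynamics appear only through their best linear lag-1
  approximation.
- With three samples per window, within-window nonstationarity is folded
  into the estimate; the window centre labeling is a convention.
- Measurement noise in the latent series attenuates eigenvalue estimates
  toward zero (classical errors-in-variables); comparisons across ages are
  unaffected as long as the noise level does not itself change with age.
- The eigenvalue entering the behavior couplings is the session's
  stimulus-epoch ground-truth value; real analyses would use the estimated
  window-wise eigenvalues, which is exactly what the inference stage
  consumes.
- Bootstrap calibration is asymptotic in recordings; with very few
  sessions the add-one convention keeps p-values honest but conservative.

## A short worked run

```{r, eval = FALSE}
library(eegdynamics)

cfg <- run_config(
  cohort = cohort_config(n_subjects = 40, n_trials = 64, n_sensors = 16,
                         fs_raw = 30),
  inference = list(reps = 1000),
  seed = 42)
run <- run_pipeline(cfg)
run$age_tests
autoplot(run$dynamics, eigenvalue = "eig2")

jc <- run_jitter_control(n_subjects = 40, n_trials = 64, seed = 42,
                         compare = TRUE)
jc
```
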