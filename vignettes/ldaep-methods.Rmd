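---
title: "Measuring the loudness dependence of auditory evoked potentials: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the loudness dependence of auditory evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldaepr)
```

## The measurement model

The loudness dependence of auditory evoked potentials (LDAEP) indexes how
strongly the auditory cortex response scales with stimulus intensity.
Tones at five sound levels (55, 65, 75, 85, 95 dB SPL) are presented many
times; per subject and intensity, the stimulus-locked EEG epochs at
electrode Cz are averaged, the N1 peak (most negative deflection in
60–140 ms) and P2 peak (most positive in 150–250 ms) are located, and the
ordinary least-squares slope of peak amplitude on intensity is the LDAEP
of that component. The N1P2 peak-to-peak amplitude is P2 − N1 at each
intensity; because all three lines are fitted on the same abscissa, the
N1P2 slope equals the P2 slope minus the N1 slope exactly — an identity
the unit tests assert at machine precision.

A steeper slope (more negative N1, more positive P2/N1P2 slope) is the
"higher LDAEP" convention. The package asserts only this numeric
convention; the neurochemical interpretation (inverse relation to central
serotonergic tone) is the domain context, not a computed quantity.

Slopes are fitted against the physical dB values (55–95), not against
ranks 1–5. This puts slopes in microvolts/dB and makes magnitudes of
0.05–0.2 µV/dB typical for the N1/P2 components; the abscissa is
config-overridable in `computeLdaep()`.

## The synthetic cohort

`generateCohort()` draws subjects whose generative ERP parameters are
known, so every downstream stage can be validated against ground truth.

* **Group structure.** 30 current hormonal-contraceptive users, 17 past
  users, 7 never-users; past and never users are merged into "non-users"
  for inference (`mergeNonUsers()`), mirroring the standard design in
  which only ongoing exposure is contrasted.
* **Slopes.** True N1 slopes are Normal(−0.080, 0.033) in users and
  Normal(−0.052, 0.040) in non-users; P2 slopes Normal(0.120, 0.068) vs
  Normal(0.084, 0.046) (µV/dB). N1 and P2 slope variation is treated as
  independent, so the N1P2 slope is their difference with SD
  `sqrt(sd_N1^2 + sd_P2^2)` — slightly below the marginal SDs one would
  get under positive coupling. This independence is a modeling choice;
  only group-level summaries constrain it.
* **Sign convention.** The Gaussian slope distributions place a small
  probability mass on positive N1 slopes (about 0.8% at the user
  parameters). They are deliberately not truncated: truncation would
  shift the group means that the statistics layer is calibrated against.
  The "N1 slope ≤ 0" property therefore holds in distribution, not
  surely.
* **Component intercepts.** N1 amplitude at 75 dB is drawn from a normal
  with mean −5 µV (SD 0.8) truncated above at −4, P2 from the mirrored
  distribution, guaranteeing the N1 stays negative and P2 positive over
  the whole 55–95 dB span for any plausible slope draw.
* **Covariates.** Ages are group-specific truncated normals (means
  25.3/27.2/23.4 years); BDI-II cognitive and somatic-affective subscale
  scores are negative-binomial (right-skewed counts, calibrated so
  roughly a third of subjects exceed the clinical cut-off of 13);
  subjects flagged with adverse mood effects (prevalence 11/30 in
  current users, 14/17 in past users) receive an additive Poisson(3)
  shift on the somatic-affective subscale — a medium standardized effect,
  so that adverse-mood contrasts are detectable but not trivial.
  Menstrual-phase frequencies and the 17/13 combined/progestin-only
  split follow the cohort's descriptive table.

### The raw EEG simulator

`simulateRecording()` renders continuous multichannel EEG at 2048 Hz:

* **Evoked response.** Each stimulus adds
  `A_N1 * g(t; 100 ms, 15 ms) + A_P2 * g(t; 180 ms, 25 ms)` with
  unit-peak Gaussians, where `A_N1 = intercept + slope * (dB − 75)`
  (centering at 75 dB leaves the slope untouched and makes the intercept
  the mid-level amplitude). The kernel latencies sit mid-window of the
  N1/P2 search windows so the detector is genuinely exercised.
* **Topography.** The ERP projects to the montage with a dipolar spatial
  profile: weight exactly 1 at Cz, polarity inversion at
  inferior-temporal sites, and — by construction — zero mean across EEG
  channels. The zero-mean normalization means average re-referencing
  leaves the Cz amplitude equal to the generative amplitude; without it,
  re-referencing would scale every measured amplitude by an unknowable
  montage-dependent factor and ground-truth recovery would be
  ill-defined. EOG channels carry no ERP.
* **Noise.** Background noise is pink (1/f), RMS 10 µV per channel
  (about 5 µV inside the 1–30 Hz analysis band per epoch — a realistic
  resting-EEG level that also makes simulated between-subject slope
  variability consistent with the group SDs above). Crucially it is
  spatially *correlated*: 75% of each EEG channel's noise variance comes
  from four smooth shared spatial patterns (two quadrature pairs across
  the montage), emulating volume conduction. Without this, the
  inter-channel correlation criterion of the bad-channel detector would
  flag healthy channels wholesale. Line noise is a 50 Hz sinusoid with
  per-channel amplitude jitter (so it survives average re-referencing);
  blinks are Poisson-scheduled (0.25 Hz) biphasic ~400 ms transients of
  100–200 µV on EOG, frontally weighted on EEG.
* **What is not emulated.** No head-model/leadfield physics, no acoustic
  waveforms, no resting-state block, no non-stationary drifts or
  electrode impedance changes, no muscle EMG. Passing tests therefore
  demonstrate correctness of the measurement chain under a controlled
  generative model — not robustness to every artifact class of real EEG.

Event onsets are quantized to the acquisition sample grid and recordings
are padded to 5-smooth lengths so whole-recording FFTs stay fast.

## The preprocessing chain

`preprocess()` executes, in order: average re-reference → resample to
512 Hz (Fourier method, implicit anti-aliasing) → bad-channel detection
on a detection copy (1 Hz high-passed, 50 Hz spectrally interpolated) →
exclusion of bad channels and re-referencing to the remainder → 1–100 Hz
band-pass → 50 Hz spectral interpolation → 5-s bad-segment rule →
EOG-regression ocular correction → 30 Hz low-pass → 600 ms epoching
(−100 to +500 ms) with pre-stimulus baseline correction → statistical
epoch rejection. The executed order and all exclusion counts are recorded
in the returned manifest.

Key parameter choices (all exposed in `preprocConfig()`):

| parameter | default | rationale |
|---|---|---|
| resample rate | 512 Hz | halves cost 4× with ample bandwidth for 30 Hz signals |
| bad channel: robust z of log-variance | \|z\| > 5 | catches dead *and* wild channels; two-sided because a flatline is as pathological as a noise burst |
| bad channel: max abs correlation floor | 0.4 | volume-conducted EEG channels correlate strongly; an uncorrelated channel is not measuring brain |
| bad channel: robust z of >40 Hz relative power | z > 5 *and* relative power > 0.1 | the absolute floor prevents misfires when all channels are essentially free of high-frequency power (e.g. noiseless or heavily filtered data), where the robust z of numerical residue is meaningless |
| bad segment rule | 5-s blocks; drop iff >25% of channels have SD > 25 µV | both inequalities strict; the trailing partial block is evaluated the same way |
| epoch rejection | \|z\| > 3 on three per-epoch metrics | amplitude range, variance and channel-mean deviation, each averaged over EEG channels; a constant metric yields z = 0 (no rejection), and fewer than 3 epochs skip rejection with a warning |
| filters | zero-phase Hamming-window FIR | linear-phase design applied with exact group-delay compensation via FFT convolution; transition width 25% of the cutoff, clamped to [1, 8] Hz |

Ocular correction replaces each EEG channel by the residual of its
least-squares regression on all EOG channels over the whole recording
(rank-tolerant, so duplicated EOG channels are harmless; silent EOG makes
it a no-op). This is a deliberate, fully testable stand-in for
ICA-based ocular removal: it has the same contract — stimulus-locked
signal uncorrelated with the EOG is preserved in expectation — without
depending on the non-reproducible internals of specific ICA toolboxes.
For the same reason, the ICA-based bad-channel criterion is omitted; the
variance/correlation/spectral criteria above carry that role.

Baseline correction (subtracting the −100–0 ms mean) is standard ERP
practice and is config-switchable, since reasonable pipelines differ
here.

## Numerical behavior of the measurement chain

Linear filtering cannot be transparent to time-limited kernels. The 1 Hz
high-pass removes the lowest-frequency content of the P2 kernel (partly
restored by baseline correction), the 30 Hz low-pass clips a sliver of
the N1 kernel's spectrum, Hamming FIRs have ~0.2% passband ripple, the
P2 kernel's filtered tail bleeds marginally into the N1 window, and peak
latencies do not fall exactly on the 512 Hz sample grid. Together these
give a deterministic *transfer bias* of the measured slopes of up to a
few percent of the slope magnitude — bounded by 0.01 µV/dB for
physiological slopes in the unit tests, and measured at ~2–6 × 10⁻³
µV/dB for noiseless simulated subjects. This bias is a property of the
prescribed cutoffs, not of filter quality: sharpening the FIR transitions
does not reduce it. Exact (1e-6) recovery of generative slopes through
the full filter chain is therefore not achievable for any kernel that
both separates 100 ms from 180 ms components and passes a 30 Hz
low-pass; the acceptance suite documents this by asserting the strict
tolerance and the test remains an honest failure, with the attainable
bound stated here.

Other numerical conventions: epoch windows are half-open with
`round()` at each edge (307 samples at 512 Hz, onset at 1-based index
52); peak windows are inclusive at both endpoints, the extremum rule is
used (no local-peak requirement), and ties resolve to the earliest
latency; degenerate inputs (zero-variance EOG, < 4 channels for the
correlation criterion, < 3 epochs for rejection, missing design points
for the slope fit) degrade gracefully with warnings or flags rather than
errors wherever a partial result is meaningful.

## The statistics layer

* **Normality screening** uses the Lilliefors-corrected one-sample KS
  test (parameters estimated from the data); n ≥ 5 is required.
* **Primary contrast**: one-way ANOVA of each slope on the two merged
  groups. Partial η² is `F·df1 / (F·df1 + df2)`; its interval is the
  one-sided 95% construction from the noncentral-F distribution with the
  upper bound fixed at 1 — the convention under which effect-size CIs
  print as, e.g., (0.02, 1.00). For two groups the pooled-variance mean
  difference and its 95% t-CI are attached, and F = t² against the
  pooled t test holds to 1e-10 (tested).
* **Covariate adjustment**: Type II ANCOVA (each term's SS from the
  full-vs-reduced model comparison) with age and the two BDI-II
  subscales; estimated marginal means at covariate means; VIF per
  predictor. The Type II sums of squares are cross-checked against an
  independent brute-force refit oracle on random small designs (1e-8).
* **Rank/exact tests**: Wilcoxon rank-sum (exact for untied n ≤ 25,
  normal approximation with tie correction otherwise), Pearson χ²
  without continuity correction, Fisher's exact test for 2×2 tables
  (two-sided p by hypergeometric enumeration, verified against an
  exhaustive oracle). For r×c tables larger than 2×2 the χ² test is
  used.
* **Power**: exact noncentral-t evaluation; `powerTwoSampleT()` returns
  the smallest equal-allocation total n reaching the target power. For
  d = 0.77, α = 0.05, power 0.80, two-tailed, this is 56 (28 per group);
  one-tailed assumptions give smaller n. The routine is validated by
  self-consistency (power(n) ≥ target > power(n−2)) and against Monte
  Carlo simulation within 0.01.
* **Multiplicity**: no correction is applied; every test is reported
  per-analysis at two-tailed α = 0.05, and `runGroupAnalysis()` returns
  tidy per-analysis tables so users can apply their own correction.

`momentNormalSample()` deserves a note: it produces a deterministic
normal-shaped sample with *exactly* the requested mean and SD, which
reproduces any statistic that depends on the data only through first and
second moments. This is how printed group summaries (means, SDs, n) are
turned back into runnable analyses.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own balance of fidelity and turnaround: unit
tests simulate subjects at 512–2048 Hz with 1–8 trials per intensity;
the noiseless-recovery check uses 4 subjects; the noisy-recovery check
uses 20 subjects at the full 80 trials per intensity (plus a 10-trial
arm to verify error shrinks with trial count); calibration checks use
1000 null cohorts (type-I error) and 10000 draws (power agreement). The
acceptance script runs the full 54-subject cohort at 20 trials per
intensity and reports the measured slope-recovery error alongside the
moment-reconstruction statistics.

## Known limitations

* The EOG-regression ocular stand-in removes any EEG variance linearly
  predictable from the EOG over the whole recording; with very high
  blink rates it can subtract slightly more background noise than ICA
  would, and it cannot remove muscle artifacts.
* The simulator's noise is stationary; real EEG drifts, and bad channels
  in real data are often intermittent rather than uniformly flat/noisy.
* Peak detection is fully automatic (extremum in window). Pathological
  waveforms that a human rater would reject are flagged only indirectly
  (via the fit R² and the epoch screen), not re-measured.
* The measured slopes carry the small deterministic transfer bias
  described above; comparisons *between* groups are unaffected, because
  the bias is common to all subjects processed with the same
  configuration.
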