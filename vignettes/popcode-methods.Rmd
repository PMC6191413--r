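---
title: "Methods: simulating and testing population-code accounts of action-based expectation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and testing population-code accounts of action-based expectation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popcode)
```

## Scope and design

`popcode` packages two things: a generative simulator of voxel populations
whose responses to observed actions are modulated by action-based
expectation under competing *sharpening*, *cancellation* and *null*
hypotheses, and the multivariate analysis pipeline that discriminates those
hypotheses — searchlight decoding, data-driven ROI definition, congruency
ANOVAs and a voxel-tuning analysis. The simulator exists so that every
stage of the pipeline is testable: its ground truth is known, so chance
levels, false-positive rates and model recovery can all be measured.

## The experimental design being emulated

The simulated experiment has participants execute index or little finger
abductions and observe an action outcome that is congruent or incongruent
with the executed movement, or observe a movement without acting (*no-move*
trials). Defaults follow the emulated protocol: 8 scanning runs of 48
trials, of which 16 are congruent, 16 incongruent and 16 no-move per run,
with the observed stimulus (index/little) balanced 8/8 within each
condition. The judgement task (finger vs. colour) is blocked within a run
— one half-session each — with the leading task alternating over runs and
counterbalanced over subjects. Onsets are spaced by a fixed trial duration
(default 6 s) plus a uniform jitter (default 2–6 s, the emulated
inter-trial interval); all later modelling locks to the onset of the
observed stimulus, so the short fixed delay between action and outcome on
no-move trials is not modelled. Whether no-move trials were interleaved or
grouped is not specified by the protocol we emulate; we interleave them
uniformly at random. The cue–action mapping and its mid-experiment reversal
have no consequence for any simulated quantity and are not modelled.

When the trial count per run is divisible by 12 the shuffle is stratified so
each half-run carries half of every condition × stimulus cell; this keeps
the task-split analysis (which halves the trials behind every beta)
estimable by design rather than by luck.

## The generative population model

Each informative voxel carries a preferred stimulus. Its mean response to
one trial is

$$\mu(p, s, c) \;=\; \beta_0 + a(p,s)\, g(p,s,c), \qquad
a(p,s) = \begin{cases} A_{\mathrm{pref}} & s = p\\
A_{\mathrm{non}} & s \neq p \end{cases}$$

with \(g = \gamma\) exactly when the trial is congruent *and* the hypothesis
targets the voxel (sharpening: \(s \neq p\); cancellation: \(s = p\)), and
\(g = 1\) otherwise. Under the null hypothesis \(\gamma\) is ignored.
Modulation is applied as congruent *suppression*; a congruent suppression
and an incongruent facilitation differ only by a constant and are
indistinguishable to every contrast the pipeline computes. The gain
multiplies the evoked amplitude, not the baseline, because the hypotheses
concern modulation of stimulus-evoked population responses. No-move trials
carry tuning signal but never congruency modulation — this is what makes
them usable for ROI definition independent of the effects under test.

Two consequences, asserted analytically in the test suite: for
\(\gamma < 1\) the Euclidean distance between the index- and little-evoked
mean patterns over informative voxels is strictly larger on congruent than
incongruent trials under sharpening, strictly smaller under cancellation
and equal under null; and the mean congruent-minus-incongruent univariate
difference is negative only over tuned-away voxels under sharpening, and
only over tuned-toward voxels under cancellation.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| grid | 12×12×12, 3 mm voxels | voxels | desk-scale stand-in for a visual-cortex volume at the emulated resolution |
| informative region | two 3×3×3 blobs on the grid diagonal | voxels | compact blobs give cluster inference a spatial target; diagonal placement keeps their searchlight footprints disconnected |
| preference assignment | 50/50 checkerboard within blobs | — | deterministic, spatially interleaved tuning, as in interdigitated feature maps |
| baseline \(\beta_0\) | 100 | signal units | arbitrary offset; every analysis is baseline-invariant (tested) |
| \(A_{\mathrm{pref}}, A_{\mathrm{non}}\) | 2, 1 | signal units | only the ordering \(A_{\mathrm{pref}} > A_{\mathrm{non}}\) matters |
| gain \(\gamma\) | 0.7 | — | a moderate (30%) suppression; \(\gamma = 1\) makes all hypotheses indistinguishable |
| noise_sd | 4 | signal units | see below |
| TR | 3.36 | s | emulated acquisition |

`noise_sd` is the one free scale that decides what the pipeline can see,
and it was fixed by a power consideration with two constraints. Run-wise
betas carry noise `noise_sd / sqrt(m)` (`m` = trials per cell, 8 at the
defaults), emulating within-run averaging. With noise much below ~2 the
radius-3 searchlight saturates at 100% accuracy in *both* congruency
conditions, and a ceiling accuracy cannot express the congruency contrast
that distinguishes the hypotheses; with noise much above ~6 the univariate
suppression in tuned-away voxels (\(A_{\mathrm{non}}(1-\gamma) = 0.3\)
units) becomes undetectable by a paired t test at the default 8 subjects.
`noise_sd = 4` leaves single-condition accuracy at informative sites in the
~80–90% range and the expected tuned-away paired t near 4. These are
design-time choices about what regime the simulator occupies, not
measurements.

### What the simulator does not emulate

White Gaussian noise only: no physiological noise spectra, no motion, no
spatial autocorrelation of noise, no anatomical variability (all subjects
share one grid, standing in for normalised data), no between-subject
variation in effect size beyond sampling noise, and no pre-activation of
expected representations before stimulus onset. Passing tests therefore
show that the *pipeline* is correct and calibrated under its stated
assumptions — they do not show that real fMRI noise satisfies those
assumptions.

## First-level modelling

The time-series mode convolves each trial's evoked amplitude
(\(\mu - \beta_0\)) with a canonical double-gamma HRF (gamma densities with
shapes 6 and 16, unit rate, second term weighted 1/6; peak near 5 s),
riding on the baseline plus an optional linear drift. Events are modelled
as zero-duration impulses — the stimulus duration (500 ms) is far below the
TR — so each regressor is exactly a sum of onset-shifted HRFs, evaluated in
continuous time at the scan times. Each run's design matrix holds one event
regressor per condition × stimulus cell present in the run, plus a linear
drift and a constant (real-data mode accepts arbitrary extra nuisance
columns, e.g. motion parameters). Estimation is ordinary least squares
without temporal prewhitening: point estimates stay unbiased under serial
correlation and every downstream analysis consumes the estimates, never
their standard errors. The noiseless round trip — simulate, fit, recover
\(\mu - \beta_0\) to 1e-6 — is the module's oracle test.

## Searchlight decoding

Per mask voxel, the features are the run-wise betas of all voxels within a
3-voxel (9 mm) radius, truncated at the mask boundary (no padding — the
common searchlight convention). Within one condition there are
8 runs × 2 stimuli = 16 patterns; leave-one-run-out cross-validation gives
8 folds of 14 training and 2 test patterns, and accuracy is the fraction of
the 16 test classifications that are correct, stored as accuracy − 0.5.
The classifier is a linear soft-margin SVM with C = 1 and no feature
scaling, the convention of the decoding toolbox this pipeline mirrors; the
cost and radius are configurable since neither is dictated by theory.

Numerics: the SVM dual is solved by a small compiled SMO
(maximal-violating-pair working set, KKT gap below 1e-8, offset from free
support vectors or the midpoint of the feasible interval). Training sets
here are tiny (14 patterns), so the solver works on the 16×16 Gram matrix
and never forms the weight vector. The test suite cross-checks it against
an independent SVM implementation (libsvm via `e1071`) on random problems:
decisions agree exactly away from ties. Decision ties (f = 0, e.g. training
patterns identical across classes) go to the first stimulus level
("index"), a fixed documented order, which makes uninformative balanced
data score exactly 0.5 in expectation.

## Group inference and ROI definition

Per-subject no-move accuracy maps are smoothed with a separable Gaussian
(FWHM 4 mm; \(\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})\) converted to voxel
units). The volume is zero-filled outside the mask before convolution and
the mask reapplied after: a constant map is preserved in the interior and
attenuates at the boundary, and an interior impulse keeps unit mass (both
tested). Voxels with zero across-subject variance get t = 0 and a flag
rather than ±Inf.

Clusters are voxels exceeding the one-sided height threshold
\(t > t_{1-p_h, n-1}\) (default \(p_h = 0.001\)), connected under
26-connectivity (6/18 configurable; 26 is the most inclusive and the
default here). The extent threshold is calibrated by sign-flip permutation:
under the symmetric null the subject maps' signs are exchangeable, so the
maximum suprathreshold cluster size over `n_perm` random sign flips
(recomputing the t map each time; all flips are applied as one matrix
product) gives the null distribution, and clusters larger than its
\(1 - p_{\mathrm{FWE}}\) quantile survive. This replaces random-field
theory deliberately: it needs no smoothness estimate, is exact under
symmetric nulls, and is implementable and testable at desk scale. Each
surviving cluster also reports an empirical FWE p value. With integer
cluster sizes the "strictly exceeds the quantile" rule errs conservative
under heavy ties. No minimum cluster size is imposed beyond the permutation
threshold. Anatomical restriction is a user-supplied mask option.

Small-sample caveat: with \(n\) subjects there are only \(2^n\) distinct
sign patterns, and when strong true signal is present the near-identity
flips contaminate the null; below about 8 subjects the extent threshold
becomes very conservative. The default configuration uses 8 subjects partly
for this reason.

## Condition effects and display intervals

Cluster-mean accuracies per condition (and per task, when decoding is split
by judgement task) enter repeated-measures ANOVAs — cluster × congruency,
or cluster × congruency × task. The implementation delegates to
`stats::aov` with `Error(subject/(...))` strata and reports F, degrees of
freedom, p and partial \(\eta^2 = SS_e/(SS_e + SS_{err})\); the test suite
checks it against an independently coded brute-force sum-of-squares
decomposition (inclusion–exclusion over cell means) to 1e-10, and the
\(F = t^2\) identity for two-level factors. No sphericity correction is
applied: every factor of interest has two levels, where sphericity is moot;
the three-level cluster factor is accepted uncorrected, a deliberate
divergence noted here. Post-hoc strategy is interaction followed by
per-cluster ANOVAs or paired t tests without multiplicity correction,
mirroring the emulated analysis. Error bars use the within-participant
convention: the 95% CI of the per-subject condition difference divided by
\(\sqrt 2\), applied to both condition means.

## Voxel tuning and the signature verdict

Each voxel's preference is the sign of a paired t contrast of
beta(index) − beta(little) over the run × condition cells — by default
across *all* conditions including no-move (a move-only mode is provided;
the protocol text is ambiguous and the choice is configurable). t = 0
voxels are excluded: the binary rule is defined only for nonzero t, and
ties are measure-zero under continuous noise. Univariate betas
(unsmoothed, native grid, as in the emulated analysis) are then averaged
per subject × cluster × congruency × preference-status, a preferred cell
being one where the observed stimulus matches the voxel's own preference.

`sharpening_signature()` runs the cluster × congruency × preference ANOVA
and two post-hoc paired t tests (congruent vs incongruent within preferred
and within non-preferred voxels) and returns a verdict: suppression only in
non-preferred voxels is `sharpening`, only in preferred is `cancellation`,
both is `mixed`, neither `none` (suppression = two-sided p < 0.05 with the
congruent mean lower). Because preference classification uses the average
over all conditions, the selection is orthogonal to the congruency
contrast; the test suite verifies by simulation that selecting preferences
from the same noisy data does not inflate the congruency × preference
interaction above its nominal rate.

## Orchestration, seeds and reproducibility

`run_pipeline()` executes design → simulation (direct betas or time series
+ GLM) → per-condition searchlight maps → ROI definition from no-move maps
only → accuracy extraction and ANOVAs → tuning analysis. Every stage draws
from a substream derived deterministically from the master seed, so the
whole bundle — including permutation results — is a pure function of the
configuration, and configurations round-trip losslessly through JSON. ROI
independence is asserted by a mutation test: corrupting the congruent and
incongruent maps cannot change the cluster set. In direct-beta mode the
task-split analysis simulates its halved-trial betas as a separate
realisation from a dedicated substream (a first-level GLM re-models shared
data; a direct-beta shortcut has no shared data to re-model).

`recovery_experiment()` repeats the pipeline under all three generative
hypotheses with per-replicate seeds and tabulates generating vs recovered
verdicts (null is recovered as `none`).

## Problem sizes used by the calibration experiments

The package's own calibration experiments (test suite and acceptance
script) use: chance calibration — 8 subjects × 3 conditions of
information-free betas on a 10×10×10 grid, radius-3 searchlight; model
recovery — 20 replicates per hypothesis, 8 subjects, 12×12×12 grid,
200 sign-flip permutations per replicate; FWE calibration — 200 null
datasets of 8 smoothed noise maps each, 150 permutations per dataset;
ANOVA type-I calibration — 250 null cluster-mean tables. These sizes are
the package's choices for desk-scale characterisation of the method.

## Known limitations

Sign-flip extent calibration is conservative for small subject counts and
heavily tied cluster-size distributions. OLS without prewhitening forfeits
efficiency (not validity) under autocorrelated noise, and the simulator's
white noise cannot exercise that. The direct-beta mode's noise model
(`noise_sd/sqrt(m)`) idealises the GLM's averaging; design-correlation
effects between regressors appear only in time-series mode. The verdict
rule is a fixed decision procedure at \(\alpha = 0.05\), not a model
comparison; with very strong effects in both voxel classes it returns
`mixed` rather than weighing the relative strength of evidence. Real-data mode expects spatially
normalised, preprocessed inputs — acquisition and preprocessing are out of
scope.
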