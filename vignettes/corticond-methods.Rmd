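---
title: "Methods: models, parameters and design choices in corticond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in corticond}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`corticond` simulates and analyses an appetitive Pavlovian trace
conditioning experiment in which head-restrained mice learn to discriminate
a rewarded (CS+) from an unrewarded (CS−) whisker stimulus while layer-5
IT-like or ET-like cortical populations are imaged at 30 Hz. This vignette
documents the scientific assumptions, the tunable parameters, and the
design decisions taken where the problem was genuinely open.

## Task structure and behavioural scoring

Every session delivers `n_per_cs` trials of each CS in random order
(default 100, i.e. 200 trials), with a 1 s stimulus, a 0.5 s trace
interval, reward at stimulus onset + 1.5 s on CS+ trials only, and
inter-trial intervals drawn uniformly from 6–8 s. Anticipatory licking is
counted in the half-open window `[onset, onset + 1.5)`: the half-open
convention prevents a lick at the instant of reward delivery from being
counted as both anticipatory and consummatory. Session performance is the
auROC between the CS+ and CS− anticipatory count distributions, computed
by the rank-sum identity with 0.5 credit for ties — exact on count data
and identical to trapezoidal ROC integration. The first 10 % of trials
(`floor(0.1 n)`; the rounding rule is ours, the discard fraction is the
protocol's) are discarded to exclude impulsive licking at session start,
and a session is proficient when auROC > 0.7.

## Synthetic populations

The generator emulates the statistical structure the analyses assume, not
calcium biophysics:

* **IT-like** populations: a fraction (default 0.56) of ROIs respond to
  stimuli with transients time-locked to onset, fully reliably, with
  identical tuning on every day. Tuning is non-selective (both CSs, 50 %)
  or selective (25 % each CS).
* **ET-like** populations: a smaller fraction (default 0.36) respond
  non-selectively and unreliably (per-trial response probability 0.5) with
  a linear ramp from stimulus onset to the expected reward time whose
  amplitude grows over days (`ramp_gain_by_day`, default 0.05→0.4 ΔF/F,
  nondecreasing), and with day-to-day identity turnover that declines with
  learning (default 0.4→0.1). Turnover hands a responsive ROI's role to a
  member of the silent pool, conserving the responsive fraction. The
  turnover schedule is exposed as a free parameter because its true value
  is not quantified; only its ordering (ET ≫ IT = 0) is constrained.

The calcium kernel is a peak-normalized double exponential (rise 0.05 s,
decay 0.7 s), a jGCaMP8m-like default; only relative statistics matter
downstream, so the kernel shape is configurable and untuned. The ET ramp
is linear with a hard stop at reward time — the minimal parameterization
of "ramping toward the expected reward". Fluorescence is
`F = baseline_F · (1 + signal + noise)` with `noise ~ N(0, noise_sd)` in
ΔF/F units, so the noise level seen by ΔF/F analyses equals `noise_sd`
regardless of the baseline. What passing tests show is therefore that the
analysis chain is correct and sensitive at realistic signal-to-noise; they
do not certify behaviour under motion artifacts, neuropil contamination,
or non-stationary baselines, none of which are modelled.

Licking is an inhomogeneous Poisson process: baseline rate (0.5 Hz)
outside special windows, CS- and day-specific anticipatory rates in the
1.5 s window, and a consummatory rate (6 Hz) for 2 s after reward. The
2 s bound exists so anticipatory and consummatory epochs are separable by
the cross-epoch decoder; its exact value is unconstrained.

## Imaging analyses

ΔF/F is computed per trial against the mean of the 30 baseline frames (1 s)
before onset; a non-positive baseline raises an error naming the ROI. An
ROI is condition-responsive iff a paired two-sided Wilcoxon signed-rank
test of window-averaged post vs baseline activity gives p < 0.01 *and* the
post mean exceeds the baseline mean *and* the baseline-subtracted mean
response exceeds 0.05 ΔF/F. The "normalized response" threshold is
interpreted as this baseline-subtracted window mean and exposed as
`amp_threshold`; the amplitude criterion is applied per CS condition. The
Wilcoxon test uses the exact distribution for ≤ 25 paired trials and the
normal approximation with tie correction above. One-sidedness is enforced
by the direction requirement on top of the two-sided p-value, mirroring a
"significantly increased" criterion.

The selectivity index is SI = (AUC − 0.5) × 2 with CS+ as the ROC positive
class, so SI > 0 means CS+ preference; `si_sign = -1` flips the convention
for comparability with analyses that report the opposite sign. Stability
matrices correlate trial-averaged traces over 3 s (90 frames) from onset
per ROI and day pair, then average ROI → mouse → cohort. Fraction
comparisons use the Pearson χ² on the 2×2 table without continuity
correction — the variant consistent with the reference statistics
(χ² = 17.00 and 0.73 on the naive-population counts). Clustering z-scores
each ROI, computes 1 − Pearson r distances, and applies Ward linkage
(`ward.D2`); the partition is deterministic and invariant to ROI order.

## Decoding

Activity is averaged in non-overlapping 500 ms bins (15 frames) and each
bin decoded independently — no temporal pooling. Classification uses a
linear SVM (C = 1), stratified 5-fold cross-validation, and 100 random
fold resamplings per bin (configurable; reduced in tests for speed —
see problem sizes below). Features are z-scored with training-fold
statistics only. Regression uses linear ε-insensitive SVM (ε = 0.1) scored
by cross-validated R²; folds whose test targets are constant have
undefined R² and are excluded and counted. For cross-epoch decoding the
trial folds are shared between epochs so no trial contributes to both
training and testing.

## The two-channel Rescorla–Wagner model

The value-encoding network maps the concatenated IT representation
(50 units) and raw non-S1 stimulus (20 units) through a single linear
hidden layer (116 units) to a sigmoid output V ∈ (0, 1). Weights follow
the Rescorla–Wagner update Δw = α δ ∇V with δ = R − V, R(CS+) = 1,
R(CS−) = 0. Stimuli are eight 20-dimensional Gaussian classes with
unit-norm random mean directions and isotropic σ = 0.5; two classes are
designated CS+/CS−. The IT channel is an autoencoder
(20–50–50–15–50–50–20, tanh hidden layers, linear reconstruction) trained
by full-batch gradient descent with momentum 0.9 on the L2 loss and frozen
afterwards; the relayed representation is the second encoder layer
expressed as a nonnegative rate h = (1 + a)/2.

Design choices where the design was open, and why:

* **Channel combination and gain.** Channels are concatenated, and the IT
  representation enters with a gain of 4 (`it_gain`). The gain implements
  the channel asymmetry — IT conveys the *rich* representation, the non-S1
  channel only a *coarse* one — by letting IT separations dominate value
  learning. Without it, learning tracks the raw-stimulus geometry and the
  representational-overlap analysis loses its meaning.
* **Rate-coded IT representation.** Mapping tanh activations to (0, 1)
  treats the relayed signal as firing rates. The shared positive baseline
  of these rates is the substrate of cross-stimulus generalization: early
  CS+ updates raise the value of *both* stimuli, producing the
  characteristic joint rise before discrimination develops, and under ET
  silencing (no corrective prediction errors) both associations saturate
  together.
* **Initialization.** Weights start near zero (`init_sd = 0.1` before
  fan-in scaling) and the output bias at `qlogis(0.1)`, i.e. a naive
  association of ~0.1, emulating low pre-training anticipatory licking.
  Near-zero weights route early learning through the shared components;
  stimulus-specific weights bootstrap later.
* **Learning rates.** α = 0.1 paces acquisition over the five sessions;
  smaller values leave the model short of asymptote within the
  experiment's 1 000 trials, larger ones saturate in session 1. The
  transfer sub-network (same architecture on the 20-dim channel, its own
  free choice since its form is unspecified) is distilled with
  `lr_subnet = 0.2` toward the relayed value predictions by squared loss.
* **Silencing noise.** IT-silencing noise is zero-mean Gaussian with s.d.
  matched to the empirical spread of the replaced (scaled) representation;
  ET-silencing noise replaces the value inside δ only (the silenced signal
  is the one relayed to the prediction-error circuit; the *recorded*
  associations remain the network's true predictions), with s.d. 0.25 —
  roughly the spread of value predictions mid-learning.
* **Overlap analysis.** Representational distance is the Euclidean
  distance between class centroids in IT space (averaging per-sample
  representations first removes the within-class noise floor that would
  otherwise swamp the between-class separation). Learning performance per
  pair is the CS+/CS− association difference after session 2, averaged
  over three runs because a single two-session run is trial-order noisy.
  The saturating form a·(1 − e^(−b·d)) is fit by Levenberg–Marquardt; it
  is chosen because association differences are bounded. The positive
  distance–learning association is robust, but its Spearman strength
  varies across stimulus banks (roughly 0.5–0.9) because the encoder
  preserves distances only approximately (non-isometric warping).

In the one-hot linear limit (single weight, no bias, identity output) the
update reduces exactly to tabular Rescorla–Wagner,
V_t = 1 − (1 − α)^t, which the tests verify to 1e-10 together with
finite-difference checks of all gradients.

## Numerical choices and degenerate inputs

Moving-average smoothing truncates windows at the edges. Zero-variance
traces are excluded (and counted) from correlation-based analyses rather
than propagating NaN. Ties in rank statistics receive 0.5 credit.
Degenerate stimulus banks (σ → 0) collapse samples onto class means and
remain valid inputs. All generators take explicit seeds, restore the
caller's RNG state, and derive independent sub-streams from one master
seed so behaviour and imaging noise are independently reproducible;
identical seeds give bit-identical outputs.

## Problem sizes

The test suite and the acceptance script use the experiment's native
session structure (5 sessions × 100 trials per CS) for the model analyses,
with 10 matched simulations per condition, 20 stimulus pairs for the
overlap analysis, and populations of 40–100 ROIs with 40–80 trials and 20
decoder resamplings for the imaging/decoding checks; these sizes give
stable statistics for every property tested while keeping a full run in
the minutes range.

## Known limitations

The generator does not model motion artifacts, neuropil contamination,
spike inference, or session-to-session baseline drift, and the lick
process has no refractory period. The network model is a conceptual
bridge, not a mechanistic account: it contains no spiking dynamics, no
dopamine circuit for the prediction-error computation, and its parameters
are not fit to animal data. Cohort-level inferential statistics (mixed
ANOVAs across mice) are out of scope because they require the original
recordings.
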