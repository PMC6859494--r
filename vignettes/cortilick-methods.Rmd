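---
title: "Models and methods behind cortilick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortilick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortilick)
```

`cortilick` implements, as tested reusable functions, the analysis chain of a
head-fixed mouse sensorimotor experiment in which animals lick a spout (or
one of two spouts) in response to whisker or auditory stimuli while neuronal
activity is recorded with calcium imaging, the face is filmed at high speed,
and cortex is mapped with wide-field imaging and optogenetic stimulation.
Every analysis stage is paired with a seeded synthetic-data generator that
emulates the trial structure and signal statistics of such experiments, so
each estimator carries a ground-truth recovery test.  This vignette explains
the models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic data do and do not establish about real recordings.

## The behavioral tasks and outcome taxonomy

Two paradigms are modeled.  In the *multisensory detection* task, whisker
deflections, auditory tones and no-stimulus catch trials are interleaved; a
lick within the reward window after a stimulus is a **hit**, no lick a
**miss**; a lick on a catch trial is a **false alarm**, otherwise a
**correct rejection**.  In the *multimotor* task only whisker stimuli are
used, two spouts are present, and the rewarded side alternates in blocks of
about 50 trials; the spout of the *first* in-window contact decides between
**hit** and **error**.  Associative (auto-rewarded) trials are flagged and
excluded from all analyses.

Timing defaults: interstimulus intervals of 12 +/- 1 s, a 3 s pre-stimulus
quiet period with no licking, and a 1.5 s reward window.  Catch trials carry
a virtual stimulus time drawn from the same interval process.  Two
conventions were genuinely open and are resolved as follows:

* The reward window is half-open, `[0, 1.5)` s after the stimulus: a contact
  at exactly +1.5 s does not count.  Any convention is defensible at a
  measurement resolution of milliseconds; half-open intervals compose
  without double-counting.
* Simultaneous first contacts on both spouts (same sample) are classified as
  an error — the conservative choice for estimating performance.
* The optogenetic light flag never modifies an outcome; it is an analysis
  grouping.

Lick latencies are modeled log-normal (median 300 ms, log-SD 0.35),
chosen for positivity and right skew; observed median first-lick latencies
in such tasks fall in the 270–600 ms range.  After a block switch the
probability of perseverating on the old spout decays exponentially with a
configurable time constant (default: adaptation within ~10 trials), which
reproduces the characteristic sigmoid of switch-aligned lick probability.
Confidence intervals on per-offset lick probabilities use the Wilson score
interval, which behaves sensibly at small n and at probabilities near 0
and 1; empty offsets report missing values rather than a clamped interval.

## Calcium trace conditioning

Somatic fluorescence is contaminated by out-of-focus neuropil; the standard
correction subtracts the scaled surround-ring signal:

$$F(t) = F_{soma}(t) - \alpha\, F_{surround}(t).$$

The coefficient $\alpha$ is produced upstream by the ROI-extraction tool and
is taken as given, one value per neuron (population mean 0.38, SD 0.30; the
generator truncates draws at zero).  Values outside $[0,1]$ are accepted
with a warning because the empirical distribution is wide.

Traces are then standardized against a **mode-based noise model**: in blocks
of 100 s, the baseline level `f_mode` is the mode of the block's
fluorescence distribution, and the noise SD `sigma_noise` is estimated by
taking the values below the mode and symmetrizing them around it (the
values at or below the mode together with their reflection above it).
Because calcium transients are strictly positive-going, the sub-mode half of
the distribution is nearly signal-free, which makes this estimator robust to
transient-induced skew — its design purpose, verified by simulation at 5%
transient duty.  The z-score is then

$$z(t) = \frac{F(t) - F_{mode}}{\sigma_{Noise}}$$

per block, concatenated without cross-block smoothing.  A final partial
block is merged into the preceding one; traces shorter than one block form a
single block.

**Numerical choice: the mode estimator.**  The obvious histogram mode
(Freedman–Diaconis bins, midpoint of the max-count bin) turns out to be too
noisy at realistic block sizes: near the flat peak of the distribution,
adjacent bin counts differ by less than their Poisson noise, so the argmax
wanders several bins (about +/-0.3 noise SDs at 3000 samples).  The default
estimator is therefore the argmax of a Gaussian kernel density estimate with
*twice* the rule-of-thumb (`bw.nrd0`) bandwidth: at a locally symmetric peak
the wider kernel contributes no leading-order bias but substantially reduces
argmax variance.  Measured on the synthetic acceptance condition, the KDE
mode is unbiased with median absolute error ~0.03 noise SDs, and sigma is
recovered within ~1–3%.  The histogram variant remains available via
`fit_noise_model(..., mode_method = "histogram")`.

Neurons that are infrequently active — fewer than 0.05 upward crossings of
$z = 5$ per second — are discarded.  A plateau above threshold counts as one
crossing.  The "baseline SD" implied by the 5-SD rule is interpreted as the
noise model's own sigma, i.e. the threshold is `z = 5`; the source analysis
defines no separate baseline SD.

Event-aligned analysis (`align_trace`) samples the native frame grid nearest
each event with no interpolation; events whose window leaves the trace are
dropped with a warning.  Responsiveness is a two-sided Wilcoxon rank-sum
test of per-event baseline means against response-window means
(stimulus-triggered: baseline -300..0 ms, response 0..200 ms;
lick-triggered: baseline -800..-500 ms, response -100..100 ms), with at
least 15 events required, at an uncorrected 0.05 level (configurable; no
multiple-testing correction is applied, matching common practice for
per-neuron category tests).  The empirical type-I error of this procedure is
checked by simulation and sits at the nominal level.

Population summaries use PCA applied *over neuron identities*: the
observations are time points of the per-category mean responses
(-1000..3500 ms), the variables are neurons, and each category's time course
in PC1–PC2 is its population trajectory.

## The lick-direction decoder

The decoder is a two-class probabilistic population code.  Tuning curves
come from *spontaneous* licks — contacts outside stimulus reward windows —
so that decoding stimulus-trial activity never reuses its training events;
`compute_tuning` and the evaluation functions keep these sets disjoint by
construction.  For neuron $n$ and direction $d \in \{L, R\}$, the tuning
$f_n(d)$ is the mean z-score in a -100..100 ms window around that
direction's licks.  Inclusion requires a significant lick response
(baseline -700..-500 ms) in at least one direction, at least 15 licks per
direction, and at least 5 qualifying neurons per field of view; a field
failing the last rule is excluded with an explicit status.

Given a trial's population activity vector $r$ (the window-averaged z in the
pre-stimulus -1000..0 ms or post-stimulus 0..200 ms window), the
log-likelihood of each direction is a matrix product with the logged tuning
curves,

$$LL(d) = \sum_n r_n \left[\log(f_n(d) + \varepsilon) - b_n\right],$$

and the decoded direction maximizes $LL$.  Three numerical choices:

* **Positivity floor.** Mean z tuning can be zero or negative; logs cannot.
  Negative tuning is clamped at zero and $\varepsilon$ added before the log,
  with $\varepsilon = \max(10^{-3},\ 1\%\ \text{of}\ \max|f|)$ by default.
* **Bias term.** $b_n$ is the across-direction mean of the log tuning
  (default), or alternatively the log of the mean tuning
  (`bias_mode = "raw_mean"`).  Either form cancels exactly in the
  left–right difference, so decisions are bias-invariant — a property the
  tests verify rather than assume — and the bias only makes log-likelihood
  magnitudes comparable across fields.
* **Ties.** A zero log-likelihood difference (up to floating-point rounding,
  relative tolerance $10^{-9}$) is flagged and resolved by a seeded coin
  flip whose seed is recorded in the output.

Performance is the fraction of correctly decoded hit and error trials
(trials with evoked licking).  For the pre-stimulus window, trials with any
tongue contact inside the window are excluded, so above-chance pre-stimulus
decoding cannot be an artifact of overt licking.  The decoder is validated
three ways: exact agreement with a brute-force $\sum r \log f$ oracle on
small instances, chance-level behavior under symmetric tuning and label
permutation, and performance within 5 percentage points of the
Bayes-optimal classifier on a Poisson-count population whose generative
model is known.

## Small jaw movements from facial video

Jaw movement is the frame-to-frame difference of the mean pixel value in a
jaw ROI.  Onsets of small movements are detected where this motion signal
exceeds **twice the SD of motion pooled over all trials' -2000..0 ms
pre-stimulus epochs**; on stimulus trials only times up to -500 ms before
the stimulus are eligible (the implementation also keeps a 3 s post-stimulus
guard so evoked movement is never counted as spontaneous), and onsets closer
than 1500 ms to the previous accepted onset are suppressed greedily left to
right, guaranteeing the isolation gap as a hard invariant.

**What the jaw noise model assumes.**  For a fixed-multiple-of-SD threshold
to be a *specific* detector, the baseline motion noise must be bounded: with
Gaussian-tailed frame-to-frame noise, ~2% of baseline samples exceed 2 SD
and the detector would fire continuously on noise at any signal strength.
Real resting-face video at 100–200 Hz behaves like the bounded case — the
ROI mean changes between consecutive frames by small, quantization-limited
amounts.  The generator therefore draws frame-to-frame jitter from a uniform
distribution, in two regimes: `"wander"` integrates the jitter with a slow
mean reversion (a realistic resting face for onset-detection studies), and
`"iid"` keeps position jitter independent per frame, which makes per-window
position SDs stable and is the regime for window-SD ratio analyses.  This is
a deliberate idealization: real video also contains breathing artifacts and
illumination drift that the generator omits, so detector performance on real
data depends on how closely its noise floor approaches the bounded ideal.
Small-movement amplitude is parameterized as a signal-to-noise ratio on the
motion signal (the detection scale); the rate and amplitude of small jaw
movements are free parameters, as no reference values exist.

The optogenetic-inactivation metric compares, on correct-rejection catch
trials only, the SD of jaw *position* during the catch window against the
immediately preceding baseline window of equal length (default 1.5 s, the
light-stimulus duration): the ratio `SD_catch / SD_baseline`, averaged per
mouse and light condition.  The figure legend of the source analysis words
the ratio the other way around; the metric's own definition
(`SD_Catch/SD_Baseline`) is implemented and the discrepancy noted.  Under
the null the mean ratio is 1 within a few percent; suppressing small
movements during light-on windows lowers the light-on ratio below the
light-off ratio, detectable across 7 synthetic mice with a signed-rank test.

Block tuning of preparatory activity is quantified by the Pearson
correlation, across lick-responsive neurons, of the right-minus-left spout
contact response difference against the right-minus-left block difference of
responses aligned to small jaw movements.

## Wide-field imaging

The normalized signal is
$\Delta F/F_0(i,j,t) = (F(i,j,t) - F_0(i,j)) / F_0(i,j)$ with $F_0$ the mean
of the last 5 frames before the stimulus; pixels with non-positive baseline
are masked and counted.  Response images average the 0..100 ms (early,
primary sensory spot) and 100..200 ms (late, frontal spot) windows — exactly
10 + 10 disjoint adjacent frames on the 100 Hz grid.  Peak localization
smooths with a Gaussian of sigma = 3 px (separable kernel, reflective
padding; the border mode is unspecified upstream and reflective padding
avoids edge dimming) and takes the integer-pixel argmax within a search mask
(for frontal spots, by default the anterior third of the image; an
anatomical mask can be supplied).  No sub-pixel refinement is applied: at
100 µm pixels, integer-pixel precision matches the reported coordinate
resolution.  A low-confidence flag marks peaks that do not exceed the
in-mask median by 5 robust (MAD) SDs; simulation shows signal-free smoothed
fields reach ~3 robust SDs by chance, while genuine spots exceed the
smoothed noise floor by an order of magnitude, so 5 separates the regimes.

## Optogenetic motor maps

Stimulation sites form a 0.5 mm grid.  A trial is included only if the
pre-stimulation angle SD stays at or below 2 deg (whisker; 100 ms window) or
0.75 deg (jaw; 250 ms window).  The evoked movement is the mean angle over
the first 200 ms of stimulation minus the mean over the 4 ms immediately
before it (positive = protraction / jaw opening).  Site values are means
over included trials; sites with no included trial stay missing and are
excluded from the centroid.  The map center is the value-weighted centroid
of sites whose value *strictly* exceeds 50% of the map maximum ("exceed"
is read strictly; a site at exactly half the maximum is excluded).  Weights
are the raw site values, not the threshold-subtracted values — the plainer
reading of a weighted centroid of supra-threshold pixels; the alternative
would pull the centroid slightly toward the peak.  The centroid is computed
on the positive-signed map for the part's named movement direction.

## The synthetic-data generator

The generator is first-class, tested code.  Its defaults *are* the study
conditions: 12 +/- 1 s ISI, 3 s quiet period, 1.5 s reward window, 50-trial
blocks, 69% hit regime, ~15% catch trials, 30 Hz imaging, alpha
0.38 +/- 0.30, 100x100 px wide-field frames at 100 Hz with a 2 s / 3.12 s
trial, 500 Hz angle traces on a 0.5 mm grid.  Values the source does not
state were chosen once on domain grounds and not revisited: spontaneous
lick rate 0.06 Hz (tens of tuning events per side per session), calcium
kernel rise/decay 50/500 ms with ~30% dF/F transients (a generic fast
indicator surrogate), a shared AR(1) low-frequency surround contaminant
(surround signal is spatially shared in real fields of view), a 100 ms motor
lead of neural events before tongue contact (motor cortical activity
precedes movement), and preparatory block-tuned event rates of 0.4 Hz where
a motor-cortex-like population is simulated.

Every generator draws from its own RNG stream derived deterministically from
the master seed, so changing the number of neurons cannot perturb the
behavioral schedule, and identical configurations are byte-identical.
Ground truth (intended outcomes, event times, spot centers, hotspot
locations) is returned alongside the data.

**What passing tests establish — and what they do not.**  The recovery tests
show the estimators are correct under the generative assumptions: bounded
jaw jitter, Gaussian pixel noise, double-exponential calcium kernels,
Poisson event trains, multiplicative wide-field bumps.  Real data violate
all of these to some degree (indicator nonlinearity, motion artifacts,
hemodynamic contamination, correlated noise), so the tests certify the
*analysis chain*, not the biology: they demonstrate that where signals of
the modeled form exist, the chain recovers them at the stated accuracy, and
that under nulls it does not fabricate them.

## Problem sizes and reproducibility

The shipped test and acceptance runs use 100 noise-model traces of 600 s,
1000 null neurons for the type-I check, 20-seed batches of 200-trial
sessions with 20 neurons for decoder validation, 50-seed batches for
wide-field and motor-map recovery, and 7 synthetic mice for the inactivation
contrast — sizes at which the property bands (e.g. type-I error 0.05 +/-
0.02, chance band at n = 200) are well resolved while a full run stays in
the minutes range on one CPU.  `scripts/acceptance.R --seed S --out f.json`
recomputes all headline quantities from scratch; the master seed controls
every stream, and two runs with the same seed produce identical JSON.

## Known limitations

* Trace-level synthesis only: no pixel-level somata, no motion artifacts, no
  spike-to-fluorescence nonlinearity; ROI extraction, deconvolution and
  motion correction are upstream tools and out of scope.
* The decoder is strictly two-class with no cross-validation machinery
  (train/test disjointness comes from the spontaneous/evoked split, which is
  enforced, not assumed).
* Wide-field outputs are in pixel coordinates; anatomical (bregma-based)
  registration is the caller's responsibility.
* The two jaw-noise regimes bracket, but do not span, real facial-video
  noise; the inactivation ratio inherits the usual small-n caveats of
  per-mouse averaging.
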