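# cortilick

Analysis of cortical calcium imaging and licking behavior in head-fixed
mice: a tested R implementation of the analysis chain used in sensorimotor
detection experiments where mice lick one or two reward spouts in response
to whisker or auditory stimuli while neurons are imaged, the face is filmed
at high speed, and cortex is mapped with wide-field imaging and optogenetic
stimulation.

The package is for experimentalists and analysts who need these standard
steps as reusable, validated functions rather than one-off scripts:

* **Behavior** — trial outcome classification (hit / miss / false alarm /
  correct rejection / error-left / error-right), session summaries,
  switch-aligned lick probabilities with Wilson confidence intervals.
* **Calcium conditioning** — neuropil correction
  `F(t) = F_soma(t) − α·F_surround(t)`; mode-based z-scoring
  `z(t) = (F(t) − F_mode)/σ_Noise` in 100-s blocks, where `σ_Noise` comes
  from symmetrizing the sub-mode values around the mode (robust to
  positive-going transients); a 5 SD / 0.05 Hz activity filter;
  event-aligned responses; Wilcoxon responsiveness tests; population PCA
  trajectories.
* **Lick-direction decoding** — a two-class probabilistic population code:
  per-neuron tuning `f_n(d)` from spontaneous licks, decision by
  `argmax_d Σ_n r_n [log(f_n(d)+ε) − b_n]` on pre-stimulus (−1000..0 ms) or
  post-stimulus (0..200 ms) population activity, with bias correction, tie
  handling, and inclusion rules (15 licks per direction, 5 neurons per
  field).
* **Jaw videography** — frame-difference motion energy, small-movement
  onset detection (2× pooled pre-stimulus SD, 1500 ms isolation),
  the `SD_catch/SD_baseline` inactivation ratio, block-tuning correlation.
* **Wide-field maps** — `ΔF/F₀` with a 5-frame baseline, early (0–100 ms)
  and late (100–200 ms) response images, σ = 3 px smoothed peak
  localization with masks.
* **Optogenetic motor maps** — part-specific trial inclusion (2° whisker /
  0.75° jaw), 4 ms-vs-200 ms evoked movement, and the 50 %-of-max weighted
  centroid hotspot.
* **Synthetic sessions** — a seeded generator for all of the above
  (block-structured multimotor sessions, tuned calcium with neuropil
  contamination, jaw traces, two-spot wide-field movies, motor-map grids)
  with ground truth, so every estimator has a recovery test.

See the methods vignette (`vignettes/cortilick-methods.Rmd`) for the models,
assumptions, parameter defaults, and numerical choices.

## Worked example

Simulate a 200-trial two-spout (multimotor) session with 20 neurons whose
tuned subpopulations carry preparatory block-tuned activity, then run the
whole chain — classification, trace conditioning, decoder fitting on
spontaneous licks, decoding of stimulus trials in both windows, and jaw
onset detection:

```r
library(cortilick)

rep <- run_pipeline(
  session_config(n_trials = 200, task = "multimotor", seed = 42),
  calcium_config(n_neurons = 20, preparatory_rate_hz = 0.4, seed = 42),
  seed = 42)
print(rep)
#> Pipeline run (seed 42)
#>   trials:       200
#>   hit rate:      0.566
#>   kept neurons: 20
#>   decoder:       pre 0.746 / post 0.820
#>   jaw onsets:   264
```

The hit rate is the fraction of whisker trials whose *first* in-window
contact was on the rewarded spout (perseverative errors after block switches
keep it below the configured 69 % lick probability).  The decoder reads lick
direction from population activity well above chance both after the stimulus
(0.82) and — the interesting part — *before* it (0.75), from preparatory
activity alone; trials with any pre-stimulus spout contact are excluded, so
this is not overt licking.

```r
print(rep$behavior)
#> Session outcome summary (200 trials)
#>       category   n  k  rate
#>    whisker_hit 175 99 0.566
#>  whisker_error 175 23 0.131
#>    false_alarm  25  7 0.280
#> Median first-lick latency (ms):
#>  error_left error_right false_alarm         hit
#>         253         356         437         271

summary(rep$decoder)
#> Lick-direction decoder: 16 neurons (of 20 candidates), epsilon = 0.04862
#> Bias correction: mean log of the tuning curves
#> Preferred side: 8 right, 8 left
#> Tuning range (z): -0.096 .. 4.862
```

Sixteen of the twenty simulated neurons passed the inclusion rules
(significant spontaneous-lick response, ≥ 15 licks per direction); their
tuning curves span ~5 z and split evenly between left- and
right-preferring, as constructed.

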