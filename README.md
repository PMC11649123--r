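# steplock

Windowed classification of step-to-beat auditory-motor coupling, and
modelling of gait variability under it.

## What problem this solves

People instructed to walk in time with music or a metronome drift in and
out of synchrony within a single trial. `steplock` is for researchers in
sensorimotor synchronisation and gait rehabilitation who have **event
times** — footfall timestamps from ankle sensors and beat timestamps of
the stimulus — and want, per 20-second window of a 180-second trial, a
defensible *locked* / *unlocked* label, plus a downstream account of how
lock state, tempo and stimulus type affect step-timing variability.

The core quantity is the relative phase angle (rPA) of step *j* against
its enclosing beat interval,

    r_j = 360 * (Step_j − Beat_j) / (Beat_{j+1} − Beat_j)   [degrees],

mapped to (−180°, 180°] so that a footfall before the beat is negative.
Each window is labelled twice and the labels conjoined:

1. **Fluctuation** — a circular-range uniformity test (statistic
   `w = 360° − largest gap` between sorted angles, exact null p-value
   `p = Σ_k (−1)^{k−1} C(n,k) (1 − k t)_+^{n−1}`, `t = 1 − w/360°`).
   Rejection means the phases sit on a short arc: locking evidence.
2. **Trend** — a linear mixed model `rPA = β0 + β1·s + b0(k) + b1(k)·s + ε`
   over the trial's stacked windows (`s` = seconds since window start),
   REML-fitted; each window's slope deviation BLUP `b1(k)` is tested
   against zero with its prediction standard error. A significant
   deviation from the trial's overall slope is unlocking evidence.

A window is **locked** only if both tests say locked. Per-window SDs of
the inter-step interval `δ_j = Step_{j+1} − Step_j` (population
denominator), cleaned by a median ± 3·sd rule, then enter a log-scale
linear mixed model with tempo, stimulus, window, lock state,
Tempi×Stimuli and Tempi×Lock effects and a subject random intercept.

Because no public recordings of this protocol exist, the package includes
a synthetic walking-to-beat generator (von Mises phase jitter for locked
segments; uniform-phase or period-detuned regimes for unlocked ones) with
known ground-truth window labels, and confusion-matrix / Cohen's-kappa
utilities to score classifications against truth.

## Worked example

Simulate a trial that walks locked for a minute, loses the beat for a
minute, and relocks; then classify its windows:

```r
library(steplock)

m <- trial_meta("S01", "music", -8)   # music, 8% below baseline cadence
plan <- segment_plan(180, c("locked", "unlocked_uniform", "locked"),
                     breaks = c(60, 120))
sim <- simulate_trial(m, plan, seed = 42)
cl <- classify_trial(sim$trial)
print(cl)
```

```
Step-to-beat lock classification (S01, music, tempo -8%)
 window_index  n    circ_p  slope_p circ_label slope_label final_label
            1 24 5.904e-14 0.221015     locked      locked      locked
            2 23 3.022e-15 0.208742     locked      locked      locked
            3 22 1.695e-11 0.157689     locked      locked      locked
            4 23 3.616e-01 0.009705   unlocked    unlocked    unlocked
            5 23 1.810e-01 0.012805   unlocked    unlocked    unlocked
            6 24 2.479e-01 0.006917   unlocked    unlocked    unlocked
            7 23 9.746e-11 0.379009     locked      locked      locked
            8 23 3.269e-14 0.163756     locked      locked      locked
            9 21 7.689e-14 0.131378     locked      locked      locked
```

Windows 1–3 and 7–9 show tiny circular-test p-values (phases concentrated
on a short arc — locked), while windows 4–6, where the generator decoupled
the steps, fail to reject uniformity and show significant slope
deviations. Scoring against the generator's ground truth:

```r
cc <- confusion(cl$windows$final_label, sim$truth$true_label)
classification_metrics(cc)
```

```
Confusion counts (locked = positive): TP 6, TN 3, FP 0, FN 0
 accuracy precision    recall
        1         1         1
```

`run_pipeline()` does this for a batch of trials and finishes with the
log-SD variability model (`fit_variability_model()` /
`model_reduction()`); a thin command-line front-end with `simulate`,
`classify`, `model`, `evaluate` and `run` subcommands lives at
`inst/scripts/steplock.R`.

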