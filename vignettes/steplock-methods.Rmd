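---
title: "Classifying step-to-beat phase locking in windowed gait trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying step-to-beat phase locking in windowed gait trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steplock)
```

## The problem

When a person walks to music or a metronome, their step-to-beat coupling is
not a fixed trait of the trial: within the same three minutes they may lock
onto the beat, lose it, and recapture it. A single per-trial synchronisation
score hides these dynamics. `steplock` takes the event times — footfalls
from ankle-worn inertial sensors and beats of the auditory stimulus — and
labels each 20-second window of a 180-second trial as **locked** (steps
aligned with the beat) or **unlocked**, then asks how lock state, tempo and
stimulus type shape the variability of the walking pattern itself.

The unit of analysis is the **relative phase angle** (rPA) of step $j$:

$$ r_j = 360\,\frac{\mathrm{Step}_j - \mathrm{Beat}_j}
  {\mathrm{Beat}_{j+1} - \mathrm{Beat}_j} \quad (\text{degrees}), $$

with $\mathrm{Beat}_j$ the beat at or before the step. Raw phases in
$[0^\circ, 360^\circ)$ are re-expressed on $(-180^\circ, 180^\circ]$ by
subtracting $360^\circ$ above $180^\circ$, so a footfall shortly *before* a
beat carries a negative angle and one shortly *after* a positive one. This
mapping is the standard closest-beat convention; it is the only one
consistent with both the stated range and the stated sign semantics.

## The two-test window classifier

Each window receives two labels that are then conjoined.

**Fluctuation: circular-range uniformity test.** Locked walking shows rPA
concentrated on a short arc; unlocked walking spreads it around the circle.
We test uniformity with the circular range $w$ — $360^\circ$ minus the
largest gap between sorted angles — whose exact null probability is

$$ P(W \le w) = \sum_{k\ge 1} (-1)^{k-1} \binom{n}{k}
   \left(1 - k\,t\right)_+^{\,n-1}, \qquad t = 1 - w/360^\circ . $$

Small $p$ means the angles occupy an unusually short arc; rejection is
evidence of locking. The alternative is concentration on an arc, with no
modal direction estimated or required, which is exactly what a slowly
wandering but bounded phase produces. One structural fact worth knowing:
with $n$ points the range cannot exceed $360^\circ (n-1)/n$ (some gap is
always at least $360^\circ/n$), so the null CDF saturates at 1 there.

**Trend: mixed-model slope test.** A window can be concentrated yet
drifting. Within a trial we stack the windows on a common clock
$s \in [0, 20)$ (seconds since window start) and fit, by REML,

$$ r = \beta_0 + \beta_1 s + b_0(k) + b_1(k)\, s + \varepsilon, $$

with jointly Gaussian window-level random intercept and slope
(unstructured $2\times2$ covariance by default; a switch gives independent
effects). Each window's predicted slope deviation $\hat b_1(k)$ — the BLUP
— is tested against zero with its conditional (prediction) standard error
and a standard-normal reference. A significant deviation from the trial's
overall slope labels the window unlocked. The normal reference is an
approximation chosen for portability: there is no generally agreed
degrees-of-freedom rule for BLUP tests, and at 20–30 observations per
window times nine windows the difference is immaterial.

**Combination.** A window is finally locked only when *both* evaluations
say locked; unlocked otherwise; windows with fewer than `min_obs = 8`
observations are unevaluable and propagate as such. The two tests fail in
complementary ways — drift that wraps around the circle produces a sawtooth
whose fitted slope is near zero (missed by the slope test) but whose phases
cover the circle (caught by the uniformity test); a slow unidirectional
drift can stay on a short arc (caught by the slope test) — which is why the
conjunction outperforms either test alone.

### A contamination property of the slope test

The slope test measures deviation from the trial's *mean* slope. If one
window of nine drifts steeply without wrapping, the overall slope is itself
displaced by about drift/9, so truly flat windows sit that far below it;
with 25 observations and 20° noise this displacement is about 2.6
prediction SEs at a 15°/s drift, and flat windows get flagged as deviating
too. We document rather than "fix" this: it is inherent to
deviation-from-mean testing, in practice steep sustained drift wraps (and
is then caught by the uniformity test), and the per-window test suite
asserts the drifting window dominates — not that it is the only flag.

rPA values enter the slope model on their raw $(-180, 180]$ scale with no
unwrapping; unwrapping would make sawtooth drift trivially detectable but
would change the method.

## Inter-step-interval variability model

The inter-step interval $\delta_j = \mathrm{Step}_{j+1} - \mathrm{Step}_j$
is stamped at the initiating step ($t_j = \mathrm{Step}_j$), cleaned by a
single-pass median $\pm 3\,$sd rule (sample sd with $n-1$ denominator,
computed once on the raw per-trial series — the rule is not iterated),
truncated at 180 s and windowed on the same grid as the rPA, so an interval
straddling a boundary belongs to the window of its initiating step. Each
window's spread is the population-denominator standard deviation

$$ S = \sqrt{\tfrac{1}{J}\sum_j (\delta_j - \mu)^2 }, $$

a repeated measure over windows. $S$ is right-skewed, so we model its
natural logarithm (the base is configurable; it only rescales
coefficients):

$$ \log S = \beta_0 + \mathrm{Tempi} + \mathrm{Stimuli}
 + \mathrm{Window}/10 + \mathrm{Lock}
 + \mathrm{Tempi}{\times}\mathrm{Stimuli}
 + \mathrm{Tempi}{\times}\mathrm{Lock} + u_{\text{subject}} + \varepsilon,
$$

with a subject random intercept, REML estimation, reference levels tempo
0, metronome, locked, and the window index rescaled by 10 (a pure
numerical-conditioning choice: it keeps the slope coefficient on the scale
of the factor effects). Fixed-effect p-values again use the normal
approximation on $t = \hat\beta/\mathrm{SE}$. Coefficients are reported in
the n12/n8/n4/p4/p8/p12 tempo dialect so fits are directly comparable
across software.

`model_reduction()` implements backward elimination over *interaction
blocks only* — main effects are never dropped — using likelihood-ratio
tests on ML refits with a 0.05 retention threshold, starting from all
two-way interactions of Tempi and Lock with the other covariates. The
elimination order (drop the least significant block first) is one
defensible convention among several; it is exposed rather than hard-coded
so the candidate set can be changed.

Zero SDs (constant intervals in a window) have no log; the fit refuses
them with instructions rather than silently flooring, because a zero SD in
real gait data is almost certainly a sensor artefact.

## The synthetic walking generator

No public recordings of this protocol exist, so the package ships a
generator that emulates the study conditions and provides known
ground-truth labels:

* **Beats**: isochronous at the trial tempo, `baseline_cadence * (1 +
  tempo_offset/100)` bpm. The default baseline of 75 steps/min gives an
  0.8-s inter-beat interval and about 25 steps per 20-s window, inside
  the 20–30 band typical of these trials.
* **Locked segments**: one step per beat at a mean phase offset of −30°
  (a slight anticipation of the beat, typical of cued walking) with von
  Mises jitter of concentration $\kappa = 8$ (circular sd ≈ 21°), plus
  5 ms of Gaussian timing noise.
* **Unlocked segments**: either uniform phase per beat interval, or an
  isochronous step train whose period is detuned 4–6% from the beat
  period, so the phase advances $3.6 \times \text{detuning}\%$ degrees
  per beat and wraps.
* **Plans**: by default three 60-s segments per trial, aligned with the
  window grid; each segment is locked with probability 1/2. Ground truth
  per window is majority occupancy, unambiguous under aligned boundaries.

These choices were fixed once, as the package's definition of "strongly
separated regimes", before any performance was measured. What the
generator does **not** emulate: step-length/asymmetry structure,
autocorrelated timing noise, gradual relocking transients, tempo-adaptive
stimuli, or rater ambiguity about borderline windows. Passing the
simulation benchmarks therefore shows the pipeline recovers cleanly
separated regimes, not that it reproduces human-rater judgments on
clinical data.

Von Mises draws use the Best–Fisher rejection sampler; all randomness in a
trial set flows from one caller-supplied seed.

## Numerical and degenerate-input conventions

* Windows are half-open $[(k-1)w, kw)$; the 180-s point is excluded.
  Window partition requires the window length to divide the trial length
  exactly — no partial windows.
* A constant interval series has sd 0 and the outlier rule removes
  nothing.
* If the random-slope variance is estimated at the boundary (zero), all
  slope deviations are zero: every evaluable window is slope-locked, with
  a warning. This is the correct degenerate answer for a trial with no
  between-window trend heterogeneity (e.g. a fully locked trial).
* Antipodal angle sets have resultant length 0; the circular mean is then
  reported as `NA` rather than an arbitrary direction.
* No multiple-testing correction is applied across the nine windows by
  default (per-window inference is the method); `p_adjust` switches on
  Bonferroni and friends.

## Problem sizes used in the shipped checks

The test suite exercises the classifier on 126 simulated trials (9
subjects × 14 conditions), calibrates the uniformity test on 20,000
uniform samples per $n \in \{10, 20, 30\}$ with a $10^5$-replicate null
CDF comparison, runs 500 null trials through the slope test, and checks
variability-model recovery over 200 replicates of a 12-subject × 14-trial
× 9-window design with coefficients of realistic magnitude. These sizes
were chosen so each check's Monte-Carlo error is small relative to the
property being asserted. On the recovery check, note that per-coefficient
coverage estimated from 200 replicates carries a Monte-Carlo SE of about
0.015, so coverage is asserted in aggregate across coefficients, with a
0.90 per-coefficient floor.

## Known limitations

* The slope test's normal reference and the variability model's
  normal-approximation p-values are approximations; with few windows or
  few subjects they are mildly anticonservative.
* Window length is a free parameter (default 20 s); populations with
  slower cadence need longer windows to keep 20+ steps per window, and
  the classifier has no protection against windows that mix regimes —
  ground truth by majority occupancy is a modelling convenience, not a
  perceptual standard.
* The log-LMM treats per-window SDs as Gaussian on the log scale; gamma
  GLMMs or GEEs are plausible alternatives and are deliberately out of
  scope.
* Beat times are taken as given; no audio or IMU signal processing is
  performed.

## A worked run

```{r, eval = FALSE}
design <- c(enumerate_design(subject_id = "S01"),
            enumerate_design(subject_id = "S02"))
sims <- generate_trial_set(design, seed = 42)
out <- run_pipeline(sims, pipeline_config(seed = 42))
print(out)

truth <- unlist(lapply(sims, function(s) s$truth$true_label))
m <- classification_metrics(confusion(out$labels$final_label, truth))
round(m, 3)
```
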