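---
title: "Measuring facial-expression synchrony in live audiences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial-expression synchrony in live audiences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiencesync)
```

## The measurement problem

When an audience watches a live performance, individual faces respond to
the same unfolding events. Automated expression classification reduces
each filmed face to eight bounded intensity channels (neutral, happy,
sad, angry, surprise, fear, disgust, contempt), sampled at 50 frames/s,
each value in [0, 1]. Synchrony between two audience members is then a
statistical question: how correlated are their intensity series for the
same channel? This package implements that question end to end —
inter-subject correlation (ISC) time courses, pair-level synchrony, and
the inferential layer that relates synchrony to predicted engagement,
seat proximity and audience-member characteristics.

Three modelling commitments shape everything downstream:

* **A frame is atomic.** Face-model fitting fails for a whole frame, not
  for one channel, so a frame missing any channel is invalid and all
  eight values are treated as missing. Every operation is invariant to
  whatever values sit at invalid frames (they are physically removed at
  construction).
* **Correlations use pairwise-complete frames.** The data format allows
  dropout anywhere; each pairwise correlation uses the frames jointly
  valid for the two series involved, and is *missing* — never zero —
  when coverage or variance is insufficient. Coercing undefined
  correlations to zero would bias ISC toward zero exactly where faces
  were occluded.
* **Raw r for description, Fisher z for inference.** ISC time courses
  average raw correlations; anything entering a test, regression or
  Bayes factor is first transformed with z = atanh(r), clipping |r| at
  1 − 1e−7 so perfect correlations stay finite (z ≈ 8.39).

## Sliding-window ISC

The window specification defaults to the field convention for 50 frames/s
recordings: 3000-frame (60 s) windows advanced in 100-frame (2 s) steps,
so a performance of `n` frames yields `floor((n − 3000)/100) + 1`
windows; a trailing partial window is dropped. Within a window, a pair's
correlation is defined only when at least `min_valid_fraction` (default
0.5) of the window is jointly valid and both series vary. The per-window
ISC is the arithmetic mean over defined pairs, with the contributing
pair count reported.

Internally all windowed correlations come from masked crossprod prefix
sums over the shared window boundaries, making the whole time course
O(channels² × frames) regardless of window count; the result matches a
naive per-window Pearson recomputation to better than 1e−10 (this
equivalence is itself a test).

Pair-level ISC supports two aggregations, because how a single synchrony
number per pair should be built is genuinely underdetermined:
`whole_series` (default) correlates the full jointly valid series;
`window_mean` averages per-window Fisher-z values and back-transforms.
Both are exposed and logged; no analysis in the package depends on the
choice being one or the other.

## Inclusion rules

A participant enters analysis only if strictly more than 90% of their
frames are valid and their questionnaires are complete; a performance is
analyzed only if more than one participant qualifies, otherwise the
whole recording is excluded (with a log of who fell where). The
threshold is a strict inequality — exactly 90% is excluded — and the
filter is idempotent.

## The inferential layer

**Engagement.** Scene-level 1–3 engagement predictions (whole-second
boundaries, half-open intervals `[start, end)` so a boundary frame
belongs to the later scene) are expanded to frames and resampled with
the same windows as the ISC, which slightly smooths transitions; a
window inside one scene reproduces that scene's score exactly. The
ISC–engagement relation is quantified per channel by Pearson correlation
with a JZS-style Bayes factor, and jointly by exhaustive all-subsets
least-squares regression over the 2⁸ channel subsets. Successive
overlapping windows are autocorrelated; like standard practice for this
design, no correction is applied, and the output carries a note saying
so.

**Proximity.** Seats live on a unit grid (adjacent seats and adjacent
rows are both 1 unit); pair distance is Euclidean. Because seat
distances are right-skewed, the correlation with pair ISC uses
√distance. Inference is by permutation: pair z values are shuffled
across pairs (10,000 draws by default) and the p value is the proportion
of permuted correlations at least as extreme in the tested direction
(default: negative, i.e. closer pairs more synchronized). The
"at least as extreme" counting rule is direction-ambiguous for negative
observed correlations, so three rules are exposed and logged: `plain`
(k/n in the tested direction, the default), `add_one` ((k+1)/(n+1),
never exactly zero), and `ge_observed` (counts permuted r ≥ observed r
regardless of direction). Calibration under the null generator is a
test: the plain rule rejects at 3–7% at α = 0.05.

**Pair characteristics.** Pairs carry total (summed) age and empathy and
two groupings: gender (`female`/`male` when both members share that
gender, `different` for mixed pairs, `excluded` when either member's
gender is other/unknown) and age (`young` both under 25, `old` both over
25, else `different` — a member aged exactly 25 defeats both strict
inequalities by construction). Age is hypothesized to lower synchrony
and empathy to raise it, so the Bayes factors are one-sided in those
directions. The gender contrast compares `z ~ age_group`,
`+ gender_group` and `* gender_group` models, age-only being the null
because the age effect is assessed separately.

**Bayes factors.** The paired t test BF integrates the noncentral-t
marginal likelihood over a Cauchy prior on the standardized effect
(scale 0.5 by default, truncated to positive effects for directional
hypotheses), by adaptive quadrature on a log-scaled integrand with the
domain cut at the prior's and likelihood's own scales so well-separated
peaks are never missed; integration must achieve 1e−6 relative error or
it errors out rather than returning silently. Posterior median and
central 95% interval come from the same normalized integrand on a grid
refined until the endpoints move by less than 1e−3. The correlation BF
uses the exact sampling density of Pearson r (its hypergeometric factor
summed by series) under a stretched Beta(1/κ, 1/κ) prior on ρ with width
κ equal to the Cauchy scale — the standard width mapping for correlation
priors. Both integrators are validated against independent dense-grid
trapezoid integration to 1% relative error. Regression and ANOVA-style
model comparisons use a BIC proxy — BIC = n·log(RSS/n) + k·log(n),
scores ∝ exp(−BIC/2) normalized under a uniform model prior — and every
result is tagged `bic-approx`; exact parity with any particular Bayesian
regression implementation is not claimed. A perfect fit has RSS = 0,
which the BIC cannot absorb; RSS is floored at 1e−12 × TSS, which keeps
the perfect model first at a finite score.

## The synthetic-audience generator

The generator exists so that every analysis stage has a recovery test
with known ground truth. Per configuration it draws, in a documented
order from one seeded stream: traits (age ~ Uniform(18, 80); empathy ~
truncated Normal within the declared scale's range; gender ~
Bernoulli(1/2)); a per-channel shared signal (standardized moving
average, 50 frames by default, of white noise); a per-channel spatial
field over participants with covariance exp(−d/λ) drawn independently
per 50-frame block and standardized; and i.i.d. observation noise.
Participant i's channel-c intensity is

```
x_ic(t) = clip( mu_c + kappa_c * g(t) * w_i * (s_c(t) + omega * u_ic(t)) * 0.1
                + sigma * eps_ic(t), 0, 1 )
```

with gain `g(t) = (e(t)/3)^gamma` from the scene score e(t), and
coupling weight `w_i = logistic(beta_age z(age) + beta_emp z(empathy) +
beta_gender 1[female])`. Dropout marks `ceiling(delta * n_frames)`
frames invalid per participant as up to three contiguous runs at random
positions — the validity fraction is exact by construction.

Defaults (chosen once, as the package's standing study conditions):
baselines with neutral dominant (0.55) and emotional channels sparse
(0.15–0.25); `kappa = 0.3`, `sigma = 0.15` and `omega = 2` — calibrated
so that windowed ISCs land in the 0.01–0.1 range and single-channel
engagement correlations near r ≈ 0.3–0.6, the magnitudes reported for
real audiences. That calibration matters: with a much stronger signal
the ISC–engagement relation saturates, and the linear R² of the
engagement regression is then governed by the curvature of the gain map
rather than by the gating strength, inverting the expected ordering
across `gamma`. `omega = 2` makes local (neighbour-to-neighbour)
coupling dominate the globally shared signal, which is what an emotional
contagion account of proximity effects implies; `lambda = 3` seat units,
`beta_age = −0.5`, `beta_emp = +0.5`, `beta_gender = +0.5` per
standardized unit, dropout 5%.

What the generator deliberately does not emulate: temporal lags in
mimicry (synchrony is lag-0), actor/stage dynamics, non-stationary
baselines, realistic facial dynamics, and the upstream classifier's
per-face calibration error. Passing recovery tests therefore shows the pipeline
recovers the *structure* the generator encodes — engagement gating,
spatial decay, trait modulation — not that real audiences behave this
way.

## Problem sizes in the test suite

The recovery and calibration tests run at sizes chosen to make each
property identifiable: permutation calibration on 500 null audiences of
20 participants × 3000 frames (1000 permutations each); proximity
recovery on 100 audiences of 40 participants × 6000 frames at λ = 3;
engagement recovery on 30 seeds per `gamma` with 4 participants, 30,000
frames and 10 s non-overlapping windows — a small audience and short
windows keep window-ISC noise comparable to the engagement signal, the
regime in which gating strength is identifiable and best-subset
regression cannot overfit smooth overlapping series; trait recovery on
30 audiences of 30 participants × 3000 frames. Oracle-equivalence
checks run on 50 random small recordings (≤ 6 participants, ≤ 600
frames, 5–30% missingness).

## Known limitations

* Overlapping windows make neighbouring ISC values strongly dependent;
  correlations and regressions against engagement inherit that and no
  effective-sample-size correction is applied (flagged in output).
* The BIC model scores approximate Bayesian model comparison; they agree
  in ordering and order of magnitude, not digit for digit, with
  JZS-style regression Bayes factors.
* Pair observations in the proximity and trait analyses are not
  independent (pairs share participants); the permutation test treats
  pair ISCs as exchangeable, which is mildly optimistic for short
  recordings.
* Fully deterministic regeneration holds for a fixed configuration;
  adding participants reuses the single RNG stream and therefore changes
  all subsequent draws.
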