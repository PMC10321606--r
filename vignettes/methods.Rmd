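---
title: "Methods: frame-differencing analysis of articulatory preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame-differencing analysis of articulatory preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In conversation, speakers often begin planning their turn while still
listening to the previous one. The question this package's analysis targets
is whether that planning runs all the way down to *articulatory preparation*
— moving the tongue into position before any sound is produced — and when.
The experimental design it serves is a quiz paradigm: a participant hears a
pre-recorded question whose answer-enabling *critical word* arrives either
mid-question (early planning, EP) or question-finally (late planning, LP),
and answers aloud. Tongue movement is recorded with an ultrasound probe fixed
under the chin (here emulated at 91.65 frames/s, 57 x 842-pixel grayscale
frames), with a sync pulse marking question onset on the video clock.

## The movement statistic (Delta)

Movement is quantified without tracking the tongue contour: for consecutive
frames $F_k, F_{k+1}$ (intensity vectors over all pixels), the trace value is
the Euclidean distance

$$\Delta_k = \lVert F_{k+1} - F_k \rVert_2
  = \sqrt{\textstyle\sum_{i} (F_{k+1,i} - F_{k,i})^2},$$

optionally divided by $\sqrt{HW}$ (`per_pixel_rms`) so traces are comparable
across image sizes. `none` reproduces the unnormalized distance that a
fixed-geometry study would use. Intensities are promoted to double before
differencing (no unsigned-integer wraparound), and each $\Delta_k$ is
timestamped at the *midpoint* of its two frames: nothing in the source
material fixes whether a difference belongs to its first or second frame,
and the midpoint avoids a systematic half-frame (~5.5 ms) lag.

## Epoching and averaging

Each trial's trace is anchored to the trial clock through the sync pulse and
re-referenced to one of three lock points: TL1 = question offset, TL2 =
critical-word onset (EP) or an equivalently placed control word (LP), TL3 =
response onset. Trials vary in length, so traces are linearly interpolated
onto a lock-relative uniform grid with step $1/91.65\,\mathrm{s} \approx
10.911$ ms whose point $k$ sits at exactly $k \cdot \mathrm{step}$; grids of
different trials therefore align by integer index and always contain time 0.
Averages per participant and condition carry a per-timepoint count of
contributing trials. The analysis window is restricted to timepoints where
*every* participant has at least `min_trials` (default 1) contributing
trials in *both* conditions — the stricter complete-data rule — so the
paired t-test below has constant degrees of freedom across time. No baseline
correction is applied.

Exclusions are applied sequentially before epoching, each stage reported
against its own denominator: incorrect responses including those slower than
5 s (of all trials), hesitations (of correct answers), and onset phonemes
that image poorly — d, f, ɣ, ɦ, m, p, r, v, ʋ — (of correct answers without
hesitations). The kept set is order-independent; only the reported
percentages depend on the order.

## Cluster-based permutation test

Per timepoint, a paired t statistic compares the two condition matrices
($P$ participants x $T$ timepoints). Timepoints with $|t|$ above the
two-sided critical value at $\alpha_{cluster} = .05$ (df $= P-1$) are grouped
into maximal contiguous same-sign runs; each cluster's *mass* is the sum of
its t values ("SumT"). The null distribution of the maximum $|$mass$|$ is
built by randomly sign-flipping each participant's difference trace
(equivalent to swapping condition labels within participant — the exact
group for a paired design), 1000 times by default. One symmetric
max-$|$mass$|$ null serves both signs, since the source analysis reports
positive and negative clusters without describing tail handling. With three
lockings analyzed, the per-locking significance level is Bonferroni-corrected
to $\alpha_{final} = .05/3 = .017$.

Numerical choices:

* **p estimator.** Monte-Carlo p values use $(1+k)/(1+n)$, where $k$ counts
  null draws at least as large as the observed $|$mass$|$ (ties count as
  larger — conservative). This deviates deliberately from the literal
  "proportion larger than the observed one": it is never 0 and is valid at
  finite $n$. In exhaustive mode (all $2^P$ patterns, which include the
  identity) the exact proportion is used.
* **Degenerate timepoints.** A zero-variance, zero-mean difference column is
  $0/0$ and is set to $t = 0$ (cannot seed clusters). A zero-variance,
  *nonzero*-mean column is a noise-free constant offset: it is reported as
  signed infinity, flagged, and does seed a cluster (infinite mass, whose p
  counts only infinite null entries). This is the only reading under which a
  noise-free injected offset is detected as exactly one significant cluster
  while pure-zero columns stay inert.
* **Vectorized null.** Sign flips leave each column's sum of squares
  unchanged, so all permutation t series follow from one matrix product
  $SD/P$; tiny negative variances from cancellation are clamped to 0.
* The permutation seed is a required, recorded configuration item.

## Response-time model

Response time is response onset minus question offset (negative when the
answer overlaps the question). The behavioral model is
`RT ~ condition + (1 | participant) + (1 | item)` by REML (lme4); random
slopes are deliberately absent (singular with data of this shape). Reported
are the model-implied condition means, their difference, its t (effect/SE,
$|t|>2$ read as significant at 5%), and the three variance components.
Fitting is delegated to lme4 — this stage is reproduction plumbing, not the
package's analytical contribution — but the degenerate zero-residual case is
short-circuited to the exact closed form, because lmer cannot represent it.

## What the synthetic generator emulates

The generator states a world with the structure the analysis assumes:

* **Design:** 25 participants x 29 trials per condition (58 items shared
  across participants in a two-list design).
* **Timeline:** question-onset-to-word-onset and word-onset-to-question-offset
  intervals drawn from truncated normals with the published stimulus means
  and SDs (EP: 1619/740 and 2839/655 ms; LP: 1788/950 and 2669/866 ms). The
  published ranges for the control word are internally inconsistent in the
  source text, so fixed truncation floors (0.1 s and 0.5 s) are used instead.
* **Response times:** shifted lognormal per condition. A shifted lognormal
  cannot match mean, median *and* SD simultaneously here (the minimum
  achievable SD given the EP mean-median gap is ~729 ms vs the reported
  662 ms), so the calibration matches mean and median exactly in closed form
  (`rt_lognormal_params()`): EP 626/407 ms, LP 900/741 ms, shift -150 ms so
  a realistic fraction of answers overlaps the question.
* **Kinematics:** latent speed = declining baseline while listening (level
  1.0 a.u., -0.12 a.u./s, frozen after question offset) + piecewise-linear
  preparatory ramp reaching 0.8 a.u. at response onset, starting a
  condition-dependent lead earlier (EP 1.2 +/- 0.2 s, LP 0.3 +/- 0.1 s;
  clipped at question onset if needed) + raised-cosine articulation burst
  (3.0 a.u., 0.8 s) + half-normal noise (scale 0.3). Lognormal heterogeneity
  multiplies the amplitudes per trial (CV 0.3) and per participant (CV 0.2);
  applied to both conditions alike, it preserves exchangeability under a
  null configuration. These magnitudes are one-time realism choices — real
  Delta traces are noisy, with trial-to-trial variability comparable to the
  preparatory signal itself — not quantities the source reports.
* **Rendering:** frames are background (30) + Gaussian-profile bright ridge
  (amplitude 160, sd 3 px) around a smooth arch, displaced between frames by
  exactly `displacement_gain * speed` pixels (zig-zagging inside the image),
  plus speckle (sd 8), quantized to integers in [0, 255]. This is a
  measurement model, not ultrasound physics: beam geometry, fan masking,
  probe drift and real speckle statistics are out of scope. Its purpose is
  the verifiable property that the extracted Delta trace is monotonically
  related to the latent speed (Spearman rho > 0.95 on noise-free renders).
* **Recording window:** question onset - 0.5 s to response offset + 1.5 s
  (unstated in the source; chosen to cover all three locks with margin).
* **Exclusions:** incorrect 8.1%, hesitation 11.5%, excluded phoneme 4.9%,
  sampled independently and removed sequentially, reproducing the published
  retained counts (~23.4 / 22.1 trials per condition).

A green simulation test therefore establishes that the *pipeline* recovers
the structure this world puts in — not that the world is a faithful model of
tongues. In particular, trial lengths, item identity and participant skill
are iid draws here, whereas real items have fixed timings shared across
participants.

## Test-budget scaling and the two observation paths

Simulation studies (type-I calibration, effect-pattern reproduction) run the
pipeline through `delta_from_kinematics()`, an observation path that reads
the movement magnitude directly off the latent speed instead of rendering
~10^7 pixel frames (hours of compute at study scale). The rendered path is
validated separately: Delta-vs-oracle equivalence, the displacement/speed
rank correlation, and an end-to-end frames-mode pipeline run all execute at
small scale in the test suite. The default test image is 57 x 128 px; the
(normalized) Delta statistic is size-agnostic.

## Interpreting the early-window criterion at TL2

The acceptance study asks that no significant EP>LP cluster lie *within* the
first 2 s after TL2. With the published timing SDs and RT spread, the EP
preparatory ramp's onset relative to TL2 (word-to-offset + RT - lead) is
smeared with an SD near 1 s, so the genuine late cluster's left edge
fluctuates around ~2 s and occasional early suprathreshold runs are a real
property of this stated world, not a pipeline artifact. The criterion is
therefore operationalized as: no significant positive cluster whose entire
extent falls inside [0, 2] s — the analogue of the source's Early-AP test,
which is about an early effect existing, not about the left edge of the late
effect.

A related caveat concerns cluster *extents* at TL3. Both conditions'
preparatory ramps reach the same plateau exactly at response onset, so the
EP−LP difference decays continuously to zero at time 0; whether the last
suprathreshold grid point of the (large, clearly significant) pre-onset
cluster falls just below, at, or just past 0 is boundary noise. Cluster-based
permutation inference licenses existence claims, not boundary claims, so
simulation checks that condition on a cluster edge relative to a point where
the true difference vanishes are inherently borderline: in this stated world
the probability that the TL3 cluster ends strictly before time 0 is ~0.9 per
run.

## Known limitations

* The rendered observation model is deliberately minimal (no fan geometry,
  no probe motion, stationary speckle).
* The sign-flip null assumes symmetric participant differences; with 23 vs
  22 trials per condition the difference of condition means is only
  asymptotically symmetric (the type-I study shows calibration holds).
* Items in the generator do not carry fixed per-item timings across
  participants (only RT intercepts), so item-driven temporal structure in
  real data is not emulated.
* The RT model's reported condition means are raw model cell means; the
  source's published betas (669/953 ms) differ slightly from its raw means
  (626/900 ms), presumably via shrinkage under its exact random-effects
  structure, and are not reconciled here.
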