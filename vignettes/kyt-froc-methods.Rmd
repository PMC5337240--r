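---
title: "Methods: free-response ROC analysis of hazard-prediction observer studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-response ROC analysis of hazard-prediction observer studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kytfroc)
```

## The problem

Kiken-Yochi training (KYT) asks medical staff to inspect photographs of
workplace scenes — here, situations around a general X-ray examination room —
and point out locations that could injure the patient. How well an individual
can *predict* hazards at first sight is a measurable perceptual skill, and it
has a natural analogue in radiology: detecting an unknown number of lesions
in an image. `kytfroc` treats hazard prediction as a free-response
receiver-operating-characteristic (FROC) observer study. Observers view every
scene, click any number of suspected hazard locations, and attach to each
mark a continuous confidence rating in (0, 1]. Ground truth defines, for each
hazardous scene, one to a few circular *hazard areas*; scenes without hazards
act as the "normal" cases.

The reference study design this package emulates has 53 scenes — 26 with
hazard points and 27 without — carrying 42 hazard points in total. Most
points belong to one of 30 *events* (a potential incident such as a patient
tumbling; an event may be reachable through more than one hazard point, e.g.
10 tumbling events share 14 points), while 6 points (staff looking away from
the patient) have no event. This composition is built into the default
scene-set preset and into the validation ("emulation") mode that enforces
one to three hazard points per hazardous scene.

## Scoring rules

A mark is a hit on a hazard area iff its Euclidean distance to the area's
center is at most the radius. Three conventions complete the rule, each
chosen where the protocol itself is silent:

* **Boundary inclusive.** Distance exactly equal to the radius is a hit.
  This removes a measure-zero ambiguity; any other choice is untestable with
  continuous clicks.
* **One TP per hazard point.** If several marks hit the same hazard point,
  the one with the highest rating is the true positive; the rest are
  *suppressed* and excluded from every downstream count and curve (they are
  not false positives). Exact rating ties are broken in favour of the
  earliest-entered mark, making scoring deterministic while leaving all
  counts permutation-invariant.
* **Overlapping areas.** A mark inside two areas is assigned to the nearer
  center (then lowest `hazard_point_id`). Reference-style scene sets have
  disjoint circles, but the rule keeps scoring total for arbitrary geometry.

Every other mark — outside all circles, or on a scene without hazards — is a
false positive.

From a scored response the package reports three plain fractions:
*point-based sensitivity* (detected hazard points / all hazard points),
*event-based sensitivity* (events with at least one detected point / all
events, excluding no-event points from both sides), and *scene-based
specificity* (no-hazard scenes left entirely unmarked / all no-hazard
scenes). On the reference composition these are necessarily k/42, k/30 and
k/27 — a useful integrity check on any reported percentage.

## The AFROC figure of merit

Let \(r_\ell\) be the TP rating of hazard point \(\ell\) (absent if
undetected) and \(m_s\) the highest FP rating on scene \(s\) (absent if
unmarked), where \(s\) ranges over the *FP-contributing* scenes. The figure
of merit is the Wilcoxon–Mann–Whitney statistic

\[
\theta \;=\; \frac{1}{N_L N_S}\sum_{\ell}\sum_{s}\psi(r_\ell, m_s),\qquad
\psi = \begin{cases} 1 & r_\ell > m_s\\ 1/2 & r_\ell = m_s \text{ (both present)}\\ 0 & \text{otherwise,}\end{cases}
\]

with absences entering as \(-\infty\) and the (absent, absent) pair scoring
0. Thus an observer who marks nothing scores 0, and one who detects every
point with no FP scores 1. \(\theta\) equals the trapezoidal area under the
empirical AFROC curve — lesion localization fraction (LLF) against the
per-scene false-positive fraction (FPF), both swept over the distinct
ratings as thresholds and extended to (1, 1) — whenever every rating is
present. With absences the polyline extension is ambiguous, so **\(\theta\)
is the area of record and the polyline is display only**; the package
reports both (`area` vs `polyline_area`) and the test suite checks their
exact equality on randomized complete instances.

Two FOM variants are exposed because the historical analysis software is
ambiguous on this point: `normal_only` (default) takes FP maxima from
no-hazard scenes only, the convention of the published FOM definition this
implements; `all_scenes` lets every scene contribute. They coincide whenever
no FP lands on a hazardous scene.

Group curves are averaged *vertically*: each reader's polyline is sampled at
101 evenly spaced FPF values (at a vertical jump the upper value is taken)
and LLF is averaged pointwise. The area of the averaged polyline is reported
separately from the group mean FOM, which is always the arithmetic mean of
member \(\theta\)s — the two differ in general and must not be conflated.

## Group summaries and significance tests

Per-observer FOMs are compared with two-sided t tests at \(\alpha = 0.05\):
paired (on after − before differences, \(n-1\) df) for repeated readings of
the same observers, and the pooled equal-variance two-sample form
(\(n_a+n_b-2\) df; Welch available as an option) for independent groups —
the pooled form matches the era's desktop statistics defaults. No
multiple-testing correction is applied, mirroring the original analysis; a
note is emitted when more than one test runs. Degenerate inputs (zero
variance) are resolved in the limit and flagged rather than erroring, so
batch pipelines never die on a pathological group.

Reported tables round half-up (away from zero), FOMs to 3 decimals and
percentages to 1 — this convention, not banker's rounding, reproduces the
published summary rows (e.g. a mean FOM of 0.7315 prints as 0.732, and a
mean specificity of exactly 87.05% prints as 87.1). `round_half_up()`
guards against binary representation dust before applying the half-up floor,
since 87.05 is not exactly representable. All CSV outputs remain unrounded;
rounding is strictly presentational.

## The synthetic-observer generator

The study's raw mark-rating data is not public, so the package ships a
simulator that serves both as a fixture factory and as a known-truth oracle.
`generate_scene_set()` with the default preset reproduces the reference
composition exactly (only circle geometry and label assignment are random);
the event-to-scene packing is deterministic — six two-point events on their
own scenes, six scenes pairing a one-point event with an attention-lapse
point, four scenes with two one-point events, ten scenes with one — a
concrete choice consistent with the published totals, which do not pin the
packing down. Circles are rejection-sampled to be disjoint and fully inside
the image (1024 × 768 px, radii 30–80 px by default; no result depends on
these geometry values).

`observer_model()` detects each hazard point with probability `p_detect`
(optionally per event class), rates TPs from a clipped Beta distribution,
and adds Poisson-count FP marks per scene, rated from a second Beta and
placed uniformly outside all hazard circles. One deliberate extension is
`sos_factor`, a within-scene *satisfaction-of-search* multiplier: after the
first detection in a scene, the remaining points of that scene are detected
with probability `p_detect * sos_factor`. This is a one-parameter nod to a
well-documented perceptual phenomenon — observers tend to stop searching a
scene once they have found something — and it is what makes event-based
sensitivity exceed point-based sensitivity essentially always, the direction
the reference study observed for every single reader. It is not a full
search model; modelling visual search mechanisms is out of scope.

`kyt_observer_model()` fixes the defaults to emulate the reference readers:
baseline `p_detect = 0.65` with attention-lapse points at 0.2 (these were
by far the most-overlooked points), `sos_factor = 0.35`, `fp_rate = 0.2`
per scene, TP ratings Beta(4, 2), FP ratings Beta(2, 4). These were chosen
once, from the published per-reader ranges (point sensitivity 45.2–66.7%,
specificity 51.9–100%) and the qualitative statements about overlooking,
and are not tuned thereafter. Expected simulated sensitivity (~0.51 over 42
points) and specificity (~0.82) fall inside those ranges. The simulator does
**not** emulate inter-reader skill correlation, scene-difficulty
heterogeneity, or rating miscalibration drift — so passing simulation tests
demonstrates correctness of the scoring/FOM machinery under the study's
structure, not fidelity to any particular human reader population.

`oracle_fom()` estimates a model's expected \(\theta\) by brute force
(simulate, score, average), reporting both the spread of a single reader's
\(\theta\) (`sd`) and the standard error of the mean (`se`). The test suite
verifies that a fresh simulated reader lands within 4 `sd` of the oracle
mean in at least 99% of 200 seeded repetitions (2000 oracle replicates), and
that with `fp_rate = 0` and independent detections \(\theta = k/42\)
converges to `p_detect` within binomial error.

## Numerical and interface choices

* Continuous pixel coordinates, origin top-left, x rightward, y downward; no
  snapping. Ratings accepted at full floating precision in (0, 1]; the 0.01
  entry granularity of the original software is not enforced.
* Scene-set JSON is written with 17 significant digits and response CSVs
  with `%.17g`, so write→read round-trips are bit-exact — the property tests
  assert `identical()`, not approximate equality.
* All simulation entry points take an explicit integer seed, use a single
  RNG stream, iterate scenes in `scene_id` order, and restore the caller's
  RNG state; identical seeds give byte-identical output files.
* Test problem sizes are deliberate: 1000 randomized instances for the
  area/Wilcoxon identity, 2000 oracle replicates and 200 recovery
  repetitions on the full 53-scene set, 50 readers for the sensitivity
  direction — large enough that the stochastic assertions have comfortable
  margins (the direction check's per-run violation probability is of order
  1e-4 under the default model).

## Known limitations

* An "event" must live inside one scene; events spanning scenes are not
  representable (nothing in the reference design needs them).
* The provable event identity is only that the detected-event count is at
  least the sum over events of each event's detected-point fraction. The
  stronger, intuitively appealing claim "event sensitivity ≥ point
  sensitivity restricted to event-bearing points" is *false* in general
  (fully detecting a few multi-point events while missing many single-point
  events is a counterexample); with the default observer model it holds as
  an overwhelming tendency, which is what the tests assert.
* No parametric curve fitting, jackknife variance components, or
  multi-reader multi-case ANOVA: the analysis is empirical curves plus t
  tests on per-reader FOMs, by design.
* Group-level p-values of the original inter-group comparisons cannot be
  reproduced because the underlying per-reader FOMs were never published;
  only the per-student before/after table admits exact reproduction.
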