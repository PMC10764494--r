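---
title: "Detecting myoclonic jerks from home-cage video tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myoclonic jerks from home-cage video tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myodetect)
```

## The problem

Mouse models of progressive myoclonus epilepsy (for example the *Cstb*-null
mouse modelling Unverricht–Lundborg disease) show brief involuntary jerks —
a nod to the side, a jerk forward, occasionally a jump — that occur
predominantly while the animal sleeps. Counting these events by watching
hours of video is slow and subjective. A practical alternative is to record
a single mouse from above in a small home cage (a 30 × 30 cm arena), extract
the three standard body landmarks (center-point, nose-point, tail-base) with
a video tracker, and scan the resulting kinematic time series for the jerk
signature: a *short* (about one second) velocity burst of roughly 20–60 cm/s
that erupts out of a *long immobile period* and coincides with
characteristic posture/kinematics conditions. A human then audits the short
list instead of the whole recording.

`myodetect` implements that screening pipeline as open, tested code:

* the per-sample classifiers of the tracker's analysis profile
  (velocity, hysteretic movement state, three-level mobility state, and the
  two "multi conditions"),
* the event scanner, automated voluntary-movement rejection, consecutive-event
  pairing, and the session-level count,
* a seeded behavioral simulator that produces tracking tables *with ground
  truth*, so the whole detector is measurable without any recorded animal,
* a minimal overhead blob tracker plus a frame renderer, closing the loop
  from synthetic video back to tracking tables,
* evaluation (event matching) and cohort statistics (two-way ANOVA with
  Šídák-adjusted group comparisons).

## The detection model

All state logic runs on per-sample signals derived from the tracked points
at the configured rate (default 25 Hz, so 100 samples = 4 s).

**Velocity and acceleration.** Speed is the Euclidean center-point
displacement between consecutive samples times the rate (cm/s), unsmoothed
by default ("averaging interval 1 sample"). Acceleration is the absolute
speed change times the rate (cm/s²) — a magnitude, because the condition
that consumes it is a magnitude bound.

**Movement (hysteresis).** Two thresholds define a moving/not-moving
automaton: the state turns on above the start threshold (3.20 cm/s for the
center-point), off below the stop threshold (2.25 cm/s), and otherwise holds.
The initial state is Not-moving; missing samples hold the previous state.
The start/stop reading of the two published numbers follows the tracking
software's documented semantics.

**Mobility.** Commercial trackers measure mobility as the fraction of body
pixels that changed between frames — a quantity that distinguishes in-place
movement from locomotion. Without pixels, `mobility_raw()` uses a documented
surrogate: a weighted sum of the three points' displacements (normalized by
a 7 cm body-length scale, weights 0.3/0.3/0.3) plus posture change
(|Δelongation|/100, weight 0.1), clipped at 1 and scaled to percent. The
trace is averaged over 15 samples and thresholded: HighlyMobile above 60%,
Immobile below 5%, Mobile between. Averaging precedes thresholding; the
alternative order is not documented, and averaging first gives the smoother,
more conservative labels. When rendered video is tracked, `track_video()`
also returns the pixel-faithful mobility (changed body pixels over the union
of consecutive masks); either source plugs into the detector. In practice
the pixel-change trace flickers near the 5% immobility bound for a sleeping
animal at coarse resolution, so the point-based surrogate is the default.

**Multi Condition 1** is a per-sample conjunction on the center-point:
movement state true **and** 100-sample mean velocity ≤ 0.45 cm/s **and**
body elongation ≤ 75% **and** body angle ≤ 20°. The first two clauses look
contradictory — moving, yet almost zero average velocity — and that is the
point: the conjunction fires only for an instantaneous spike inside a long
quiescent window, which is exactly the jerk signature. We deliberately do
not "fix" it.

**Multi Condition 2**: center-point acceleration ≤ 180 cm/s² **and**
movement state true simultaneously for center, nose and tail-base at the
lower 2.00/1.75 cm/s thresholds — the whole body moves, but not explosively
at that instant.

**Event scan.** Within the analysis window, maximal runs of center velocity
above 20 cm/s are found; runs closer than 1 s merge (one jerk fragmented by
smoothing must not count twice). A merged run is a candidate iff (a) it
lasts at most `burst_max_dur_s`; (b) its peak stays within the 20–60 cm/s
band; (c) the mobility state was Immobile for at least `pre_immobile_min_s`,
ending within 1 s of onset — the "break in the immobile state"; (d) MC1
and/or MC2 is true at some sample within 0.2 s of the run. The published
description gives "short (1 s)" and "long immobile state" qualitatively;
`burst_max_dur_s = 1.5` s (margin for smoothing spread) and
`pre_immobile_min_s = 10` s operationalize them and are configuration
parameters, not constants.

**Voluntary-movement rejection.** The original workflow confirmed events by
eye and rejected animals clearly walking. The automated stand-in rejects a
candidate that (i) was preceded by a mostly-Mobile 5 s ("walking-in"),
(ii) translated more than 10 cm during the burst without any sample
exceeding 1.5× the pre-burst velocity maximum ("sustained locomotion, no
spike"), or (iii) overlaps an unresolvable tracking gap. Movement *after*
the event never rejects — animals often move briefly while recovering.
Every rejection carries its reason so a human can audit the decision, and
all rule parameters are exposed in `detection_config()`.

**Pairing and counting.** Accepted events whose onsets are 1–20 s apart are
flagged as consecutive pairs (greedy left-to-right, each event in at most
one pair) but still count as two events. The session statistic is the
number of accepted events with onset inside the analysis window — the last
three hours of a four-hour recording, because animals explore during the
first hour and the jerks are a sleep phenomenon.

## The simulator as ground truth

`simulate_session()` draws a bout schedule from a semi-Markov chain
(exponential holding times; no self-transitions) biased toward exploration
for the first hour and toward sleep afterwards — the structure behind the
"first hour discarded" rule. Within bouts:

* **explore** — a correlated random walk at 5–15 cm/s with smooth steering
  away from walls (an instantaneous bounce would rotate the body within one
  sample, which no animal does), stretched posture (elongation ~85–97%),
  small bend, rhythmic head sway;
* **sleep** — stationary, curled (elongation ~55–68%), slow breathing
  oscillation, body angle under ~15°;
* **groom** — in-place rocking and head bobbing with moderate bend.

Jerks are injected at Poisson times within *established* sleep (at least
15 s after sleep onset, so the immobility precondition reflects biology
rather than placement luck). Each jerk is an out-and-back displacement
pulse `E sin²(πt/d)` along a direction biased toward the arena center, with
`E` chosen so the peak speed hits a target drawn from 25–55 cm/s and `d`
drawn from 0.2–0.8 s; the pulse returns near the starting point, matching
the "nod/jerk" phenomenology, and is followed by a few seconds of slow
(3–5 cm/s) recovery drift — the paper-described brief movement while the
animal recovers. With probability 0.15 a jerk spawns a partner 1–20 s later
(the consecutive-event phenomenon). Tracking imperfection is modelled as
AR(1) jitter (φ = 0.9, stationary SD 0.05 cm) on every coordinate — real
tracker noise is strongly frame-to-frame correlated; white noise of the
same amplitude would put a spurious ~2 cm/s floor under the velocity of a
sleeping animal — plus random dropouts (p = 0.001 per sample).

The stored body angle is computed from the stored points (including sway),
so the posture descriptors and the point geometry can never disagree.

What the simulator does **not** emulate: bedding occlusion, grooming that
mimics jerk kinematics, multi-animal cages, circadian structure beyond
explore-then-sleep, and real infra-red image statistics. Passing the
recovery benchmark therefore shows the detector implements its definition
faithfully under realistic noise — not that the definition captures every
real-world confound; the confirm-by-eye audit trail exists for exactly that
reason.

## Rendering and tracking

`render_frames()` draws each sample as a bright blob on a dark arena: disks
along a quadratic spine from tail-base to nose whose control point is chosen
so the blob centroid lands exactly on the center-point, resampled to equal
arc length so mass is uniform along the body. The body width is solved per
frame from a capsule mass model so that the blob's second-moment axis ratio
encodes the stored elongation (`100·(1 − minor/major)`) even for bent
spines; a brighter terminal nose disk orients the head with negligible
centroid bias. Extreme elongations (> ~95%) saturate against the minimum
drawable width at 5 px/cm and read a few points low.

`track_video()` segments each frame against a background (Otsu threshold on
the absolute difference; largest connected component), takes the mask
centroid, principal axis, and spine-binned tips, pulls the tail tip 15%
inward to a tail-base, orients head/tail by tip brightness on the first
frame and by nearest-neighbor continuity afterwards, and converts to cm.
`estimate_background()` (per-pixel median over ≤ 200 frames) is correct
when the animal keeps moving; a *sleeping* mouse burns itself into the
median, so for sleep-dominated sessions supply the empty-arena frame
(`render_background()`), mirroring the background-capture step of a real
tracking experiment.

## Statistics

`two_way_anova_sidak()` analyses per-session counts with a conventional
two-factor linear model and Type II sums of squares (the cohorts such
experiments produce are mildly unbalanced), then performs the planned
genotype comparison within each age with the pooled residual variance and
Šídák adjustment `p_adj = 1 − (1 − p)^m`, `m` = number of ages (recorded in
the output). A repeated-measures variant (`Error(subject)`) is available
for designs where animals repeat across ages; the between-subjects variant
is the default. Counts are analysed untransformed to mirror standard
practice in this literature.

## Numerical choices and degenerate inputs

* Sliding averages are centered boxcars, truncated at the edges; for even
  windows the extra sample comes from the future side. Missing samples are
  excluded from each window's mean; an all-missing window is missing.
  Centered (rather than trailing) alignment minimizes event-onset bias.
* First-sample derivatives are 0, not missing, so the state machines have
  defined input from t = 0.
* Tracking gaps up to 1 s are linearly interpolated before state logic;
  longer gaps stay missing, state machines hold across them, and candidates
  overlapping them are rejected as unscorable rather than guessed at.
* The burst band is applied strictly (a peak of exactly 60 cm/s passes,
  80 fails); the published "~20–60" tilde is honored by making both bounds
  configuration parameters.
* Comparisons in the multi conditions are inclusive (≤), matching the
  published wording.
* A 0-sample series, an empty event list, and a single-genotype cohort are
  all legal degenerate inputs: they produce an empty table, a zero count,
  and a summary with the ANOVA skipped (with a notice), respectively.

## Problem sizes used by the test suite

The bundled acceptance suite runs, on one CPU: the detector-versus-oracle
comparison on 100 randomized series of up to 5,000 samples; the cohort
benchmark of 24 four-hour sessions at 25 Hz (12 at 4 jerks/h versus 12 at
0.2 jerks/h), requiring precision and recall ≥ 0.90 at ±2 s onset
tolerance; a 10-minute video-mode chain at 5 px/cm requiring recall ≥ 0.85,
centroid RMSE ≤ 0.2 cm and body-angle MAE ≤ 5°; 1,000-signal property
checks of the state machines; and a 1,000-replicate null calibration of the
genotype F-test (empirical type-I error within [0.03, 0.07] at α = 0.05).
These sizes keep the full suite within a few minutes while leaving each
estimate's Monte-Carlo error well below the margin it is tested against.

## Known limitations

* The commercial tracker's outlier filter, mobility definition, and
  elongation/body-angle formulas are unpublished; ours are documented
  stand-ins with the same monotone behavior, and the corresponding MC1
  thresholds (75%, 20°) may need recalibration against other definitions —
  they are exposed in the configuration for that purpose.
* Wake-state myoclonus during locomotion is outside the method's reach by
  construction: events during walking are rejected on purpose.
* Consecutive jerks closer than ~12 s to their predecessor fail the
  10 s immobility precondition and are not detectable at the default
  configuration; at the simulator's default pairing parameters this caps
  recall near 0.93, which is the main gap between the benchmark recall and
  1.
* The renderer and tracker target the synthetic imaging model; no claim is
  made about robustness to real infra-red footage, bedding occlusion, or
  multi-animal scenes.
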