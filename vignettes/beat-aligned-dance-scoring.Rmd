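---
title: "Beat-aligned dance scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-aligned dance scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danceval)
```

## The problem

Scoring a dance performance against a reference recording by comparing every
video frame is wasteful and noisy: dance movements are choreographed to the
musical beat, so the informative frames are the ones that fall on beats.
`danceval` implements that idea as a pipeline:

1. **Beat tracking.** An onset strength envelope is computed from the audio;
   a global tempo period $\tau_p$ is estimated from its prior-weighted
   autocorrelation; a dynamic programme selects beat instants that are both
   strong in onset energy and regularly spaced.
2. **Keyframe mapping.** Beat times become 0-based video frame indices at
   the video frame rate; beat-free stretches (silence) are reported as gaps
   and simply skipped.
3. **Pose quantification.** Each keyframe's 2-D pose keypoints (from an
   external estimator, read in its JSON layout) are reduced to an
   $n \times m$ matrix of joint angles $\theta_{ij}$ — elbows, shoulders,
   knees, hips, optionally trunk inclination.
4. **Scoring.** Two complementary statistics compare an evaluated sequence
   $Q$ with a standard one $\Theta$: **ASCS**, the mean over features of the
   cosine similarity between the two angle sequences (static accuracy), and
   **SMACR**, a ROUGE-L-style longest-common-subsequence ratio over
   threshold-filtered similarity sequences (movement continuity).

## The beat tracker

The onset strength envelope follows the classic spectral-flux recipe: audio
is resampled to 8 kHz; a short-time spectrogram (32 ms Hann window, 4 ms
hop, frames fully inside the signal — no padding, which avoids spurious
edge onsets) is pooled into 40 triangular Mel bands spanning 0–4 kHz and
converted to dB relative to the strongest band–frame with an $-80$ dB
floor. Per-band first-order time differences are half-wave rectified and
summed; the sum is high-passed at 0.4 Hz (first-order Butterworth, run
forward–backward for zero phase) so its local mean is $\approx 0$, smoothed
with a Gaussian kernel ($\sigma = 20$ ms, truncated at $4\sigma$, unit
sum), and divided by its standard deviation. The dB differencing makes the
envelope exactly invariant to a uniform gain change, and the final
normalization makes the tracker's weight $\omega$ scale-free.

Frames are time-stamped at the **centre** of the analysis window. With
trailing-edge stamps the envelope peak of an isolated click sits a full
window late relative to the physical onset (the dB ramp spreads over one
window); centre stamps put it within about one hop (4 ms). One boundary
case is inherent: an onset at $t = 0$ coincides with the first frame, where
the time difference is defined to be zero, so a click exactly at the start
of the signal is localized only loosely.

Given the envelope $O(t)$, the tempo period strength is
$\mathrm{TPS}(\tau) = W(\tau) \sum_t O(t)\,O(t-\tau)$ over lags 0.2–2.0 s
(30–300 BPM), where
$W(\tau) = \exp\left(-\tfrac12 \left(\log_2(\tau/\tau_0)/\sigma_\tau\right)^2\right)$
is the perceptual preference centred at $\tau_0 = 0.5$ s (120 BPM) with
width $\sigma_\tau = 1$ octave. Exact ties break toward the lag closest to
$\tau_0$.

Beats maximize
$C(\{t_i\}) = \sum_i O(t_i) + \omega \sum_i F(t_i - t_{i-1}, \tau_p)$ with
the spacing penalty $F(\Delta t, \tau_p) = -\left(\ln(\Delta t/\tau_p)\right)^2$
(natural log; any base is absorbed into $\omega$, default 100). The
recursion $C^*(t) = O(t) + \max_{\tau} \{\omega F(t-\tau, \tau_p) +
C^*(\tau)\}$ searches $\tau \in [t - 2\tau_p,\, t - \tau_p/2]$; frames too
early to have an admissible predecessor start chains with $C^*(t) = O(t)$,
the final beat is the arg-max of $C^*$ over the last $\tau_p$, and the
sequence is recovered by backtracking (earliest predecessor on ties, for
determinism). Consecutive intervals are therefore confined to
$[\tau_p/2,\ 2\tau_p]$ by construction. The suite verifies the programme
against exhaustive enumeration of every admissible chain on short
envelopes.

### Octave ambiguity and the tempo prior

On a *perfectly periodic* click track every integer multiple of the true
period is an equally good autocorrelation peak up to the end effect: at lag
$k p$ roughly $(T - kp)/T$ of the signal overlaps, so the fundamental beats
its double only by about 1% on a 30 s track. The prior ratio
$W(2p)/W(p)$ can exceed that easily: at 180 BPM
($p = 1/3$ s) and $\sigma_\tau = 1$ the prior favours the 90 BPM
subharmonic by $\exp(0.085/\sigma_\tau^2) \approx 9\%$, so the estimate
folds to 90 BPM — exactly the behaviour that makes a 240 BPM track fold
usefully to 120 BPM. The crossover sits near $\sigma_\tau \approx 2.75$
octaves. Consequently the package's tempo-recovery validation runs with an
effectively flat prior ($\sigma_\tau = 10$), isolating the
autocorrelation's own behaviour, and tests the informative default
($\sigma_\tau = 1$) for what it is designed to do: fold fast tempi toward
the 120 BPM preference. Real music is not perfectly self-similar one period
apart, which is why an informative prior works better in practice than on
these fixtures.

### Silent gaps

The dynamic programme cannot stop: its spacing window forces a beat at
least every $2\tau_p$, so a silent stretch is bridged by regularly spaced
beats with near-zero onset support. Those bridge beats are honest output of
the objective, but they carry no musical evidence, so the pipeline exposes
`prune_weak_beats()` (drop beats with strength below 10% of the median beat
strength) before gap reporting. On clean material nothing is pruned; across
a silence the pruned sequence shows one long interval, which
`find_beat_gaps()` reports (default threshold: twice the median interval).
Following the simpler of the two possible strategies, no keyframes are
synthesized inside gaps — the interval is simply ignored; the alternative
(filling with $\tau_p$-spaced beats) is available as `fill_beat_gaps()` but
is used nowhere by default.

## Pose features

Angles are the interior angle at the middle joint of a triple, in
$[0^\circ, 180^\circ]$, computed from the arc-cosine of the normalized dot
product. They are invariant to translation, rotation, and uniform scaling
of the keypoints, hence to image resolution and to the y-down image
convention. A keypoint with zero confidence is missing, and a feature is
absent exactly when one of its joints is missing; absence is data, not an
error, and propagates to scoring by pairwise deletion (with at least two
retained positions, otherwise an insufficient-data error). When several
people are detected in a frame, the one with the highest mean keypoint
confidence is kept. The default eight-feature set (left/right elbow,
shoulder, knee, hip) covers the limbs that matter for dance scoring with
standard goniometric definitions; it is a package default, fully
user-overridable, not a claim about any particular upstream feature
catalogue.

## Scoring

For feature $j$, ASCS uses
$s_j = \frac{\sum_i Q_{ij}\Theta_{ij}}{\sqrt{\sum_i Q_{ij}^2}\sqrt{\sum_i \Theta_{ij}^2}} \in [0, 1]$
(angles are nonnegative), and the overall score is the mean over features,
reported as a percentage. Per-keyframe similarities (cosine between the two
$m$-vectors of a frame) are computed alongside. Worth knowing: cosine
similarity of two long positive angle sequences is a *lenient* statistic —
even $20^\circ$ of noise leaves it near 0.98 — which is precisely why the
continuity score applies a hard threshold instead of averaging.

SMACR converts similarities to 0/1 tokens with an inclusive threshold
(`filter`, default 0.85 — a score exactly at the threshold passes) and
compares the token sequence against the standard's own, which is all ones
by construction. With equal lengths $n$,
$R_{LCS} = P_{LCS} = \mathrm{LCS}/n$ and the $F_\beta$ combination
collapses to $R_{LCS}$ independently of $\beta$ (asserted in the tests).
Against an all-ones reference the LCS degenerates to the count of passing
tokens — token order cannot matter — but the general LCS machinery is
implemented (and oracle-tested) because the construction extends directly
to richer token alphabets; a three-level quantization at `filter` and
`(1 + filter)/2` is a natural extension.

Two token constructions are provided, because the per-feature sequence
indexing and the per-keyframe narrative suggest different axes:

* **per_feature** (default): for each feature, a length-$n$ token sequence
  from per-position similarities. A scalar angle pair has no meaningful
  cosine (a 1-vector's cosine is identically 1), so the per-position
  similarity is defined as $\max(0, \cos(\Delta\theta))$ — the cosine of
  the angle between the two unit limb directions. At `filter = 0.85` a
  position fails when the angles disagree by more than
  $\arccos(0.85) \approx 31.8^\circ$. The final score is the mean of the
  per-feature $F_{LCS}$.
* **per_frame**: one length-$n$ sequence from the per-keyframe cosine
  similarities. Because whole-frame cosines are so lenient, this mode only
  discriminates grossly wrong frames.

## The synthetic generators

The generators define the package's test conditions; they are first-class,
tested code.

* **Click tracks**: 30 ms, 1 kHz sine bursts with 5 ms linear fades at
  sample-exact multiples of $60/\mathrm{BPM}$ — broadband enough at onset
  for the Mel-difference envelope, fully deterministic. Optional white
  noise at a stated SNR (power relative to the click signal) and silent
  gaps that zero the waveform and remove the affected ground-truth beats.
  What they do *not* emulate: sustained harmonic content, tempo drift,
  expressive timing, or percussion-free passages, so a pass here shows the
  machinery is correct, not that real music is easy.
* **Pose pairs**: per feature, the standard trajectory is a sum of 2–4
  low-frequency sinusoids around a centre in $[70^\circ, 120^\circ]$,
  clipped to $[20^\circ, 175^\circ]$ — smooth and bounded like real limb
  angles, without the kinematic coupling of a true skeleton. The evaluated
  copy adds i.i.d. Gaussian angular noise, optional linear drift, and
  dropout to absent. Both generators are pure functions of their
  parameters, seed included.

Default validation sizes (chosen to exercise the asymptotics while staying
desk-scale): 30 s tracks at 60–240 BPM, five seeds for noisy runs; 100
seeded pose pairs of 40 keyframes by 8 features per noise level; 50 short
envelopes for the DP-optimality check; exhaustive LCS oracles to length 5
and sampled enumeration to length 12, plus a free-gap global-alignment
cross-check on longer pairs.

## Numerical choices and degenerate inputs

* dB floor at $-80$ relative to the global maximum; digital silence is all
  floor by convention.
* A constant envelope (no energy change anywhere) is a degenerate-envelope
  error rather than a zero-division.
* Frame indices round half away from zero; duplicate indices collapse to
  the first beat; indices past the last frame drop with a warning.
* Angle computations clamp the cosine to $[-1, 1]$ before `acos`; near
  collinear joints the angle is accurate to about $10^{-6}$ degrees (the
  conditioning of `acos` near $\pm 1$), which bounds the tolerance used in
  the similarity-invariance tests.
* DP ties (both the predecessor arg-max and the final-beat arg-max) break
  toward the earliest frame; tempo ties toward the lag nearest $\tau_0$.

## Known limitations

* A single global tempo: no tempo drift, no downbeats, no metre.
* The beat tracker's output on heavily syncopated or rubato material
  depends on the prior in ways the click-track fixtures do not probe.
* SMACR against an all-ones standard reduces to a pass rate; its LCS
  formulation pays off only with richer token alphabets.
* Pose input is 2-D: out-of-plane rotation changes apparent angles; no
  temporal smoothing of keypoints is attempted.
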