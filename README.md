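# danceval

Beat-aligned evaluation of dance motion from audio and 2-D pose sequences.

Dance movements are choreographed to the musical beat, so the frames worth
scoring are the ones that fall on beats. `danceval` is for researchers and
tool builders in human-movement analysis who want an automated,
reproducible score of a dance performance against a reference: it detects
beats in the accompanying audio, maps them to video keyframes, quantifies
each keyframe's posture as joint angles, and reports two complementary
statistics — static accuracy and movement continuity.

## What it computes

**Beat tracking.** An onset strength envelope O(t) is computed from the
audio (8 kHz analysis rate, 32 ms/4 ms Mel spectrogram over 40 bands, dB
differencing, half-wave rectification, 0.4 Hz high-pass, 20 ms Gaussian
smoothing, unit-variance normalization). The global tempo period τₚ
maximizes the prior-weighted autocorrelation

    TPS(τ) = W(τ) · Σₜ O(t) O(t−τ),   W(τ) = exp(−½ (log₂(τ/τ₀)/σ_τ)²)

with the perceptual preference centred at τ₀ = 0.5 s (120 BPM). Beats then
maximize Σᵢ O(tᵢ) + ω Σᵢ F(Δtᵢ, τₚ) with the spacing penalty
F(Δt, τₚ) = −(ln(Δt/τₚ))², solved exactly by dynamic programming with the
predecessor search confined to [t − 2τₚ, t − τₚ/2].

**Keyframes.** Beat times become 0-based frame indices (index = round(t·fps));
beat-free stretches are reported as gaps and skipped.

**Scoring.** From the n×m matrices of joint angles θᵢⱼ of the evaluated (Q)
and standard (Θ) performances:

* **ASCS** — mean over features j of the cosine similarity between Qⱼ and
  Θⱼ, in percent: static accuracy.
* **SMACR** — per-position similarities are thresholded (filter = 0.85,
  inclusive) into 0/1 sequences and compared with the standard's all-ones
  sequence through the longest common subsequence: R_LCS = P_LCS = LCS/n,
  combined with the F_β formula (which equals R_LCS at equal lengths):
  movement continuity.

## Worked example

```r
library(danceval)

# a 20 s click track at 120 BPM with known beat times
ct <- generate_click_track(bpm = 120, duration_s = 20, seed = 1)
res <- detect_beats(ct$audio)
res$tempo
#> <tempo_estimate: tau_p = 0.5000 s (120.0 BPM), 451 lags searched>
beat_f_measure(res$beats, ct$beat_times)
#> # A tibble: 1 × 7
#>   f_measure precision recall   mae_s n_matched n_detected n_reference
#> 1         1         1      1 0.00430        40         40          40

# map beats to 24 fps video frames
kf <- beats_to_keyframes(prune_weak_beats(res$beats), fps = 24, n_frames = 480)
head(kf, 3)
#>   beat_time_s frame_index
#> 1       0.016           0
#> 2       0.496          12
#> 3       0.996          24

# score a perturbed performance against its standard
pair <- generate_pose_pair(n_frames = 40, angle_noise_sd = 15,
                           dropout_prob = 0.02, seed = 1)
report <- evaluate_performance(pair$evaluated, pair$standard, filter = 0.85)
report
#> Dance performance evaluation (40 keyframes, 8 features)
#>   ASCS  (static accuracy):      98.8%
#>   SMACR (movement continuity):  96.5%
#>   filter = 0.85, beta = 1, mode = per_feature
head(tidy(report), 4)
#>   feature    cosine_similarity n_used pass_rate similarity_mean r_lcs f_lcs
#> 1 elbow_l                0.987     40     0.95            0.969 0.95  0.95
#> 2 elbow_r                0.993     39     1               0.977 1     1
#> 3 shoulder_l             0.978     40     1               0.966 1     1
#> 4 shoulder_r             0.990     39     0.923           0.959 0.923 0.923
```

The tempo estimate recovers the true 0.5 s period; every detected beat sits
within ~4 ms of a true click (F-measure 1.0 at the ±70 ms matching window).
With 15° of angular noise the per-feature cosine similarities stay high
(ASCS 98.8% — cosine similarity of angle sequences is lenient by design)
while the thresholded continuity score reacts to the positions that drift
beyond arccos(0.85) ≈ 31.8° (SMACR 96.5%).

Real pose data enters through `read_keypoint_files()` (per-frame JSON in
the usual `people[].pose_keypoints_2d` layout) or `read_keypoint_table()`
(a `frame_index, joint, x, y, confidence` CSV), then
`pose_description(keypoints, keyframes, default_feature_def())`.

A command-line wrapper lives at `inst/cli/danceval.R`
(`Rscript danceval.R demo --seed 7 --out out/` runs the whole pipeline on
generated fixtures; `beats`, `keyframes`, `features`, `score`, `simulate`
cover the individual stages).

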