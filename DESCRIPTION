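Package: danceval
Title: Beat-Aligned Evaluation of Dance Motion from Audio and Pose Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring a dance performance against a reference by
    aligning evaluation to the musical beat. Detects beats with a
    dynamic-programming tracker over a Mel-band onset strength envelope,
    estimates the global tempo period from a prior-weighted autocorrelation
    centred near 120 beats per minute, maps beats to video keyframe indices,
    quantifies per-keyframe posture as joint-angle feature vectors from 2-D
    pose keypoints, and reports two complementary statistics: ASCS (average
    cosine similarity of action feature sequences, static accuracy) and SMACR
    (a longest-common-subsequence continuity score over threshold-filtered
    similarity sequences). Includes generators for ground-truthed click-track
    audio and paired standard/perturbed pose sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
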