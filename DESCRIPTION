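Package: dyadcues
Title: Non-Verbal Speech Cues from Dyadic Clinical Interviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts objective non-verbal speech markers from two-channel
    dyadic interview recordings (one lapel microphone per speaker) and relates
    them to clinician-rated negative symptoms of schizophrenia on the 16-item
    Negative Symptom Assessment (NSA-16). Provides frame-level voice activity
    detection, turn-taking event detection (turns, interruptions, failed
    interruptions, interjections, response times), prosodic descriptors (volume,
    fundamental frequency, formants, MFCCs) with session-level functionals
    including histogram entropy, Pearson correlation of cues with ordinal
    ratings, Kruskal-Wallis group comparisons, correlation-based feature subset
    selection (CFS), and leave-one-subject-out cross-validated classification of
    observable vs non-observable symptom items and patient vs control status.
    Includes a seeded synthetic dyadic-conversation generator (activity
    schedules, rendered audio, coupled ratings) so the full pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    randomForest,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
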