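frames <- function(n, on = integer(0)) {
  x <- logical(n)
  x[on] <- TRUE
  x
}

test_that("utterance segmentation finds maximal active runs", {
  act <- dyad_activity(frames(1000, 1:300), frames(1000))
  utt <- segment_utterances(act)
  expect_identical(nrow(utt), 1L)
  expect_equal(utt$start, 0)
  expect_equal(utt$end, 3.0)

  expect_identical(nrow(segment_utterances(
    dyad_activity(frames(100), frames(100)))), 0L)

  # one inactive frame splits a run
  act2 <- dyad_activity(frames(100, c(1:40, 42:80)), frames(100))
  expect_identical(nrow(segment_utterances(act2)), 2L)
})

test_that("event classification follows the rule cascade", {
  # successful interruption: B starts during A and outlasts it
  act <- dyad_activity(frames(1000, 1:500), frames(1000, 401:800))
  ev <- classify_events(segment_utterances(act))
  expect_identical(nrow(ev$interruptions), 1L)
  expect_identical(ev$interruptions$speaker, "B")
  expect_identical(nrow(ev$turns), 2L)
  expect_identical(sum(ev$turns$type == "natural"), 1L)

  # short utterance inside the other's turn: speaking interjection, not a turn
  act <- dyad_activity(frames(1000, 1:500), frames(1000, 201:260))
  ev <- classify_events(segment_utterances(act), interjection_max = 1.0)
  expect_identical(nrow(ev$speaking_interjections), 1L)
  expect_identical(sum(ev$turns$speaker == "B"), 0L)

  # same shape but 1.5 s long: failed interruption
  act <- dyad_activity(frames(1000, 1:500), frames(1000, 201:350))
  ev <- classify_events(segment_utterances(act), interjection_max = 1.0)
  expect_identical(nrow(ev$failed_interruptions), 1L)
  expect_identical(nrow(ev$speaking_interjections), 0L)

  # short gap-filling utterance between two turns of the other speaker:
  # natural interjection
  act <- dyad_activity(frames(1000, c(1:200, 400:600)),
                       frames(1000, 260:310))
  ev <- classify_events(segment_utterances(act))
  expect_identical(nrow(ev$natural_interjections), 1L)
  expect_identical(ev$natural_interjections$speaker, "B")

  expect_error(classify_events(segment_utterances(act), interjection_max = 0),
               "positive")
})

test_that("feature arithmetic matches hand-computed fixtures", {
  act <- dyad_activity(frames(1000, 1:300), frames(1000, 351:700))
  ev <- classify_events(segment_utterances(act))
  fa <- conversational_features(ev, act, "A")
  fb <- conversational_features(ev, act, "B")
  expect_equal(unname(fa["speaking_pct"]), 30)
  expect_equal(unname(fb["speaking_pct"]), 35)
  expect_equal(unname(fa["mutual_silence_pct"]), 35)
  expect_equal(unname(fa["overlap_pct"]), 0)
  expect_equal(unname(fb["response_time"]), 0.5)
  expect_equal(unname(fa["turn_duration"]), 3.0)
  expect_equal(unname(fa["natural_turns"]), 6)

  # all-silent recording: zero rates, missing means
  act0 <- dyad_activity(frames(500), frames(500))
  f0 <- conversational_features(classify_events(segment_utterances(act0)),
                                act0, "A")
  expect_equal(unname(f0["speaking_pct"]), 0)
  expect_equal(unname(f0["mutual_silence_pct"]), 100)
  expect_equal(unname(f0["natural_turns"]), 0)
  expect_true(is.na(f0["turn_duration"]))
  expect_true(is.na(f0["response_time"]))

  # interruption exchange is excluded from response time
  act2 <- dyad_activity(frames(1000, 1:500), frames(1000, 401:800))
  ev2 <- classify_events(segment_utterances(act2))
  fb2 <- conversational_features(ev2, act2, "B")
  expect_equal(unname(fb2["overlap_pct"]), 10)
  expect_equal(unname(fb2["interruptions"]), 6)
  expect_true(is.na(fb2["response_time"]))
})

test_that("features equal the brute-force oracle on random streams", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(20:300, 1)
    a <- random_activity_stream(n)
    b <- random_activity_stream(n)
    for (sp in c("A", "B")) {
      got <- package_features(a, b, sp)
      want <- oracle_features(a, b, 0.010, sp)
      expect_identical(names(got), names(want))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("speaker swap symmetry and silence-append monotonicity hold", {
  set.seed(303)
  for (rep in 1:30) {
    n <- sample(50:300, 1)
    a <- random_activity_stream(n)
    b <- random_activity_stream(n)
    fa <- package_features(a, b, "A")
    fb_swapped <- package_features(b, a, "B")
    expect_equal(fa, fb_swapped, tolerance = 1e-12)

    dyad_cols <- c("overlap_pct", "mutual_silence_pct",
                   "difference_speaking_pct", "difference_turns")
    fb <- package_features(a, b, "B")
    fswap <- package_features(b, a, "A")
    expect_equal(fb[dyad_cols], fswap[dyad_cols], tolerance = 1e-12)
  }

  # appending mutual silence: silence share rises, speaking shares fall,
  # event counts (per-minute rates times duration) are preserved
  a <- random_activity_stream(200); b <- random_activity_stream(200)
  if (!any(a)) a[50:80] <- TRUE
  f1 <- package_features(a, b, "A")
  a2 <- c(a, logical(100)); b2 <- c(b, logical(100))
  f2 <- package_features(a2, b2, "A")
  expect_gt(f2["mutual_silence_pct"], f1["mutual_silence_pct"])
  expect_lt(f2["speaking_pct"], f1["speaking_pct"])
  rate_cols <- c("natural_turns", "interruptions", "failed_interruptions",
                 "interjections", "speaking_interjections")
  expect_equal(f2[rate_cols] * 300, f1[rate_cols] * 200, tolerance = 1e-9)
})

test_that("conservation identity holds on every stream", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(10:500, 1)
    a <- random_activity_stream(n)
    b <- random_activity_stream(n)
    fa <- package_features(a, b, "A")
    fb <- package_features(a, b, "B")
    total <- fa["speaking_pct"] + fb["speaking_pct"] -
      fa["overlap_pct"] + fa["mutual_silence_pct"]
    expect_equal(unname(total), 100, tolerance = 1e-9)
  }
})

test_that("speaking rate tracks the syllabic modulation frequency", {
  sr <- 16000
  t <- seq_len(10 * sr) / sr
  am <- 0.5 * (0.5 * (1 + sin(2 * pi * 4 * t - pi / 2))) *
    sin(2 * pi * 200 * t)
  rec <- audio_recording(cbind(am, 0 * am), sr)
  act <- build_dyad_activity(rec)
  expect_equal(speaking_rate(rec, act, "A"), 4.0, tolerance = 0.5)

  # unmodulated tone has no internal envelope dips: at most one nucleus
  tone <- make_tone(200, dur = 10, sr = sr)
  rec2 <- audio_recording(cbind(tone, 0 * tone), sr)
  act2 <- build_dyad_activity(rec2)
  expect_lte(speaking_rate(rec2, act2, "A"), 0.11)

  # silent speaker -> missing
  expect_true(is.na(speaking_rate(rec2, act2, "B")))
})
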