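test_that("dyad simulation is deterministic and respects its parameters", {
  prof <- subject_profile(0.5)
  a1 <- simulate_dyad(prof, seed = 9)
  a2 <- simulate_dyad(prof, seed = 9)
  expect_identical(a1$active_a, a2$active_a)
  expect_identical(a1$active_b, a2$active_b)

  # no interruptions/interjections -> strictly alternating, zero overlap
  prof0 <- subject_profile(0.5, p_interruption = 0, p_interjection = 0)
  int0 <- interviewer_profile()
  int0$p_interruption <- 0; int0$p_interjection <- 0
  act <- simulate_dyad(prof0, int0, duration = 300, seed = 10)
  expect_equal(sum(act$active_a & act$active_b), 0)
  ev <- classify_events(segment_utterances(act))
  expect_identical(nrow(ev$interruptions), 0L)
  expect_identical(nrow(ev$failed_interruptions), 0L)

  expect_error(simulate_dyad(prof, duration = 30), "60")
  expect_error(subject_profile(1.5), "severity")
  expect_error(subject_profile(0.5, rt_scale = -1), "positive")
})

test_that("severity increases extracted response times", {
  int <- interviewer_profile()
  rt_of <- function(sev, seed) {
    act <- simulate_dyad(subject_profile(sev), int, duration = 300,
                         seed = seed)
    ev <- classify_events(segment_utterances(act))
    conversational_features(ev, act, "A")[["response_time"]]
  }
  rt_low <- vapply(1:25, function(s) rt_of(0, 2000 + s), numeric(1))
  rt_high <- vapply(1:25, function(s) rt_of(1, 3000 + s), numeric(1))
  expect_gt(mean(rt_high, na.rm = TRUE), mean(rt_low, na.rm = TRUE))
  expect_gte(mean(rt_high > mean(rt_low, na.rm = TRUE), na.rm = TRUE), 0.9)
})

test_that("ratings track severity and always satisfy the sum identities", {
  r0 <- ratings_from_severity(0, noise_sd = 0, seed = 1)
  expect_true(all(unlist(r0[paste0("nsa_", 1:16)]) == 1))
  expect_identical(r0$nsa_total, 16)

  r1 <- ratings_from_severity(1, noise_sd = 0, seed = 1)
  expect_true(all(unlist(r1[paste0("nsa_", 1:16)]) == 6))
  expect_identical(r1$nsa_total, 96)
  expect_identical(r1$communication, 24)

  set.seed(77)
  sev <- stats::runif(200)
  recs <- do.call(rbind, lapply(seq_along(sev), function(i) {
    ratings_from_severity(sev[i], noise_sd = 0.5, seed = 5000 + i)
  }))
  expect_silent(validate_ratings(recs))
  expect_gt(stats::cor(recs$nsa_1, sev), 0.8)
  expect_gt(stats::cor(recs$nsa_total, sev), 0.8)
})

test_that("rendered audio reflects the profile's voice parameters", {
  act <- dyad_activity(rep(TRUE, 1000), rep(FALSE, 1000))
  # constant F0 (integer period at 16 kHz) -> zero F0 entropy
  prof_const <- subject_profile(0.5, f0_base = 200, f0_sd = 0)
  aud <- render_audio(act, prof_const, prof_const, seed = 3)
  d <- extract_descriptors(aud, 1, mask = act$active_a)
  expect_equal(summarize_prosody(d)[["ent_freq"]], 0)

  # all-false activity renders silence
  act0 <- dyad_activity(rep(FALSE, 500), rep(FALSE, 500))
  aud0 <- render_audio(act0, prof_const, prof_const, seed = 3)
  expect_true(all(aud0$samples == 0))

  # wider F0 draw dispersion -> higher extracted F0 entropy (seeded pairs)
  wins <- 0L
  for (s in 1:20) {
    e <- vapply(c(5, 25), function(sdv) {
      p <- subject_profile(0.5, f0_base = 160, f0_sd = sdv)
      au <- render_audio(act, p, p, seed = 400 + s)
      summarize_prosody(
        extract_descriptors(au, 1, mask = act$active_a))[["ent_freq"]]
    }, numeric(1))
    wins <- wins + (e[1] < e[2])
  }
  expect_gte(wins, 19L)
})

test_that("cohorts are reproducible with exact group counts", {
  co <- simulate_cohort(4, 3, duration = 120, master_seed = 5)
  expect_length(co$subjects, 7L)
  expect_identical(sum(co$ratings$group == "patient"), 4L)
  expect_identical(sum(co$ratings$group == "control"), 3L)
  expect_silent(validate_ratings(co$ratings))
  sev <- vapply(co$subjects, `[[`, numeric(1), "severity")
  grp <- vapply(co$subjects, `[[`, character(1), "group")
  expect_true(all(sev[grp == "control"] <= 0.2))
  expect_true(all(sev[grp == "patient"] >= 0.2))

  co2 <- simulate_cohort(4, 3, duration = 120, master_seed = 5)
  expect_identical(co$ratings, co2$ratings)
  expect_identical(co$subjects[[3]]$activity$active_a,
                   co2$subjects[[3]]$activity$active_a)
  expect_error(simulate_cohort(1, 3), ">= 2")
})

test_that("simulate -> extract -> associate -> classify closes end to end", {
  co <- simulate_cohort(5, 5, duration = 120, master_seed = 8, audio = TRUE)
  feats <- cohort_features(co)
  expect_identical(nrow(feats), 10L)
  expect_true(all(c("response_time", "ent_freq", "speaking_rate")
                  %in% names(feats)))
  res <- suppressWarnings(
    run_analyze(feats, co$ratings, targets = 2,
                classifier = "svm", selection = "correlation", seed = 2))
  expect_s3_class(res$correlations, "cue_correlations")
  expect_s3_class(res$reports$patient_vs_control, "classification_report")
  expect_identical(sum(res$reports$patient_vs_control$confusion), 10L)
})
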