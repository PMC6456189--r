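#' All non-verbal cues for one subject of a dyad
#'
#' Combines the conversational cues for the chosen speaker with, when audio
#' is available, the speaking rate and the prosodic functionals of that
#' speaker's channel (masked to the speaker's own active frames, so the
#' faint cross-talk from the other lapel microphone is ignored).
#'
#' @param activity A \code{\link{dyad_activity}}.
#' @param recording Optional matching 2-channel
#'   \code{\link{audio_recording}}; without it the prosodic columns and
#'   speaking rate are \code{NA}.
#' @param speaker "A" (channel 1) or "B" (channel 2).
#' @param subject_id Identifier stored in the output row.
#' @param config A \code{\link{frame_config}}.
#' @param interjection_max Interjection duration ceiling, seconds.
#' @param n_bins Histogram bins for entropy functionals.
#' @return One-row data frame: \code{subject_id}, conversational cues,
#'   \code{speaking_rate}, prosodic functionals.
#' @export
extract_features <- function(activity, recording = NULL, speaker = "A",
                             subject_id = "s1", config = frame_config(),
                             interjection_max = 1.0, n_bins = 50L) {
  utt <- segment_utterances(activity)
  ev <- classify_events(utt, interjection_max = interjection_max)
  conv <- conversational_features(ev, activity, speaker = speaker)

  rate <- NA_real_
  pros <- stats::setNames(
    rep(NA_real_, 8L + 13L),
    c("vol_mean", "vol_max", "vol_min", "ent_vol", "ent_freq",
      "ent_f1", "ent_f2", "ent_f3", paste0("mfcc_mean_", 1:13)))
  if (!is.null(recording)) {
    active <- if (speaker == "A") activity$active_a else activity$active_b
    if (any(active)) {
      rate <- speaking_rate(recording, activity, speaker = speaker,
                            config = config)
      ch <- if (speaker == "A") 1L else 2L
      desc <- extract_descriptors(recording, channel = ch, config = config,
                                  mask = active)
      pros <- summarize_prosody(desc, n_bins = n_bins)
    }
  }
  cbind(data.frame(subject_id = subject_id),
        as.data.frame(t(conv)),
        data.frame(speaking_rate = rate),
        as.data.frame(t(pros)))
}

#' Feature table for a synthetic cohort
#'
#' @param cohort A \code{\link{simulate_cohort}} result.
#' @param ... Passed to \code{\link{extract_features}}.
#' @return Data frame with one feature row per subject (speaker A = the
#'   subject channel).
#' @export
cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort$subjects, function(s) {
    extract_features(s$activity, recording = s$audio, speaker = "A",
                     subject_id = s$id, ...)
  })
  do.call(rbind, rows)
}

#' Extract features from recorded interview files
#'
#' Reads each 2-channel WAV, runs voice activity detection on both channels,
#' and emits one feature row per file for the subject channel. Unreadable or
#' non-stereo files are recorded as errors and the run continues.
#'
#' @param paths Character vector of WAV paths.
#' @param subject_channel 1 or 2: which channel carries the subject
#'   (explicit, never inferred).
#' @param subject_ids Identifiers, defaulting to file base names.
#' @param config A \code{\link{frame_config}}.
#' @param threshold_db,min_speech,min_pause VAD parameters
#'   (\code{\link{detect_activity}}).
#' @param interjection_max,n_bins Passed to \code{\link{extract_features}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{features.csv} and \code{extract_errors.csv}.
#' @return Data frame of feature rows, with attribute \code{"errors"}
#'   (data frame path/message) for failed files.
#' @export
run_extract <- function(paths, subject_channel = 1L,
                        subject_ids = tools::file_path_sans_ext(basename(paths)),
                        config = frame_config(), threshold_db = -40,
                        min_speech = 0.1, min_pause = 0.2,
                        interjection_max = 1.0, n_bins = 50L,
                        out_dir = NULL) {
  stopifnot(subject_channel %in% c(1L, 2L))
  speaker <- if (subject_channel == 1L) "A" else "B"
  rows <- list(); errors <- list()
  for (i in seq_along(paths)) {
    row <- tryCatch({
      rec <- read_wav(paths[i])
      act <- build_dyad_activity(rec, config, threshold_db = threshold_db,
                                 min_speech = min_speech,
                                 min_pause = min_pause)
      extract_features(act, recording = rec, speaker = speaker,
                       subject_id = subject_ids[i], config = config,
                       interjection_max = interjection_max, n_bins = n_bins)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- data.frame(
        path = paths[i], message = conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0))
  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(path = character(0), message = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(out) > 0L) {
      utils::write.csv(out, file.path(out_dir, "features.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(err, file.path(out_dir, "extract_errors.csv"),
                     row.names = FALSE)
  }
  attr(out, "errors") <- err
  out
}

#' Run the association and classification analyses
#'
#' Produces (i) the feature x NSA-item Pearson correlation table, (ii)
#' Kruskal-Wallis patient-vs-control tests per feature, and (iii)
#' leave-one-subject-out classification reports for each requested NSA item
#' (observable vs non-observable, patients only by default, mirroring the
#' clinical design) plus patient-vs-control.
#'
#' @param features Feature table (\code{subject_id} + numeric cues).
#' @param ratings Ratings table (\code{subject_id}, \code{group}, NSA
#'   columns).
#' @param targets Integer vector of NSA items to classify (default
#'   \code{integer(0)}: correlations only).
#' @param classify_group Also classify patient vs control (default TRUE).
#' @param classifier,selection,k Passed to \code{\link{loocv}}.
#' @param correlation_cohort "patients" (default) or "all": rows used for
#'   the correlation table.
#' @param seed Base seed for stochastic classifiers.
#' @param out_dir Optional output directory (writes correlations.csv,
#'   group_tests.json, reports.json).
#' @return List with \code{correlations}, \code{group_tests},
#'   \code{reports} (one per target, named \code{nsa_<item>} /
#'   \code{patient_vs_control}).
#' @export
run_analyze <- function(features, ratings, targets = integer(0),
                        classify_group = TRUE,
                        classifier = "svm", selection = "correlation",
                        k = 5L, correlation_cohort = c("patients", "all"),
                        seed = 1L, out_dir = NULL) {
  correlation_cohort <- match.arg(correlation_cohort)
  shared <- intersect(features$subject_id, ratings$subject_id)
  if (length(shared) == 0L) stop("feature and rating tables share no subjects")
  features <- features[features$subject_id %in% shared, , drop = FALSE]
  ratings <- ratings[match(features$subject_id, ratings$subject_id), ,
                     drop = FALSE]

  corr_rows <- if (correlation_cohort == "patients") {
    ratings$group == "patient"
  } else {
    rep(TRUE, nrow(ratings))
  }
  correlations <- correlation_table(features[corr_rows, , drop = FALSE],
                                    ratings[corr_rows, , drop = FALSE])
  group_tests <- kruskal_wallis_table(features, ratings$group)

  reports <- list()
  for (t in targets) {
    col <- paste0("nsa_", t)
    use <- corr_rows  # classification of symptom items runs on patients
    y <- binarize_nsa(ratings[[col]][use])
    if (length(unique(y)) < 2L) {
      warning("target ", col, " skipped: all subjects fall in one class")
      next
    }
    reports[[col]] <- loocv(features[use, , drop = FALSE], y,
                            classifier = classifier, selection = selection,
                            k = k, positive = "non_observable", seed = seed)
  }
  if (classify_group) {
    y <- factor(ratings$group, levels = c("control", "patient"))
    reports$patient_vs_control <- loocv(features, y, classifier = classifier,
                                        selection = selection, k = k,
                                        positive = "patient", seed = seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    corr_df <- data.frame(feature = rownames(correlations$r),
                          correlations$r, check.names = FALSE)
    utils::write.csv(corr_df, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(group_tests$tests,
                         file.path(out_dir, "group_tests.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    rep_json <- lapply(reports, function(r) {
      list(classifier = r$classifier, selection = r$selection,
           confusion = unclass(r$confusion), accuracy = r$accuracy,
           auc = r$auc, precision = as.list(r$precision),
           recall = as.list(r$recall), f_score = as.list(r$f_score),
           best_features = r$best_features)
    })
    jsonlite::write_json(rep_json, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(correlations = correlations, group_tests = group_tests,
       reports = reports)
}
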